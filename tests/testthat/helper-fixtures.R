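# Shared fixture builders; everything is generated in code at test time.

# minimal hand-written PDB text: one CA atom of LYS 429
pdb_one_atom <- function() {
  paste(
    "ATOM      1  CA  LYS A 429       1.000   2.000   3.000  1.00 20.00           C",
    "END", sep = "\n")
}

# k models of the same n-atom CA chain, coordinates shifted per model
pdb_models <- function(n = 5, k = 3, shift = 1.0) {
  lines <- character()
  for (m in seq_len(k)) {
    lines <- c(lines, sprintf("MODEL     %4d", m))
    for (i in seq_len(n)) {
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        i, i, i * 3.8 + (m - 1) * shift, 0, 0))
    }
    lines <- c(lines, "ENDMDL")
  }
  paste(c(lines, "END"), collapse = "\n")
}

# small two-domain bundle: 4 helices x 20 residues, two 40-residue halves
two_domain_bundle <- function() {
  gen_helix_bundle(n_helices = 4, residues_per_helix = 20, spacing = 14,
                   seed = 1)
}

two_domain_map <- function() load_domain_map("NBD1: 1-40\nNBD2: 41-80")

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b),
           a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

rigidly_move <- function(coords, rot, shift) {
  sweep(coords %*% rot, 2, shift, `+`)
}

# independently coded Welch test (the reference oracle)
welch_oracle <- function(a, b) {
  v1 <- var(a) / length(a); v2 <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(a) - 1) + v2^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# brute-force all-pairs contact oracle
contact_oracle <- function(protein, ligand, cutoff) {
  hits <- integer()
  for (r in unique(protein$residue_number)) {
    pr <- protein[protein$residue_number == r, ]
    dmin <- Inf
    for (i in seq_len(nrow(pr))) {
      for (j in seq_len(nrow(ligand))) {
        d <- sqrt((pr$x[i] - ligand$x[j])^2 + (pr$y[i] - ligand$y[j])^2 +
                    (pr$z[i] - ligand$z[j])^2)
        dmin <- min(dmin, d)
      }
    }
    if (dmin <= cutoff) hits <- c(hits, r)
  }
  sort(hits)
}
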