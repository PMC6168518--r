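#' Dynamical cross-correlation matrix of Ca displacements
#'
#' Frames of the window are superposed onto the window-mean structure (same
#' two-pass convention as [rmsf()]); with `dr_i` the displacement of atom
#' `i` from its window-mean position,
#' `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2> <|dr_j|^2>)`.
#' Positive entries mark atoms moving along the same direction, negative
#' entries opposed motion. The raw estimator is reported — no smoothing or
#' shrinkage.
#'
#' Atoms with zero total fluctuation in the window cannot be normalised;
#' their off-diagonal entries are set to 0 with a warning.
#'
#' Because superposition removes each frame's best-fit rigid motion,
#' collective modes lying in the rigid-body space (a common translation of
#' the whole selection) are invisible to the default estimator; set
#' `superpose = FALSE` to correlate raw displacements when frames are
#' already aligned or when such modes are the object of study.
#'
#' @inheritParams rmsf
#' @param superpose Superpose frames onto the window mean first (two-pass,
#'   as in [rmsf()]). Default `TRUE`.
#' @return A `cadyn_dccm`: `N x N` symmetric matrix with unit diagonal,
#'   entries in `[-1, 1]`; the selection roster and window are carried in
#'   attributes `"roster"` and `"window"`.
#' @export
compute_dccm <- function(traj, atoms = "CA", chain = NULL, residues = NULL,
                         window = NULL, fraction = 1, superpose = TRUE) {
  idx <- roster_index(traj, atoms = atoms, chain = chain,
                      residues = residues)
  win <- window_frames(n_frames(traj), window, fraction)
  if (length(win) < 2) abort("DCCM needs at least 2 frames in the window")
  sub <- traj$coords[win, idx, , drop = FALSE]
  if (superpose) {
    aligned <- align_frames(sub, ref = matrix(sub[1, , ], ncol = 3))
    mean1 <- apply(aligned, c(2, 3), mean)
    aligned <- align_frames(sub, ref = mean1)
  } else {
    aligned <- sub
  }
  mean2 <- apply(aligned, c(2, 3), mean)
  dev <- sweep(aligned, c(2, 3), mean2)
  f <- length(win)
  ## <dr_i . dr_j> accumulated per axis: dx dx^T + dy dy^T + dz dz^T
  cross <- matrix(0, length(idx), length(idx))
  for (ax in 1:3) {
    d <- matrix(dev[, , ax], nrow = f)
    cross <- cross + crossprod(d)
  }
  cross <- cross / f
  msf <- diag(cross)
  zero <- msf <= 0
  if (any(zero)) {
    warn(sprintf("%d atom(s) with zero fluctuation; correlations set to 0",
                 sum(zero)))
    msf[zero] <- 1
  }
  cmat <- cross / sqrt(outer(msf, msf))
  if (any(zero)) {
    cmat[zero, ] <- 0
    cmat[, zero] <- 0
  }
  cmat <- (cmat + t(cmat)) / 2
  cmat[cmat > 1] <- 1
  cmat[cmat < -1] <- -1
  diag(cmat) <- 1
  new_dccm(cmat, roster = traj$roster[idx, ], window = range(win))
}

new_dccm <- function(cmat, roster, window = c(NA, NA)) {
  structure(cmat, roster = as_tibble(roster), window = window,
            class = c("cadyn_dccm", "matrix", "array"))
}

#' @export
print.cadyn_dccm <- function(x, ...) {
  cat(sprintf("<cadyn_dccm> %d x %d, mean off-diagonal %.3f\n",
              nrow(x), ncol(x),
              mean(x[upper.tri(x)])))
  invisible(x)
}

#' Mean cross-correlation between two domain-map regions
#'
#' Averages the correlation matrix over the block of atom pairs
#' `(i in region_a, j in region_b)`, excluding the self pairs that appear
#' when the regions overlap — the block statistic used to read domain-level
#' coupling (e.g. the strong anti-correlation between the two
#' nucleotide-binding domains of an ABC transporter).
#'
#' @param cmat A `cadyn_dccm`.
#' @param map A `cadyn_domain_map`.
#' @param region_a,region_b Region names.
#' @return Tibble with `region_a`, `region_b`, `n_pairs`, `mean_corr`.
#' @export
block_summary <- function(cmat, map, region_a, region_b) {
  roster <- attr(cmat, "roster")
  ia <- which(roster$residue_number %in% region_residues(map, region_a))
  ib <- which(roster$residue_number %in% region_residues(map, region_b))
  if (length(ia) == 0) abort(paste0("region '", region_a, "' selects no atoms"))
  if (length(ib) == 0) abort(paste0("region '", region_b, "' selects no atoms"))
  block <- cmat[ia, ib, drop = FALSE]
  self <- outer(ia, ib, `==`)
  vals <- block[!self]
  tibble(region_a = region_a, region_b = region_b,
         n_pairs = length(vals), mean_corr = mean(vals))
}
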