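#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimising the (optionally
#' weighted) RMSD between two matched point sets, via singular value
#' decomposition of the cross-covariance with the usual determinant
#' correction so the rotation is proper (det = +1).
#'
#' The transform maps mobile points as `p %*% rotation + translation` (row
#' vectors).
#'
#' @param mobile,reference `N x 3` matrices of matched points (`N >= 3`,
#'   not all collinear), or `cadyn_structure`s (their shared-key Ca atoms
#'   are matched automatically).
#' @param weights Optional non-negative per-point weights.
#' @return A `cadyn_superposition`: list with `rotation` (3x3),
#'   `translation` (length 3), `rmsd` (Angstrom) and `n_atoms`.
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  if (inherits(mobile, "cadyn_structure") ||
      inherits(reference, "cadyn_structure")) {
    mats <- shared_ca(mobile, reference)
    mobile <- mats$mobile; reference <- mats$reference
  }
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference)) {
    abort("mobile and reference must have the same number of points")
  }
  n <- nrow(mobile)
  if (n < 3) abort("superposition needs at least 3 points")
  w <- weights %||% rep(1, n)
  if (length(w) != n || any(w < 0) || sum(w) == 0) {
    abort("weights must be non-negative with positive sum")
  }
  w <- w / sum(w)
  cm <- colSums(mobile * w); cr <- colSums(reference * w)
  p <- sweep(mobile, 2, cm); q <- sweep(reference, 2, cr)
  if (qr(p)$rank < 2) abort("degenerate (collinear) point set")
  s <- svd(crossprod(p * w, q))
  d <- sign(det(s$u) * det(s$v))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- p %*% rot
  rmsd <- sqrt(sum(w * rowSums((fitted - q)^2)))
  structure(list(rotation = rot, translation = cr - drop(cm %*% rot),
                 rmsd = rmsd, n_atoms = n),
            class = "cadyn_superposition")
}

## match the Ca atoms two structures share, by (chain-agnostic) residue
## number when each is single-chain, so "mol A vs mol B" pairs residues
shared_ca <- function(a, b) {
  ca <- function(s) {
    s <- s[!s$het & s$atom_name == "CA", ]
    s[!duplicated(s$residue_number), ]
  }
  sa <- ca(a); sb <- ca(b)
  common <- intersect(sa$residue_number, sb$residue_number)
  if (length(common) < 3) abort("fewer than 3 shared Ca residues")
  sa <- sa[match(common, sa$residue_number), ]
  sb <- sb[match(common, sb$residue_number), ]
  list(mobile = cbind(sa$x, sa$y, sa$z), reference = cbind(sb$x, sb$y, sb$z))
}

#' @export
print.cadyn_superposition <- function(x, ...) {
  cat(sprintf("<cadyn_superposition> %d atoms, rmsd %.4f A\n",
              x$n_atoms, x$rmsd))
  invisible(x)
}

#' Apply a superposition to coordinates
#' @param coords `N x 3` matrix.
#' @param sp A `cadyn_superposition`.
#' @export
apply_superposition <- function(coords, sp) {
  sweep(as.matrix(coords) %*% sp$rotation, 2, sp$translation, `+`)
}

#' Per-frame RMSD against a reference structure
#'
#' Each frame is Kabsch-superposed onto the reference over the selection
#' before the deviation is measured.
#'
#' @param traj A `cadyn_trajectory`.
#' @param reference A `cadyn_structure`, or an `N x 3` matrix matching the
#'   selection.
#' @inheritParams roster_index
#' @return Tibble with `frame`, `time_ps`, `rmsd` (Angstrom), one row per
#'   frame.
#' @export
rmsd_series <- function(traj, reference, atoms = "CA", chain = NULL,
                        residues = NULL) {
  idx <- roster_index(traj, atoms = atoms, chain = chain,
                      residues = residues)
  ref <- resolve_reference(reference, traj$roster[idx, ])
  rmsds <- vapply(seq_len(n_frames(traj)), function(i) {
    kabsch_superpose(frame_coords(traj, i)[idx, , drop = FALSE], ref)$rmsd
  }, numeric(1))
  tibble(frame = seq_len(n_frames(traj)),
         time_ps = (seq_len(n_frames(traj)) - 1) * traj$frame_interval_ps,
         rmsd = rmsds)
}

resolve_reference <- function(reference, roster) {
  if (inherits(reference, "cadyn_structure")) {
    key <- atom_key(roster)
    rkey <- atom_key(reference)
    pos <- match(key, rkey)
    if (anyNA(pos)) {
      abort(paste0("selection atom ", key[which(is.na(pos))[1]],
                   " absent from reference"))
    }
    cbind(reference$x[pos], reference$y[pos], reference$z[pos])
  } else {
    m <- as.matrix(reference)
    if (nrow(m) != nrow(roster)) {
      abort("reference matrix does not match the selection size")
    }
    m
  }
}

#' Frame windows
#'
#' `window_frames()` resolves a window specification to frame indices. The
#' default is the final 20% of frames, the convention used for equilibrium
#' ensemble averages (for a 10 000-frame, 10 ps/frame run this is the
#' 2000-frame last-20 ns window).
#'
#' @param n_total Total number of frames.
#' @param window `NULL` (use `fraction`), an integer vector of frame
#'   indices, or a length-2 `c(first, last)` range.
#' @param fraction Final fraction of frames used when `window` is `NULL`.
#' @return Integer frame indices.
#' @export
window_frames <- function(n_total, window = NULL, fraction = 0.2) {
  if (is.null(window)) {
    if (fraction <= 0 || fraction > 1) abort("fraction must be in (0, 1]")
    idx <- seq.int(n_total - floor(fraction * n_total) + 1L, n_total)
  } else if (length(window) == 2 && window[2] >= window[1]) {
    idx <- seq.int(window[1], window[2])
  } else {
    idx <- as.integer(window)
  }
  if (any(idx < 1 | idx > n_total)) abort("window outside the trajectory")
  idx
}

#' Root-mean-square fluctuation profile
#'
#' Frames of the window are superposed onto the window-average structure in
#' two passes (align to the first window frame, average, re-align to the
#' mean), then `RMSF_i = sqrt(mean_f |r_i(f) - <r_i>|^2)` and the
#' crystallographic displacement parameter `B_i = 8 pi^2 RMSF_i^2`.
#'
#' @inheritParams rmsd_series
#' @inheritParams window_frames
#' @return A `cadyn_fluct` tibble: `chain_id`, `residue_number`,
#'   `atom_name`, `rmsf` (Angstrom), `bfactor` (Angstrom^2); the window is
#'   kept in the `"window"` attribute.
#' @export
rmsf <- function(traj, atoms = "CA", chain = NULL, residues = NULL,
                 window = NULL, fraction = 0.2) {
  idx <- roster_index(traj, atoms = atoms, chain = chain,
                      residues = residues)
  win <- window_frames(n_frames(traj), window, fraction)
  if (length(win) < 2) abort("RMSF needs a window of at least 2 frames")
  sub <- traj$coords[win, idx, , drop = FALSE]
  aligned <- align_frames(sub, ref = matrix(sub[1, , ], ncol = 3))
  mean1 <- apply(aligned, c(2, 3), mean)
  aligned <- align_frames(sub, ref = mean1)
  mean2 <- apply(aligned, c(2, 3), mean)
  dev2 <- sweep(aligned, c(2, 3), mean2)^2
  msf <- unname(apply(dev2, 2, sum)) / length(win)
  out <- tibble(chain_id = traj$roster$chain_id[idx],
                residue_number = traj$roster$residue_number[idx],
                atom_name = traj$roster$atom_name[idx],
                rmsf = sqrt(msf),
                bfactor = bfactor_from_rmsf(sqrt(msf)))
  class(out) <- c("cadyn_fluct", class(tibble()))
  attr(out, "window") <- range(win)
  out
}

## superpose every frame of an F x N x 3 slab onto ref (N x 3), in place
align_frames <- function(slab, ref) {
  for (i in seq_len(dim(slab)[1])) {
    m <- matrix(slab[i, , ], ncol = 3)
    slab[i, , ] <- apply_superposition(m, kabsch_superpose(m, ref))
  }
  slab
}

#' Crystallographic B-factor from RMSF
#'
#' `B = 8 pi^2 RMSF^2`, the conversion used when refining atomic
#' displacement parameters.
#'
#' @param rmsf Non-negative fluctuation(s), Angstrom.
#' @return B-factor(s), Angstrom squared.
#' @export
bfactor_from_rmsf <- function(rmsf) {
  if (any(rmsf < 0)) abort("rmsf must be non-negative")
  8 * pi^2 * rmsf^2
}

#' Interior angle at a vertex
#'
#' @param a,b,c Length-3 points; `b` is the vertex.
#' @return Angle in degrees, in \[0, 180\].
#' @export
angle_points <- function(a, b, c) {
  u <- as.numeric(a) - as.numeric(b)
  v <- as.numeric(c) - as.numeric(b)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) abort("zero-length arm: vertex coincides with an end point")
  acos(pmin(1, pmax(-1, sum(u * v) / (nu * nv)))) * 180 / pi
}

#' Centroid (centre of mass) of a point set
#'
#' Unweighted by default — for Ca-only selections the centroid is the
#' conventional stand-in for the centre of mass; pass `weights` (e.g.
#' residue masses) for a mass-weighted centre.
#'
#' @param coords `N x 3` matrix.
#' @param weights Optional non-negative weights.
#' @return Length-3 numeric vector.
#' @export
com <- function(coords, weights = NULL) {
  coords <- as.matrix(coords)
  if (nrow(coords) == 0) abort("empty selection has no centre of mass")
  w <- weights %||% rep(1, nrow(coords))
  colSums(coords * (w / sum(w)))
}

#' Distance between two centroids
#' @param a,b `N x 3` matrices.
#' @param weights_a,weights_b Optional weights for each set.
#' @export
com_distance <- function(a, b, weights_a = NULL, weights_b = NULL) {
  sqrt(sum((com(a, weights_a) - com(b, weights_b))^2))
}

#' Per-frame centroid distance between two regions
#'
#' The standard monitor for nucleotide-binding-domain separation: the
#' distance between the Ca centroids of two domain-map regions, per frame.
#'
#' @inheritParams rmsd_series
#' @param map A `cadyn_domain_map`.
#' @param region_a,region_b Region names (default the two NBDs).
#' @return Tibble with `frame`, `time_ps`, `distance` (Angstrom).
#' @export
com_distance_series <- function(traj, map = pgp_domain_map(),
                                region_a = "NBD1", region_b = "NBD2",
                                chain = NULL) {
  ia <- roster_index(traj, atoms = "CA", chain = chain,
                     residues = region_residues(map, region_a, chain))
  ib <- roster_index(traj, atoms = "CA", chain = chain,
                     residues = region_residues(map, region_b, chain))
  d <- vapply(seq_len(n_frames(traj)), function(i) {
    m <- frame_coords(traj, i)
    com_distance(m[ia, , drop = FALSE], m[ib, , drop = FALSE])
  }, numeric(1))
  tibble(frame = seq_len(n_frames(traj)),
         time_ps = (seq_len(n_frames(traj)) - 1) * traj$frame_interval_ps,
         distance = d)
}
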