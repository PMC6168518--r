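#' Anisotropic network model (ANM) of a Ca structure
#'
#' Builds the elastic-network Hessian of an anisotropic network model:
#' every Ca pair within the cutoff radius is joined by a Hookean spring,
#' and the 3x3 off-diagonal super-element for a connected pair `(i, j)` is
#' `-gamma / |d|^2 * d d^T` with `d = r_i - r_j`; diagonal super-elements
#' make every super-row sum to zero, so rigid-body translations (and, for a
#' connected network, rotations) span the six-dimensional null space. The
#' defaults — cutoff 15 Angstrom, gamma 1 — are the conventional ANM
#' parameters. The spring direction form `-gamma/|d|^2 d d^T` equals the
#' unit-direction outer product `gamma d^ d^T` up to the units of gamma.
#'
#' Eigenpairs are computed lazily by [anm_modes()]; a model of `N` nodes
#' always has `3N` modes, of which `3N - 6` are non-zero when the network
#' is connected. A network in which some node has no neighbour within the
#' cutoff is flagged disconnected with a warning (it has more than six zero
#' modes).
#'
#' @param x A `cadyn_structure` (its Ca atoms are the nodes) or an `N x 3`
#'   coordinate matrix.
#' @param cutoff Spring cutoff radius, Angstrom (> 0).
#' @param gamma Uniform spring constant (arbitrary units).
#' @return A `cadyn_anm` list: `coords`, `cutoff`, `gamma`, `hessian`
#'   (`3N x 3N`), `n_nodes`, `connected`, plus `eigenvalues` /
#'   `eigenvectors` once [anm_modes()] has run.
#' @export
build_anm <- function(x, cutoff = 15, gamma = 1) {
  coords <- if (inherits(x, "cadyn_structure")) coords_matrix(x, "CA")
            else as.matrix(x)
  n <- nrow(coords)
  if (n < 2) abort("an ANM needs at least 2 nodes")
  if (cutoff <= 0) abort("cutoff must be > 0")
  d2 <- as.matrix(stats::dist(coords))^2
  adj <- d2 <= cutoff^2 & upper.tri(d2)
  pairs <- which(adj, arr.ind = TRUE)
  hess <- matrix(0, 3 * n, 3 * n)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    d <- coords[i, ] - coords[j, ]
    blk <- -(gamma / sum(d^2)) * tcrossprod(d)
    ri <- (3 * i - 2):(3 * i); rj <- (3 * j - 2):(3 * j)
    hess[ri, rj] <- blk
    hess[rj, ri] <- blk
    hess[ri, ri] <- hess[ri, ri] - blk
    hess[rj, rj] <- hess[rj, rj] - blk
  }
  connected <- network_connected(n, pairs)
  if (!connected) {
    warn("elastic network is disconnected: more than 6 zero modes")
  }
  structure(list(coords = coords, cutoff = cutoff, gamma = gamma,
                 hessian = hess, n_nodes = n, connected = connected,
                 eigenvalues = NULL, eigenvectors = NULL),
            class = "cadyn_anm")
}

## union-find over the spring graph
network_connected <- function(n, pairs) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) parent[a] <- b
  }
  length(unique(vapply(seq_len(n), find, integer(1)))) == 1
}

#' @export
print.cadyn_anm <- function(x, ...) {
  cat(sprintf("<cadyn_anm> %d nodes, %d modes, cutoff %.4g A, gamma %.4g%s\n",
              x$n_nodes, 3 * x$n_nodes, x$cutoff, x$gamma,
              if (x$connected) "" else " [disconnected]"))
  invisible(x)
}

#' Eigen-decompose an ANM Hessian
#'
#' Dense symmetric eigendecomposition, eigenvalues ascending. Zero modes
#' are those below `1e-8` times the largest eigenvalue. Idempotent: returns
#' the model with `eigenvalues` / `eigenvectors` filled.
#'
#' @param model A `cadyn_anm`.
#' @export
anm_modes <- function(model) {
  if (!is.null(model$eigenvalues)) return(model)
  e <- eigen(model$hessian, symmetric = TRUE)
  ord <- order(e$values)
  model$eigenvalues <- e$values[ord]
  model$eigenvectors <- e$vectors[, ord, drop = FALSE]
  model
}

zero_mode_mask <- function(model) {
  ev <- model$eigenvalues
  ev < 1e-8 * max(ev)
}

#' Number of (numerically) zero modes
#' @inheritParams anm_modes
#' @export
n_zero_modes <- function(model) {
  model <- anm_modes(model)
  sum(zero_mode_mask(model))
}

#' Analytic mean-square fluctuations of an ANM
#'
#' Per-node square fluctuation proportional to the trace of the node's
#' 3x3 diagonal block of the Hessian pseudo-inverse (zero modes excluded):
#' `msf_i = sum_(lambda>0) |v_i|^2 / lambda`. Units are arbitrary (they
#' scale as 1/gamma); the profile's shape is the prediction.
#'
#' @inheritParams anm_modes
#' @return Tibble with `node`, `msf`, `rmsf` (= sqrt msf, arbitrary units).
#' @export
analytic_fluctuations <- function(model) {
  if (!model$connected) abort("disconnected network: fluctuations undefined")
  model <- anm_modes(model)
  keep <- !zero_mode_mask(model)
  v <- model$eigenvectors[, keep, drop = FALSE]
  lam <- model$eigenvalues[keep]
  contrib <- sweep(v^2, 2, lam, `/`)
  per_coord <- rowSums(contrib)
  msf <- colSums(matrix(per_coord, nrow = 3))
  tibble(node = seq_len(model$n_nodes), msf = msf, rmsf = sqrt(msf))
}

#' Analytic cross-correlation matrix of an ANM
#'
#' The normalised covariance predicted by the model:
#' `C_ij = tr(G_ij) / sqrt(tr(G_ii) tr(G_jj))` with `G` the Hessian
#' pseudo-inverse in 3x3 blocks. This is the closed-form counterpart of the
#' trajectory estimator [compute_dccm()] and serves as its oracle on
#' model-sampled trajectories.
#'
#' @inheritParams anm_modes
#' @return A `cadyn_dccm` matrix.
#' @export
analytic_dccm <- function(model) {
  if (!model$connected) abort("disconnected network: covariance undefined")
  model <- anm_modes(model)
  keep <- !zero_mode_mask(model)
  v <- model$eigenvectors[, keep, drop = FALSE]
  lam <- model$eigenvalues[keep]
  n <- model$n_nodes
  vx <- v[seq(1, 3 * n, by = 3), , drop = FALSE]
  vy <- v[seq(2, 3 * n, by = 3), , drop = FALSE]
  vz <- v[seq(3, 3 * n, by = 3), , drop = FALSE]
  w <- 1 / lam
  tr <- tcrossprod(sweep(vx, 2, w, `*`), vx) +
    tcrossprod(sweep(vy, 2, w, `*`), vy) +
    tcrossprod(sweep(vz, 2, w, `*`), vz)
  msf <- diag(tr)
  cmat <- tr / sqrt(outer(msf, msf))
  cmat <- (cmat + t(cmat)) / 2
  cmat[cmat > 1] <- 1
  cmat[cmat < -1] <- -1
  diag(cmat) <- 1
  new_dccm(cmat, roster = tibble(chain_id = "A",
                                 residue_number = seq_len(n),
                                 atom_name = "CA"))
}

#' Animate a normal mode as a trajectory
#'
#' Displaces the structure sinusoidally along one non-zero eigenvector and
#' returns a standard trajectory (usable by every analysis function and
#' writable as multi-model PDB for molecular viewers).
#'
#' @inheritParams anm_modes
#' @param mode Index among the non-zero modes, lowest-frequency first
#'   (mode 1 = softest internal motion).
#' @param amplitude Peak displacement scale, Angstrom.
#' @param n_frames Frames per oscillation period.
#' @param frame_interval_ps Declared frame interval, ps.
#' @return A `cadyn_trajectory`.
#' @export
mode_animation <- function(model, mode = 1, amplitude = 2, n_frames = 20,
                           frame_interval_ps = 10) {
  model <- anm_modes(model)
  nz <- which(!zero_mode_mask(model))
  if (mode < 1 || mode > length(nz)) {
    abort(sprintf("mode %d does not address a non-zero mode (1..%d)",
                  mode, length(nz)))
  }
  vec <- matrix(model$eigenvectors[, nz[mode]], ncol = 3, byrow = TRUE)
  phases <- sin(2 * pi * (seq_len(n_frames) - 1) / n_frames)
  coords <- array(0, dim = c(n_frames, model$n_nodes, 3))
  for (i in seq_len(n_frames)) {
    coords[i, , ] <- model$coords + amplitude * phases[i] * vec
  }
  new_trajectory(tibble(chain_id = "A",
                        residue_number = seq_len(model$n_nodes),
                        atom_name = "CA", residue_name = "GLY",
                        element = "C"),
                 coords, frame_interval_ps)
}
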