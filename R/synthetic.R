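#' Synthetic helix-bundle structures
#'
#' Builds an idealised Ca trace of `n_helices` alpha-helices (rise 1.5
#' Angstrom per residue, helical radius 2.3 Angstrom, 100 degrees twist per
#' residue — so consecutive Ca-Ca distances are ~3.8 Angstrom) with helix
#' axes placed on a ring such that adjacent axes are `spacing` apart.
#' Residues are numbered sequentially across helices and a domain map
#' assigning one `TM<k>` region per helix travels with the structure (see
#' [structure_domain_map()]).
#'
#' The construction is fully deterministic; `seed` is accepted for API
#' uniformity with the other generators and recorded in the output label.
#'
#' @param n_helices Number of helices (>= 1).
#' @param residues_per_helix Residues per helix (>= 2).
#' @param spacing Distance between adjacent helix axes, Angstrom.
#' @param seed Integer seed recorded with the structure.
#' @return A `cadyn_structure` with a `"domain_map"` attribute.
#' @export
gen_helix_bundle <- function(n_helices = 12, residues_per_helix = 25,
                             spacing = 20, seed = 1) {
  if (n_helices < 1 || residues_per_helix < 2 || spacing <= 0) {
    abort("n_helices >= 1, residues_per_helix >= 2, spacing > 0 required")
  }
  rise <- 1.5; radius <- 2.3; twist <- 100 * pi / 180
  ring_r <- if (n_helices == 1) 0 else spacing / (2 * sin(pi / n_helices))
  rows <- list()
  map_lines <- character()
  resnum <- 0L
  for (h in seq_len(n_helices)) {
    phi <- 2 * pi * (h - 1) / n_helices
    centre <- c(ring_r * cos(phi), ring_r * sin(phi), 0)
    k <- seq_len(residues_per_helix) - 1
    local <- cbind(radius * cos(k * twist), radius * sin(k * twist),
                   rise * k - rise * (residues_per_helix - 1) / 2)
    nums <- resnum + seq_len(residues_per_helix)
    rows[[h]] <- tibble(
      atom_name = "CA", residue_name = "ALA", chain_id = "A",
      residue_number = as.integer(nums),
      x = local[, 1] + centre[1], y = local[, 2] + centre[2],
      z = local[, 3] + centre[3], element = "C")
    map_lines <- c(map_lines,
                   sprintf("TM%d: %d-%d", h, min(nums), max(nums)))
    resnum <- resnum + residues_per_helix
  }
  s <- new_structure(dplyr::bind_rows(rows),
                     label = sprintf("helix_bundle(seed=%d)", seed))
  attr(s, "domain_map") <- load_domain_map(paste(map_lines, collapse = "\n"))
  s
}

#' Domain map attached to a synthetic structure
#' @param structure A structure from a generator.
#' @export
structure_domain_map <- function(structure) {
  m <- attr(structure, "domain_map")
  if (is.null(m)) abort("structure carries no domain map")
  m
}

#' Isotropic Gaussian fluctuation trajectory
#'
#' Frame `f` = structure + i.i.d. isotropic Gaussian displacement with
#' per-axis standard deviation `sigma_r` for residue `r`, so the true RMSF
#' of residue `r` is `sigma_r * sqrt(3)`. This is the ground-truth
#' generator for the RMSF/B-factor pipeline.
#'
#' @param structure A `cadyn_structure` (all atoms become the roster).
#' @param sigma Per-axis displacement SD, Angstrom; scalar or one value per
#'   atom.
#' @param n_frames Number of frames (>= 2).
#' @param seed Integer RNG seed; the same (structure, sigma, seed) triple
#'   reproduces the trajectory exactly.
#' @param frame_interval_ps Frame cadence, ps (default 10, i.e. 10 000
#'   frames span 100 ns).
#' @return A `cadyn_trajectory`.
#' @export
gen_fluctuation_traj <- function(structure, sigma = 0.5, n_frames = 10000,
                                 seed = 1, frame_interval_ps = 10) {
  if (n_frames < 2) abort("n_frames must be >= 2")
  if (any(sigma < 0)) abort("sigma must be non-negative")
  base <- coords_matrix(structure, atoms = NULL, het = TRUE)
  n <- nrow(base)
  sigma <- rep(sigma, length.out = n)
  set.seed(seed)
  coords <- array(rnorm(n_frames * n * 3, sd = rep(sigma, each = n_frames)),
                  dim = c(n_frames, n, 3))
  coords <- sweep(coords, c(2, 3), base, `+`)
  new_trajectory(structure[, c("chain_id", "residue_number", "atom_name",
                               "residue_name", "element")],
                 coords, frame_interval_ps)
}

#' Block-correlated displacement trajectory
#'
#' Residue displacements follow a one-axis factor model: each block `b`
#' has a scalar factor series `f_b(t)` and every atom of the block is
#' displaced by `a * f_b(t)` along a common unit axis `u` (default: the
#' axis joining the first two block centroids), plus isotropic Gaussian
#' noise. Amplitudes are set so the expected displacement cross-correlation
#' (the [compute_dccm()] statistic) is exactly `rho_within` inside a block
#' and `rho_between` across blocks. Block factors are correlated as
#' `corr(f_b, f_b') = rho_between / rho_within`, which requires
#' `|rho_between| <= rho_within`; a negative `rho_between` needs exactly
#' two blocks.
#'
#' When `rho_between == -rho_within` (the anti-phase design emulating the
#' opposed motion of the two nucleotide-binding domains) the two blocks
#' move in exact opposition along their separation axis: the coherent mode
#' is then a pure stretch with no net translation or torque, so rigid-body
#' superposition leaves it intact and the planted correlations are
#' recovered by the superposed estimator. Coherent modes that overlap the
#' rigid-body space (e.g. `rho_within = 1` single-block translation) are
#' invisible after superposition by construction; probe those with
#' `compute_dccm(..., superpose = FALSE)`.
#'
#' @inheritParams gen_fluctuation_traj
#' @param blocks Assignment of atoms to blocks: integer vector (one entry
#'   per atom) or named list of residue-number vectors.
#' @param rho_within Within-block displacement correlation, in `[0, 1]`.
#' @param rho_between Between-block correlation, `|rho_between| <=
#'   rho_within`.
#' @param sigma Overall per-axis displacement SD scale, Angstrom.
#' @param axis Coherent-motion axis (length-3); default the separation
#'   axis of the first two block centroids (z axis for one block).
#' @export
gen_correlated_traj <- function(structure, blocks, rho_within = 0.6,
                                rho_between = -0.6, n_frames = 5000,
                                seed = 1, sigma = 1, axis = NULL,
                                frame_interval_ps = 10) {
  base <- coords_matrix(structure, atoms = NULL, het = TRUE)
  n <- nrow(base)
  if (is.list(blocks)) {
    assign <- integer(n)
    for (b in seq_along(blocks)) {
      assign[structure$residue_number %in% blocks[[b]]] <- b
    }
    if (any(assign == 0)) abort("some atoms belong to no block")
  } else {
    assign <- as.integer(blocks)
    if (length(assign) != n) abort("blocks must assign every atom")
  }
  nb <- max(assign)
  if (rho_within < 0 || rho_within > 1) abort("rho_within must be in [0, 1]")
  if (abs(rho_between) > rho_within) {
    abort("infeasible correlation: |rho_between| must be <= rho_within")
  }
  eta <- if (rho_within == 0) 0 else rho_between / rho_within
  if (eta < 0 && nb != 2) {
    abort("negative rho_between requires exactly two blocks")
  }
  sgn <- if (eta < 0) c(1, -1) else rep(1, nb)
  if (n_frames < 2) abort("n_frames must be >= 2")
  if (is.null(axis)) {
    axis <- if (nb >= 2) {
      com(base[assign == 2, , drop = FALSE]) -
        com(base[assign == 1, , drop = FALSE])
    } else c(0, 0, 1)
    if (sum(axis^2) == 0) axis <- c(0, 0, 1)
  }
  u <- axis / sqrt(sum(axis^2))
  amp <- sigma * sqrt(3 * rho_within)       # coherent amplitude along u
  noise_sd <- sigma * sqrt(1 - rho_within)  # per-axis isotropic noise
  set.seed(seed)
  g <- rnorm(n_frames)
  h <- matrix(rnorm(n_frames * nb), n_frames, nb)
  fac <- sqrt(1 - abs(eta)) * h + outer(g * sqrt(abs(eta)), sgn)
  coherent <- amp * fac[, assign, drop = FALSE]   # frames x atoms
  coords <- array(0, dim = c(n_frames, n, 3))
  for (ax in 1:3) {
    eps <- matrix(rnorm(n_frames * n, sd = noise_sd), n_frames, n)
    coords[, , ax] <- sweep(coherent * u[ax] + eps, 2, base[, ax], `+`)
  }
  new_trajectory(structure[, c("chain_id", "residue_number", "atom_name",
                               "residue_name", "element")],
                 coords, frame_interval_ps)
}

#' Hinge-closure trajectory following a prescribed schedule
#'
#' Moves a rigid sub-structure so that a designated landmark follows a
#' prescribed per-frame schedule exactly:
#'
#' * **angle mode** — the moving region is rotated about a hinge axis; the
#'   per-frame rotation angle is solved numerically (bracketing scan +
#'   root refinement to ~1e-10 degree) so the monitored Ca triplet matches
#'   the scheduled interior angle. A schedule value outside the range the
#'   rigid rotation can reach raises an error.
#' * **com mode** — the moving region is translated along the line joining
#'   the two region centroids so their centroid distance matches the
#'   schedule exactly (closed form).
#'
#' Optional isotropic Gaussian jitter can be added on top (applied after
#' the rigid motion, so the expected landmark series still follows the
#' schedule).
#'
#' @inheritParams gen_fluctuation_traj
#' @param moving Residue numbers forming the moving rigid body.
#' @param schedule Numeric vector, one target value per frame (degrees in
#'   angle mode, Angstrom in com mode).
#' @param landmark For angle mode: length-3 residue numbers `(a, b, c)` of
#'   the monitored Ca triplet (vertex `b`).
#' @param region_a For com mode: residue numbers of the static partner
#'   region (the moving region is the other centroid).
#' @param hinge_point,hinge_axis Hinge definition for angle mode; defaults
#'   to the moving region's centroid and the z axis.
#' @param jitter Per-axis SD of additive Gaussian noise, Angstrom.
#' @export
gen_closure_traj <- function(structure, moving, schedule,
                             landmark = NULL, region_a = NULL,
                             hinge_point = NULL, hinge_axis = c(0, 0, 1),
                             jitter = 0, seed = 1,
                             frame_interval_ps = 10) {
  base <- coords_matrix(structure, atoms = NULL, het = TRUE)
  n <- nrow(base)
  mov <- structure$residue_number %in% moving
  if (!any(mov)) abort("moving region selects no atoms")
  f <- length(schedule)
  if (f < 1) abort("schedule must cover at least one frame")
  coords <- array(0, dim = c(f, n, 3))
  if (!is.null(landmark)) {
    stopifnot(length(landmark) == 3)
    idx <- vapply(landmark, function(r) {
      which(structure$residue_number == r & structure$atom_name == "CA")[1]
    }, integer(1))
    if (anyNA(idx)) abort("landmark residues not resolvable on structure")
    hinge_point <- hinge_point %||% com(base[mov, , drop = FALSE])
    axis <- hinge_axis / sqrt(sum(hinge_axis^2))
    measure <- function(phi) {
      m <- base
      m[mov, ] <- rotate_about(base[mov, , drop = FALSE], hinge_point,
                               axis, phi)
      angle_points(m[idx[1], ], m[idx[2], ], m[idx[3], ])
    }
    grid <- seq(-pi, pi, length.out = 721)
    vals <- vapply(grid, measure, numeric(1))
    phi_prev <- 0
    for (i in seq_len(f)) {
      target <- schedule[i]
      dif <- vals - target
      hit <- which(dif[-1] * dif[-length(dif)] <= 0)
      if (length(hit) == 0) {
        abort(sprintf(
          "schedule value %.3f deg unreachable by rotation (range %.3f..%.3f)",
          target, min(vals), max(vals)))
      }
      ## solve every bracket; follow the branch nearest the previous frame
      roots <- vapply(hit, function(h) {
        if (dif[h] == 0) return(grid[h])
        stats::uniroot(function(p) measure(p) - target,
                       c(grid[h], grid[h + 1]), tol = 1e-12)$root
      }, numeric(1))
      phi <- roots[which.min(abs(roots - phi_prev))]
      phi_prev <- phi
      m <- base
      m[mov, ] <- rotate_about(base[mov, , drop = FALSE], hinge_point,
                               axis, phi)
      coords[i, , ] <- m
    }
  } else if (!is.null(region_a)) {
    ia <- structure$residue_number %in% region_a & !mov
    if (!any(ia)) abort("region_a selects no static atoms")
    ca <- com(base[ia, , drop = FALSE])
    cb <- com(base[mov, , drop = FALSE])
    d0 <- sqrt(sum((cb - ca)^2))
    if (d0 == 0) abort("region centroids coincide; direction undefined")
    u <- (cb - ca) / d0
    for (i in seq_len(f)) {
      m <- base
      shift <- (schedule[i] - d0) * u
      m[mov, ] <- sweep(base[mov, , drop = FALSE], 2, shift, `+`)
      coords[i, , ] <- m
    }
  } else {
    abort("give either `landmark` (angle mode) or `region_a` (com mode)")
  }
  if (jitter > 0) {
    set.seed(seed)
    coords <- coords + array(rnorm(length(coords), sd = jitter),
                             dim = dim(coords))
  }
  new_trajectory(structure[, c("chain_id", "residue_number", "atom_name",
                               "residue_name", "element")],
                 coords, frame_interval_ps)
}

rotate_about <- function(coords, point, axis, phi) {
  k <- axis / sqrt(sum(axis^2))
  kx <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  rot <- diag(3) + sin(phi) * kx + (1 - cos(phi)) * (kx %*% kx)
  sweep(sweep(coords, 2, point) %*% t(rot), 2, point, `+`)
}

#' Sample a trajectory from an ANM's thermal ensemble
#'
#' Frames are drawn i.i.d. from the zero-mean Gaussian with covariance
#' `scale x` Hessian pseudo-inverse, added to the model coordinates — the
#' consistency bridge between the elastic-network prediction and the
#' trajectory estimators ([rmsf()], [compute_dccm()]).
#'
#' @param model A connected `cadyn_anm`.
#' @param scale Covariance scale factor.
#' @inheritParams gen_fluctuation_traj
#' @export
gen_anm_traj <- function(model, scale = 1, n_frames = 5000, seed = 1,
                         frame_interval_ps = 10) {
  if (!model$connected) abort("disconnected model: ensemble undefined")
  model <- anm_modes(model)
  keep <- !zero_mode_mask(model)
  v <- model$eigenvectors[, keep, drop = FALSE]
  amp <- sqrt(scale / model$eigenvalues[keep])
  n <- model$n_nodes
  set.seed(seed)
  z <- matrix(rnorm(n_frames * length(amp)), n_frames)
  disp <- z %*% (t(v) * amp)   # frames x 3N
  coords <- array(0, dim = c(n_frames, n, 3))
  for (ax in 1:3) {
    coords[, , ax] <- sweep(disp[, seq(ax, 3 * n, by = 3), drop = FALSE],
                            2, model$coords[, ax], `+`)
  }
  new_trajectory(tibble(chain_id = "A", residue_number = seq_len(n),
                        atom_name = "CA", residue_name = "GLY",
                        element = "C"),
                 coords, frame_interval_ps)
}

#' Plant ligand atoms at prescribed distances from target residues
#'
#' Rejection-samples one (or more) ligand atom per target residue whose
#' minimum distance to that residue lies in `[band[1], band[2]]` while
#' staying farther than `band[2]` from every other residue — so with a
#' contact cutoff inside the band the planted contact set is recovered
#' exactly, and with a cutoff below the band no contacts exist. Fails
#' loudly when the geometry leaves no room after `max_tries` attempts.
#'
#' @param structure A `cadyn_structure`.
#' @param targets Residue numbers to put in contact.
#' @param band Length-2 distance band `[d_lo, d_hi]`, Angstrom, `d_lo > 0`.
#' @param n_atoms Ligand atoms per target residue.
#' @param seed RNG seed.
#' @param max_tries Rejection-sampling attempts per atom.
#' @return Ligand atom tibble (`atom_name`, `residue_name = "LIG"`,
#'   `chain_id = "L"`, `x`, `y`, `z`, `element = "C"`, `het = TRUE`,
#'   `partner = "ligand"`), with the target list in attribute
#'   `"targets"`.
#' @export
plant_ligand <- function(structure, targets, band = c(2.5, 2.95),
                         n_atoms = 1, seed = 1, max_tries = 2000) {
  if (band[1] <= 0 || band[2] < band[1]) {
    abort("band must satisfy 0 < d_lo <= d_hi")
  }
  prot <- structure[!structure$het, ]
  if (!all(targets %in% prot$residue_number)) {
    abort("some target residues are absent from the structure")
  }
  pm <- cbind(prot$x, prot$y, prot$z)
  set.seed(seed)
  rows <- list()
  serial <- 0L
  for (tr in targets) {
    own <- prot$residue_number == tr
    for (a in seq_len(n_atoms)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        anchor <- pm[which(own)[sample.int(sum(own), 1)], ]
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        d <- stats::runif(1, band[1], band[2])
        q <- anchor + d * u
        dist_all <- sqrt(colSums((t(pm) - q)^2))
        ok_own <- min(dist_all[own]) >= band[1] &&
          min(dist_all[own]) <= band[2]
        ok_other <- all(dist_all[!own] > band[2])
        if (ok_own && ok_other) {
          serial <- serial + 1L
          rows[[length(rows) + 1]] <- tibble(
            atom_name = paste0("C", serial), residue_name = "LIG",
            chain_id = "L", residue_number = 9000L + serial,
            x = q[1], y = q[2], z = q[3], element = "C", het = TRUE,
            partner = "ligand")
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort(sprintf(
          "could not place a ligand atom near residue %d within %d tries",
          tr, max_tries))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "targets") <- sort(unique(targets))
  out
}
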