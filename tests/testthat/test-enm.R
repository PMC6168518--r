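test_that("a single spring has one mode with eigenvalue 2 gamma", {
  for (gamma in c(1, 1.3, 0.25)) {
    m <- anm_modes(build_anm(rbind(c(0, 0, 0), c(5, 0, 0)), cutoff = 15,
                             gamma = gamma))
    ev <- m$eigenvalues
    expect_equal(sum(ev > 1e-9), 1)
    expect_equal(max(ev), 2 * gamma, tolerance = 1e-9)
  }
})

test_that("rigid translations lie in the Hessian null space", {
  set.seed(2)
  coords <- matrix(rnorm(90, sd = 4), 30, 3)
  m <- suppressWarnings(build_anm(coords, cutoff = 12))
  for (ax in 1:3) {
    v <- rep(0, 90)
    v[seq(ax, 90, by = 3)] <- 1
    expect_lt(max(abs(m$hessian %*% v)), 1e-10)
  }
})

test_that("node pairs beyond the cutoff yield no springs", {
  expect_warning(m <- build_anm(rbind(c(0, 0, 0), c(50, 0, 0)),
                                cutoff = 15), "disconnected")
  expect_equal(sum(abs(m$hessian)), 0)
  expect_false(m$connected)
  expect_error(analytic_fluctuations(anm_modes(m)), "disconnected")
})

test_that("mode count is 3N and connected networks have 6 zero modes", {
  set.seed(3)
  for (k in 1:5) {
    n <- sample(15:40, 1)
    coords <- matrix(rnorm(3 * n, sd = 4), n, 3)
    m <- build_anm(coords, cutoff = 14)
    if (!m$connected) next
    m <- anm_modes(m)
    expect_length(m$eigenvalues, 3 * n)
    expect_equal(n_zero_modes(m), 6)
    expect_true(all(m$eigenvalues > -1e-8 * max(m$eigenvalues)))
  }
  # a transporter-sized model: 1186 residues -> 3558 modes
  big <- gen_helix_bundle(n_helices = 2, residues_per_helix = 593,
                          spacing = 10, seed = 1)
  mb <- build_anm(coords_matrix(big), cutoff = 15)
  expect_equal(3 * mb$n_nodes, 3558)
})

test_that("eigendecomposition reconstructs the Hessian", {
  set.seed(4)
  coords <- matrix(rnorm(75, sd = 4), 25, 3)
  m <- anm_modes(build_anm(coords, cutoff = 14))
  H2 <- m$eigenvectors %*% (m$eigenvalues * t(m$eigenvectors))
  expect_lt(max(abs(H2 - m$hessian)) / max(abs(m$hessian)), 1e-6)
  expect_lt(max(abs(crossprod(m$eigenvectors) - diag(75))), 1e-9)
})

test_that("analytic fluctuations equal the dense pseudo-inverse oracle", {
  set.seed(5)
  coords <- matrix(rnorm(120, sd = 5), 40, 3)
  m <- anm_modes(build_anm(coords, cutoff = 13))
  fl <- analytic_fluctuations(m)
  g <- MASS::ginv(m$hessian)
  oracle <- vapply(seq_len(40), function(i) {
    idx <- (3 * i - 2):(3 * i)
    sum(diag(g[idx, idx]))
  }, numeric(1))
  expect_equal(fl$msf, oracle, tolerance = 1e-6)
  # gamma scaling: fluctuations scale as 1/k
  mk <- anm_modes(build_anm(coords, cutoff = 13, gamma = 2.5))
  expect_equal(analytic_fluctuations(mk)$msf, fl$msf / 2.5,
               tolerance = 1e-9)
})

test_that("symmetric dimers have swap-symmetric fluctuations", {
  half <- gen_helix_bundle(1, 15, 10, seed = 1)
  m1 <- coords_matrix(half)
  m2 <- cbind(12 - m1[, 1], -m1[, 2], m1[, 3])  # C2 copy about x = 6
  m <- anm_modes(build_anm(rbind(m1, m2), cutoff = 15))
  fl <- analytic_fluctuations(m)$msf
  expect_equal(fl[1:15], fl[16:30], tolerance = 1e-9)
  cm <- analytic_dccm(m)
  expect_equal(diag(cm), rep(1, 30))
  expect_equal(cm[1:15, 1:15], cm[16:30, 16:30], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("trajectories sampled from the model reproduce its predictions", {
  set.seed(6)
  coords <- matrix(rnorm(90, sd = 5), 30, 3)
  m <- anm_modes(build_anm(coords, cutoff = 14))
  tr <- gen_anm_traj(m, scale = 1, n_frames = 4000, seed = 7)
  fl <- analytic_fluctuations(m)
  prof <- rmsf(tr, fraction = 1)
  expect_equal(prof$rmsf, fl$rmsf, tolerance = 0.06)
  cm <- compute_dccm(tr)
  ca <- analytic_dccm(m)
  expect_lt(max(abs(unclass(cm) - unclass(ca))), 0.08)
  expect_lt(mean(abs(unclass(cm) - unclass(ca))), 0.02)
})

test_that("mode animations oscillate along the chosen eigenvector", {
  b <- two_domain_bundle()
  m <- anm_modes(build_anm(coords_matrix(b), cutoff = 12))
  still <- mode_animation(m, mode = 1, amplitude = 0, n_frames = 8)
  expect_equal(max(abs(sweep(still$coords, c(2, 3),
                             still$coords[1, , ]))), 0)
  anim <- mode_animation(m, mode = 1, amplitude = 3, n_frames = 36)
  prof <- rmsf(anim, fraction = 1)
  vec <- matrix(m$eigenvectors[, which(m$eigenvalues >
                                         1e-8 * max(m$eigenvalues))[1]],
                ncol = 3, byrow = TRUE)
  pernode <- sqrt(rowSums(vec^2))
  # RMSF proportional to per-node eigenvector magnitude
  ratio <- prof$rmsf[pernode > 1e-6] / pernode[pernode > 1e-6]
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-3)
  # animations survive the frame-table round trip
  f <- withr::local_tempfile(fileext = ".tsv")
  write_frame_table(anim, f)
  back <- read_frame_table(f)
  expect_lt(max(abs(back$coords - anim$coords)), 1e-9)
  expect_error(mode_animation(m, mode = 0), "non-zero mode")
})
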