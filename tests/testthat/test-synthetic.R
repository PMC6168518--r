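test_that("helix bundles have ideal alpha-helix geometry", {
  one <- gen_helix_bundle(1, 18, 10, seed = 1)
  d <- sqrt(rowSums(diff(coords_matrix(one))^2))
  expect_true(all(abs(d - 3.83) < 0.01))
  twelve <- gen_helix_bundle(12, 25, 20, seed = 1)
  expect_equal(nrow(twelve), 300)
  map <- structure_domain_map(twelve)
  expect_setequal(intersect(paste0("TM", 1:12), map$region),
                  paste0("TM", 1:12))
  expect_equal(range(region_residues(map, "TM12")), c(276, 300))
  expect_error(gen_helix_bundle(0, 10, 10), "required")
})

test_that("generators are deterministic in (spec, seed)", {
  b <- two_domain_bundle()
  expect_identical(coords_matrix(gen_helix_bundle(3, 10, 15, seed = 5)),
                   coords_matrix(gen_helix_bundle(3, 10, 15, seed = 5)))
  t1 <- gen_fluctuation_traj(b, 0.5, 50, seed = 9)
  t2 <- gen_fluctuation_traj(b, 0.5, 50, seed = 9)
  expect_identical(t1$coords, t2$coords)
  t3 <- gen_fluctuation_traj(b, 0.5, 50, seed = 10)
  expect_false(identical(t1$coords, t3$coords))
  l1 <- plant_ligand(b, c(5, 60), seed = 3)
  l2 <- plant_ligand(b, c(5, 60), seed = 3)
  expect_identical(l1$x, l2$x)
})

test_that("different seeds agree on the planted fluctuation amplitude", {
  b <- two_domain_bundle()
  r1 <- rmsf(gen_fluctuation_traj(b, 0.5, 3000, seed = 1), fraction = 1)
  r2 <- rmsf(gen_fluctuation_traj(b, 0.5, 3000, seed = 2), fraction = 1)
  expect_equal(mean(r1$rmsf), mean(r2$rmsf), tolerance = 0.02)
  expect_equal(mean(r1$rmsf), 0.5 * sqrt(3), tolerance = 0.03)
  # zero sigma: static trajectory
  r0 <- rmsf(gen_fluctuation_traj(b, 0, 10, seed = 1), fraction = 1)
  expect_equal(r0$rmsf, rep(0, 80))
  expect_error(gen_fluctuation_traj(b, 0.5, 1), "n_frames")
})

test_that("infeasible correlation structures are rejected", {
  b <- two_domain_bundle()
  blocks <- list(1:40, 41:80)
  expect_error(gen_correlated_traj(b, blocks, rho_within = 0.4,
                                   rho_between = -0.6, n_frames = 10),
               "infeasible")
  expect_error(gen_correlated_traj(b, list(1:20, 21:50, 51:80),
                                   rho_within = 0.8, rho_between = -0.2,
                                   n_frames = 10),
               "two blocks")
  expect_error(gen_correlated_traj(b, list(1:80), rho_within = 1.4,
                                   rho_between = 0, n_frames = 10),
               "rho_within")
})

test_that("a fully coherent single block is perfectly correlated", {
  b <- two_domain_bundle()
  tr <- gen_correlated_traj(b, list(1:80), rho_within = 1,
                            rho_between = 1, n_frames = 500, seed = 2)
  # the coherent mode is a rigid translation: visible only unsuperposed
  cm <- compute_dccm(tr, superpose = FALSE)
  off <- cm[upper.tri(cm)]
  expect_true(all(off > 1 - 1e-9))
})

test_that("closure schedules outside the reachable range fail loudly", {
  b <- two_domain_bundle()
  expect_error(gen_closure_traj(b, moving = 41:80, schedule = 179.9,
                                landmark = c(10, 45, 75)),
               "unreachable")
  expect_error(gen_closure_traj(b, moving = 41:80, schedule = 30),
               "landmark.*region_a|angle mode")
  # constant schedule: constant series
  tr <- gen_closure_traj(b, moving = 41:80, schedule = rep(40, 5),
                         landmark = c(10, 45, 75))
  lm <- new_landmarks(triplets = tibble::tibble(name = "p", a = 10L,
                                                b = 45L, c = 75L))
  v <- landmark_timeseries(tr, lm)$value
  expect_lt(diff(range(v)), 1e-8)
})

test_that("planted ligands respect the distance band by construction", {
  b <- two_domain_bundle()
  lig <- plant_ligand(b, targets = c(10, 30, 55), band = c(2.5, 2.95),
                      seed = 6)
  m <- coords_matrix(b)
  for (k in seq_len(nrow(lig))) {
    d <- sqrt(colSums((t(m) - c(lig$x[k], lig$y[k], lig$z[k]))^2))
    dres <- tapply(d, b$residue_number, min)
    near <- as.integer(names(dres)[dres <= 2.95])
    expect_length(near, 1)
    expect_true(near %in% c(10, 30, 55))
    expect_gte(dres[as.character(near)][[1]], 2.5)
  }
  expect_error(plant_ligand(b, targets = 10, band = c(-1, 2)), "d_lo")
  expect_error(plant_ligand(b, targets = 9999), "absent")
  # an over-tight geometry cannot be satisfied
  dense <- gen_helix_bundle(6, 10, 5, seed = 1)
  expect_error(plant_ligand(dense, targets = 35, band = c(9, 60),
                            max_tries = 50), "could not place")
})

test_that("generated trajectories satisfy the shared invariants", {
  b <- two_domain_bundle()
  trajs <- list(
    gen_fluctuation_traj(b, 0.3, 5, seed = 1),
    gen_correlated_traj(b, list(1:40, 41:80), 0.6, -0.6, 5, seed = 1),
    gen_closure_traj(b, moving = 41:80, schedule = seq(45, 40, -1),
                     landmark = c(10, 45, 75)))
  for (tr in trajs) {
    expect_s3_class(tr, "cadyn_trajectory")
    expect_equal(nrow(tr$roster), dim(tr$coords)[2])
    expect_true(all(is.finite(tr$coords)))
    f <- withr::local_tempfile(fileext = ".tsv")
    write_frame_table(tr, f)
    expect_lt(max(abs(read_frame_table(f)$coords - tr$coords)), 1e-9)
  }
})
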