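test_that("kabsch superposition recovers rigid motions exactly", {
  b <- two_domain_bundle()
  m <- coords_matrix(b)
  expect_equal(kabsch_superpose(m, m)$rmsd, 0, tolerance = 1e-12)
  # copy rotated 90 degrees about z and translated (10, 0, 0)
  rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  moved <- rigidly_move(m, rz, c(10, 0, 0))
  sp <- kabsch_superpose(moved, m)
  expect_lt(sp$rmsd, 1e-9)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  expect_lt(max(abs(apply_superposition(moved, sp) - m)), 1e-9)
  expect_error(kabsch_superpose(m[1:4, ], m[1:5, ]), "same number")
  expect_error(kabsch_superpose(m[1:2, ], m[1:2, ]), "at least 3")
  expect_error(kabsch_superpose(cbind(1:5, 0, 0), cbind(1:5, 0, 0)),
               "collinear")
})

test_that("superposed RMSD never exceeds the unsuperposed RMSD", {
  set.seed(42)
  b <- two_domain_bundle()
  m <- coords_matrix(b)
  for (k in 1:10) {
    other <- m + matrix(rnorm(length(m), sd = 2), ncol = 3)
    other <- rigidly_move(other, random_rotation(), rnorm(3, sd = 5))
    raw <- sqrt(mean(rowSums((other - m)^2)))
    expect_lte(kabsch_superpose(other, m)$rmsd, raw + 1e-12)
  }
})

test_that("RMSD, angle and centroid distance are rigid-motion invariant", {
  set.seed(7)
  b <- two_domain_bundle()
  m <- coords_matrix(b)
  other <- m + matrix(rnorm(length(m), sd = 1), ncol = 3)
  base_rmsd <- kabsch_superpose(other, m)$rmsd
  a <- m[3, ]; v <- m[20, ]; c <- m[50, ]
  base_angle <- angle_points(a, v, c)
  base_dist <- com_distance(m[1:40, ], m[41:80, ])
  for (k in 1:10) {
    rot <- random_rotation(); shift <- rnorm(3, sd = 20)
    mm <- rigidly_move(m, rot, shift)
    expect_equal(kabsch_superpose(rigidly_move(other, rot, shift), mm)$rmsd,
                 base_rmsd, tolerance = 1e-9)
    expect_equal(angle_points(mm[3, ], mm[20, ], mm[50, ]), base_angle,
                 tolerance = 1e-9)
    expect_equal(com_distance(mm[1:40, ], mm[41:80, ]), base_dist,
                 tolerance = 1e-9)
  }
})

test_that("rmsd_series is zero for identical or rigidly rotated frames", {
  b <- two_domain_bundle()
  m <- coords_matrix(b)
  set.seed(3)
  frames <- lapply(1:6, function(i) rigidly_move(m, random_rotation(),
                                                 rnorm(3, sd = 10)))
  frames[[1]] <- m
  tr <- new_trajectory(b[, c("chain_id", "residue_number", "atom_name")],
                       frames)
  s <- rmsd_series(tr, b)
  expect_equal(nrow(s), 6)
  expect_lt(max(s$rmsd), 1e-9)
})

test_that("rmsd_series grows monotonically under progressive closure", {
  b <- two_domain_bundle()
  sched <- seq(45, 30, length.out = 40)
  tr <- gen_closure_traj(b, moving = 41:80, schedule = sched,
                         landmark = c(10, 45, 75))
  ref <- frame_coords(tr, 1)  # the open state the closure starts from
  s <- rmsd_series(tr, ref)
  # brute-force per-frame oracle
  oracle <- vapply(seq_len(40), function(i) {
    kabsch_superpose(frame_coords(tr, i), ref)$rmsd
  }, numeric(1))
  expect_equal(s$rmsd, oracle, tolerance = 1e-12)
  expect_true(all(diff(s$rmsd) > -1e-9))
})

test_that("rmsf recovers planted isotropic jitter and B = 8 pi^2 rmsf^2", {
  b <- two_domain_bundle()
  tr <- gen_fluctuation_traj(b, sigma = 0.5, n_frames = 4000, seed = 11)
  prof <- rmsf(tr, fraction = 1)
  expect_equal(mean(prof$rmsf), 0.5 * sqrt(3), tolerance = 0.03)
  expect_equal(prof$bfactor, 8 * pi^2 * prof$rmsf^2)
  # static trajectory: all zero
  st <- new_trajectory(b[, c("chain_id", "residue_number", "atom_name")],
                       list(coords_matrix(b), coords_matrix(b)))
  p0 <- rmsf(st, fraction = 1)
  expect_equal(p0$rmsf, rep(0, 80))
  expect_equal(p0$bfactor, rep(0, 80))
  expect_error(rmsf(st, window = c(1, 1)), "at least 2")
})

test_that("the B-factor transform is exact and order-preserving", {
  expect_equal(bfactor_from_rmsf(0), 0)
  expect_equal(bfactor_from_rmsf(1), 8 * pi^2, tolerance = 1e-12)
  expect_equal(bfactor_from_rmsf(0.5), 19.7392088, tolerance = 1e-7)
  expect_error(bfactor_from_rmsf(-0.1), "non-negative")
  r <- runif(50)
  expect_equal(order(bfactor_from_rmsf(r)), order(r))
})

test_that("interior angles follow the textbook cases", {
  expect_equal(angle_points(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), 180)
  expect_equal(angle_points(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)), 90)
  expect_error(angle_points(c(1, 1, 1), c(1, 1, 1), c(2, 0, 0)),
               "zero-length")
})

test_that("centroid distances behave as constructed", {
  expect_equal(com_distance(matrix(c(0, 0, 0), 1), matrix(c(5, 0, 0), 1)), 5)
  m <- coords_matrix(two_domain_bundle())
  expect_equal(com_distance(m, sweep(m, 2, c(0, 0, 12), `+`)), 12)
  expect_error(com(m[0, ]), "empty")
})

test_that("the default window is the final 20% (2000 of 10000 frames)", {
  w <- window_frames(10000)
  expect_length(w, 2000)
  expect_equal(range(w), c(8001, 10000))
  expect_error(window_frames(10, c(5, 20)), "outside")
})
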