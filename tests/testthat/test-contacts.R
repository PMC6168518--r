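test_that("single-atom contact cases respect the 3.0 A cutoff", {
  prot <- new_structure(tibble::tibble(
    atom_name = "CA", residue_name = "ALA", chain_id = "A",
    residue_number = 1L, x = 0, y = 0, z = 0, element = "C"))
  lig <- tibble::tibble(atom_name = "C1", x = 2.9, y = 0, z = 0,
                        element = "C")
  hit <- find_contacts(prot, lig, cutoff = 3.0)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$min_dist, 2.9)
  lig$x <- 3.1
  expect_equal(nrow(find_contacts(prot, lig, cutoff = 3.0)), 0)
  expect_error(find_contacts(prot, lig[0, ]), "empty")
})

test_that("hydrogens are excluded unless requested", {
  prot <- new_structure(tibble::tibble(
    atom_name = c("CA", "HA"), residue_name = "ALA", chain_id = "A",
    residue_number = 1L, x = c(0, 2), y = 0, z = 0, element = c("C", "H")))
  lig <- tibble::tibble(atom_name = "C1", x = 4.5, y = 0, z = 0,
                        element = "C")
  expect_equal(nrow(find_contacts(prot, lig, cutoff = 3.0)), 0)
  expect_equal(nrow(find_contacts(prot, lig, cutoff = 3.0,
                                  include_hydrogens = TRUE)), 1)
})

test_that("planted contact sets are recovered exactly, no extras", {
  b <- two_domain_bundle()
  targets <- c(3, 17, 25, 33, 52, 61, 70, 77, 44, 12)
  lig <- plant_ligand(b, targets, band = c(2.5, 2.95), seed = 3)
  rec <- find_contacts(b, lig, cutoff = 3.0)
  expect_setequal(rec$residue_number, targets)
  expect_equal(sort(rec$residue_number),
               contact_oracle(b, lig, 3.0))
  # band strictly above the cutoff: no contacts at all
  far <- plant_ligand(b, targets = c(5, 70), band = c(3.05, 3.5), seed = 4)
  expect_equal(nrow(find_contacts(b, far, cutoff = 3.0)), 0)
})

test_that("contact detection equals the brute-force scan on random complexes", {
  set.seed(21)
  for (k in 1:20) {
    n <- sample(10:25, 1)
    prot <- new_structure(tibble::tibble(
      atom_name = "CA", residue_name = "ALA", chain_id = "A",
      residue_number = seq_len(n),
      x = runif(n, 0, 25), y = runif(n, 0, 25), z = runif(n, 0, 25),
      element = "C"))
    lig <- tibble::tibble(atom_name = paste0("C", 1:4),
                          x = runif(4, 0, 25), y = runif(4, 0, 25),
                          z = runif(4, 0, 25), element = "C")
    cutoff <- runif(1, 2, 8)
    got <- sort(find_contacts(prot, lig, cutoff = cutoff)$residue_number)
    expect_equal(got, contact_oracle(prot, lig, cutoff))
  }
})

test_that("contact sets are monotone in the cutoff", {
  set.seed(5)
  b <- two_domain_bundle()
  lig <- tibble::tibble(atom_name = paste0("C", 1:6),
                        x = runif(6, -10, 25), y = runif(6, -10, 25),
                        z = runif(6, -15, 15), element = "C")
  cuts <- c(2, 4, 6, 9, 12)
  sets <- lapply(cuts, function(cc) {
    find_contacts(b, lig, cutoff = cc)$residue_number
  })
  for (i in seq_along(cuts)[-1]) {
    expect_true(all(sets[[i - 1]] %in% sets[[i]]))
  }
})

test_that("per-TM aggregation counts distinct residues per helix", {
  b <- two_domain_bundle()   # TM1: 1-20 ... TM4: 61-80
  map <- structure_domain_map(b)
  lig <- plant_ligand(b, targets = c(22, 25, 28, 31, 34, 37, 63, 66, 70, 74),
                      band = c(2.5, 2.95), seed = 8)
  rec <- find_contacts(b, lig, cutoff = 3.0, map = map)
  prof <- aggregate_per_tm(rec, map)
  expect_equal(prof$per_tm$n_residues[prof$per_tm$region == "TM2"], 6L)
  expect_equal(prof$per_tm$n_residues[prof$per_tm$region == "TM4"], 4L)
  expect_equal(prof$per_tm$n_residues[prof$per_tm$region %in%
                                        c("TM1", "TM3", "other")],
               c(0L, 0L, 0L))
  # empty record set: all-zero profile
  empty <- aggregate_per_tm(rec[0, ], map)
  expect_true(all(empty$per_tm$n_residues == 0))
})

test_that("a residue in contact in every frame has frequency exactly 1", {
  b <- two_domain_bundle()
  lig <- plant_ligand(b, targets = 40, band = c(2.5, 2.95), seed = 2)
  roster <- dplyr::bind_rows(
    b[, c("chain_id", "residue_number", "atom_name", "residue_name",
          "element")],
    lig[, c("chain_id", "residue_number", "atom_name", "residue_name",
            "element")])
  base <- rbind(coords_matrix(b), cbind(lig$x, lig$y, lig$z))
  tr <- new_trajectory(roster, list(base, base, base, base))
  rec <- contact_timeseries(tr, partner_chain = "L", cutoff = 3.0)
  prof <- aggregate_per_tm(rec, structure_domain_map(b))
  expect_equal(prof$per_residue$frequency, 1)
  expect_equal(prof$per_residue$n_frames_in_contact, 4L)
})

test_that("the aromatic census reports planted aromatics exactly", {
  b <- two_domain_bundle()
  b <- mutate_residues(b, c(6, 7, 10, 14), "PHE")
  b <- mutate_residues(b, 12, "TYR")
  b <- mutate_residues(b, 33, "TRP")
  cen <- aromatic_census(b, residues = 1:20)
  expect_equal(cen$n[cen$residue_name == "PHE"], 4)
  expect_equal(cen$residues[cen$residue_name == "PHE"], "6,7,10,14")
  expect_equal(cen$n[cen$residue_name == "TYR"], 1)
  expect_equal(cen$n[cen$residue_name == "TRP"], 0)  # 33 outside range
  none <- aromatic_census(b, residues = 41:60)
  expect_true(all(none$n == 0))
  byregion <- aromatic_census(b, region = "TM1",
                              map = structure_domain_map(b))
  expect_equal(sum(byregion$n), 5)
})
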