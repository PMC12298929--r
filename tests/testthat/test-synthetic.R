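test_that("spec validation rejects degenerate geometry", {
  expect_error(synthetic_spec("cavity_monomer", cavity_radius = 0),
               "positive")
  expect_error(synthetic_spec("cavity_monomer", cavity_radius = -2),
               "positive")
  expect_error(synthetic_spec("homolog_ensemble",
                              ligand_plan = list(c(11L, 10L))),
               "cannot exceed")
  # radius too small to enclose any voxel at the default grid spacing
  expect_error(make_cavity_monomer(
    synthetic_spec("cavity_monomer", cavity_radius = 1)),
    "too small")
})

test_that("cavity monomer carries the closed-form ground-truth volume", {
  r <- 4.15
  st <- make_cavity_monomer(synthetic_spec("cavity_monomer",
                                           cavity_radius = r))
  truth <- attr(st, "ground_truth")
  expect_equal(truth$cavity_volume, 4 / 3 * pi * r^3)
  expect_equal(truth$cavity_volume, 300, tolerance = 0.01)
  expect_gt(length(truth$lining_residues), 0)
  # hemisphere gets half the sphere volume
  hm <- make_cavity_monomer(synthetic_spec("cavity_monomer",
                                           cavity_radius = r,
                                           shape = "hemisphere"))
  expect_equal(attr(hm, "ground_truth")$cavity_volume, 2 / 3 * pi * r^3)
})

test_that("generation is deterministic and seed-independent at zero noise", {
  sp1 <- synthetic_spec("cavity_monomer", cavity_radius = 4, seed = 1)
  sp2 <- synthetic_spec("cavity_monomer", cavity_radius = 4, seed = 2)
  st1 <- make_cavity_monomer(sp1)
  st1b <- make_cavity_monomer(sp1)
  st2 <- make_cavity_monomer(sp2)
  expect_identical(st1$atoms, st1b$atoms)
  # zero noise: coordinates do not depend on the seed at all
  expect_identical(st1$atoms[, c("x", "y", "z")],
                   st2$atoms[, c("x", "y", "z")])
  # with noise, same seed reproduces and different seeds differ
  spn <- synthetic_spec("cavity_monomer", cavity_radius = 4,
                        noise_sigma = 0.3, seed = 5)
  expect_identical(make_cavity_monomer(spn)$atoms,
                   make_cavity_monomer(spn)$atoms)
  spn2 <- synthetic_spec("cavity_monomer", cavity_radius = 4,
                         noise_sigma = 0.3, seed = 6)
  expect_false(identical(make_cavity_monomer(spn)$atoms$x,
                         make_cavity_monomer(spn2)$atoms$x))
})

test_that("written PDB fixtures are byte-identical and round-trip", {
  st <- make_cavity_monomer(synthetic_spec("cavity_monomer",
                                           cavity_radius = 4, seed = 3))
  f1 <- tempfile(fileext = ".pdb")
  f2 <- tempfile(fileext = ".pdb")
  write_structure(st, f1)
  write_structure(st, f2)
  expect_identical(readLines(f1), readLines(f2))
  # round trip through PDB: prepare(read(write(x))) == prepare(x)
  back <- prepare(read_structure(f1))
  ref <- prepare(st)
  cols <- c("elety", "resname", "chain", "resid", "x", "y", "z", "het",
            "element")
  expect_equal(back$atoms[, cols], ref$atoms[, cols])
})

test_that("interface dimer plants a partner-occupied cavity", {
  fx <- interface_dimer_result()
  expect_setequal(fx$complex$chains, c("A", "B"))
  expect_true(fx$truth$pocket_on_A_contains_B)
  expect_gt(fx$truth$b_atoms_inside, 0)
  # chain B helix tip sits below the surface inside the pit
  b <- fx$complex$atoms[fx$complex$atoms$chain == "B", ]
  expect_true(any(b$z < 0))
})

test_that("flat dimer ground truth tracks the separation", {
  near <- make_interface_dimer(synthetic_spec("flat_dimer", seed = 1))
  far <- make_interface_dimer(synthetic_spec("flat_dimer", gap = 50,
                                             seed = 1))
  expect_true(attr(near, "ground_truth")$shared_lining)
  expect_false(attr(far, "ground_truth")$shared_lining)
  # overlapping slabs violate sterics
  expect_error(make_interface_dimer(synthetic_spec("flat_dimer", gap = 2,
                                                   seed = 1)),
               "steric clash")
})

test_that("homolog ensemble members are rigid copies with planted ligands", {
  sp <- synthetic_spec("homolog_ensemble", cavity_radius = 4.5,
                       ligand_plan = list(c(4L, 10L), c(0L, 8L)),
                       n_homologs = 2, seed = 11)
  ens <- make_homolog_ensemble(sp)
  expect_length(ens$homologs, 2)
  for (h in ens$homologs) {
    expect_equal(det(h$rotation), 1, tolerance = 1e-9)
    expect_equal(nrow(h$ligands), 2)
    # protein atoms are exactly the base atoms under the stored motion
    prot <- h$structure$atoms[!h$structure$atoms$het, ]
    base_xyz <- as.matrix(ens$base$atoms[, c("x", "y", "z")])
    moved <- base_xyz %*% t(h$rotation) +
      matrix(h$translation, nrow(base_xyz), 3, byrow = TRUE)
    expect_equal(as.matrix(prot[, c("x", "y", "z")]), moved,
                 ignore_attr = TRUE, tolerance = 1e-9)
    # planted ligand atom counts inside the cavity, checked in base frame
    lig <- h$structure$atoms[h$structure$atoms$het, ]
    for (i in seq_len(nrow(h$ligands))) {
      lx <- as.matrix(lig[lig$resid == h$ligands$resid[i],
                          c("x", "y", "z")])
      back <- sweep(lx, 2, h$translation) %*% h$rotation
      d <- sqrt(rowSums(sweep(back, 2,
                              attr(ens$base, "ground_truth")$cavity_center)^2))
      expect_equal(sum(d < attr(ens$base, "ground_truth")$cavity_radius),
                   h$ligands$n_inside[i])
      expect_equal(nrow(lx), h$ligands$n_total[i])
    }
  }
})
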