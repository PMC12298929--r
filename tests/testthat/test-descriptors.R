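test_that("globularity is 1 for spheres and lower for elongated shapes", {
  sph <- make_voxel_sphere(6, 0.5)
  expect_equal(globularity(sph$idx, sph$dims, sph$spacing), 1,
               tolerance = 0.05)
  dims <- c(24L, 6L, 6L)
  bar <- make_voxel_box(dims, 3:22, 3:4, 3:4)
  expect_lt(globularity(bar, dims, 1), 1)
  # elongating an ellipsoid at fixed volume strictly decreases globularity
  ellipsoid <- function(a, b) {
    centers <- seq(-14, 14, by = 0.5)
    n <- length(centers)
    g <- expand.grid(x = centers, y = centers, z = centers)
    list(idx = which((g$x / a)^2 + (g$y / b)^2 + (g$z / b)^2 <= 1),
         dims = c(n, n, n))
  }
  r <- 4
  gs <- vapply(c(1, 2, 3.5), function(s) {
    e <- ellipsoid(r * s, r / sqrt(s))
    globularity(e$idx, e$dims, 0.5)
  }, numeric(1))
  expect_true(all(diff(gs) < 0))
})

test_that("rugosity reproduces the closed forms", {
  sph <- make_voxel_sphere(6, 0.5)
  expect_equal(rugosity(sph$idx, sph$dims, sph$spacing), 2,
               tolerance = 0.05)
  # a single voxel of edge h is a cube: V/S = h/6, exactly
  expect_equal(rugosity(14L, c(3L, 3L, 3L), 0.7), 0.7 / 6)
  # scaling law: doubling the voxel edge doubles rugosity exactly
  dims <- c(12L, 12L, 12L)
  blob <- make_voxel_box(dims, 3:9, 4:8, 3:7)
  expect_equal(rugosity(blob, dims, 1.6), 2 * rugosity(blob, dims, 0.8))
})

test_that("field-thresholded volumes count strictly sub-threshold voxels", {
  dims <- c(4L, 4L, 4L)
  dry <- array(0, dims)
  vox <- 1:20
  expect_equal(hydrophobic_volume(vox, dry, 1), 0)
  dry[1:10] <- -1
  expect_equal(hydrophobic_volume(vox, dry, 1), 10)
  # threshold is strict: energy exactly at the cutoff does not count
  dry[11] <- -0.5
  expect_equal(hydrophobic_volume(vox, dry, 1, threshold = -0.5), 10)
  # lowering the threshold never increases the result
  expect_lte(hydrophobic_volume(vox, dry, 1, threshold = -0.9),
             hydrophobic_volume(vox, dry, 1, threshold = -0.5))
  oh2 <- array(0, dims)
  oh2[1:25 <= 25] <- -4
  expect_equal(hydrophilic_volume(1:25, oh2, 0.8), 25 * 0.8^3)
})

test_that("solvent exposure separates open and enclosed cavities", {
  fx <- cavity_monomer_pockets()
  p <- fx$pockets$pockets[[1]]
  expect_equal(exposed_to_solvent(p$voxels, fx$pockets$field,
                                  fx$structure), 0)
  hm <- make_cavity_monomer(synthetic_spec("cavity_monomer",
                                           cavity_radius = 5,
                                           shape = "hemisphere"))
  hp <- find_pockets(hm, source = "detached_partner_A")
  expect_gt(length(hp$pockets), 0)
  e22 <- exposed_to_solvent(hp$pockets[[1]]$voxels, hp$field, hm, 2.2)
  e40 <- exposed_to_solvent(hp$pockets[[1]]$voxels, hp$field, hm, 4.0)
  expect_gt(e22, 0)
  expect_lte(e40, e22)  # raising the distance never increases the area
})

test_that("buried volume spans its endpoints and matches the ray oracle", {
  fx <- cavity_monomer_pockets()
  p <- fx$pockets$pockets[[1]]
  bv <- buried_volume(p$voxels, fx$pockets$field, fx$structure)
  expect_equal(as.numeric(bv), p$volume)  # fully enclosed: all rays hit
  # free-floating voxels with no protein: zero
  no_protein <- tiny_structure(matrix(numeric(0), 0, 3))
  expect_equal(as.numeric(buried_volume(p$voxels, fx$pockets$field,
                                        no_protein)), 0)
  # open pit: strictly between 0 and the volume, equal to the oracle
  hm <- make_cavity_monomer(synthetic_spec("cavity_monomer",
                                           cavity_radius = 4,
                                           shape = "hemisphere"))
  hp <- find_pockets(hm, source = "detached_partner_A")
  q <- hp$pockets[[1]]
  bvh <- buried_volume(q$voxels, hp$field, hm)
  expect_gt(as.numeric(bvh), 0)
  expect_lt(as.numeric(bvh), q$volume)
  sub <- q$voxels[seq(1, length(q$voxels), length.out = 12)]
  dirs <- pocketome:::fibonacci_directions(50)
  ob <- oracle_burial(pocketome:::voxel_centers(hp$field, sub),
                      as.matrix(hm$atoms[, c("x", "y", "z")]),
                      pocketome:::element_vdw(hm$atoms$element), dirs, 12)
  got <- pocketome:::cpp_ray_burial(
    pocketome:::voxel_centers(hp$field, sub),
    as.matrix(hm$atoms[, c("x", "y", "z")]),
    pocketome:::element_vdw(hm$atoms$element), dirs, 12)
  expect_equal(got, ob)
})

test_that("all six descriptors are invariant under voxel-aligned motion", {
  st <- make_cavity_monomer(synthetic_spec("cavity_monomer",
                                           cavity_radius = 4, seed = 2))
  shifted <- st
  shifted$atoms$x <- shifted$atoms$x + 1.6
  shifted$atoms$y <- shifted$atoms$y - 2.4
  d1 <- compute_descriptors(find_pockets(st, source = "complex"))
  d2 <- compute_descriptors(find_pockets(shifted, source = "complex"))
  expect_equal(d1$pockets[[1]]$descriptors, d2$pockets[[1]]$descriptors,
               tolerance = 1e-9)
})

test_that("matched-shape pockets separate only in their field composition", {
  # same geometry, different chemistry: carbon-lined vs oxygen-lined cavity
  carbon <- make_cavity_monomer(synthetic_spec("cavity_monomer",
                                               cavity_radius = 4.5))
  oxygen <- carbon
  oxygen$atoms$element <- "O"
  oxygen$atoms$elety <- "O"
  pc <- compute_descriptors(find_pockets(carbon, source = "complex"))
  dc <- pc$pockets[[1]]$descriptors
  # reuse the carbon pocket's voxels on the oxygen structure's fields
  fo <- build_grid(oxygen, grid_params())
  fo <- compute_probe_field(fo, oxygen, "DRY",
                            subset = pc$pockets[[1]]$voxels)
  fo <- compute_probe_field(fo, oxygen, "OH2",
                            subset = pc$pockets[[1]]$voxels)
  hydrophobic_o <- hydrophobic_volume(pc$pockets[[1]]$voxels,
                                      fo$probes$DRY, 0.8)
  hydrophilic_o <- hydrophilic_volume(pc$pockets[[1]]$voxels,
                                      fo$probes$OH2, 0.8)
  expect_gt(dc[["hydrophobic_volume"]], hydrophobic_o)
  expect_gt(hydrophilic_o, dc[["hydrophilic_volume"]])
})

test_that("integy moment follows its closed form and symmetries", {
  # centro-symmetric hydrophilic atoms cancel
  xyz <- rbind(c(2, 0, 0), c(-2, 0, 0), c(0, 3, 0), c(0, -3, 0))
  expect_equal(as.numeric(integy_moment(xyz, rep("O", 4))), 0)
  # heavy core at the origin with one polar atom at x = 4
  core <- matrix(0, 200, 3)
  m <- integy_moment(rbind(core, c(4, 0, 0)), c(rep("C", 200), "O"))
  expect_equal(as.numeric(m), 4, tolerance = 0.05)
  # rotation invariance
  R <- rotation_z(0.7)
  xyz2 <- rbind(core, c(4, 0, 0)) %*% t(R)
  expect_equal(as.numeric(integy_moment(xyz2, c(rep("C", 200), "O"))),
               as.numeric(m), tolerance = 1e-9)
  # no hydrophilic atoms: defined 0 and flagged
  none <- integy_moment(core, rep("C", 200))
  expect_equal(as.numeric(none), 0)
  expect_true(attr(none, "no_hydrophilic"))
})

test_that("ligand descriptor panel and PCA behave as specified", {
  set.seed(41)
  xyz <- matrix(rnorm(30), ncol = 3)
  d <- ligand_descriptors(xyz, c(rep("C", 6), "N", "N", "O", "S"))
  expect_equal(d[["n_hba"]], 3)
  expect_equal(d[["n_hbd"]], 2)
  expect_equal(d[["molecular_weight"]],
               6 * 12.011 + 2 * 14.007 + 15.999 + 32.06)
  # variance concentrated on one axis: PC1 explains everything
  x <- rnorm(50)
  one_axis <- cbind(a = x, b = 2 * x, c = -0.5 * x)
  p1 <- descriptor_pca(one_axis)
  expect_equal(p1$explained_variance[1], 1, tolerance = 1e-12)
  # isotropic 3-d Gaussian: each component near 1/3
  iso <- matrix(rnorm(3 * 10000), ncol = 3)
  colnames(iso) <- c("a", "b", "c")
  p2 <- descriptor_pca(iso)
  expect_equal(p2$explained_variance, rep(1 / 3, 3), tolerance = 0.03)
  expect_true(all(diff(p2$explained_variance) <= 0))
  # exact reconstruction of the standardized table at full rank
  m <- matrix(rnorm(40), ncol = 4)
  colnames(m) <- letters[1:4]
  p3 <- descriptor_pca(m)
  rec <- p3$scores %*% t(p3$loadings)
  expect_equal(rec, scale(m), ignore_attr = TRUE, tolerance = 1e-8)
  # constant columns are dropped with a warning
  withcst <- cbind(m, e = 1)
  expect_warning(p4 <- descriptor_pca(withcst), "constant")
  expect_equal(p4$dropped, "e")
  expect_error(descriptor_pca(m[1, , drop = FALSE]), "at least 2")
})

test_that("MIF surface export writes one mask per probe", {
  st <- make_cavity_monomer(synthetic_spec("cavity_monomer",
                                           cavity_radius = 4))
  gp <- grid_params(spacing = 1.2, probe_set = c("DRY", "O", "N1"))
  f <- compute_fields(st, gp)
  prefix <- tempfile()
  paths <- export_mif_surfaces(f, prefix)
  expect_length(paths, 3)
  expect_true(all(file.exists(paths)))
})
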