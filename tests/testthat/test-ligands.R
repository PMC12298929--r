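test_that("superposition recovers exact rigid motions", {
  fx <- cavity_monomer_pockets()
  base <- fx$structure
  expect_equal(superpose(base, base)$rmsd, 0, tolerance = 1e-12)
  # 90 degree rotation about z plus a translation is inverted exactly
  R <- rotation_z(pi / 2)
  moved <- base
  xyz <- as.matrix(base$atoms[, c("x", "y", "z")]) %*% t(R) +
    matrix(c(5, -3, 7), nrow(base$atoms), 3, byrow = TRUE)
  moved$atoms$x <- xyz[, 1]; moved$atoms$y <- xyz[, 2]
  moved$atoms$z <- xyz[, 3]
  sp <- superpose(moved, base)
  expect_lt(sp$rmsd, 1e-9)
  back <- apply_superposition(sp, xyz)
  expect_equal(back, as.matrix(base$atoms[, c("x", "y", "z")]),
               ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
})

test_that("Kabsch fit matches the brute-force RMSD oracle and is optimal", {
  set.seed(31)
  for (rep in 1:4) {
    n <- 20
    P <- matrix(rnorm(3 * n, sd = 4), ncol = 3)
    R <- pocketome:::random_rotation()
    Q <- P %*% t(R) + matrix(runif(3, -5, 5), n, 3, byrow = TRUE) +
      matrix(rnorm(3 * n, sd = 1), ncol = 3)
    sp <- pocketome:::kabsch_fit(P, Q)
    # reported rmsd equals an independent recomputation at the transform
    expect_equal(sp$rmsd, oracle_rmsd(P, Q, sp$rotation, sp$translation),
                 tolerance = 1e-8)
    expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
    # no random rotation (about the optimal translation) does better
    for (k in 1:25) {
      Rr <- pocketome:::random_rotation()
      tr <- colMeans(Q) - as.numeric(Rr %*% colMeans(P))
      expect_gte(oracle_rmsd(P, Q, Rr, tr) + 1e-9, sp$rmsd)
    }
  }
  # mirrored points still give a proper rotation, not a reflection
  P <- matrix(rnorm(30, sd = 3), ncol = 3)
  Qm <- P %*% diag(c(-1, 1, 1))
  expect_equal(det(pocketome:::kabsch_fit(P, Qm)$rotation), 1,
               tolerance = 1e-9)
  expect_error(superpose(tiny_structure(rbind(c(0, 0, 0), c(1, 0, 0))),
                         tiny_structure(rbind(c(0, 0, 0), c(1, 0, 0)))),
               "at least 3")
})

test_that("rmsd filter retains alignments up to the inclusive cutoff", {
  mk <- function(r) structure(list(rmsd = r), class = "superposition")
  kept <- rmsd_filter(list(mk(0.5), mk(7), mk(3.0)), 3.0)
  expect_equal(vapply(kept, `[[`, numeric(1), "rmsd"), c(0.5, 3.0))
})

test_that("ligand harvest applies the exclusion rules", {
  junk <- raw_atoms_df(
    atom_row("ALA", "A", 1),
    atom_row("SO4", "A", 101, 5, 0, 0, het = TRUE, elety = "S",
             element = "S"),
    atom_row("HOH", "A", 102, 6, 0, 0, het = TRUE, elety = "O",
             element = "O"))
  st <- tiny_structure(c(0, 0, 0))
  st$atoms <- junk
  expect_length(harvest_ligands(st), 0)
  # 20-atom drug-like ligand becomes one transformed pose
  lig <- do.call(raw_atoms_df, c(
    list(atom_row("ALA", "A", 1)),
    lapply(1:20, function(i) atom_row("DRG", "A", 500, i, 0, 0,
                                      het = TRUE, elety = "C1",
                                      element = "C"))))
  st2 <- tiny_structure(c(0, 0, 0)); st2$atoms <- lig
  shift <- structure(list(rotation = diag(3), translation = c(0, 0, 5),
                          rmsd = 0, n_paired_atoms = 3),
                     class = "superposition")
  poses <- harvest_ligands(st2, transform = shift)
  expect_length(poses, 1)
  expect_equal(poses[[1]]$n_atoms, 20)
  expect_equal(unique(poses[[1]]$atoms[, 3]), 5)
  # metals flagged with their reason; small fragments too
  mg <- tiny_structure(c(0, 0, 0))
  mg$atoms <- raw_atoms_df(atom_row("MG", "A", 300, het = TRUE,
                                    elety = "MG", element = "MG"))
  expect_length(harvest_ligands(mg), 0)
  flagged <- harvest_ligands(mg, include_excluded = TRUE)
  expect_equal(flagged[[1]]$reason, "metal")
  tiny <- tiny_structure(c(0, 0, 0))
  tiny$atoms <- raw_atoms_df(atom_row("XYZ", "A", 301, het = TRUE,
                                      elety = "C1", element = "C"))
  expect_equal(harvest_ligands(tiny, include_excluded = TRUE)[[1]]$reason,
               "too_few_atoms")
})

test_that("overlap fractions equal planted atom-count fractions exactly", {
  ens <- make_homolog_ensemble(
    synthetic_spec("homolog_ensemble", cavity_radius = 4.5,
                   ligand_plan = list(c(4L, 10L), c(10L, 10L), c(3L, 10L),
                                      c(0L, 8L)),
                   n_homologs = 1, seed = 4))
  pk <- find_pockets(ens$base, source = "detached_partner_A")
  m <- map_ligand_occupancy(pk, list(ens$homologs[[1]]$structure))
  expect_equal(sort(m$ligand_table$overlap_fraction),
               c(0, 0.3, 0.4, 1.0))
  # strictly-above-0.3 rule: 0.3 is not bound, 0.4 and 1.0 are
  expect_equal(m$ligand_table$bound[order(m$ligand_table$overlap_fraction)],
               c(FALSE, FALSE, TRUE, TRUE))
  p <- m$pocket_set$pockets[[1]]
  expect_true(p$ligand_bound)
  expect_equal(sort(p$ligand_occupancy$overlap_fraction), c(0.4, 1.0))
})

test_that("overlap is invariant under a common rigid motion", {
  ens <- make_homolog_ensemble(
    synthetic_spec("homolog_ensemble", cavity_radius = 4.5,
                   ligand_plan = list(c(4L, 10L)), n_homologs = 1,
                   seed = 9))
  score <- function(mod) {
    pk <- find_pockets(mod(ens$base), source = "detached_partner_A")
    m <- map_ligand_occupancy(pk, list(mod(ens$homologs[[1]]$structure)))
    m$ligand_table$overlap_fraction
  }
  ident <- score(identity)
  translate <- function(s) {
    s$atoms$x <- s$atoms$x + 1.6; s$atoms$y <- s$atoms$y - 0.8
    s$atoms$z <- s$atoms$z + 2.4; s
  }
  rot90 <- function(s) {
    x <- s$atoms$x; s$atoms$x <- -s$atoms$y; s$atoms$y <- x; s
  }
  expect_equal(ident, 0.4)
  expect_equal(score(translate), ident)
  expect_equal(score(rot90), ident)
})

test_that("alignments beyond the RMSD cutoff contribute no ligands", {
  noisy <- make_homolog_ensemble(
    synthetic_spec("homolog_ensemble", cavity_radius = 4.5,
                   noise_sigma = 5, n_homologs = 1, seed = 13))
  clean <- make_homolog_ensemble(
    synthetic_spec("homolog_ensemble", cavity_radius = 4.5,
                   n_homologs = 1, seed = 13))
  expect_gt(superpose(noisy$homologs[[1]]$structure, noisy$base)$rmsd, 3)
  pk <- find_pockets(clean$base, source = "detached_partner_A")
  m <- map_ligand_occupancy(pk, list(noisy$homologs[[1]]$structure,
                                     clean$homologs[[1]]$structure),
                            reference = clean$base)
  # only the well-aligned homolog's ligand is transferred
  expect_equal(nrow(m$ligand_table), 1)
  expect_match(m$ligand_table$ligand_id, "homolog1")
})

test_that("local annotation join classifies ligands without web access", {
  tab <- data.frame(ligand_id = c("DRG:A:1@x", "UNK:A:2@x"),
                    resname = c("DRG", "UNK"),
                    n_atoms = c(20L, 10L), best_pocket = "P01",
                    overlap_fraction = c(0.5, 0.1),
                    bound = c(TRUE, FALSE))
  ann <- data.frame(ligand = "DRG", phase = "approved", atc = "L01")
  out <- annotate_ligands(tab, ann)
  expect_equal(out$phase, c("approved", "no_data"))
  expect_equal(out$atc, c("L01", NA))
})
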