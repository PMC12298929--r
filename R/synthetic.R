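#' Synthetic structures with analytically known ground truth
#'
#' Pseudo-protein generators used to exercise the whole pocket pipeline
#' offline: monomers with planted spherical or hemispherical cavities of
#' known volume, dimers whose interface geometry is constructed (a cavity on
#' chain A holding a helix-like segment of chain B, or two flat slabs that
#' enclose a groove only on complexation), and homolog ensembles related by
#' known rigid motions carrying planted ligands with a known fraction of
#' atoms inside the base cavity.
#'
#' Pseudo-proteins are poly-alanine-like: residues of a few carbon heavy
#' atoms (first atom named CA) so that residue bookkeeping works without
#' real chemistry. Cavities are built by tessellating atom shells whose van
#' der Waals surface lies exactly on the target cavity sphere, which gives
#' analytic control of the open cavity volume.
#'
#' @name synthetic_data
NULL

.carbon_vdw <- 1.7

#' Specification for a synthetic structure
#'
#' @param kind One of `"cavity_monomer"`, `"interface_dimer"`,
#'   `"flat_dimer"`, `"homolog_ensemble"`.
#' @param cavity_radius Planted cavity radius in Angstrom (> 0).
#' @param cavity_center Numeric length-3 cavity center (Angstrom).
#' @param n_shell_atoms Atom count of the innermost shell; `NULL` picks a
#'   tessellation with ~1.6 A spacing.
#' @param noise_sigma Per-coordinate Gaussian jitter (Angstrom). Default 0
#'   so ground truth stays analytic.
#' @param seed Integer seed; identical spec + seed gives byte-identical
#'   structures.
#' @param ligand_plan List of integer pairs `c(n_atoms_inside,
#'   n_atoms_total)` for planted ligands (homolog ensembles).
#' @param shape `"sphere"` (fully enclosed cavity) or `"hemisphere"`
#'   (open surface pit) for cavity monomers.
#' @param gap Slab separation in Angstrom for flat dimers.
#' @param n_homologs Number of ensemble members (homolog ensembles).
#' @return A validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(kind = c("cavity_monomer", "interface_dimer",
                                    "flat_dimer", "homolog_ensemble"),
                           cavity_radius = 4.5,
                           cavity_center = c(0, 0, 0),
                           n_shell_atoms = NULL,
                           noise_sigma = 0,
                           seed = 1L,
                           ligand_plan = list(c(4L, 10L)),
                           shape = c("sphere", "hemisphere"),
                           gap = 7.5,
                           n_homologs = 3L) {
  kind <- match.arg(kind)
  shape <- match.arg(shape)
  if (!is.numeric(cavity_radius) || length(cavity_radius) != 1 ||
      cavity_radius <= 0)
    stop("cavity_radius must be a single positive length (Angstrom)")
  stopifnot(length(cavity_center) == 3, is.finite(cavity_center),
            noise_sigma >= 0, gap > 0, n_homologs >= 1)
  for (lp in ligand_plan) {
    stopifnot(length(lp) == 2, lp[1] >= 0, lp[2] >= 1)
    if (lp[1] > lp[2])
      stop("ligand_plan: n_atoms_inside cannot exceed n_atoms_total")
  }
  structure(list(kind = kind, cavity_radius = cavity_radius,
                 cavity_center = as.numeric(cavity_center),
                 n_shell_atoms = n_shell_atoms,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 ligand_plan = ligand_plan, shape = shape, gap = gap,
                 n_homologs = as.integer(n_homologs)),
            class = "synthetic_spec")
}

# run expr with a deterministic local RNG, restoring global state afterwards
with_spec_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# near-uniform tessellation of a sphere of radius R (Fibonacci lattice)
sphere_points <- function(n, radius, center = c(0, 0, 0)) {
  dirs <- fibonacci_directions(n)
  sweep(dirs * radius, 2, center, "+")
}

# group atom coordinates into pseudo-residues of `per` atoms on one chain
atoms_to_residues <- function(xyz, chain, per = 5L, resid_start = 1L) {
  xyz <- round(xyz, 3)  # PDB coordinate precision, so files round-trip
  n <- nrow(xyz)
  resid <- resid_start + (seq_len(n) - 1L) %/% per
  names4 <- c("CA", "CB", "CG", "CD", "CE", "CZ", "CH", "CK")
  elety <- names4[((seq_len(n) - 1L) %% per) + 1L]
  df <- empty_atoms(n)
  df$serial <- seq_len(n)
  df$elety <- elety
  df$resname <- "ALA"
  df$chain <- chain
  df$resid <- as.integer(resid)
  df$icode <- ""
  df$x <- xyz[, 1]; df$y <- xyz[, 2]; df$z <- xyz[, 3]
  df$het <- FALSE
  df$occupancy <- 1
  df$altloc <- ""
  df$element <- "C"
  df$cofactor <- FALSE
  df
}

shell_counts <- function(radius, n_inner = NULL, spacing = 1.6) {
  if (!is.null(n_inner)) return(max(14L, as.integer(n_inner)))
  max(14L, as.integer(round(4 * pi * radius^2 / spacing^2)))
}

#' Build a monomer with a planted cavity of known volume
#'
#' Sphere shape: concentric atom shells whose inner van der Waals surface
#' sits exactly at `cavity_radius`, enclosing an empty ball of analytic
#' volume (4/3) pi r^3. Hemisphere shape: a slab with a hemispherical pit
#' (volume (2/3) pi r^3) open to solvent.
#'
#' @param spec A [synthetic_spec()] with `kind = "cavity_monomer"`.
#' @return A `prepared_structure` with attribute `ground_truth`: list with
#'   `cavity_volume` (Angstrom^3), `lining_residues` (residue keys of the
#'   cavity-facing shell), `cavity_center`, `cavity_radius`, `shape`.
#' @export
make_cavity_monomer <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$kind != "cavity_monomer")
    stop("spec kind must be cavity_monomer")
  r <- spec$cavity_radius
  if (r < 1.6)
    stop("cavity radius ", r,
         " A is too small to enclose any voxel at the default 0.8 A spacing")
  ctr <- spec$cavity_center
  with_spec_rng(spec$seed, {
    if (spec$shape == "sphere") {
      radii <- r + .carbon_vdw + c(0, 1.9, 3.8)
      shells <- lapply(seq_along(radii), function(k) {
        n <- shell_counts(radii[k],
                          if (k == 1) spec$n_shell_atoms else NULL)
        sphere_points(n, radii[k], ctr)
      })
      n_inner <- nrow(shells[[1]])
      xyz <- do.call(rbind, shells)
      truth_volume <- 4 / 3 * pi * r^3
    } else {
      slab <- slab_lattice(half = r + 8, zmin = -(r + 4.5), zmax = 0,
                           spacing = 1.8)
      keep <- sqrt(rowSums(sweep(slab, 2, ctr, "-")^2)) > r + .carbon_vdw + 0.6
      slab <- slab[keep, , drop = FALSE]
      rim_all <- sphere_points(shell_counts(r + .carbon_vdw,
                                            spec$n_shell_atoms, 1.4),
                               r + .carbon_vdw, ctr)
      rim <- rim_all[rim_all[, 3] <= ctr[3] + 1e-9, , drop = FALSE]
      n_inner <- nrow(rim)
      xyz <- rbind(rim, slab)
      truth_volume <- 2 / 3 * pi * r^3
    }
    if (spec$noise_sigma > 0)
      xyz <- xyz + matrix(rnorm(length(xyz), 0, spec$noise_sigma),
                          ncol = 3)
    atoms <- atoms_to_residues(xyz, chain = "A")
    st <- new_prepared_structure(atoms, "A",
                                 source = sprintf("synthetic:%s:%s:seed%d",
                                                  spec$kind, spec$shape,
                                                  spec$seed))
    lining <- unique(res_key(atoms$chain[seq_len(n_inner)],
                             atoms$resid[seq_len(n_inner)]))
    attr(st, "ground_truth") <- list(cavity_volume = truth_volume,
                                     lining_residues = lining,
                                     cavity_center = ctr,
                                     cavity_radius = r,
                                     shape = spec$shape)
    st
  })
}

slab_lattice <- function(half, zmin, zmax, spacing = 1.8) {
  xs <- seq(-half, half, by = spacing)
  zs <- seq(zmin, zmax, by = spacing)
  as.matrix(expand.grid(x = xs, y = xs, z = zs))
}

#' Build a two-chain complex with constructed interface geometry
#'
#' `interface_dimer`: chain A is a slab with a hemispherical pit into which
#' a helix-like segment of chain B inserts (ground truth: a pocket detected
#' on detached A contains part of B). `flat_dimer`: two flat slabs facing
#' each other across `spec$gap`; in contact they enclose a groove lined by
#' residues of both chains, far apart they do not.
#'
#' @param spec A [synthetic_spec()] with `kind` `"interface_dimer"` or
#'   `"flat_dimer"`.
#' @return A `prepared_structure` (chains A and B) with attribute
#'   `ground_truth`: list with `pocket_on_A_contains_B`, `shared_lining`,
#'   and geometry details.
#' @export
make_interface_dimer <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!spec$kind %in% c("interface_dimer", "flat_dimer"))
    stop("spec kind must be interface_dimer or flat_dimer")
  with_spec_rng(spec$seed, {
    if (spec$kind == "interface_dimer") {
      r <- max(spec$cavity_radius, 4.5)
      mono_spec <- synthetic_spec("cavity_monomer", cavity_radius = r,
                                  cavity_center = c(0, 0, 0),
                                  noise_sigma = 0, seed = spec$seed,
                                  shape = "hemisphere")
      a_st <- make_cavity_monomer(mono_spec)
      a_atoms <- a_st$atoms
      truth_a <- attr(a_st, "ground_truth")
      # helix-like chain B descending into the pit along -z
      zs <- seq(8, -(r - 2.9), by = -1.4)
      t <- seq_along(zs)
      bxyz <- cbind(1.0 * cos(1.75 * t), 1.0 * sin(1.75 * t), zs)
      b_atoms <- atoms_to_residues(bxyz, chain = "B", per = 3L,
                                   resid_start = 1000L)
      truth <- list(pocket_on_A_contains_B = TRUE, shared_lining = TRUE,
                    cavity_radius = r, cavity_center = c(0, 0, 0),
                    lining_residues_A = truth_a$lining_residues,
                    b_atoms_inside = sum(rowSums(bxyz^2) < r^2 &
                                           bxyz[, 3] < 0))
      atoms <- rbind(a_atoms, b_atoms)
    } else {
      g <- spec$gap
      half <- 12
      a_xyz <- slab_lattice(half, zmin = -3.6, zmax = 0)
      b_xyz <- slab_lattice(half, zmin = g, zmax = g + 3.6)
      a_atoms <- atoms_to_residues(a_xyz, chain = "A", per = 5L)
      b_atoms <- atoms_to_residues(b_xyz, chain = "B", per = 5L,
                                   resid_start = 1000L)
      atoms <- rbind(a_atoms, b_atoms)
      truth <- list(pocket_on_A_contains_B = FALSE,
                    shared_lining = g <= 8,
                    gap = g)
    }
    if (spec$noise_sigma > 0) {
      xyz <- as.matrix(atoms[, c("x", "y", "z")]) +
        matrix(rnorm(3 * nrow(atoms), 0, spec$noise_sigma), ncol = 3)
      atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
    }
    check_clash(atoms)
    st <- new_prepared_structure(atoms, c("A", "B"),
                                 source = sprintf("synthetic:%s:seed%d",
                                                  spec$kind, spec$seed))
    attr(st, "ground_truth") <- truth
    st
  })
}

check_clash <- function(atoms, tol = 2.2) {
  a <- as.matrix(atoms[atoms$chain == "A", c("x", "y", "z")])
  b <- as.matrix(atoms[atoms$chain == "B", c("x", "y", "z")])
  if (nrow(a) == 0 || nrow(b) == 0) return(invisible(TRUE))
  dmin <- min(cpp_min_atom_dist(b, a))
  if (dmin < tol)
    stop(sprintf("steric clash between chains: minimum A-B distance %.2f A < %.2f A",
                 dmin, tol))
  invisible(TRUE)
}

random_rotation <- function() {
  # uniform random rotation via quaternion
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' Build a homolog ensemble with planted ligands
#'
#' Generates a base cavity monomer plus `spec$n_homologs` copies under known
#' random rigid motions (optionally with per-atom coordinate noise). Each
#' copy carries one planted ligand per entry of `spec$ligand_plan`, placed
#' so that exactly `n_atoms_inside` of its `n_atoms_total` heavy atoms lie
#' well inside the base cavity (in the base frame) and the rest far outside.
#'
#' @param spec A [synthetic_spec()] with `kind = "homolog_ensemble"`.
#' @return List with `base` (a `prepared_structure`) and `homologs`, a list
#'   of entries `structure` (protein + LIG HETATM records, transformed),
#'   `rotation`, `translation`, and `ligands` (data frame: resid, n_inside,
#'   n_total).
#' @export
make_homolog_ensemble <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$kind != "homolog_ensemble")
    stop("spec kind must be homolog_ensemble")
  base_spec <- synthetic_spec("cavity_monomer",
                              cavity_radius = spec$cavity_radius,
                              cavity_center = spec$cavity_center,
                              n_shell_atoms = spec$n_shell_atoms,
                              noise_sigma = 0, seed = spec$seed,
                              shape = "sphere")
  base <- make_cavity_monomer(base_spec)
  truth <- attr(base, "ground_truth")
  r <- truth$cavity_radius
  ctr <- truth$cavity_center
  with_spec_rng(spec$seed + 1L, {
    homologs <- lapply(seq_len(spec$n_homologs), function(i) {
      R <- random_rotation()
      tr <- runif(3, -20, 20)
      atoms <- base$atoms
      xyz <- as.matrix(atoms[, c("x", "y", "z")])
      if (spec$noise_sigma > 0)
        xyz <- xyz + matrix(rnorm(length(xyz), 0, spec$noise_sigma), ncol = 3)
      xyz <- xyz %*% t(R) + matrix(tr, nrow(xyz), 3, byrow = TRUE)
      atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
      lig_rows <- list()
      lig_info <- list()
      next_resid <- 9000L
      for (lp in spec$ligand_plan) {
        n_in <- lp[1]; n_tot <- lp[2]
        inside <- random_ball_points(n_in, max(0.4, r - 1.8), ctr)
        outside_dir <- fibonacci_directions(max(1, n_tot - n_in))
        outside <- sweep(outside_dir * (r + 14), 2, ctr, "+") +
          matrix(runif(3 * max(1, n_tot - n_in), -0.3, 0.3), ncol = 3)
        lxyz <- rbind(inside, outside[seq_len(n_tot - n_in), , drop = FALSE])
        lxyz <- lxyz %*% t(R) + matrix(tr, nrow(lxyz), 3, byrow = TRUE)
        df <- empty_atoms(n_tot)
        df$serial <- seq_len(n_tot)
        df$elety <- sprintf("C%d", seq_len(n_tot))
        df$resname <- "LIG"
        df$chain <- "A"
        df$resid <- next_resid
        df$icode <- ""
        df$x <- lxyz[, 1]; df$y <- lxyz[, 2]; df$z <- lxyz[, 3]
        df$het <- TRUE
        df$occupancy <- 1
        df$altloc <- ""
        df$element <- "C"
        df$cofactor <- FALSE
        lig_rows[[length(lig_rows) + 1]] <- df
        lig_info[[length(lig_info) + 1]] <-
          data.frame(resid = next_resid, n_inside = n_in, n_total = n_tot)
        next_resid <- next_resid + 1L
      }
      all_atoms <- rbind(atoms, do.call(rbind, lig_rows))
      st <- new_prepared_structure(all_atoms, "A",
                                   source = sprintf("synthetic:homolog%d:seed%d",
                                                    i, spec$seed))
      list(structure = st, rotation = R, translation = tr,
           ligands = do.call(rbind, lig_info))
    })
    list(base = base, homologs = homologs)
  })
}

random_ball_points <- function(n, radius, center) {
  if (n == 0) return(matrix(numeric(0), 0, 3))
  out <- matrix(NA_real_, n, 3)
  got <- 0
  while (got < n) {
    p <- runif(3, -radius, radius)
    if (sum(p^2) <= radius^2) {
      got <- got + 1
      out[got, ] <- p + center
    }
  }
  out
}
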