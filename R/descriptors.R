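#' Geometric and energetic pocket descriptors
#'
#' Six per-pocket descriptors: globularity (sphericity, 1 for a perfect
#' sphere), rugosity (volume-to-surface ratio, in Angstrom), hydrophobic
#' volume (DRY field below threshold), hydrophilic volume (OH2 field below
#' threshold), exposed-to-solvent surface (boundary points at least 2.2 A
#' from the protein) and buried volume (ray-collision buriedness averaged
#' over the pocket). Volumes are voxel counts times the voxel volume.
#'
#' Boundary surface is measured on the voxel set with an oriented-face
#' estimator: each exposed voxel face contributes `spacing^2 * |n . e|`,
#' where `n` is the local outward normal estimated from the occupancy in a
#' small neighbourhood. The estimator is exact for axis-aligned flat
#' surfaces (a single voxel measures `6 h^2`) and asymptotically unbiased
#' for smooth surfaces, so a voxelized sphere measures `4 pi r^2` rather
#' than the 1.5-fold staircase overestimate a raw face count would give.
#'
#' @name descriptors
NULL

.atomic_mass <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                  P = 30.974, H = 1.008, F = 18.998, CL = 35.45,
                  BR = 79.904, I = 126.90)

element_mass <- function(element) {
  m <- .atomic_mass[toupper(element)]
  m[is.na(m)] <- 12.011
  unname(m)
}

voxel_mask <- function(voxels, dims) {
  mask <- logical(prod(dims))
  mask[voxels] <- TRUE
  mask
}

# oriented-face boundary surface (Angstrom^2); normal_radius in voxels
pocket_surface <- function(voxels, dims, spacing, normal_radius = 2.5) {
  cpp_surface_area(voxel_mask(voxels, dims), as.integer(dims), spacing,
                   normal_radius)
}

#' Globularity of a voxel set
#'
#' Surface area of the sphere having the set's volume, divided by the
#' measured boundary surface; 1 for a perfect sphere (capped at 1 within
#' discretization tolerance), below 1 for elongated shapes.
#'
#' @param voxels Integer vector of linear voxel indices.
#' @param dims Grid dimensions.
#' @param spacing Voxel edge length (Angstrom).
#' @return Dimensionless value in (0, 1].
#' @export
globularity <- function(voxels, dims, spacing) {
  stopifnot(length(voxels) > 0)
  V <- length(voxels) * spacing^3
  A <- pocket_surface(voxels, dims, spacing)$area
  A_eq <- (36 * pi)^(1 / 3) * V^(2 / 3)
  min(1, A_eq / A)
}

#' Rugosity of a voxel set
#'
#' Volume-to-surface ratio in Angstrom (r/3 for an ideal sphere of radius
#' r, h/6 for a single voxel of edge h). Higher values mean smoother,
#' bulkier pockets.
#'
#' @inheritParams globularity
#' @return Length in Angstrom.
#' @export
rugosity <- function(voxels, dims, spacing) {
  stopifnot(length(voxels) > 0)
  V <- length(voxels) * spacing^3
  A <- pocket_surface(voxels, dims, spacing)$area
  V / A
}

#' Hydrophobic volume of a pocket
#'
#' Volume of the pocket voxels whose DRY energy is strictly below
#' `threshold`.
#'
#' @param voxels Integer vector of linear voxel indices.
#' @param dry_field Numeric array of DRY energies (kcal/mol).
#' @param spacing Voxel edge length (Angstrom).
#' @param threshold Energy threshold (kcal/mol, default -0.5).
#' @return Volume in Angstrom^3.
#' @export
hydrophobic_volume <- function(voxels, dry_field, spacing,
                               threshold = -0.5) {
  sum(dry_field[voxels] < threshold) * spacing^3
}

#' Hydrophilic volume of a pocket
#'
#' Volume of the pocket voxels whose OH2 (water probe) energy is strictly
#' below `threshold`.
#'
#' @param voxels Integer vector of linear voxel indices.
#' @param oh2_field Numeric array of OH2 energies (kcal/mol).
#' @param spacing Voxel edge length (Angstrom).
#' @param threshold Energy threshold (kcal/mol, default -3.5).
#' @return Volume in Angstrom^3.
#' @export
hydrophilic_volume <- function(voxels, oh2_field, spacing,
                               threshold = -3.5) {
  sum(oh2_field[voxels] < threshold) * spacing^3
}

#' Solvent-exposed surface proxy of a pocket
#'
#' Counts pocket boundary voxels whose center is at least `min_dist` from
#' every protein atom's van der Waals surface, times `spacing^2`. Fully
#' enclosed cavities score 0 (every boundary voxel hugs the wall); open
#' pocket mouths score positively.
#'
#' @param voxels Integer vector of linear voxel indices.
#' @param field The pocket's `volumetric_field`.
#' @param structure The `prepared_structure` sharing the frame.
#' @param min_dist Minimum distance to the protein (Angstrom, default 2.2).
#' @return Area proxy in Angstrom^2.
#' @export
exposed_to_solvent <- function(voxels, field, structure, min_dist = 2.2) {
  dims <- field$dims
  mask <- voxel_mask(voxels, dims)
  # boundary voxels: at least one 6-neighbour outside the set
  er <- cpp_erode(mask, as.integer(dims), 1)
  boundary <- which(mask & !er)
  if (length(boundary) == 0) boundary <- voxels
  vox <- voxel_centers(field, boundary)
  dmin <- cpp_min_surface_dist(vox, atom_coords(structure),
                               element_vdw(structure$atoms$element))
  sum(dmin >= min_dist) * field$spacing^2
}

#' Buried volume of a pocket
#'
#' Per-voxel buriedness is the fraction of `n_rays` fixed directions that
#' collide with the protein; the descriptor is the pocket volume weighted
#' by mean buriedness (Angstrom^3). The complementary low-buriedness
#' subvolume (buriedness below 0.5) is attached as attribute
#' `low_buried_volume`.
#'
#' @param voxels Integer vector of linear voxel indices.
#' @param field The pocket's `volumetric_field`.
#' @param structure The `prepared_structure` sharing the frame.
#' @param n_rays Number of ray directions.
#' @param cutoff Ray length cutoff (Angstrom).
#' @return Volume in Angstrom^3 with attribute `low_buried_volume`.
#' @export
buried_volume <- function(voxels, field, structure, n_rays = 50,
                          cutoff = 12) {
  vox <- voxel_centers(field, voxels)
  atoms <- atom_coords(structure)
  if (nrow(atoms) == 0) {
    out <- 0
    attr(out, "low_buried_volume") <- length(voxels) * field$spacing^3
    return(out)
  }
  b <- cpp_ray_burial(vox, atoms, element_vdw(structure$atoms$element),
                      fibonacci_directions(n_rays), cutoff)
  vol <- length(voxels) * field$spacing^3
  out <- vol * mean(b)
  attr(out, "low_buried_volume") <- sum(b < 0.5) * field$spacing^3
  out
}

#' Descriptor thresholds
#'
#' @param hydrophobic DRY threshold (kcal/mol).
#' @param hydrophilic OH2 threshold (kcal/mol).
#' @param solvent_min_dist Minimum protein distance for solvent exposure
#'   (Angstrom).
#' @param buried_rays Ray count for buriedness.
#' @return List of class `descriptor_params`.
#' @export
descriptor_params <- function(hydrophobic = -0.5, hydrophilic = -3.5,
                              solvent_min_dist = 2.2, buried_rays = 50L) {
  structure(list(hydrophobic = hydrophobic, hydrophilic = hydrophilic,
                 solvent_min_dist = solvent_min_dist,
                 buried_rays = as.integer(buried_rays)),
            class = "descriptor_params")
}

#' Compute all six descriptors for every pocket of a set
#'
#' Requires DRY and OH2 fields on the set's `volumetric_field` (computed on
#' demand if missing).
#'
#' @param pocket_set A `pocket_set`.
#' @param dparams A [descriptor_params()] object.
#' @return The `pocket_set` with `$descriptors` (named numeric vector:
#'   volume, globularity, rugosity, hydrophobic_volume,
#'   hydrophilic_volume, buried_volume, exposed_to_solvent) on each pocket.
#' @export
compute_descriptors <- function(pocket_set, dparams = descriptor_params()) {
  field <- pocket_set$field
  st <- pocket_set$structure
  all_vox <- unique(unlist(lapply(pocket_set$pockets, `[[`, "voxels")))
  for (p in c("DRY", "OH2")) {
    have <- !is.null(field$probes[[p]]) &&
      !anyNA(field$probes[[p]][all_vox])
    if (!have && length(all_vox) > 0)
      field <- compute_probe_field(field, st, p, subset = all_vox)
  }
  pocket_set$field <- field
  h <- field$spacing
  pocket_set$pockets <- lapply(pocket_set$pockets, function(pk) {
    bv <- buried_volume(pk$voxels, field, st, dparams$buried_rays)
    pk$descriptors <- c(
      volume = pk$volume,
      globularity = globularity(pk$voxels, field$dims, h),
      rugosity = rugosity(pk$voxels, field$dims, h),
      hydrophobic_volume = hydrophobic_volume(pk$voxels, field$probes$DRY,
                                              h, dparams$hydrophobic),
      hydrophilic_volume = hydrophilic_volume(pk$voxels, field$probes$OH2,
                                              h, dparams$hydrophilic),
      buried_volume = as.numeric(bv),
      low_buried_volume = attr(bv, "low_buried_volume"),
      exposed_to_solvent = exposed_to_solvent(pk$voxels, field, st,
                                              dparams$solvent_min_dist))
    pk
  })
  pocket_set
}

#' Integy moment of a small molecule
#'
#' Euclidean norm of the vector from the molecule's center of mass to the
#' centroid of its hydrophilic atoms (N, O, and H bonded to N/O when
#' hydrogens are present). Returns 0 (flagged) when no hydrophilic atom
#' exists.
#'
#' @param xyz Numeric matrix (n x 3) of atom coordinates.
#' @param elements Character vector of element symbols.
#' @return Length in Angstrom, attribute `no_hydrophilic` when flagged.
#' @export
integy_moment <- function(xyz, elements) {
  el <- toupper(elements)
  mass <- element_mass(el)
  com <- colSums(xyz * mass) / sum(mass)
  philic <- el %in% c("N", "O")
  if (!any(philic)) {
    out <- 0
    attr(out, "no_hydrophilic") <- TRUE
    return(out)
  }
  centroid <- colMeans(xyz[philic, , drop = FALSE])
  sqrt(sum((centroid - com)^2))
}

#' Reduced 3D ligand descriptor panel
#'
#' Seven interpretable shape/polarity descriptors per ligand, standing in
#' for a full MIF-derived descriptor panel: molecular weight, polar volume
#' (vdW volume of N/O atoms), hydrophobic volume (vdW volume of C/S
#' atoms), integy moment, radius of gyration, and H-bond acceptor/donor
#' counts (heavy-atom approximation: acceptors = N+O, donors = N).
#'
#' @param xyz Numeric matrix (n x 3).
#' @param elements Character vector of element symbols.
#' @return Named numeric vector.
#' @export
ligand_descriptors <- function(xyz, elements) {
  el <- toupper(elements)
  mass <- element_mass(el)
  vdw <- element_vdw(el)
  vols <- 4 / 3 * pi * vdw^3
  com <- colSums(xyz * mass) / sum(mass)
  rg <- sqrt(sum(mass * rowSums(sweep(xyz, 2, com)^2)) / sum(mass))
  c(molecular_weight = sum(mass),
    polar_volume = sum(vols[el %in% c("N", "O")]),
    hydrophobic_volume = sum(vols[el %in% c("C", "S")]),
    integy_moment = as.numeric(integy_moment(xyz, elements)),
    radius_of_gyration = rg,
    n_hba = sum(el %in% c("N", "O")),
    n_hbd = sum(el == "N"))
}

#' PCA of a ligand descriptor table
#'
#' Columns are standardized (zero mean, unit variance); constant columns
#' are dropped with a warning. Thin wrapper over [stats::prcomp()]
#' returning scores, loadings and explained-variance fractions.
#'
#' @param table Numeric matrix or data frame (ligands x descriptors).
#' @param n_components Number of components to keep (default: all).
#' @return List with `scores`, `loadings`, `explained_variance` (fractions,
#'   descending) and `dropped` (names of constant columns).
#' @export
descriptor_pca <- function(table, n_components = NULL) {
  m <- as.matrix(table)
  if (nrow(m) < 2 || ncol(m) < 2)
    stop("descriptor PCA needs at least 2 rows and 2 columns")
  sds <- apply(m, 2, sd)
  dropped <- colnames(m)[sds == 0 | is.na(sds)]
  if (length(dropped) > 0) {
    warning("dropping constant descriptor column(s): ",
            paste(dropped, collapse = ", "))
    m <- m[, !(colnames(m) %in% dropped), drop = FALSE]
  }
  if (ncol(m) < 2) stop("fewer than 2 varying columns")
  pc <- prcomp(m, center = TRUE, scale. = TRUE)
  k <- if (is.null(n_components)) ncol(pc$rotation)
       else min(n_components, ncol(pc$rotation))
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       loadings = pc$rotation[, seq_len(k), drop = FALSE],
       explained_variance = ev[seq_len(k)],
       dropped = dropped)
}

#' Export thresholded MIF surfaces
#'
#' Writes one OpenDX file per probe containing the 0/1 mask of voxels with
#' energy below the probe's display threshold (defaults: hydrophobic DRY
#' -1.0, donor N1 -4.5, acceptor O -4.5 kcal/mol).
#'
#' @param field A `volumetric_field` with the probes computed.
#' @param prefix Output path prefix; files are `<prefix>_<probe>.dx`.
#' @param thresholds Named numeric vector of display thresholds.
#' @return Character vector of written paths, invisibly.
#' @export
export_mif_surfaces <- function(field, prefix,
                                thresholds = c(DRY = -1.0, N1 = -4.5,
                                               O = -4.5)) {
  out <- character(0)
  for (p in names(thresholds)) {
    if (is.null(field$probes[[p]])) stop("probe field not computed: ", p)
    f <- field
    f$probes[[p]] <- array(as.numeric(field$probes[[p]] < thresholds[[p]]),
                           dim = field$dims)
    path <- paste0(prefix, "_", p, ".dx")
    write_dx(f, p, path)
    out <- c(out, path)
  }
  invisible(out)
}
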