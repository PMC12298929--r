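#' Pocket detection on the voxel grid
#'
#' Candidate pocket voxels ("seeds") are the exterior voxels that are both
#' sufficiently buried and hydrophobic (DRY energy below a threshold). Seeds
#' are grouped into 26-connected components and smoothed by a morphological
#' opening (erosion then dilation with a spherical structuring element),
#' which removes specks and splits thin bridges. By default each smoothed
#' cluster is then expanded to the full buried cavity that contains it
#' (geodesic reconstruction within the buried, non-interior voxel mask), so
#' that the reported pocket volume measures the cavity rather than only its
#' hydrophobic core. Finally pockets too small to hold a drug-like molecule
#' are discarded.
#'
#' @name pocket_finder
NULL

#' Pocket-detection parameters
#'
#' @param burial_min Minimum burial fraction for seed voxels.
#' @param dry_max Maximum DRY energy (kcal/mol, surrogate scale) for seed
#'   voxels.
#' @param erosion_radius,dilation_radius Structuring-element radii in
#'   voxels for the morphological opening.
#' @param min_volume Minimum pocket volume in Angstrom^3 ("large enough for
#'   a drug-like molecule").
#' @param contact_cutoff Heavy-atom distance (Angstrom) defining lining
#'   residues.
#' @param fill_buried Expand smoothed clusters to the enclosing buried
#'   cavity before measuring volume.
#' @return List of class `pocket_params`.
#' @export
pocket_params <- function(burial_min = 0.6, dry_max = -0.2,
                          erosion_radius = 1, dilation_radius = 1,
                          min_volume = 150, contact_cutoff = 4.0,
                          fill_buried = TRUE) {
  stopifnot(burial_min >= 0, burial_min <= 1, erosion_radius >= 0,
            dilation_radius >= 0, min_volume >= 0, contact_cutoff >= 0)
  structure(list(burial_min = burial_min, dry_max = dry_max,
                 erosion_radius = erosion_radius,
                 dilation_radius = dilation_radius,
                 min_volume = min_volume,
                 contact_cutoff = contact_cutoff,
                 fill_buried = fill_buried),
            class = "pocket_params")
}

#' Select buried, hydrophobic seed voxels
#'
#' @param field A `volumetric_field` with burial and DRY fields computed.
#' @param burial_min Minimum burial fraction.
#' @param dry_max Maximum DRY energy (kcal/mol).
#' @return Integer vector of linear voxel indices.
#' @export
select_seed_voxels <- function(field, burial_min = 0.6, dry_max = -0.2) {
  if (is.null(field$burial)) stop("burial field not computed")
  if (is.null(field$probes$DRY)) stop("DRY field not computed")
  which(!field$inside & field$burial >= burial_min &
          field$probes$DRY <= dry_max)
}

#' Cluster seed voxels and smooth by morphological opening
#'
#' Splits the seeds into 26-connected components, opens each component
#' (erosion then dilation by Euclidean balls of the given voxel radii),
#' drops components emptied by the erosion, and re-splits the result.
#'
#' @param seeds Integer vector of linear voxel indices.
#' @param dims Grid dimensions (length-3 integer).
#' @param erosion_radius,dilation_radius Ball radii in voxels.
#' @return List of integer vectors (sorted linear indices), one per
#'   component.
#' @export
cluster_and_smooth <- function(seeds, dims, erosion_radius = 1,
                               dilation_radius = 1) {
  dims <- as.integer(dims)
  n <- prod(dims)
  if (length(seeds) == 0) return(list())
  mask <- logical(n)
  mask[seeds] <- TRUE
  lab <- cpp_label26(mask, dims)
  out_mask <- logical(n)
  for (k in seq_len(max(lab))) {
    comp <- lab == k
    if (erosion_radius > 0) {
      er <- cpp_erode(comp, dims, erosion_radius)
      if (!any(er)) next
    } else er <- comp
    di <- if (dilation_radius > 0) cpp_dilate(er, dims, dilation_radius)
          else er
    out_mask <- out_mask | di
  }
  if (!any(out_mask)) return(list())
  relab <- cpp_label26(out_mask, dims)
  lapply(seq_len(max(relab)), function(k) which(relab == k))
}

#' Filter pockets by minimum volume
#'
#' @param pockets List of pocket objects (with `$volume`).
#' @param min_volume Minimum volume in Angstrom^3.
#' @return Filtered list, input order preserved.
#' @export
size_filter <- function(pockets, min_volume) {
  Filter(function(p) p$volume >= min_volume, pockets)
}

#' Residues lining a pocket
#'
#' Residues of the structure having at least one heavy atom within
#' `contact_cutoff` of at least one pocket voxel center.
#'
#' @param voxels Integer vector of linear voxel indices.
#' @param field The `volumetric_field` the indices refer to.
#' @param structure The `prepared_structure` sharing the field's frame.
#' @param contact_cutoff Contact distance in Angstrom.
#' @return Character vector of residue keys (`"chain:resid"`).
#' @export
lining_residues <- function(voxels, field, structure, contact_cutoff = 4.0) {
  vox <- voxel_centers(field, voxels)
  near <- cpp_atoms_near_voxels(atom_coords(structure), vox, contact_cutoff)
  res <- unique(res_key(structure$atoms$chain[near],
                        structure$atoms$resid[near],
                        structure$atoms$icode[near]))
  if (length(res) == 0)
    stop("pocket has no lining residues at contact cutoff ",
         contact_cutoff, " A")
  res
}

new_pocket <- function(voxels, field, structure, source, pparams) {
  voxels <- sort(voxels)
  structure(list(voxels = voxels,
                 volume = length(voxels) * field$spacing^3,
                 lining_residues = lining_residues(voxels, field, structure,
                                                   pparams$contact_cutoff),
                 source = source,
                 category = "unclassified",
                 descriptors = NULL,
                 ligand_occupancy = NULL),
            class = "pocket")
}

#' Detect pockets on a structure
#'
#' Runs the full detection chain: fields (burial + DRY), seed selection,
#' clustering with morphological opening, optional expansion to the buried
#' cavity, size filter, lining residues. Pockets are ordered by descending
#' volume, ties broken by smallest voxel index.
#'
#' @param structure A `prepared_structure`.
#' @param params Grid parameters ([grid_params()]).
#' @param pparams Pocket parameters ([pocket_params()]).
#' @param source Label recorded on each pocket (`"detached_partner_A"`,
#'   `"detached_partner_B"` or `"complex"`).
#' @param field Optional precomputed `volumetric_field` (with burial and
#'   DRY) to reuse.
#' @return Object of class `pocket_set`: list with `pockets`, `field`,
#'   `structure`, `params`, `pparams`.
#' @export
find_pockets <- function(structure, params = grid_params(),
                         pparams = pocket_params(),
                         source = "complex", field = NULL) {
  if (is.null(field)) {
    field <- build_grid(structure, params)
    field <- compute_burial(field, structure, params)
    # DRY is only consulted where the burial criterion can hold
    candidates <- which(!field$inside & field$burial >= pparams$burial_min)
    field <- compute_probe_field(field, structure, "DRY", params,
                                 subset = candidates)
  }
  seeds <- select_seed_voxels(field, pparams$burial_min, pparams$dry_max)
  comps <- cluster_and_smooth(seeds, field$dims, pparams$erosion_radius,
                              pparams$dilation_radius)
  if (length(comps) > 0 && pparams$fill_buried) {
    fillable <- as.logical(!field$inside & field$burial >= pparams$burial_min)
    markers <- logical(prod(field$dims))
    markers[unlist(comps)] <- TRUE
    filled <- cpp_reconstruct(markers, fillable, as.integer(field$dims))
    relab <- cpp_label26(filled, as.integer(field$dims))
    comps <- if (max(relab) == 0) list()
             else lapply(seq_len(max(relab)), function(k) which(relab == k))
  }
  pockets <- lapply(comps, new_pocket, field = field, structure = structure,
                    source = source, pparams = pparams)
  pockets <- size_filter(pockets, pparams$min_volume)
  # deterministic ordering: descending volume, then smallest voxel index
  if (length(pockets) > 1) {
    ord <- order(-vapply(pockets, `[[`, numeric(1), "volume"),
                 vapply(pockets, function(p) p$voxels[1], numeric(1)))
    pockets <- pockets[ord]
  }
  for (i in seq_along(pockets)) pockets[[i]]$id <- sprintf("P%02d", i)
  structure(list(pockets = pockets, field = field, structure = structure,
                 params = params, pparams = pparams, source = source),
            class = "pocket_set")
}

#' @export
print.pocket_set <- function(x, ...) {
  cat("pocket set (", x$source, "): ", length(x$pockets), " pocket(s)\n",
      sep = "")
  for (p in x$pockets)
    cat(sprintf("  %s  volume %.1f A^3  %d voxels  %d lining residues  [%s]\n",
                p$id, p$volume, length(p$voxels),
                length(p$lining_residues), p$category))
  invisible(x)
}

#' @export
print.pocket <- function(x, ...) {
  cat(sprintf("pocket %s (%s): volume %.1f A^3, %d voxels, category %s\n",
              if (is.null(x$id)) "?" else x$id, x$source, x$volume,
              length(x$voxels), x$category))
  invisible(x)
}

#' Summarise a pocket set as a data frame
#'
#' @param object A `pocket_set`.
#' @param ... Unused.
#' @return Data frame with one row per pocket (id, source, volume,
#'   n_voxels, category, lining residues).
#' @export
summary.pocket_set <- function(object, ...) {
  ps <- object$pockets
  data.frame(
    pocket_id = vapply(ps, function(p) p$id, character(1)),
    source = vapply(ps, function(p) p$source, character(1)),
    volume = vapply(ps, function(p) p$volume, numeric(1)),
    n_voxels = vapply(ps, function(p) length(p$voxels), integer(1)),
    category = vapply(ps, function(p) p$category, character(1)),
    residues = vapply(ps, function(p)
      paste(p$lining_residues, collapse = ";"), character(1)),
    stringsAsFactors = FALSE)
}

#' Write pocket voxels as PDB pseudo-atoms
#'
#' One HETATM record per voxel center (residue name PKT, one residue per
#' pocket), for visual inspection alongside the protein.
#'
#' @param pocket_set A `pocket_set`.
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_pocket_pdb <- function(pocket_set, path) {
  lines <- character(0)
  serial <- 0L
  for (i in seq_along(pocket_set$pockets)) {
    p <- pocket_set$pockets[[i]]
    vox <- voxel_centers(pocket_set$field, p$voxels)
    for (j in seq_len(nrow(vox))) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "HETATM%5d  C   PKT P%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial %% 100000L, i %% 10000L, vox[j, 1], vox[j, 2], vox[j, 3]))
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
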