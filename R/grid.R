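#' Voxel grids, burial and surrogate probe fields
#'
#' A structure is embedded in an axis-aligned voxel grid. Two per-voxel
#' quantities drive pocket detection: *burial*, the fraction of rays cast
#' from the voxel center (fixed Fibonacci-sphere direction set) that hit a
#' protein atom within a cutoff, and probe interaction energies from a
#' surrogate molecular-interaction-field model. Five probes are exposed,
#' named after their GRID counterparts: H (shape), DRY (hydrophobic), OH2
#' (water-like polar), O (H-bond acceptor), N1 (H-bond donor). The energy
#' model is a documented surrogate -- a 6-12 pair potential with probe- and
#' element-dependent well depths plus a flat polar bonus for the polar
#' probes near N/O atoms -- not a reimplementation of any proprietary force
#' field; the detection thresholds are therefore configuration keys defined
#' on this surrogate's kcal/mol scale.
#'
#' @name mif_grid
NULL

.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                H = 1.10, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
                SE = 1.90, MG = 1.73, ZN = 1.39, FE = 1.40, MN = 1.40,
                CA = 1.75, `NA` = 2.27, K = 2.75)
.vdw_default <- 1.70

element_vdw <- function(element) {
  r <- .vdw_radii[toupper(element)]
  r[is.na(r)] <- .vdw_default
  unname(r)
}

#' Grid parameters
#'
#' @param spacing Voxel edge length in Angstrom.
#' @param padding Margin added around the structure bounding box (Angstrom);
#'   must cover the probe interaction cutoff.
#' @param burial_rays Number of ray directions for burial (fixed
#'   Fibonacci-sphere set, deterministic).
#' @param burial_threshold Burial fraction above which a voxel counts as
#'   buried in downstream pocket detection.
#' @param probe_set Probes to compute, subset of H, DRY, OH2, O, N1.
#' @param burial_cutoff Maximum ray length in Angstrom.
#' @param probe_cutoff Pair-potential cutoff in Angstrom.
#' @return List of class `grid_params`.
#' @export
grid_params <- function(spacing = 0.8, padding = 6, burial_rays = 50L,
                        burial_threshold = 0.6,
                        probe_set = c("H", "DRY", "OH2", "O", "N1"),
                        burial_cutoff = 12, probe_cutoff = 8) {
  if (spacing <= 0) stop("spacing must be > 0")
  stopifnot(padding >= 0, burial_rays >= 1, burial_cutoff > 0,
            burial_threshold >= 0, burial_threshold <= 1)
  probe_set <- match.arg(probe_set, c("H", "DRY", "OH2", "O", "N1"),
                         several.ok = TRUE)
  structure(list(spacing = spacing, padding = padding,
                 burial_rays = as.integer(burial_rays),
                 burial_threshold = burial_threshold,
                 probe_set = probe_set,
                 burial_cutoff = burial_cutoff,
                 probe_cutoff = probe_cutoff),
            class = "grid_params")
}

#' Surrogate probe parameters
#'
#' Well depths (kcal/mol), probe radii (Angstrom) and polar bonus terms of
#' the surrogate interaction model, one row per probe. `eps` scales the
#' attractive 6-12 well against C/N/O/S atoms; for DRY the attractive term
#' is applied only to C and S atoms (hydrophobic contacts) while polar
#' atoms contribute a weak repulsive core only. Polar probes (OH2, O, N1)
#' additionally receive a flat `bonus` for every matching polar protein
#' atom within `polar_cut` Angstrom: OH2 near any N/O, the acceptor probe O
#' near donor N, the donor probe N1 near acceptor O.
#'
#' @return Data frame of probe parameters.
#' @export
probe_params <- function() {
  data.frame(
    probe = c("H", "DRY", "OH2", "O", "N1"),
    radius = c(1.20, 1.70, 1.40, 1.40, 1.45),
    eps = c(0.03, 0.12, 0.08, 0.08, 0.08),
    bonus = c(0, 0, 1.2, 1.5, 1.5),
    polar_cut = c(0, 0, 3.5, 3.5, 3.5),
    stringsAsFactors = FALSE)
}

#' Build the voxel grid around a structure
#'
#' The grid covers the structure bounding box plus `padding` on every side.
#' Voxels overlapping the protein van der Waals volume are masked as
#' interior.
#'
#' @param structure A `prepared_structure`.
#' @param params A [grid_params()] object.
#' @return An object of class `volumetric_field`: origin, spacing, dims,
#'   logical `inside` array, and empty slots for `burial` and `probes`.
#' @export
build_grid <- function(structure, params = grid_params()) {
  stopifnot(inherits(structure, "prepared_structure"))
  if (nrow(structure$atoms) == 0) stop("empty structure")
  if (params$spacing <= 0) stop("spacing must be > 0")
  xyz <- atom_coords(structure)
  lo <- unname(apply(xyz, 2, min)) - params$padding
  hi <- unname(apply(xyz, 2, max)) + params$padding
  dims <- as.integer(floor((hi - lo) / params$spacing + 1e-9)) + 1L
  field <- structure(list(origin = lo, spacing = params$spacing,
                          dims = dims, params = params,
                          inside = NULL, burial = NULL,
                          probes = list()),
                     class = "volumetric_field")
  vox <- voxel_centers(field)
  radii <- element_vdw(structure$atoms$element)
  inside <- cpp_inside_mask(vox, xyz, radii)
  field$inside <- array(inside, dim = dims)
  field
}

# matrix of all voxel centers in array order (x fastest)
voxel_centers <- function(field, idx = NULL) {
  d <- field$dims
  if (is.null(idx)) {
    ix <- rep(seq_len(d[1]), times = d[2] * d[3])
    iy <- rep(rep(seq_len(d[2]), each = d[1]), times = d[3])
    iz <- rep(seq_len(d[3]), each = d[1] * d[2])
  } else {
    a <- arrayInd(idx, d)
    ix <- a[, 1]; iy <- a[, 2]; iz <- a[, 3]
  }
  cbind(field$origin[1] + (ix - 1) * field$spacing,
        field$origin[2] + (iy - 1) * field$spacing,
        field$origin[3] + (iz - 1) * field$spacing)
}

# linear voxel index containing each point (NA outside grid)
point_to_voxel <- function(field, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  d <- field$dims
  ii <- round(sweep(xyz, 2, field$origin, "-") / field$spacing) + 1
  ok <- ii[, 1] >= 1 & ii[, 1] <= d[1] &
        ii[, 2] >= 1 & ii[, 2] <= d[2] &
        ii[, 3] >= 1 & ii[, 3] <= d[3]
  out <- rep(NA_integer_, nrow(xyz))
  out[ok] <- as.integer(ii[ok, 1] + d[1] * ((ii[ok, 2] - 1) +
                                              d[2] * (ii[ok, 3] - 1)))
  out
}

#' Compute per-voxel burial by ray casting
#'
#' Burial at a voxel is the fraction of `burial_rays` fixed directions
#' whose ray hits a protein atom (van der Waals sphere) within
#' `burial_cutoff` Angstrom. Interior voxels get burial 1; voxels farther
#' than the cutoff from every atom get 0 without casting rays.
#'
#' @param field A `volumetric_field` built for `structure`.
#' @param structure The same `prepared_structure`.
#' @param params Grid parameters (defaults to those stored in `field`).
#' @return The field with `$burial` filled (array in \[0, 1\]).
#' @export
compute_burial <- function(field, structure, params = field$params) {
  stopifnot(inherits(field, "volumetric_field"))
  d <- field$dims
  xyz <- atom_coords(structure)
  radii <- element_vdw(structure$atoms$element)
  burial <- array(0, dim = d)
  burial[field$inside] <- 1
  todo <- which(!field$inside)
  if (length(todo) > 0) {
    vox <- voxel_centers(field, todo)
    # skip voxels with no atom within reach
    dmin <- cpp_min_atom_dist(vox, xyz)
    reach <- dmin <= params$burial_cutoff + max(radii)
    if (any(reach)) {
      dirs <- fibonacci_directions(params$burial_rays)
      burial[todo[reach]] <- cpp_ray_burial(vox[reach, , drop = FALSE],
                                            xyz, radii, dirs,
                                            params$burial_cutoff)
    }
  }
  field$burial <- burial
  field
}

#' Compute a surrogate probe field
#'
#' Fills `field$probes[[probe]]` with the surrogate interaction energy
#' (kcal/mol, attractive negative) at every non-interior voxel; interior
#' voxels carry an `Inf` sentinel.
#'
#' @param field A `volumetric_field` built for `structure`.
#' @param structure The same `prepared_structure`.
#' @param probe One of `"H"`, `"DRY"`, `"OH2"`, `"O"`, `"N1"`.
#' @param params Grid parameters (defaults to those stored in `field`).
#' @param probe_table Parameter table, see [probe_params()].
#' @param subset Optional integer vector of linear voxel indices to
#'   evaluate (others are left `NA`, or untouched if the probe array
#'   already exists); by default every non-interior voxel is evaluated.
#' @return The field with the probe energy array added.
#' @export
compute_probe_field <- function(field, structure, probe,
                                params = field$params,
                                probe_table = probe_params(),
                                subset = NULL) {
  stopifnot(inherits(field, "volumetric_field"))
  row <- probe_table[probe_table$probe == probe, ]
  if (nrow(row) != 1) stop("unknown probe: ", probe)
  el <- toupper(structure$atoms$element)
  rmin <- element_vdw(el) + row$radius
  eps_att <- rep(row$eps, length(el))
  eps_rep <- rep(row$eps, length(el))
  if (probe == "DRY") {
    polar <- !(el %in% c("C", "S"))
    eps_att[polar] <- 0
    eps_rep[polar] <- 0.05
  }
  bonus <- rep(0, length(el))
  if (row$bonus > 0) {
    target <- switch(probe,
                     OH2 = c("N", "O"),
                     O = "N",
                     N1 = "O",
                     character(0))
    bonus[el %in% target] <- row$bonus
  }
  d <- field$dims
  energy <- if (!is.null(field$probes[[probe]])) field$probes[[probe]]
            else array(NA_real_, dim = d)
  energy[field$inside] <- Inf
  todo <- if (is.null(subset)) which(!field$inside)
          else subset[!field$inside[subset]]
  if (length(todo) > 0) {
    vox <- voxel_centers(field, todo)
    energy[todo] <- cpp_probe_energy(vox, atom_coords(structure),
                                     eps_att, eps_rep, rmin, bonus,
                                     row$polar_cut, params$probe_cutoff)
  }
  field$probes[[probe]] <- energy
  field
}

#' Compute all fields needed for pocket detection
#'
#' Convenience wrapper: builds the grid, the burial field and the probe
#' fields in `params$probe_set`.
#'
#' @inheritParams build_grid
#' @param probes Probes to compute (default: `params$probe_set`).
#' @return A fully populated `volumetric_field`.
#' @export
compute_fields <- function(structure, params = grid_params(),
                           probes = params$probe_set) {
  field <- build_grid(structure, params)
  field <- compute_burial(field, structure, params)
  for (p in probes)
    field <- compute_probe_field(field, structure, p, params)
  field
}

#' @export
print.volumetric_field <- function(x, ...) {
  cat("volumetric field:", paste(x$dims, collapse = " x "),
      "voxels at", x$spacing, "A spacing\n")
  cat("  origin:", paste(sprintf("%.2f", x$origin), collapse = ", "), "\n")
  cat("  burial:", if (is.null(x$burial)) "not computed" else "computed",
      " probes:", if (length(x$probes) == 0) "none"
      else paste(names(x$probes), collapse = ", "), "\n")
  invisible(x)
}

#' Export a scalar field in OpenDX volumetric text format
#'
#' @param field A `volumetric_field`.
#' @param what `"burial"` or a probe name present in the field.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dx <- function(field, what, path) {
  vals <- if (what == "burial") field$burial else field$probes[[what]]
  if (is.null(vals)) stop("field '", what, "' not computed")
  d <- field$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.4f %.4f %.4f", field$origin[1], field$origin[2],
            field$origin[3]),
    sprintf("delta %.4f 0 0", field$spacing),
    sprintf("delta 0 %.4f 0", field$spacing),
    sprintf("delta 0 0 %.4f", field$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  # OpenDX stores z fastest; permute from R's x-fastest order
  v <- aperm(vals, c(3, 2, 1))
  v[!is.finite(v)] <- 999
  writeLines(apply(matrix(c(as.numeric(v),
                            rep(NA, (3 - prod(d) %% 3) %% 3)),
                          nrow = 3),
                   2, function(r) paste(signif(r[!is.na(r)], 6),
                                        collapse = " ")), con)
  invisible(path)
}
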