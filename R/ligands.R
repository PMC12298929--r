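#' Ligand transfer from superposed homologs
#'
#' Homologous structures of the same protein are rigidly superposed onto
#' the analysis frame (least-squares Kabsch fit on paired CA atoms);
#' alignments worse than an RMSD cutoff are discarded. HETATM ligands of
#' the retained homologs -- excluding cofactors, metals and crystallization
#' artifacts -- are transformed into the analysis frame, and a pocket is
#' called ligand-bound when more than 30% of a ligand's heavy atoms fall
#' inside its voxels.
#'
#' @name ligand_occupancy
NULL

.metal_resnames <- c("MG", "ZN", "CA", "NA", "K", "FE", "FE2", "MN", "CU",
                     "CU1", "NI", "CO", "CD", "HG", "MO", "PT", "AU", "AG",
                     "LI", "SR", "BA", "RB", "CS", "AL", "PB", "W", "YB",
                     "SM", "GD", "TB", "LU", "CR", "V", "TI", "ZR", "PD",
                     "RH", "RU", "OS", "IR", "RE")

#' Least-squares rigid superposition (Kabsch)
#'
#' Pairs CA atoms of the shared chain(s) by residue key and computes the
#' proper rotation + translation minimizing the RMSD of mobile onto
#' reference. Reflections are corrected to proper rotations.
#'
#' @param mobile,reference `prepared_structure` objects sharing residue
#'   numbering on at least one chain.
#' @return Object of class `superposition`: `rotation` (3x3, det +1),
#'   `translation`, `rmsd` (Angstrom over paired CAs), `n_paired_atoms`.
#' @export
superpose <- function(mobile, reference) {
  key_m <- with(mobile$atoms, res_key(chain, resid, icode))
  key_r <- with(reference$atoms, res_key(chain, resid, icode))
  ca_m <- mobile$atoms$elety == "CA" & !mobile$atoms$het
  ca_r <- reference$atoms$elety == "CA" & !reference$atoms$het
  mm <- mobile$atoms[ca_m, ]; mk <- key_m[ca_m]
  rr <- reference$atoms[ca_r, ]; rk <- key_r[ca_r]
  shared <- intersect(mk, rk)
  if (length(shared) < 3)
    stop("need at least 3 pairable CA atoms, found ", length(shared))
  P <- as.matrix(mm[match(shared, mk), c("x", "y", "z")])
  Q <- as.matrix(rr[match(shared, rk), c("x", "y", "z")])
  kabsch_fit(P, Q)
}

# core Kabsch fit of point set P (mobile) onto Q (reference), rows paired
kabsch_fit <- function(P, Q) {
  cm_p <- colMeans(P)
  cm_q <- colMeans(Q)
  Pc <- sweep(P, 2, cm_p)
  Qc <- sweep(Q, 2, cm_q)
  H <- t(Pc) %*% Qc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  translation <- as.numeric(cm_q - R %*% cm_p)
  moved <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Qc)^2)))
  structure(list(rotation = R, translation = translation, rmsd = rmsd,
                 n_paired_atoms = nrow(P)),
            class = "superposition")
}

#' Apply a superposition to coordinates
#'
#' @param sp A `superposition`.
#' @param xyz Numeric matrix (n x 3) or a `prepared_structure`.
#' @return Transformed coordinates (or structure).
#' @export
apply_superposition <- function(sp, xyz) {
  if (inherits(xyz, "prepared_structure")) {
    m <- apply_superposition(sp, atom_coords(xyz))
    xyz$atoms$x <- m[, 1]; xyz$atoms$y <- m[, 2]; xyz$atoms$z <- m[, 3]
    return(xyz)
  }
  xyz %*% t(sp$rotation) +
    matrix(sp$translation, nrow(xyz), 3, byrow = TRUE)
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: %d paired CA atoms, rmsd %.3f A\n",
              x$n_paired_atoms, x$rmsd))
  invisible(x)
}

#' Filter superpositions by alignment quality
#'
#' Retains alignments with `rmsd <= max_rmsd` (inclusive at the boundary).
#' Poor alignments must not transfer ligands into the analysis frame.
#'
#' @param superpositions List of `superposition` objects.
#' @param max_rmsd Cutoff in Angstrom.
#' @return Filtered list.
#' @export
rmsd_filter <- function(superpositions, max_rmsd = 3.0) {
  Filter(function(s) s$rmsd <= max_rmsd, superpositions)
}

#' Harvest ligand poses from a (superposed) homolog
#'
#' Every HETATM residue becomes a candidate pose with coordinates mapped
#' through `transform`. Cofactors, metals and crystallization artifacts
#' (including waters) are excluded, as are fragments below
#' `min_heavy_atoms`; excluded poses carry a reason and are dropped unless
#' `include_excluded = TRUE`.
#'
#' @param structure A `prepared_structure`-like object whose atom table
#'   still contains HETATM ligands (e.g. a raw structure passed through
#'   [read_structure()], or a synthetic homolog).
#' @param transform Optional `superposition` mapping the homolog into the
#'   analysis frame (`NULL` = identity).
#' @param cofactor_whitelist,artifact_blacklist,metal_list Exclusion lists.
#' @param min_heavy_atoms Minimum heavy atoms for a harvested ligand.
#' @param include_excluded Keep excluded poses (flagged) in the result.
#' @return List of `ligand_pose` objects: `ligand_id`, `resname`, `source`,
#'   `atoms` (n x 3 transformed heavy atoms), `n_atoms`, `excluded`,
#'   `reason`.
#' @export
harvest_ligands <- function(structure, transform = NULL,
                            cofactor_whitelist = default_cofactors(),
                            artifact_blacklist = default_artifacts(),
                            metal_list = .metal_resnames,
                            min_heavy_atoms = 6,
                            include_excluded = FALSE) {
  atoms <- raw_atoms(structure)
  src <- if (is.list(structure) && !is.null(structure$source))
    structure$source else "ligand source"
  het <- atoms[atoms$het & toupper(atoms$element) != "H", , drop = FALSE]
  poses <- list()
  if (nrow(het) > 0) {
    keys <- res_key(het$chain, het$resid, het$icode)
    for (k in unique(keys)) {
      sel <- keys == k
      rn <- het$resname[sel][1]
      xyz <- as.matrix(het[sel, c("x", "y", "z")])
      if (!is.null(transform)) xyz <- apply_superposition(transform, xyz)
      reason <- if (rn %in% .water_resnames) "artifact"
                else if (rn %in% metal_list) "metal"
                else if (rn %in% cofactor_whitelist) "cofactor"
                else if (rn %in% artifact_blacklist) "artifact"
                else if (nrow(xyz) < min_heavy_atoms) "too_few_atoms"
                else ""
      poses[[length(poses) + 1]] <- structure(
        list(ligand_id = paste0(rn, ":", k, "@", src),
             resname = rn, source = src, atoms = xyz,
             n_atoms = nrow(xyz),
             excluded = nzchar(reason), reason = reason),
        class = "ligand_pose")
    }
  }
  if (!include_excluded) poses <- Filter(function(p) !p$excluded, poses)
  poses
}

#' Fraction of a ligand inside a pocket
#'
#' Fraction of the pose's heavy-atom centers that fall inside pocket
#' voxels ("30% of the atomic structure" convention, not volumetric
#' intersection).
#'
#' @param pose A `ligand_pose` in the analysis frame.
#' @param pocket A `pocket`.
#' @param field The `volumetric_field` the pocket voxels refer to.
#' @return Fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(pose, pocket, field) {
  idx <- point_to_voxel(field, pose$atoms)
  mean(!is.na(idx) & idx %in% pocket$voxels)
}

#' Mark a pocket ligand-bound
#'
#' Records every non-excluded pose whose overlap fraction strictly exceeds
#' `threshold`; the pocket is ligand-bound iff at least one such pose
#' exists.
#'
#' @param pocket A `pocket`.
#' @param poses List of `ligand_pose` objects (analysis frame).
#' @param field The pocket's `volumetric_field`.
#' @param threshold Strict overlap threshold (default 0.3).
#' @return The pocket with `ligand_occupancy` (data frame ligand_id /
#'   fraction) and `ligand_bound` filled.
#' @export
mark_ligand_bound <- function(pocket, poses, field, threshold = 0.3) {
  poses <- Filter(function(p) !p$excluded, poses)
  fr <- vapply(poses, overlap_fraction, numeric(1),
               pocket = pocket, field = field)
  ids <- vapply(poses, function(p) p$ligand_id, character(1))
  keep <- fr > threshold
  pocket$ligand_occupancy <- data.frame(ligand_id = ids[keep],
                                        overlap_fraction = fr[keep],
                                        stringsAsFactors = FALSE)
  pocket$ligand_bound <- any(keep)
  pocket
}

#' Map crystallographic-ligand occupancy over a homolog set
#'
#' For each homolog: superpose onto the reference, drop alignments with
#' RMSD above `max_rmsd`, harvest its ligands into the analysis frame,
#' then score every pocket.
#'
#' @param pocket_set A classified `pocket_set` (its structure is the
#'   reference frame).
#' @param homologs List of structures (with HETATM ligands) to superpose.
#' @param reference Reference `prepared_structure`; defaults to the pocket
#'   set's structure.
#' @param max_rmsd Alignment RMSD cutoff (Angstrom).
#' @param threshold Strict ligand-bound overlap threshold.
#' @param ... Passed to [harvest_ligands()].
#' @return List: updated `pocket_set`, `poses`, and `ligand_table` (one row
#'   per retained pose with its best pocket and bound flag).
#' @export
map_ligand_occupancy <- function(pocket_set, homologs,
                                 reference = pocket_set$structure,
                                 max_rmsd = 3.0, threshold = 0.3, ...) {
  poses <- list()
  for (h in homologs) {
    sp <- superpose(h, reference)
    if (sp$rmsd > max_rmsd) next
    poses <- c(poses, harvest_ligands(h, transform = sp, ...))
  }
  ps <- pocket_set$pockets
  for (i in seq_along(ps))
    ps[[i]] <- mark_ligand_bound(ps[[i]], poses, pocket_set$field, threshold)
  pocket_set$pockets <- ps
  rows <- lapply(poses, function(p) {
    fr <- vapply(ps, function(pk) overlap_fraction(p, pk, pocket_set$field),
                 numeric(1))
    best <- if (length(fr) > 0) which.max(fr) else NA_integer_
    data.frame(ligand_id = p$ligand_id, resname = p$resname,
               n_atoms = p$n_atoms,
               best_pocket = if (is.na(best)) NA_character_
                             else ps[[best]]$id,
               overlap_fraction = if (is.na(best)) NA_real_ else fr[best],
               bound = if (is.na(best)) FALSE else fr[best] > threshold,
               stringsAsFactors = FALSE)
  })
  ligand_table <- if (length(rows) > 0) do.call(rbind, rows)
    else data.frame(ligand_id = character(), resname = character(),
                    n_atoms = integer(), best_pocket = character(),
                    overlap_fraction = numeric(), bound = logical())
  list(pocket_set = pocket_set, poses = poses, ligand_table = ligand_table)
}

#' Join a local ligand annotation table
#'
#' Adds clinical phase / ATC class annotations from a local table
#' (columns `ligand` = residue name, `phase`, `atc`), replacing live
#' database lookups. Unannotated ligands get phase `"no_data"`.
#'
#' @param ligand_table Output of [map_ligand_occupancy()].
#' @param annotation Data frame with columns `ligand`, `phase` and
#'   optionally `atc`.
#' @return The ligand table with `phase` and `atc` columns.
#' @export
annotate_ligands <- function(ligand_table, annotation) {
  stopifnot(all(c("ligand", "phase") %in% names(annotation)))
  m <- match(ligand_table$resname, annotation$ligand)
  ligand_table$phase <- ifelse(is.na(m), "no_data", annotation$phase[m])
  ligand_table$atc <- if ("atc" %in% names(annotation))
    ifelse(is.na(m), NA_character_, annotation$atc[m]) else NA_character_
  ligand_table
}
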