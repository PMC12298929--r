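#' Pocket classification: interface, allosteric-like, equilibrium
#'
#' Pockets detected on a detached partner are *interface* pockets when the
#' fraction of the interacting partner contained in the pocket is strictly
#' greater than a threshold (default 0), and *allosteric-like* otherwise.
#' Pockets detected on the whole complex are *equilibrium* pockets when
#' their lining residues are contributed by both partners; they exist only
#' in the bound form. The partner fraction is operationalized as the
#' fraction of partner heavy-atom centers lying inside pocket voxels --
#' exact, order-independent and directly checkable against constructed
#' geometry.
#'
#' @name pocket_classes
NULL

#' Classification rule
#'
#' @param partner_fraction_threshold Strict lower bound on the partner
#'   fraction for the interface call; must lie in `[0, 1)`.
#' @return List of class `classification_rule`.
#' @export
classification_rule <- function(partner_fraction_threshold = 0) {
  if (partner_fraction_threshold < 0 || partner_fraction_threshold >= 1)
    stop("partner_fraction_threshold must be in [0, 1)")
  structure(list(partner_fraction_threshold = partner_fraction_threshold),
            class = "classification_rule")
}

#' Fraction of the partner contained in a pocket
#'
#' Fraction of the partner's heavy-atom centers that fall inside pocket
#' voxels, evaluated in the complex frame. If the partner lies entirely
#' outside the pocket's grid (beyond the padding), a warning is issued and
#' 0 is returned.
#'
#' @param pocket A `pocket` detected on a detached partner.
#' @param field The `volumetric_field` of that detection.
#' @param partner The other partner as a `prepared_structure` (same frame).
#' @return Fraction in `[0, 1]`.
#' @export
partner_fraction <- function(pocket, field, partner) {
  xyz <- atom_coords(partner)
  lo <- field$origin
  hi <- field$origin + (field$dims - 1) * field$spacing
  if (all(apply(xyz, 2, min) > hi + field$params$padding) ||
      all(apply(xyz, 2, max) < lo - field$params$padding)) {
    warning("partner bounding box is disjoint from the pocket grid; ",
            "returning partner fraction 0")
    return(0)
  }
  idx <- point_to_voxel(field, xyz)
  mean(!is.na(idx) & idx %in% pocket$voxels)
}

#' Classify a detached-partner pocket
#'
#' @param pocket A `pocket` with `source` `"detached_partner_A"` or
#'   `"detached_partner_B"`.
#' @param field The detection field of that pocket.
#' @param partner The interacting partner (`prepared_structure`).
#' @param rule A [classification_rule()].
#' @return The pocket with `category` set to `"interface"` or
#'   `"allosteric_like"` and `partner_fraction` recorded.
#' @export
classify_detached <- function(pocket, field, partner,
                              rule = classification_rule()) {
  if (!pocket$source %in% c("detached_partner_A", "detached_partner_B"))
    stop("classify_detached() expects a pocket from a detached partner, got ",
         pocket$source)
  f <- partner_fraction(pocket, field, partner)
  pocket$partner_fraction <- f
  pocket$category <- if (f > rule$partner_fraction_threshold) "interface"
                     else "allosteric_like"
  pocket
}

#' Classify a complex pocket
#'
#' @param pocket A `pocket` with `source == "complex"`.
#' @param chain_of_residue Named character vector mapping residue keys to
#'   chain ids; defaults to parsing the `"chain:resid"` keys.
#' @return The pocket with `category` `"equilibrium"` (lining residues from
#'   both chains) or `"unclassified"`.
#' @export
classify_complex <- function(pocket, chain_of_residue = NULL) {
  if (pocket$source != "complex")
    stop("classify_complex() expects a pocket detected on the complex, got ",
         pocket$source)
  res <- pocket$lining_residues
  chains <- if (is.null(chain_of_residue)) {
    sub(":.*$", "", res)
  } else {
    unknown <- setdiff(res, names(chain_of_residue))
    if (length(unknown) > 0)
      stop("unknown residue chain for: ", paste(unknown, collapse = ", "))
    unname(chain_of_residue[res])
  }
  pocket$category <- if (length(unique(chains)) >= 2) "equilibrium"
                     else "unclassified"
  pocket
}

#' Per-partner residue share of an equilibrium pocket
#'
#' @param pocket An equilibrium `pocket`.
#' @return Named numeric vector of per-chain fractions of the lining
#'   residues (sums to 1).
#' @export
partner_residue_share <- function(pocket) {
  if (!identical(pocket$category, "equilibrium"))
    stop("partner_residue_share() is defined for equilibrium pockets only")
  chains <- sub(":.*$", "", pocket$lining_residues)
  tab <- table(chains)
  share <- as.numeric(tab) / sum(tab)
  names(share) <- names(tab)
  share
}

#' Classify every pocket of a detached or complex detection
#'
#' @param pocket_set A `pocket_set` from [find_pockets()].
#' @param partner For detached detections: the other partner
#'   (`prepared_structure`). Ignored for complex detections.
#' @param rule A [classification_rule()].
#' @return The `pocket_set` with categories filled.
#' @export
classify_pockets <- function(pocket_set, partner = NULL,
                             rule = classification_rule()) {
  ps <- pocket_set$pockets
  for (i in seq_along(ps)) {
    if (ps[[i]]$source == "complex") {
      ps[[i]] <- classify_complex(ps[[i]])
    } else {
      if (is.null(partner))
        stop("partner structure required to classify detached-partner pockets")
      ps[[i]] <- classify_detached(ps[[i]], pocket_set$field, partner, rule)
    }
  }
  pocket_set$pockets <- ps
  pocket_set
}
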