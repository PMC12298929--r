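#' MCC validation and per-cancer interaction networks
#'
#' Pocket-residue predictions are validated against crystallographically
#' observed binding residues with the Matthews correlation coefficient over
#' a residue-level confusion matrix (+1 ideal, 0 random, -1 inverted).
#' Interactions are assembled into one undirected network per cancer type;
#' a protein is a hub when it has two or more interaction partners, and
#' nodes carry interface / allosteric-like pocket counts.
#'
#' @name metrics_network
NULL

#' Residues of a structure in contact with a binder
#'
#' @param structure A `prepared_structure`.
#' @param binder A `prepared_structure` (partner chain, ligand or degrader)
#'   in the same frame, or an n x 3 coordinate matrix.
#' @param cutoff Heavy-atom contact distance (Angstrom).
#' @return Character vector of residue keys.
#' @export
observed_contact_residues <- function(structure, binder, cutoff = 5.0) {
  bxyz <- if (is.matrix(binder)) binder else atom_coords(binder)
  if (nrow(bxyz) == 0) stop("empty binder")
  near <- cpp_atoms_near_voxels(atom_coords(structure), bxyz, cutoff)
  unique(res_key(structure$atoms$chain[near], structure$atoms$resid[near],
                 structure$atoms$icode[near]))
}

#' Matthews correlation coefficient for residue predictions
#'
#' @param predicted,observed Character vectors of residue keys, both
#'   subsets of `universe`.
#' @param universe All residues considered (defaults: union of predicted
#'   and observed is not allowed -- pass the evaluated chain's residues).
#' @return Object of class `residue_comparison`: tp, fp, fn, tn, `mcc`
#'   in `[-1, 1]`, and `degenerate` flag (TRUE when a confusion-matrix
#'   margin is empty and the MCC is reported as 0).
#' @export
compute_mcc <- function(predicted, observed, universe) {
  if (length(universe) == 0) stop("empty universe")
  predicted <- unique(predicted)
  observed <- unique(observed)
  if (!all(predicted %in% universe))
    stop("predicted residues not all contained in universe")
  if (!all(observed %in% universe))
    stop("observed residues not all contained in universe")
  tp <- length(intersect(predicted, observed))
  fp <- length(setdiff(predicted, observed))
  fn <- length(setdiff(observed, predicted))
  tn <- length(universe) - tp - fp - fn
  denom <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  degenerate <- denom == 0
  mcc <- if (degenerate) 0 else (tp * tn - fp * fn) / denom
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, mcc = mcc,
                 degenerate = degenerate,
                 predicted = predicted, observed = observed,
                 n_universe = length(universe)),
            class = "residue_comparison")
}

#' @export
print.residue_comparison <- function(x, ...) {
  cat(sprintf("residue comparison: tp %d fp %d fn %d tn %d -> MCC %.3f%s\n",
              x$tp, x$fp, x$fn, x$tn, x$mcc,
              if (x$degenerate) " (degenerate margin, reported 0)" else ""))
  invisible(x)
}

.cancer_types <- c("BRCA", "COAD", "HNSC", "KIRC", "KIRP", "LIHC",
                   "LUAD", "LUSC", "PRAD", "STAD", "THCA", "UCEC")

#' Build the interaction network for one cancer type
#'
#' @param interactions Data frame with columns `protein_a`, `protein_b`,
#'   `cancer_types` (semicolon-separated labels). Rows not matching
#'   `cancer_type` are ignored. Duplicate edges are collapsed with a
#'   warning. Homodimers become self-loops and count as one partner.
#' @param pocket_summary Optional data frame with columns `protein`,
#'   `n_interface_pockets`, `n_allosteric_pockets`; missing proteins are
#'   zero-filled.
#' @param cancer_type Cancer label (e.g. `"BRCA"`).
#' @return Object of class `cancer_network`: `cancer_type`, `graph`
#'   (igraph), `nodes` (data frame with degree, hub flag, pocket counts),
#'   `edges`.
#' @export
build_network <- function(interactions, pocket_summary = NULL,
                          cancer_type) {
  stopifnot(all(c("protein_a", "protein_b") %in% names(interactions)))
  rows <- interactions
  if ("cancer_types" %in% names(rows) && !is.null(cancer_type)) {
    hit <- vapply(strsplit(as.character(rows$cancer_types), ";"),
                  function(x) cancer_type %in% trimws(x), logical(1))
    rows <- rows[hit, , drop = FALSE]
  }
  # canonical undirected edge keys; collapse duplicates
  if (nrow(rows) > 0) {
    ek <- apply(cbind(as.character(rows$protein_a),
                      as.character(rows$protein_b)), 1,
                function(x) paste(sort(x), collapse = "|"))
    if (anyDuplicated(ek)) {
      warning("collapsed ", sum(duplicated(ek)),
              " duplicate interaction row(s) for ", cancer_type)
      rows <- rows[!duplicated(ek), , drop = FALSE]
    }
  }
  proteins <- sort(unique(c(as.character(rows$protein_a),
                            as.character(rows$protein_b))))
  g <- igraph::graph_from_data_frame(
    rows[, c("protein_a", "protein_b"), drop = FALSE],
    directed = FALSE,
    vertices = if (length(proteins) > 0) data.frame(name = proteins)
               else NULL)
  # degree = number of distinct partners; a self-loop contributes one
  # partner (the protein itself)
  deg <- vapply(proteins, function(p) {
    nb <- unique(c(as.character(rows$protein_b[rows$protein_a == p]),
                   as.character(rows$protein_a[rows$protein_b == p])))
    length(nb)
  }, numeric(1))
  n_int <- n_allo <- rep(0, length(proteins))
  if (!is.null(pocket_summary) && length(proteins) > 0) {
    m <- match(proteins, pocket_summary$protein)
    n_int <- ifelse(is.na(m), 0, pocket_summary$n_interface_pockets[m])
    n_allo <- ifelse(is.na(m), 0, pocket_summary$n_allosteric_pockets[m])
  }
  nodes <- data.frame(protein = proteins,
                      degree = as.integer(deg),
                      hub = deg >= 2,
                      n_interface_pockets = n_int,
                      n_allosteric_pockets = n_allo,
                      n_total_pockets = n_int + n_allo,
                      stringsAsFactors = FALSE)
  if (length(proteins) > 0) {
    igraph::V(g)$n_interface_pockets <- nodes$n_interface_pockets
    igraph::V(g)$n_allosteric_pockets <- nodes$n_allosteric_pockets
    igraph::V(g)$n_total_pockets <- nodes$n_total_pockets
    igraph::V(g)$hub <- nodes$hub
  }
  structure(list(cancer_type = cancer_type, graph = g, nodes = nodes,
                 edges = rows[, c("protein_a", "protein_b"), drop = FALSE]),
            class = "cancer_network")
}

#' @export
print.cancer_network <- function(x, ...) {
  cat(sprintf("cancer network %s: %d proteins, %d interactions, %d hub(s)\n",
              x$cancer_type, nrow(x$nodes), nrow(x$edges),
              sum(x$nodes$hub)))
  invisible(x)
}

#' Hub table across cancer networks
#'
#' One row per (protein, cancer) with the per-cancer degree and hub flag,
#' plus a cross-cancer degree computed on the union of partners over all
#' networks.
#'
#' @param networks List of `cancer_network` objects.
#' @return Data frame: protein, cancer, degree, hub, pocket counts,
#'   cross_cancer_degree.
#' @export
hub_table <- function(networks) {
  rows <- do.call(rbind, lapply(networks, function(nw) {
    if (nrow(nw$nodes) == 0) return(NULL)
    cbind(data.frame(cancer = nw$cancer_type, stringsAsFactors = FALSE),
          nw$nodes)
  }))
  if (is.null(rows))
    return(data.frame(cancer = character(), protein = character(),
                      degree = integer(), hub = logical(),
                      cross_cancer_degree = integer()))
  # union of partners over all cancers
  all_edges <- do.call(rbind, lapply(networks, `[[`, "edges"))
  cross <- vapply(rows$protein, function(p) {
    nb <- unique(c(as.character(all_edges$protein_b[all_edges$protein_a == p]),
                   as.character(all_edges$protein_a[all_edges$protein_b == p])))
    length(nb)
  }, numeric(1))
  rows$cross_cancer_degree <- as.integer(cross)
  rownames(rows) <- NULL
  rows
}

#' Export a cancer network
#'
#' Writes GraphML plus a Cytoscape-importable edge list and node attribute
#' CSV pair (node attributes: total / interface pocket counts and hub
#' flag).
#'
#' @param network A `cancer_network`.
#' @param prefix Output path prefix; writes `<prefix>.graphml`,
#'   `<prefix>_edges.csv`, `<prefix>_nodes.csv`.
#' @return Character vector of written paths, invisibly.
#' @export
export_network <- function(network, prefix) {
  graphml <- paste0(prefix, ".graphml")
  igraph::write_graph(network$graph, graphml, format = "graphml")
  edges_csv <- paste0(prefix, "_edges.csv")
  nodes_csv <- paste0(prefix, "_nodes.csv")
  write.csv(network$edges, edges_csv, row.names = FALSE)
  write.csv(network$nodes, nodes_csv, row.names = FALSE)
  invisible(c(graphml, edges_csv, nodes_csv))
}
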