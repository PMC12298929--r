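#' End-to-end pocketome pipeline
#'
#' Orchestrates the full analysis over an interaction table: for every
#' two-chain complex, pockets are detected on each detached partner and on
#' the whole complex, classified (interface / allosteric-like /
#' equilibrium), optionally annotated with descriptors and ligand
#' occupancy, and aggregated into per-cancer networks with hub flags. All
#' numeric parameters live in one serializable configuration and every
#' output table carries the configuration hash.
#'
#' @name cli_pipeline
NULL

#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline in one round-trippable
#' list. Defaults are the package's documented detection settings.
#'
#' @param spacing,padding,burial_rays,burial_cutoff,probe_cutoff Grid
#'   settings, see [grid_params()].
#' @param burial_min,dry_max,erosion_radius,dilation_radius,min_volume,
#'   contact_cutoff,fill_buried Pocket detection, see [pocket_params()].
#' @param partner_fraction_threshold Interface rule, see
#'   [classification_rule()].
#' @param max_rmsd Homolog alignment cutoff (Angstrom).
#' @param overlap_threshold Strict ligand-bound threshold.
#' @param observed_contact_cutoff Contact cutoff for observed binding
#'   residues (Angstrom).
#' @param hydrophobic_threshold,hydrophilic_threshold,solvent_min_dist
#'   Descriptor thresholds, see [descriptor_params()].
#' @param with_descriptors Compute pocket descriptors during the run.
#' @param seed Integer seed for any stochastic stage.
#' @param output_dir Output directory.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(spacing = 0.8, padding = 6, burial_rays = 50L,
                            burial_cutoff = 12, probe_cutoff = 8,
                            burial_min = 0.6, dry_max = -0.2,
                            erosion_radius = 1, dilation_radius = 1,
                            min_volume = 150, contact_cutoff = 4.0,
                            fill_buried = TRUE,
                            partner_fraction_threshold = 0,
                            max_rmsd = 3.0, overlap_threshold = 0.3,
                            observed_contact_cutoff = 5.0,
                            hydrophobic_threshold = -0.5,
                            hydrophilic_threshold = -3.5,
                            solvent_min_dist = 2.2,
                            with_descriptors = TRUE,
                            seed = 1L, output_dir = "pocketome_out") {
  cfg <- list(spacing = spacing, padding = padding,
              burial_rays = as.integer(burial_rays),
              burial_cutoff = burial_cutoff, probe_cutoff = probe_cutoff,
              burial_min = burial_min, dry_max = dry_max,
              erosion_radius = erosion_radius,
              dilation_radius = dilation_radius,
              min_volume = min_volume, contact_cutoff = contact_cutoff,
              fill_buried = fill_buried,
              partner_fraction_threshold = partner_fraction_threshold,
              max_rmsd = max_rmsd, overlap_threshold = overlap_threshold,
              observed_contact_cutoff = observed_contact_cutoff,
              hydrophobic_threshold = hydrophobic_threshold,
              hydrophilic_threshold = hydrophilic_threshold,
              solvent_min_dist = solvent_min_dist,
              with_descriptors = isTRUE(with_descriptors),
              seed = as.integer(seed), output_dir = output_dir)
  # range checks via the per-module constructors
  grid_params(spacing, padding, burial_rays, burial_min,
              burial_cutoff = burial_cutoff, probe_cutoff = probe_cutoff)
  pocket_params(burial_min, dry_max, erosion_radius, dilation_radius,
                min_volume, contact_cutoff, fill_buried)
  classification_rule(partner_fraction_threshold)
  stopifnot(max_rmsd > 0, overlap_threshold >= 0, overlap_threshold < 1)
  structure(cfg, class = "pipeline_config")
}

config_grid_params <- function(cfg) {
  grid_params(cfg$spacing, cfg$padding, cfg$burial_rays,
              burial_threshold = cfg$burial_min,
              burial_cutoff = cfg$burial_cutoff,
              probe_cutoff = cfg$probe_cutoff)
}

config_pocket_params <- function(cfg) {
  pocket_params(cfg$burial_min, cfg$dry_max, cfg$erosion_radius,
                cfg$dilation_radius, cfg$min_volume, cfg$contact_cutoff,
                cfg$fill_buried)
}

#' Write / read a pipeline configuration (YAML)
#'
#' Round-trips losslessly: `read_config(write_config(cfg, f))` equals
#' `cfg`.
#'
#' @param cfg A `pipeline_config`.
#' @param path YAML file path.
#' @return `path` / the configuration.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Hash of a configuration (provenance stamp)
#'
#' Hashes the scientific parameters only; the output directory does not
#' change what was computed and is excluded.
#'
#' @param cfg A `pipeline_config`.
#' @return MD5 hex string of the YAML serialization.
#' @export
config_hash <- function(cfg) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  x <- unclass(cfg)
  x$output_dir <- NULL
  yaml::write_yaml(x, f)
  unname(tools::md5sum(f))
}

#' Analyse one two-chain complex
#'
#' Detects and classifies pockets in both modes: on each detached partner
#' (interface vs allosteric-like) and on the whole complex (equilibrium).
#'
#' @param complex A prepared two-chain `prepared_structure`.
#' @param cfg A [pipeline_config()].
#' @return List with `detached_A`, `detached_B`, `complex` (classified
#'   `pocket_set`s) and `partners` (the split structures).
#' @export
analyse_complex <- function(complex, cfg = pipeline_config()) {
  gp <- config_grid_params(cfg)
  pp <- config_pocket_params(cfg)
  rule <- classification_rule(cfg$partner_fraction_threshold)
  parts <- split_partners(complex)
  ch <- complex$chains
  det_a <- find_pockets(parts[[ch[1]]], gp, pp, source = "detached_partner_A")
  det_a <- classify_pockets(det_a, partner = parts[[ch[2]]], rule = rule)
  det_b <- find_pockets(parts[[ch[2]]], gp, pp, source = "detached_partner_B")
  det_b <- classify_pockets(det_b, partner = parts[[ch[1]]], rule = rule)
  cpx <- find_pockets(complex, gp, pp, source = "complex")
  cpx <- classify_pockets(cpx)
  if (cfg$with_descriptors) {
    dp <- descriptor_params(cfg$hydrophobic_threshold,
                            cfg$hydrophilic_threshold,
                            cfg$solvent_min_dist, cfg$burial_rays)
    det_a <- compute_descriptors(det_a, dp)
    det_b <- compute_descriptors(det_b, dp)
    cpx <- compute_descriptors(cpx, dp)
  }
  list(detached_A = det_a, detached_B = det_b, complex = cpx,
       partners = parts)
}

pocket_rows <- function(result, interaction_id, proteins) {
  sets <- list(result$detached_A, result$detached_B, result$complex)
  do.call(rbind, lapply(sets, function(s) {
    if (length(s$pockets) == 0) return(NULL)
    df <- summary(s)
    df$interaction <- interaction_id
    df$protein <- switch(s$source,
                         detached_partner_A = proteins[1],
                         detached_partner_B = proteins[2],
                         complex = paste(proteins, collapse = "--"))
    if (!is.null(s$pockets[[1]]$descriptors)) {
      desc <- do.call(rbind, lapply(s$pockets, `[[`, "descriptors"))
      df <- cbind(df, as.data.frame(desc))
    }
    df
  }))
}

#' Run the pocketome pipeline over an interaction table
#'
#' @param cfg A [pipeline_config()].
#' @param interactions Data frame with columns `protein_a`, `protein_b`,
#'   `cancer_types` (semicolon-separated), `structure_file`, `chain_a`,
#'   `chain_b`.
#' @param structure_dir Directory that `structure_file` paths are relative
#'   to.
#' @param write_outputs Write CSV / GraphML outputs into
#'   `cfg$output_dir`.
#' @return List of class `pocketome_run`: `pockets` (per-pocket table),
#'   `interactions` (per-interaction category tallies), `protein_summary`,
#'   `networks` (per cancer), `hubs`, `errors` (skipped rows with
#'   reasons), `config_hash`.
#' @export
run_pocketome <- function(cfg, interactions, structure_dir = ".",
                          write_outputs = TRUE) {
  needed <- c("protein_a", "protein_b", "cancer_types", "structure_file",
              "chain_a", "chain_b")
  stopifnot(all(needed %in% names(interactions)))
  set.seed(cfg$seed)
  hash <- config_hash(cfg)
  pocket_tab <- NULL
  inter_rows <- list()
  errors <- list()
  log <- character(0)
  for (i in seq_len(nrow(interactions))) {
    row <- interactions[i, ]
    id <- sprintf("%s--%s", row$protein_a, row$protein_b)
    path <- file.path(structure_dir, row$structure_file)
    res <- tryCatch({
      cpx <- prepare(read_structure(path),
                     partner_chains = c(row$chain_a, row$chain_b))
      analyse_complex(cpx, cfg)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[length(errors) + 1]] <-
        data.frame(interaction = id, reason = conditionMessage(res))
      log <- c(log, sprintf("[skip] %s: %s", id, conditionMessage(res)))
      next
    }
    cats <- table(factor(
      unlist(lapply(list(res$detached_A, res$detached_B, res$complex),
                    function(s) vapply(s$pockets, `[[`, character(1),
                                       "category"))),
      levels = c("interface", "allosteric_like", "equilibrium",
                 "unclassified")))
    inter_rows[[length(inter_rows) + 1]] <- data.frame(
      interaction = id, protein_a = row$protein_a,
      protein_b = row$protein_b, cancer_types = row$cancer_types,
      n_interface = as.integer(cats["interface"]),
      n_allosteric_like = as.integer(cats["allosteric_like"]),
      n_equilibrium = as.integer(cats["equilibrium"]),
      stringsAsFactors = FALSE)
    pocket_tab <- rbind(pocket_tab,
                        pocket_rows(res, id, c(row$protein_a, row$protein_b)))
    log <- c(log, sprintf(
      "[ok] %s: %d interface, %d allosteric-like, %d equilibrium pocket(s)",
      id, cats["interface"], cats["allosteric_like"], cats["equilibrium"]))
  }
  inter_tab <- if (length(inter_rows) > 0) do.call(rbind, inter_rows)
    else data.frame(interaction = character(), protein_a = character(),
                    protein_b = character(), cancer_types = character(),
                    n_interface = integer(), n_allosteric_like = integer(),
                    n_equilibrium = integer())
  # per-protein pocket counts from detached detections
  prot_sum <- protein_summary(pocket_tab, inter_tab)
  cancers <- sort(unique(trimws(unlist(
    strsplit(as.character(inter_tab$cancer_types), ";")))))
  networks <- lapply(cancers, function(cc)
    build_network(inter_tab, prot_sum, cc))
  names(networks) <- cancers
  hubs <- hub_table(networks)
  out <- structure(list(pockets = pocket_tab, interactions = inter_tab,
                        protein_summary = prot_sum, networks = networks,
                        hubs = hubs,
                        errors = if (length(errors) > 0)
                          do.call(rbind, errors) else NULL,
                        log = log, config_hash = hash, config = cfg),
                   class = "pocketome_run")
  if (write_outputs) write_run(out, cfg$output_dir)
  out
}

protein_summary <- function(pocket_tab, inter_tab) {
  proteins <- sort(unique(c(as.character(inter_tab$protein_a),
                            as.character(inter_tab$protein_b))))
  if (length(proteins) == 0 || is.null(pocket_tab))
    return(data.frame(protein = proteins,
                      n_interface_pockets = integer(length(proteins)),
                      n_allosteric_pockets = integer(length(proteins))))
  det <- pocket_tab[pocket_tab$source != "complex", , drop = FALSE]
  data.frame(
    protein = proteins,
    n_interface_pockets = vapply(proteins, function(p)
      sum(det$protein == p & det$category == "interface"), integer(1)),
    n_allosteric_pockets = vapply(proteins, function(p)
      sum(det$protein == p & det$category == "allosteric_like"), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

write_run <- function(run, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- function(df) {
    if (is.null(df) || nrow(df) == 0) return(df)
    df$config_hash <- run$config_hash
    df
  }
  write.csv(stamp(run$pockets), file.path(output_dir, "pockets.csv"),
            row.names = FALSE)
  write.csv(stamp(run$interactions),
            file.path(output_dir, "interactions.csv"), row.names = FALSE)
  write.csv(stamp(run$protein_summary),
            file.path(output_dir, "protein_summary.csv"), row.names = FALSE)
  write.csv(stamp(run$hubs), file.path(output_dir, "hubs.csv"),
            row.names = FALSE)
  for (cc in names(run$networks))
    export_network(run$networks[[cc]],
                   file.path(output_dir, paste0("network_", cc)))
  writeLines(c(sprintf("config_hash: %s", run$config_hash), run$log),
             file.path(output_dir, "run_log.txt"))
  invisible(output_dir)
}

#' @export
print.pocketome_run <- function(x, ...) {
  cat("pocketome run:", nrow(x$interactions), "interaction(s),",
      if (is.null(x$pockets)) 0 else nrow(x$pockets), "pocket(s)\n")
  cat("  interface:", sum(x$interactions$n_interface),
      " allosteric-like:", sum(x$interactions$n_allosteric_like),
      " equilibrium:", sum(x$interactions$n_equilibrium), "\n")
  cat("  networks:", paste(names(x$networks), collapse = ", "), "\n")
  if (!is.null(x$errors))
    cat("  skipped:", nrow(x$errors), "row(s)\n")
  invisible(x)
}

#' Validate pocket detection against known binding sites
#'
#' For each case (a structure plus a binder whose contact residues are the
#' observed truth), detects pockets on the structure, flags whether any
#' pocket lining intersects the observed contacts, and reports the best
#' pocket's MCC over the structure's residues.
#'
#' @param cfg A [pipeline_config()].
#' @param cases List of cases: each a list with `name`, `structure`
#'   (a `prepared_structure`), `binder` (structure or coordinate matrix in
#'   the same frame).
#' @return List: `table` (per-case detection flag and MCC) and
#'   `detection_rate`.
#' @export
validate_sites <- function(cfg, cases) {
  gp <- config_grid_params(cfg)
  pp <- config_pocket_params(cfg)
  rows <- lapply(cases, function(cs) {
    obs <- observed_contact_residues(cs$structure, cs$binder,
                                     cfg$observed_contact_cutoff)
    pk <- find_pockets(cs$structure, gp, pp, source = "detached_partner_A")
    universe <- structure_residues(cs$structure)
    mccs <- vapply(pk$pockets, function(p)
      compute_mcc(p$lining_residues, obs, universe)$mcc, numeric(1))
    detected <- any(vapply(pk$pockets, function(p)
      length(intersect(p$lining_residues, obs)) > 0, logical(1)))
    data.frame(case = cs$name, n_pockets = length(pk$pockets),
               detected = detected,
               mcc = if (length(mccs) > 0) max(mccs) else NA_real_,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  list(table = tab, detection_rate = mean(tab$detected))
}

#' Run the synthetic demo pipeline
#'
#' Generates three synthetic two-chain complexes (two pit-plus-helix
#' interface dimers and one flat dimer in contact), writes them as PDB
#' files, and runs the full pipeline on them. Fully deterministic at a
#' fixed seed; repeated runs produce byte-identical outputs.
#'
#' @param output_dir Output directory for the run's tables.
#' @param seed Integer seed.
#' @param spacing Grid spacing for the demo (Angstrom). The demo uses a
#'   1.0 A grid to keep the run short; analyses use the 0.8 A default.
#' @return The `pocketome_run`, invisibly.
#' @export
run_demo <- function(output_dir = "pocketome_demo", seed = 1L,
                     spacing = 1.0) {
  cfg <- pipeline_config(spacing = spacing, seed = seed,
                         output_dir = output_dir)
  sdir <- file.path(output_dir, "structures")
  dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
  specs <- list(
    d1 = synthetic_spec("interface_dimer", cavity_radius = 5,
                        seed = seed),
    d2 = synthetic_spec("interface_dimer", cavity_radius = 6,
                        seed = seed + 1L),
    d3 = synthetic_spec("flat_dimer", seed = seed + 2L))
  for (nm in names(specs))
    write_structure(make_interface_dimer(specs[[nm]]),
                    file.path(sdir, paste0(nm, ".pdb")))
  interactions <- data.frame(
    protein_a = c("PROT1", "PROT3", "PROT5"),
    protein_b = c("PROT2", "PROT4", "PROT6"),
    cancer_types = c("BRCA;LUAD", "BRCA", "LUAD"),
    structure_file = paste0(names(specs), ".pdb"),
    chain_a = "A", chain_b = "B",
    stringsAsFactors = FALSE)
  write.csv(interactions, file.path(output_dir, "interactions_input.csv"),
            row.names = FALSE)
  invisible(run_pocketome(cfg, interactions, structure_dir = sdir))
}
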