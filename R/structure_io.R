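#' Structure preparation for pocket analysis
#'
#' Reading, cleaning and splitting of two-chain protein complexes. Cleaning
#' follows the usual rules for pocket mapping on co-crystal structures:
#' waters, nucleic acids, crystallization artifacts and free ligands are
#' removed, biologically relevant cofactors (NAD, FAD, GSH, ...) are
#' retained, and only the two declared partner chains are kept.
#'
#' @name structure_io
NULL

.water_resnames   <- c("HOH", "WAT", "DOD", "H2O", "SOL")
.nucleic_resnames <- c("A", "C", "G", "U", "I",
                       "DA", "DC", "DG", "DT", "DU", "DI")
.modified_protein <- c("MSE", "SEP", "TPO", "PTR")

#' Default cofactor whitelist
#'
#' HETATM residue names retained during preparation (organic cofactors and
#' prosthetic groups commonly co-purified with their protein).
#'
#' @return Character vector of three-letter residue codes.
#' @export
default_cofactors <- function() {
  c("NAD", "NAI", "NAP", "NDP", "FAD", "FMN", "GSH", "GDS",
    "HEM", "HEC", "SAM", "SAH", "PLP", "TPP", "TDP", "COA",
    "ADP", "ATP", "AMP", "GDP", "GTP", "GNP", "ANP", "BTN")
}

#' Default crystallographic-artifact blacklist
#'
#' Residue names of cryoprotectants, buffer components and precipitants that
#' are removed as crystallization artifacts.
#'
#' @return Character vector of three-letter residue codes.
#' @export
default_artifacts <- function() {
  c("GOL", "EDO", "PEG", "PG4", "P6G", "1PE", "2PE", "PGE", "MPD",
    "SO4", "PO4", "ACT", "ACY", "FMT", "CIT", "TRS", "EPE", "MES",
    "DMS", "BME", "IMD", "NO3", "CO3", "SCN",
    "CL", "BR", "IOD", "F", "NA", "K", "CS", "LI")
}

new_prepared_structure <- function(atoms, chains, log = character(),
                                   source = "unknown") {
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  structure(list(atoms = atoms,
                 chains = chains,
                 retained_cofactors = unique(res_key(
                   atoms$chain[atoms$cofactor],
                   atoms$resid[atoms$cofactor],
                   atoms$icode[atoms$cofactor])),
                 log = log,
                 source = source),
            class = "prepared_structure")
}

empty_atoms <- function(n = 0) {
  data.frame(serial = integer(n), elety = character(n),
             resname = character(n), chain = character(n),
             resid = integer(n), icode = character(n),
             x = numeric(n), y = numeric(n), z = numeric(n),
             het = logical(n), occupancy = numeric(n),
             altloc = character(n), element = character(n),
             cofactor = logical(n), stringsAsFactors = FALSE)
}

#' Read a PDB file into a raw structure
#'
#' Thin wrapper over [bio3d::read.pdb()] returning the atom table in the
#' package's column layout, without any cleaning. Pass the result to
#' [prepare()].
#'
#' @param path Path to a PDB file.
#' @return An object of class `raw_structure`.
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  atoms <- data.frame(
    serial = at$eleno,
    elety = trimws(at$elety),
    resname = trimws(at$resid),
    chain = ifelse(is.na(at$chain), "", at$chain),
    resid = at$resno,
    icode = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    het = at$type == "HETATM",
    occupancy = ifelse(is.na(at$o), 1, at$o),
    altloc = ifelse(is.na(at$alt), "", at$alt),
    element = guess_element(at$elesy, at$elety),
    cofactor = FALSE,
    stringsAsFactors = FALSE)
  structure(list(atoms = atoms, source = path), class = "raw_structure")
}

guess_element <- function(elesy, elety) {
  el <- toupper(trimws(ifelse(is.na(elesy), "", elesy)))
  miss <- !nzchar(el)
  if (any(miss)) {
    nm <- gsub("[^A-Za-z].*$", "", trimws(elety[miss]))
    two <- toupper(substr(nm, 1, 2)) %in% c("CL", "BR", "FE", "MG", "ZN", "MN", "NA")
    el[miss] <- ifelse(two, toupper(substr(nm, 1, 2)), toupper(substr(nm, 1, 1)))
  }
  el
}

raw_atoms <- function(x) {
  if (inherits(x, c("raw_structure", "prepared_structure"))) return(x$atoms)
  if (is.character(x) && length(x) == 1) return(read_structure(x)$atoms)
  if (is.data.frame(x)) return(x)
  stop("cannot interpret input as a structure")
}

#' Prepare a structure for pocket detection
#'
#' Applies the standard cleaning rules: removes waters, nucleic acids,
#' crystallization artifacts and non-cofactor ligands, resolves alternate
#' locations (highest occupancy wins, ties broken by altloc letter), keeps
#' only the two partner chains, and flags retained cofactors. Every removed
#' residue is logged with its reason. The function is idempotent.
#'
#' @param x A `raw_structure`, a path to a PDB file, a `prepared_structure`,
#'   or an atom data frame.
#' @param partner_chains Character vector of the chain ids to keep
#'   (typically length 2). `NULL` keeps all chains.
#' @param cofactor_whitelist HETATM residue names retained as cofactors.
#' @param artifact_blacklist HETATM residue names removed as artifacts.
#' @return A `prepared_structure`: list with elements `atoms` (data frame),
#'   `chains`, `retained_cofactors`, `log` and `source`.
#' @export
prepare <- function(x, partner_chains = NULL,
                    cofactor_whitelist = default_cofactors(),
                    artifact_blacklist = default_artifacts()) {
  atoms <- raw_atoms(x)
  source <- if (inherits(x, c("raw_structure", "prepared_structure")))
    x$source else if (is.character(x)) x else "data.frame"
  if (nrow(atoms) == 0) stop("empty structure")
  if (!is.null(partner_chains)) {
    missing_ch <- setdiff(partner_chains, unique(atoms$chain))
    if (length(missing_ch) > 0)
      stop("partner chain not present in structure: ",
           paste(missing_ch, collapse = ", "))
  }
  log <- character()
  note <- function(res, reason) {
    sprintf("%s %s removed: %s", res$key[1], res$resname[1], reason)
  }

  # altloc resolution: within each (chain, resid, icode, atom name) group
  # keep the highest-occupancy conformer, ties by altloc letter order
  if (any(nzchar(atoms$altloc))) {
    grp <- paste(atoms$chain, atoms$resid, atoms$icode, atoms$elety, sep = "\r")
    ord <- order(grp, -atoms$occupancy, atoms$altloc)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(grp[ord]), , drop = FALSE]
    atoms <- atoms[order(atoms$serial), , drop = FALSE]
    atoms$altloc <- ""
  }

  atoms$key <- res_key(atoms$chain, atoms$resid, atoms$icode)
  keep <- rep(TRUE, nrow(atoms))
  atoms$cofactor <- FALSE
  for (k in unique(atoms$key)) {
    sel <- atoms$key == k
    res <- atoms[sel, , drop = FALSE]
    rn <- res$resname[1]
    is_het <- all(res$het)
    if (rn %in% .water_resnames) {
      keep[sel] <- FALSE; log <- c(log, note(res, "water"))
    } else if (rn %in% .nucleic_resnames) {
      keep[sel] <- FALSE; log <- c(log, note(res, "nucleic acid"))
    } else if (is_het && rn %in% .modified_protein) {
      # modified amino acids stay as protein
    } else if (is_het && rn %in% cofactor_whitelist) {
      atoms$cofactor[sel] <- TRUE
    } else if (is_het && rn %in% artifact_blacklist) {
      keep[sel] <- FALSE; log <- c(log, note(res, "crystallographic artifact"))
    } else if (is_het) {
      keep[sel] <- FALSE; log <- c(log, note(res, "ligand"))
    }
  }
  # chain restriction (cofactors follow their chain id here; nearest-chain
  # assignment happens at split time)
  if (!is.null(partner_chains)) {
    off <- keep & !(atoms$chain %in% partner_chains)
    for (k in unique(atoms$key[off]))
      log <- c(log, note(atoms[atoms$key == k, , drop = FALSE],
                         "chain not a declared partner"))
    keep <- keep & atoms$chain %in% partner_chains
  }
  atoms <- atoms[keep, , drop = FALSE]
  atoms$key <- NULL
  if (nrow(atoms) == 0) stop("structure empty after cleaning")
  chains <- if (is.null(partner_chains)) unique(atoms$chain) else partner_chains
  new_prepared_structure(atoms, chains, log, source)
}

#' Split a prepared complex into its two detached partners
#'
#' Protein atoms are split by chain id; retained cofactors are assigned to
#' the chain with the nearest heavy atom.
#'
#' @param complex A `prepared_structure` with exactly two chains.
#' @return Named list of two `prepared_structure` objects (one per chain).
#' @export
split_partners <- function(complex) {
  stopifnot(inherits(complex, "prepared_structure"))
  ch <- complex$chains
  if (length(ch) != 2)
    stop("split_partners() requires a two-chain complex, got ",
         length(ch), " chain(s)")
  atoms <- complex$atoms
  prot <- atoms[!atoms$cofactor, , drop = FALSE]
  cof <- atoms[atoms$cofactor, , drop = FALSE]
  assign_chain <- prot$chain
  out <- list()
  cof_assign <- character(0)
  if (nrow(cof) > 0) {
    cof_assign <- vapply(unique(res_key(cof$chain, cof$resid, cof$icode)),
                         function(k) {
      sel <- res_key(cof$chain, cof$resid, cof$icode) == k
      cxyz <- as.matrix(cof[sel, c("x", "y", "z")])
      d <- vapply(ch, function(cc) {
        pxyz <- as.matrix(prot[prot$chain == cc, c("x", "y", "z")])
        min(cpp_min_atom_dist(cxyz, pxyz))
      }, numeric(1))
      ch[which.min(d)]
    }, character(1))
  }
  for (cc in ch) {
    sel_prot <- prot$chain == cc
    part <- prot[sel_prot, , drop = FALSE]
    if (nrow(cof) > 0) {
      keys <- res_key(cof$chain, cof$resid, cof$icode)
      part <- rbind(part, cof[cof_assign[keys] == cc, , drop = FALSE])
    }
    out[[cc]] <- new_prepared_structure(
      part, cc, log = character(),
      source = paste0(complex$source, ":", cc))
  }
  out
}

#' Write a prepared structure to a PDB file
#'
#' @param x A `prepared_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  stopifnot(inherits(x, "prepared_structure"))
  a <- x$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = ifelse(a$het, "HETATM", "ATOM"),
                   resno = a$resid, resid = a$resname,
                   eleno = a$serial, elety = a$elety,
                   chain = a$chain,
                   insert = ifelse(nzchar(a$icode), a$icode, ""),
                   o = a$occupancy, b = rep(0, nrow(a)),
                   elesy = a$element)
  invisible(path)
}

#' @export
print.prepared_structure <- function(x, ...) {
  cat("prepared structure:", x$source, "\n")
  cat("  chains:", paste(x$chains, collapse = ", "),
      " atoms:", nrow(x$atoms),
      " residues:", length(unique(res_key(x$atoms$chain, x$atoms$resid,
                                          x$atoms$icode))), "\n")
  if (length(x$retained_cofactors) > 0)
    cat("  cofactors:", paste(x$retained_cofactors, collapse = ", "), "\n")
  if (length(x$log) > 0)
    cat("  removed", length(x$log), "residue(s) during preparation\n")
  invisible(x)
}

# residue keys of a prepared structure (unique, in atom order)
structure_residues <- function(x) {
  unique(res_key(x$atoms$chain, x$atoms$resid, x$atoms$icode))
}

atom_coords <- function(x) {
  as.matrix(x$atoms[, c("x", "y", "z")])
}
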