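# Shared fixtures, built once per session (detection on the synthetic
# dimers is the expensive part of the suite).

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fixture_env[[name]]))
    assign(name, make(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

interface_dimer_result <- function() {
  fixture("interface_dimer_result", function() {
    cpx <- make_interface_dimer(
      synthetic_spec("interface_dimer", cavity_radius = 5, seed = 1))
    list(complex = cpx,
         truth = attr(cpx, "ground_truth"),
         res = analyse_complex(cpx,
                               pipeline_config(with_descriptors = FALSE)))
  })
}

flat_dimer_result <- function() {
  fixture("flat_dimer_result", function() {
    cpx <- make_interface_dimer(synthetic_spec("flat_dimer", seed = 2))
    list(complex = cpx,
         truth = attr(cpx, "ground_truth"),
         res = analyse_complex(cpx,
                               pipeline_config(with_descriptors = FALSE)))
  })
}

cavity_monomer_pockets <- function() {
  fixture("cavity_monomer_pockets", function() {
    st <- make_cavity_monomer(
      synthetic_spec("cavity_monomer", cavity_radius = 4.5, seed = 1))
    list(structure = st, truth = attr(st, "ground_truth"),
         pockets = find_pockets(st, source = "detached_partner_A"))
  })
}

# minimal prepared structure from coordinates
tiny_structure <- function(xyz, chain = "A", element = "C", het = FALSE,
                           resid = NULL, resname = "ALA", elety = "CA",
                           cofactor = FALSE) {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  df <- pocketome:::empty_atoms(n)
  df$serial <- seq_len(n)
  df$elety <- rep_len(elety, n)
  df$resname <- rep_len(resname, n)
  df$chain <- rep_len(chain, n)
  df$resid <- if (is.null(resid)) seq_len(n) else rep_len(resid, n)
  df$icode <- character(n)
  df$x <- xyz[, 1]; df$y <- xyz[, 2]; df$z <- xyz[, 3]
  df$het <- rep_len(het, n)
  df$occupancy <- rep_len(1, n)
  df$altloc <- character(n)
  df$element <- rep_len(element, n)
  df$cofactor <- rep_len(cofactor, n)
  pocketome:::new_prepared_structure(df, unique(df$chain), source = "test")
}

# raw atom data frame builder for preparation tests
raw_atoms_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    df <- pocketome:::empty_atoms(1)
    for (nm in names(r)) df[[nm]] <- r[[nm]]
    df
  }))
}

atom_row <- function(resname, chain, resid, x = 0, y = 0, z = 0,
                     het = FALSE, elety = "CA", element = "C",
                     occupancy = 1, altloc = "") {
  list(resname = resname, chain = chain, resid = as.integer(resid),
       x = x, y = y, z = z, het = het, elety = elety, element = element,
       occupancy = occupancy, altloc = altloc, icode = "",
       serial = 1L, cofactor = FALSE)
}
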