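test_that("MCC hits its analytic endpoints", {
  universe <- paste0("A:", 1:20)
  obs <- paste0("A:", 1:6)
  expect_equal(compute_mcc(obs, obs, universe)$mcc, 1)
  expect_equal(compute_mcc(setdiff(universe, obs), obs, universe)$mcc, -1)
  # balanced confusion matrix: tp = fp = fn = tn = 5 gives 0
  pred <- paste0("A:", c(1:5, 11:15))
  obs2 <- paste0("A:", c(1:5, 16:20))
  cmp <- compute_mcc(pred, obs2, universe)
  expect_equal(c(cmp$tp, cmp$fp, cmp$fn, cmp$tn), c(5, 5, 5, 5))
  expect_equal(cmp$mcc, 0)
})

test_that("MCC matches a confusion-matrix oracle on random set triples", {
  set.seed(51)
  universe <- paste0("A:", 1:30)
  for (rep in 1:1000) {
    pred <- sample(universe, sample(0:30, 1))
    obs <- sample(universe, sample(0:30, 1))
    got <- compute_mcc(pred, obs, universe)
    p <- universe %in% pred
    o <- universe %in% obs
    tp <- sum(p & o); fp <- sum(p & !o); fn <- sum(!p & o)
    tn <- sum(!p & !o)
    den <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
    want <- if (den == 0) 0 else (tp * tn - fp * fn) / den
    expect_equal(got$mcc, want, tolerance = 1e-12)
    expect_equal(got$tp + got$fp + got$fn + got$tn, 30)
  }
  expect_true(compute_mcc(character(0), paste0("A:", 1:3),
                          universe)$degenerate)
  expect_error(compute_mcc("B:1", "A:1", universe), "universe")
  expect_error(compute_mcc("A:1", "A:1", character(0)), "empty")
})

test_that("observed contact residues come from plain distance geometry", {
  fx <- interface_dimer_result()
  parts <- fx$res$partners
  got <- observed_contact_residues(parts$A, parts$B, 5)
  # independent recomputation with plain R distance arithmetic
  axyz <- as.matrix(parts$A$atoms[, c("x", "y", "z")])
  bxyz <- as.matrix(parts$B$atoms[, c("x", "y", "z")])
  near <- vapply(seq_len(nrow(axyz)), function(i)
    min(sqrt(colSums((t(bxyz) - axyz[i, ])^2))) <= 5, logical(1))
  want <- unique(paste0(parts$A$atoms$chain[near], ":",
                        parts$A$atoms$resid[near]))
  expect_setequal(got, want)
  # monotone in the cutoff, empty when far, error on empty binder
  expect_true(all(got %in% observed_contact_residues(parts$A, parts$B, 8)))
  far <- parts$B
  far$atoms$x <- far$atoms$x + 500
  expect_length(observed_contact_residues(parts$A, far, 5), 0)
  none <- tiny_structure(matrix(numeric(0), 0, 3))
  expect_error(observed_contact_residues(parts$A, none, 5), "empty")
})

test_that("hub rule: two or more partners, homodimers count once", {
  tab <- data.frame(
    protein_a = c("HUB", "HUB", "HUB", "LONE", "SELF"),
    protein_b = c("P1", "P2", "P3", "P4", "SELF"),
    cancer_types = "BRCA")
  nw <- build_network(tab, cancer_type = "BRCA")
  nodes <- nw$nodes
  expect_true(nodes$hub[nodes$protein == "HUB"])
  expect_equal(nodes$degree[nodes$protein == "HUB"], 3)
  expect_false(nodes$hub[nodes$protein == "LONE"])   # one partner
  # self-interaction: one partner (itself), not a hub by itself
  expect_equal(nodes$degree[nodes$protein == "SELF"], 1)
  expect_false(nodes$hub[nodes$protein == "SELF"])
  # degree is symmetric: the edge also counts for P1
  expect_equal(nodes$degree[nodes$protein == "P1"], 1)
})

test_that("network construction is order-independent and collapses duplicates", {
  tab <- data.frame(
    protein_a = c("A", "B", "C", "A"),
    protein_b = c("B", "C", "D", "B"),
    cancer_types = "LUAD")
  expect_warning(nw <- build_network(tab, cancer_type = "LUAD"),
                 "duplicate")
  expect_equal(nrow(nw$edges), 3)
  shuffled <- tab[c(3, 1, 4, 2), ]
  suppressWarnings(nw2 <- build_network(shuffled, cancer_type = "LUAD"))
  expect_equal(nw$nodes, nw2$nodes)
  # empty interaction table: empty network, no hubs
  empty <- build_network(tab[0, ], cancer_type = "BRCA")
  expect_equal(nrow(empty$nodes), 0)
  # adding edges never demotes a hub
  more <- rbind(tab[1:3, ],
                data.frame(protein_a = "B", protein_b = "E",
                           cancer_types = "LUAD"))
  nw3 <- build_network(more, cancer_type = "LUAD")
  was_hub <- nw$nodes$protein[nw$nodes$hub]
  expect_true(all(was_hub %in% nw3$nodes$protein[nw3$nodes$hub]))
})

test_that("pocket counts attach to nodes and export round-trips", {
  tab <- data.frame(protein_a = "X", protein_b = "Y",
                    cancer_types = "BRCA")
  ps <- data.frame(protein = "X", n_interface_pockets = 2,
                   n_allosteric_pockets = 3)
  nw <- build_network(tab, ps, "BRCA")
  x <- nw$nodes[nw$nodes$protein == "X", ]
  expect_equal(x$n_total_pockets, 5)
  y <- nw$nodes[nw$nodes$protein == "Y", ]
  expect_equal(y$n_total_pockets, 0)  # zero-filled when absent
  prefix <- tempfile()
  paths <- export_network(nw, prefix)
  expect_true(all(file.exists(paths)))
  g <- igraph::read_graph(paths[1], format = "graphml")
  expect_equal(igraph::vcount(g), 2)
})

test_that("hub table merges per-cancer and cross-cancer degrees", {
  t1 <- data.frame(protein_a = c("P", "P", "P"),
                   protein_b = c("Q", "R", "S"), cancer_types = "BRCA")
  t2 <- data.frame(protein_a = "P", protein_b = "Q",
                   cancer_types = "LUAD")
  nws <- list(build_network(t1, cancer_type = "BRCA"),
              build_network(t2, cancer_type = "LUAD"))
  ht <- hub_table(nws)
  p <- ht[ht$protein == "P", ]
  expect_true(p$hub[p$cancer == "BRCA"])
  expect_false(p$hub[p$cancer == "LUAD"])
  expect_true(all(p$cross_cancer_degree == 3))
  # all degree-1 networks produce no hubs at all
  solo <- build_network(data.frame(protein_a = "A", protein_b = "B",
                                   cancer_types = "BRCA"),
                        cancer_type = "BRCA")
  expect_equal(sum(hub_table(list(solo))$hub), 0)
})
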