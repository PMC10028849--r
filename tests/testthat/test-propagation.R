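sc_cluster <- function(source, pu, ku, p, pv = NA_character_, kv = 0L,
                       O = 2L, significant = FALSE, id = NULL) {
  tibble::tibble(
    cluster_id = id %||% paste(source, pu, signif(p, 3), sep = ":"),
    source = source, protein_u = pu, protein_v = pv,
    residues_u = list(seq_len(ku)), residues_v = list(seq_len(kv)),
    k_u = as.integer(ku), k_v = as.integer(kv), k = as.integer(ku + kv),
    O_C = as.integer(O), mutation_ids = list(seq_len(O) + 100L * round(p * 0)),
    E_C = 0.1, p = p, p_adj = pmin(1, p * 10), significant = significant
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

lof_tbl <- function(...) {
  tibble::tibble(...)
}

test_that("initial heat adds capped cluster and LOF log terms", {
  sc <- sc_cluster("C1", "U", 3, 1e-4)
  lof <- tibble::tibble(protein_id = "U", O_u = 3L, E_u = 0.5, p = 1e-2,
                        p_adj = 0.02, significant = TRUE)
  h <- initial_heat("U", sc, lof)
  expect_equal(h$h_in_frame, 4)
  expect_equal(h$h_lof, 2)
  expect_equal(h$heat, 6)
  # no clusters and no LOF evidence: zero heat
  h0 <- initial_heat("W", sc, lof)
  expect_equal(h0$heat, 0)
  # underflowing p-values are capped at 300 per addend
  sc0 <- sc_cluster("C1", "U", 3, 0)
  hcap <- initial_heat("U", sc0, lof_tbl(protein_id = "U", p = 0))
  expect_equal(hcap$h_in_frame, 300)
  expect_equal(hcap$heat, 600)
})

test_that("clusters contribute heat only to proteins they have residues in", {
  sc <- sc_cluster("C2", "U", 2, 1e-6, pv = "V", kv = 0L)
  h <- initial_heat(c("U", "V"), sc, lof_tbl(protein_id = character(),
                                             p = numeric()))
  expect_equal(h$h_in_frame[h$protein_id == "U"], 6)
  expect_equal(h$h_in_frame[h$protein_id == "V"], 0) # k_v = 0
})

test_that("edge weights combine interface evidence with the baseline", {
  edges <- tibble::tibble(protein_a = c("A", "A"), protein_b = c("B", "C"))
  sc <- sc_cluster("C4", "A", 1, 1e-5, pv = "B", kv = 1L)
  w <- edge_weight(edges, sc)
  expect_equal(w$weight[w$protein_b == "B"], 6) # 5 + w0
  expect_equal(w$weight[w$protein_b == "C"], 1) # baseline
  # underflow: capped log term + w0
  w0 <- edge_weight(edges, sc_cluster("C4", "A", 1, 0, pv = "B", kv = 1L))
  expect_equal(w0$weight[w0$protein_b == "B"], 301)
  # intra clusters are ignored by edge weighting
  w1 <- edge_weight(edges, sc_cluster("C1", "A", 1, 1e-9))
  expect_true(all(w1$weight == 1))
})

test_that("transition matrix is column-stochastic with weight-proportional entries", {
  edges <- tibble::tibble(
    protein_a = c("H", "H", "H", "H"),
    protein_b = c("A", "B", "C", "D"),
    weight = 1
  )
  W <- transition_matrix(edges)
  expect_equal(unname(W[c("A", "B", "C", "D"), "H"]), rep(0.25, 4))
  edges2 <- tibble::tibble(protein_a = c("X", "X"), protein_b = c("Y", "Z"),
                           weight = c(3, 1))
  W2 <- transition_matrix(edges2)
  expect_equal(unname(W2["Y", "X"]), 0.75)
  expect_equal(unname(W2["Z", "X"]), 0.25)
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(4:30, 1)
    e <- tidyr::expand_grid(a = seq_len(n), b = seq_len(n)) %>%
      dplyr::filter(.data$a < .data$b) %>%
      dplyr::slice_sample(prop = 0.4) %>%
      dplyr::mutate(protein_a = paste0("N", .data$a),
                    protein_b = paste0("N", .data$b),
                    weight = stats::runif(dplyr::n(), 0.1, 5))
    if (nrow(e) == 0) next
    W <- transition_matrix(e)
    expect_equal(unname(colSums(W)), rep(1, ncol(W)), tolerance = 1e-12)
  }
})

test_that("two-node diffusion reproduces the closed form", {
  edges <- tibble::tibble(protein_a = "A", protein_b = "B", weight = 1)
  W <- transition_matrix(edges)
  res <- compute_exchanged_heat(W, 0.5, c(A = 1, B = 0))
  expect_equal(unname(res$F),
               matrix(c(2 / 3, 1 / 3, 1 / 3, 2 / 3), 2), tolerance = 1e-12)
  # beta = 1: no diffusion
  res1 <- compute_exchanged_heat(W, 1, c(A = 2, B = 3))
  expect_equal(unname(res1$F), diag(2), tolerance = 1e-12)
  expect_equal(unname(res1$E), diag(c(2, 3)), tolerance = 1e-12)
  # zero heats: zero exchanged heat
  res0 <- compute_exchanged_heat(W, 0.5, c(A = 0, B = 0))
  expect_true(all(res0$E == 0))
})

test_that("diffusion conserves heat and satisfies the linear system", {
  set.seed(13)
  for (rep in 1:10) {
    n <- sample(5:60, 1)
    e <- tidyr::expand_grid(a = seq_len(n), b = seq_len(n)) %>%
      dplyr::filter(.data$a < .data$b) %>%
      dplyr::slice_sample(prop = 0.3) %>%
      dplyr::mutate(protein_a = sprintf("N%03d", .data$a),
                    protein_b = sprintf("N%03d", .data$b),
                    weight = stats::runif(dplyr::n(), 0.5, 10))
    if (nrow(e) == 0) next
    W <- transition_matrix(e)
    nn <- ncol(W)
    h <- stats::setNames(stats::rexp(nn), colnames(W))
    beta <- stats::runif(1, 0.2, 0.9)
    res <- compute_exchanged_heat(W, beta, h)
    resid <- (diag(nn) - (1 - beta) * W) %*% res$F - beta * diag(nn)
    expect_lt(max(abs(resid)), 1e-9)
    expect_equal(unname(colSums(res$F)), rep(1, nn), tolerance = 1e-9)
    expect_equal(unname(colSums(res$E)), unname(h[colnames(W)]),
                 tolerance = 1e-9)
  }
})

test_that("modules are strongly connected components under a strict threshold", {
  nodes <- c("a", "b", "c")
  E <- matrix(0, 3, 3, dimnames = list(nodes, nodes))
  E["b", "a"] <- 1; E["a", "b"] <- 1 # mutual
  E["c", "a"] <- 1                   # one-way
  mods <- identify_modules(E, 0.5, size_threshold = 1)
  sizes <- sort(mods$size)
  expect_equal(sizes, c(1L, 2L))
  expect_true(any(purrr::map_lgl(mods$proteins, ~ setequal(.x, c("a", "b")))))
  # a hot hub with one-way edges yields only singletons
  Ehub <- matrix(0, 3, 3, dimnames = list(nodes, nodes))
  Ehub["b", "a"] <- 5; Ehub["c", "a"] <- 5
  mhub <- identify_modules(Ehub, 0.5)
  expect_true(all(mhub$size == 1))
  # threshold is strict: E == delta is not an edge
  Eeq <- matrix(0, 3, 3, dimnames = list(nodes, nodes))
  Eeq["b", "a"] <- 0.5; Eeq["a", "b"] <- 0.5
  expect_true(all(identify_modules(Eeq, 0.5)$size == 1))
})

test_that("strongly connected components match the transitive-closure oracle", {
  set.seed(14)
  for (rep in 1:60) {
    n <- sample(2:12, 1)
    nodes <- sprintf("n%02d", seq_len(n))
    E <- matrix(stats::runif(n * n), n, n, dimnames = list(nodes, nodes))
    E[sample(length(E), floor(0.6 * n * n))] <- 0
    diag(E) <- 0
    delta <- 0.3
    mods <- identify_modules(E, delta, size_threshold = 1)
    oc <- oracle_scc(E > delta)
    got <- sort(purrr::map_chr(mods$proteins, paste, collapse = ","))
    want <- sort(vapply(split(nodes, oc), function(v)
      paste(sort(v), collapse = ","), character(1)))
    expect_equal(got, unname(want))
  }
})

test_that("module sizes shrink monotonically as delta grows", {
  set.seed(15)
  n <- 15
  nodes <- sprintf("n%02d", seq_len(n))
  E <- matrix(stats::rexp(n * n), n, n, dimnames = list(nodes, nodes))
  diag(E) <- 0
  deltas <- sort(stats::runif(6, 0, 3))
  sizes <- vapply(deltas, function(d) {
    max(identify_modules(E, d, size_threshold = 1)$size)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

random_weighted_net <- function(n = 30, p = 0.15, seed = 20) {
  set.seed(seed)
  tidyr::expand_grid(a = seq_len(n), b = seq_len(n)) %>%
    dplyr::filter(.data$a < .data$b) %>%
    dplyr::filter(stats::runif(dplyr::n()) < p) %>%
    dplyr::mutate(protein_a = sprintf("N%03d", .data$a),
                  protein_b = sprintf("N%03d", .data$b),
                  weight = stats::runif(dplyr::n(), 0.5, 8)) %>%
    dplyr::select("protein_a", "protein_b", "weight")
}

test_that("randomization preserves degrees and the weight multiset", {
  edges <- random_weighted_net()
  set.seed(99)
  re <- randomize_network(edges)
  deg <- function(e) sort(table(c(e$protein_a, e$protein_b)))
  expect_equal(deg(re), deg(edges))
  expect_equal(sort(re$weight), sort(edges$weight))
  expect_equal(nrow(re), nrow(edges))
  # and the edge set actually changes on a graph this size
  expect_false(identical(
    sort(paste(re$protein_a, re$protein_b)),
    sort(paste(edges$protein_a, edges$protein_b))
  ))
})

test_that("delta selection is reproducible and validated on its replicates", {
  edges <- random_weighted_net(n = 25, p = 0.2, seed = 21)
  nodes <- sort(unique(c(edges$protein_a, edges$protein_b)))
  set.seed(22)
  heats <- stats::setNames(stats::rexp(length(nodes), 1 / 5), nodes)
  sel1 <- select_delta(edges, heats, beta = 0.5, n_random = 5, seed = 7)
  sel2 <- select_delta(edges, heats, beta = 0.5, n_random = 5, seed = 7)
  expect_identical(sel1$delta, sel2$delta)
  expect_identical(sel1$replicates, sel2$replicates)
  expect_equal(sel1$delta, min(sel1$replicate_deltas))
  # post-hoc: at each replicate's own delta, its components are all <= 5
  for (r in seq_along(sel1$exchanged)) {
    mods <- identify_modules(sel1$exchanged[[r]],
                             sel1$replicate_deltas[r], size_threshold = 5)
    expect_true(all(mods$size <= 5))
  }
})

test_that("zero heats degenerate to the epsilon fallback", {
  edges <- random_weighted_net(n = 10, p = 0.3, seed = 23)
  nodes <- sort(unique(c(edges$protein_a, edges$protein_b)))
  heats <- stats::setNames(rep(0, length(nodes)), nodes)
  expect_message(sel <- select_delta(edges, heats, n_random = 3, seed = 1),
                 "zero")
  expect_equal(sel$delta, .Machine$double.eps)
})

test_that("driver mutations come from each protein's best significant cluster", {
  modules <- tibble::tibble(
    module_id = "M1", proteins = list(c("A", "B")), size = 2L,
    significant = TRUE
  )
  sc <- dplyr::bind_rows(
    sc_cluster("C1", "A", 2, 1e-6, significant = TRUE, id = "best"),
    sc_cluster("C1", "A", 2, 1e-3, significant = TRUE, id = "worse"),
    sc_cluster("C1", "B", 2, 1e-2, significant = FALSE, id = "nsB"),
    sc_cluster("C4", "A", 1, 1e-4, pv = "B", kv = 1L, significant = TRUE,
               id = "iface")
  )
  sc$mutation_ids <- list(1:2, 3:4, 5:6, 7:8)
  edges <- tibble::tibble(protein_a = "A", protein_b = "B")
  dr <- extract_driver_mutations(modules, sc, edges)
  # protein A: only the 1e-6 cluster's mutations (1:2), never 3:4 from the
  # weaker cluster; protein B's best significant cluster is the interface
  # one (any family counts), so 7:8 also arrive via the protein rule;
  # the A-B interface rule contributes the iface cluster again (7:8)
  expect_setequal(dr$mutation_id[dr$via == "protein"], c(1:2, 7:8))
  expect_setequal(dr$mutation_id[dr$via == "interface"], 7:8)
  expect_false(any(dr$cluster_id == "worse"))
  # no significant module: nothing extracted
  none <- extract_driver_mutations(
    dplyr::mutate(modules, significant = FALSE), sc, edges
  )
  expect_equal(nrow(none), 0)
})

test_that("baseline configuration counts distinct mutated samples", {
  recs <- tibble::tibble(
    sample_id = c("S1", "S1", "S2", "S3", "S4"),
    cancer_type = "SYNTH", gene_id = "G",
    protein_id = c("A", "A", "A", "A", "B"),
    residue_start = 1L, residue_end = 1L,
    consequence_term = c("missense_variant", "stop_gained",
                         "missense_variant", "synonymous_variant",
                         "missense_variant"),
    consequence_class = c("in_frame", "lof", "in_frame", "background",
                          "in_frame"),
    population_af = NA_real_
  )
  edges <- tibble::tibble(protein_a = "A", protein_b = "B")
  base <- baseline_configuration(recs, edges)
  # S1 counted once despite two mutations; S3 is background-only
  expect_equal(base$heats$heat[base$heats$protein_id == "A"], 2)
  expect_equal(base$heats$heat[base$heats$protein_id == "B"], 1)
  expect_true(all(base$edges$weight == 1))
})
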