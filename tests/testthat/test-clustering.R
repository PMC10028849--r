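inframe_rec <- function(protein, start, end = start, sample = "S1",
                        term = "missense_variant") {
  tibble::tibble(
    sample_id = sample, cancer_type = "SYNTH", gene_id = paste0(protein, "G"),
    protein_id = protein, residue_start = as.integer(start),
    residue_end = as.integer(end), consequence_term = term,
    consequence_class = classify_consequence(term), population_af = NA_real_
  )
}

lengths_tbl <- tibble::tibble(protein_id = c("P1", "P2"),
                              length = c(500L, 300L))

test_that("residue footprints follow the consequence-specific convention", {
  recs <- dplyr::bind_rows(
    inframe_rec("P1", 42),
    inframe_rec("P1", 10, 12, term = "inframe_deletion"),
    inframe_rec("P1", 7, 8, term = "inframe_insertion"),
    inframe_rec("P1", 1, term = "stop_gained") # not in-frame: excluded
  )
  fp <- expand_to_residues(recs, lengths_tbl)
  expect_setequal(fp$residue[fp$mutation_id == 1], 42)
  expect_setequal(fp$residue[fp$mutation_id == 2], 10:12)
  expect_setequal(fp$residue[fp$mutation_id == 3], 7:8)
  expect_equal(dplyr::n_distinct(fp$mutation_id), 3)
})

test_that("out-of-range residues and unknown proteins are dropped loudly", {
  expect_warning(
    fp <- expand_to_residues(inframe_rec("P1", 999), lengths_tbl),
    "beyond protein length"
  )
  expect_equal(nrow(fp), 0)
  expect_message(
    fp2 <- expand_to_residues(inframe_rec("PX", 5), lengths_tbl),
    "unknown length"
  )
  expect_equal(nrow(fp2), 0)
})

# a tiny hand-built intra graph: P1 residues 1-6 in a path 1-2-3-4-5-6
path_graph <- function(kind = "intra_experimental", protein = "P1", n = 6) {
  edges <- tibble::tibble(
    protein_u = protein, res_u = 1:(n - 1),
    protein_v = protein, res_v = 2:n, dist = 3.8
  )
  vertices <- tibble::tibble(protein_id = protein, protein_resid = 1:n)
  structure(list(kind = kind, vertices = vertices, edges = edges),
            class = "contact_graph")
}

test_that("intra-protein clusters are connected components of mutated vertices", {
  recs <- dplyr::bind_rows(
    inframe_rec("P1", 2, sample = "S1"),
    inframe_rec("P1", 3, sample = "S2"),
    inframe_rec("P1", 5, sample = "S3"),
    inframe_rec("P1", 5, sample = "S4") # recurrent residue: 2 events
  )
  fp <- expand_to_residues(recs, lengths_tbl)
  cl <- intra_clusters(path_graph(), fp)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$source, c("C1", "C1"))
  expect_setequal(purrr::map_chr(cl$residues_u, paste, collapse = ","),
                  c("2,3", "5"))
  expect_equal(cl$O_C[purrr::map_lgl(cl$residues_u, ~ 5 %in% .x)], 2)
  # residue 100 is outside the graph's vertex set: excluded from C1
  fp2 <- expand_to_residues(dplyr::bind_rows(recs, inframe_rec("P1", 100)),
                            lengths_tbl)
  cl2 <- intra_clusters(path_graph(), fp2)
  expect_equal(nrow(cl2), 2)
})

test_that("cluster output is invariant to mutation and edge order", {
  recs <- dplyr::bind_rows(
    inframe_rec("P1", 2), inframe_rec("P1", 3), inframe_rec("P1", 6)
  )
  g <- path_graph()
  fp_fwd <- expand_to_residues(recs, lengths_tbl)
  fp_rev <- expand_to_residues(recs[3:1, ], lengths_tbl)
  g_rev <- g
  g_rev$edges <- g$edges[nrow(g$edges):1, ]
  a <- intra_clusters(g, fp_fwd)
  b <- intra_clusters(g_rev, fp_rev)
  expect_equal(a$cluster_id, b$cluster_id)
  expect_equal(a$residues_u, b$residues_u)
  expect_equal(a$O_C, b$O_C)
})

test_that("components match a brute-force reachability oracle on random graphs", {
  set.seed(7)
  for (rep in 1:60) {
    n <- sample(5:50, 1)
    vertices <- tibble::tibble(protein_id = "P1", protein_resid = 1:n)
    m <- sample(0:(2 * n), 1)
    e <- tibble::tibble(
      protein_u = "P1", res_u = sample(n, m, replace = TRUE),
      protein_v = "P1", res_v = sample(n, m, replace = TRUE), dist = 3
    ) %>% dplyr::filter(.data$res_u != .data$res_v)
    g <- structure(list(kind = "intra_predicted", vertices = vertices,
                        edges = e), class = "contact_graph")
    mut_res <- sort(sample(n, sample(2:n, 1)))
    fp <- tibble::tibble(mutation_id = seq_along(mut_res), protein_id = "P1",
                         residue = mut_res, sample_id = "S1",
                         cancer_type = "SYNTH")
    cl <- intra_clusters(g, fp)
    # oracle: BFS components of the induced subgraph
    keep <- e$res_u %in% mut_res & e$res_v %in% mut_res
    oc <- oracle_components(
      data.frame(a = as.character(e$res_u[keep]),
                 b = as.character(e$res_v[keep])),
      as.character(mut_res)
    )
    oracle_groups <- sort(vapply(
      split(names(oc), oc),
      function(v) paste(sort(as.integer(v)), collapse = ","), character(1)
    ))
    got_groups <- sort(purrr::map_chr(cl$residues_u, paste, collapse = ","))
    expect_equal(got_groups, unname(oracle_groups))
  }
})

inter_fixture <- function() {
  # intra edges: P1 10-11; inter edges: P1:11-P2:20, P1:30-P2:40
  g1 <- structure(list(
    kind = "intra_experimental",
    vertices = tibble::tibble(protein_id = c("P1", "P1", "P1", "P2", "P2"),
                              protein_resid = c(10L, 11L, 30L, 20L, 40L)),
    edges = tibble::tibble(protein_u = "P1", res_u = 10L,
                           protein_v = "P1", res_v = 11L, dist = 4)
  ), class = "contact_graph")
  g2 <- structure(list(
    kind = "inter_experimental",
    vertices = tibble::tibble(protein_id = c("P1", "P2", "P1", "P2"),
                              protein_resid = c(11L, 20L, 30L, 40L)),
    edges = tibble::tibble(protein_u = c("P1", "P1"), res_u = c(11L, 30L),
                           protein_v = c("P2", "P2"), res_v = c(20L, 40L),
                           dist = c(8, 8.5))
  ), class = "contact_graph")
  list(g1 = g1, g2 = g2)
}

test_that("inter-protein clusters require at least one inter-chain edge", {
  fx <- inter_fixture()
  ppi <- tibble::tibble(protein_a = "P1", protein_b = "P2")
  # only intra pair mutated: no C2 cluster
  fp_intra <- expand_to_residues(
    dplyr::bind_rows(inframe_rec("P1", 10), inframe_rec("P1", 11)),
    lengths_tbl
  )
  expect_equal(nrow(inter_clusters(fx$g1, fx$g2, fp_intra, ppi)), 0)
  # mutated pair across the interface
  fp_pair <- expand_to_residues(
    dplyr::bind_rows(inframe_rec("P1", 30), inframe_rec("P2", 40)),
    lengths_tbl
  )
  cl <- inter_clusters(fx$g1, fx$g2, fp_pair, ppi)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$k_u, 1)
  expect_equal(cl$k_v, 1)
})

test_that("merged inter clusters combine intra and inter edges", {
  fx <- inter_fixture()
  ppi <- tibble::tibble(protein_a = "P1", protein_b = "P2")
  fp <- expand_to_residues(
    dplyr::bind_rows(inframe_rec("P1", 10), inframe_rec("P1", 11),
                     inframe_rec("P2", 20)),
    lengths_tbl
  )
  cl <- inter_clusters(fx$g1, fx$g2, fp, ppi)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$residues_u[[1]], c(10L, 11L))
  expect_equal(cl$residues_v[[1]], 20L)
  expect_equal(cl$O_C, 3)
  # PPI not in the interaction set: nothing reported
  expect_equal(nrow(inter_clusters(
    fx$g1, fx$g2, fp, tibble::tibble(protein_a = "P1", protein_b = "P9")
  )), 0)
  # deleting inter edges must split every C2 across the protein boundary
  expect_true(all(purrr::map_lgl(seq_len(nrow(cl)), function(i) {
    cl$k_u[i] >= 1 && cl$k_v[i] >= 1
  })))
})

test_that("interface clusters are the mutated subset of annotated residues", {
  ann <- tibble::tibble(
    protein_a = "P1", protein_b = "P2",
    protein = c("P1", "P1", "P2"),
    residue = c(10L, 20L, 5L),
    confidence = "very high"
  )
  ppi <- tibble::tibble(protein_a = "P1", protein_b = "P2")
  fp0 <- expand_to_residues(inframe_rec("P1", 99), lengths_tbl)
  expect_equal(nrow(interface_clusters(ann, fp0, ppi)), 0)
  fp <- expand_to_residues(
    dplyr::bind_rows(inframe_rec("P1", 10), inframe_rec("P2", 5)),
    lengths_tbl
  )
  cl <- interface_clusters(ann, fp, ppi)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$residues_u[[1]], 10L)
  expect_equal(cl$residues_v[[1]], 5L)
  expect_equal(cl$source, "C4")
  # all interface residues mutated -> cluster equals the interface set
  fp_all <- expand_to_residues(
    dplyr::bind_rows(inframe_rec("P1", 10), inframe_rec("P1", 20),
                     inframe_rec("P2", 5)),
    lengths_tbl
  )
  cl_all <- interface_clusters(ann, fp_all, ppi)
  expect_equal(cl_all$residues_u[[1]], c(10L, 20L))
})

test_that("predicted clusters overlapping experimental ones are removed", {
  mk <- function(source, protein, residues) {
    tibble::tibble(
      cluster_id = paste(source, protein, residues[1], sep = ":"),
      source = source, protein_u = protein, protein_v = NA_character_,
      residues_u = list(as.integer(residues)), residues_v = list(integer()),
      k_u = length(residues), k_v = 0L, k = length(residues),
      O_C = length(residues), mutation_ids = list(seq_along(residues))
    )
  }
  c1 <- mk("C1", "P1", c(5, 6))
  c3 <- dplyr::bind_rows(
    mk("C3", "P1", c(6, 7)),   # overlaps C1 at residue 6 -> removed
    mk("C3", "P1", c(20, 21)), # disjoint -> retained
    mk("C3", "P2", 5)          # same residue number, other protein -> kept
  )
  out <- dedupe_predicted(c3, c1)
  expect_equal(out$cluster_id, c("C3:P1:20", "C3:P2:5"))
  # overlap with C2 does not trigger removal: rule names C1 only
  c2 <- mk("C2", "P1", c(20, 21))
  expect_equal(nrow(dedupe_predicted(out, c1)), 2)
})
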