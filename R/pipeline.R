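# End-to-end orchestration: preprocessed mutations + structurome + network
# -> scored clusters, LOF enrichment, heat diffusion, modules, drivers.

#' Run the full cluster-diffusion pipeline
#'
#' Expands in-frame mutations to residue footprints, identifies the four
#' cluster families (intra experimental `C1`, inter-chain `C2`, intra
#' predicted `C3` after redundancy removal against `C1`, interface `C4`),
#' scores them against the covariate-aware background model, computes
#' protein LOF enrichment, converts evidence to heats and edge weights,
#' runs insulated heat diffusion on the PPI network, selects the
#' exchanged-heat threshold `delta` on degree-preserving randomized
#' networks (unless supplied), and reports interconnected modules and
#' potential driver mutations.
#'
#' @param records Preprocessed mutation tibble (germline/expression filters
#'   already applied; see [read_mutations()], [filter_germline()],
#'   [filter_expression()]).
#' @param network Edge tibble (`protein_a`, `protein_b`).
#' @param proteins Tibble `protein_id`, `gene_id`, `length`.
#' @param covariates Covariate/coverage tibble (see [read_covariates()]).
#' @param g1,g2,g3 Contact graphs (experimental intra, experimental inter,
#'   predicted intra); any may be `NULL` to skip its family.
#' @param interfaces Interface annotation tibble, or `NULL`.
#' @param n_p Cohort size; defaults to the number of distinct samples in
#'   `records`.
#' @param beta Insulating fraction (default 0.5).
#' @param w0 Baseline edge weight (default 1).
#' @param cap Heat/weight log-term cap (default 300).
#' @param alpha Background in-frame indel fraction (default 0.09).
#' @param alpha_level Significance level (default 0.05).
#' @param module_size_threshold Modules must exceed this size (default 5).
#' @param n_random Randomized replicates for delta selection (default 20).
#' @param delta Supplied threshold, or `NULL` to select on randomized
#'   networks.
#' @param seed Seed for delta selection.
#' @param baseline If `TRUE`, run the structure-blind ablation: heats are
#'   distinct-sample mutation counts, all weights `w0`.
#' @return An object of class `mutnet_result`; see [tidy.mutnet_result()],
#'   [glance.mutnet_result()], [autoplot.mutnet_result()].
#' @export
mutnet_run <- function(records, network, proteins, covariates,
                       g1 = NULL, g2 = NULL, g3 = NULL, interfaces = NULL,
                       n_p = NULL, beta = 0.5, w0 = 1, cap = 300,
                       alpha = 0.09, alpha_level = 0.05,
                       module_size_threshold = 5, n_random = 20,
                       delta = NULL, seed = 1, baseline = FALSE) {
  if (is.null(n_p)) n_p <- dplyr::n_distinct(records$sample_id)
  stopifnot(n_p >= 1)
  lengths_tbl <- dplyr::distinct(proteins, .data$protein_id, .data$length)
  mutated <- expand_to_residues(records, lengths_tbl)

  c1 <- if (!is.null(g1)) intra_clusters(g1, mutated) else .empty_clusters()
  c3 <- if (!is.null(g3)) intra_clusters(g3, mutated) else .empty_clusters()
  c3 <- dedupe_predicted(c3, c1)
  c2 <- if (!is.null(g1) && !is.null(g2)) {
    inter_clusters(g1, g2, mutated, network)
  } else .empty_clusters()
  c4 <- if (!is.null(interfaces)) {
    interface_clusters(interfaces, mutated, network)
  } else .empty_clusters()
  clusters <- dplyr::bind_rows(c1, c2, c3, c4)

  gene_bg <- expected_gene_counts(covariates, n_p, alpha = alpha)
  protein_bg <- expected_protein_counts(
    lengths_tbl, dplyr::distinct(proteins, .data$protein_id, .data$gene_id),
    gene_bg
  )
  scored <- score_clusters(clusters, protein_bg, n_p, alpha_level)
  lof <- lof_enrichment(count_lof(records), protein_bg, n_p, alpha_level)

  # diffusion runs on the network's non-isolated vertices
  net_nodes <- sort(unique(c(network$protein_a, network$protein_b)))
  if (baseline) {
    base <- baseline_configuration(records, network)
    heats_tbl <- tibble::tibble(protein_id = net_nodes) %>%
      dplyr::left_join(base$heats, by = "protein_id") %>%
      dplyr::mutate(heat = dplyr::coalesce(.data$heat, 0))
    wedges <- dplyr::mutate(network, weight = w0)
  } else {
    heats_tbl <- initial_heat(net_nodes, scored, lof, cap) %>%
      dplyr::select("protein_id", "heat")
    wedges <- edge_weight(network, scored, w0, cap)
  }
  heats <- stats::setNames(heats_tbl$heat, heats_tbl$protein_id)
  W <- transition_matrix(wedges)
  diff <- compute_exchanged_heat(W, beta, heats)

  delta_info <- NULL
  if (is.null(delta)) {
    delta_info <- select_delta(wedges, heats, beta, n_random,
                               module_size_threshold, seed)
    delta <- delta_info$delta
  }
  modules <- identify_modules(diff$E, delta, module_size_threshold)
  drivers <- extract_driver_mutations(modules, scored, network)

  structure(list(
    clusters = scored, lof = lof, gene_backgrounds = gene_bg,
    protein_backgrounds = protein_bg, mutated = mutated,
    heats = heats_tbl, weighted_edges = wedges,
    W = W, F = diff$F, E = diff$E,
    delta = delta, delta_info = delta_info,
    modules = modules, drivers = drivers,
    params = list(n_p = n_p, beta = beta, w0 = w0, cap = cap, alpha = alpha,
                  alpha_level = alpha_level,
                  module_size_threshold = module_size_threshold,
                  n_random = n_random, seed = seed, baseline = baseline)
  ), class = "mutnet_result")
}

#' @export
print.mutnet_result <- function(x, ...) {
  cat("<mutnet_result>\n")
  cat("  cohort:", x$params$n_p, "samples\n")
  cat("  clusters:", nrow(x$clusters), "(",
      sum(x$clusters$significant), "significant )\n")
  cat("  LOF-enriched proteins:", sum(x$lof$significant), "\n")
  cat("  delta:", format(x$delta), "\n")
  cat("  modules:", nrow(x$modules), "(",
      sum(x$modules$significant), "significant )\n")
  invisible(x)
}

#' Tidy the scored clusters of a pipeline result
#'
#' One row per 3D cluster, with residue sets flattened to comma-joined
#' strings (broom-style).
#'
#' @param x A `mutnet_result`.
#' @param ... Unused.
#' @return Tibble.
#' @export
tidy.mutnet_result <- function(x, ...) {
  x$clusters %>%
    dplyr::mutate(
      residues_u = purrr::map_chr(.data$residues_u, paste, collapse = ","),
      residues_v = purrr::map_chr(.data$residues_v, paste, collapse = ",")
    ) %>%
    dplyr::select("cluster_id", "source", "protein_u", "protein_v",
                  "residues_u", "residues_v", "k", "O_C", "E_C", "p",
                  "p_adj", "significant")
}

#' One-row summary of a pipeline result
#'
#' @param x A `mutnet_result`.
#' @param ... Unused.
#' @return One-row tibble with cohort size, cluster/family counts, delta
#'   and module counts.
#' @export
glance.mutnet_result <- function(x, ...) {
  tibble::tibble(
    n_p = x$params$n_p,
    n_clusters = nrow(x$clusters),
    n_intra = sum(x$clusters$source %in% c("C1", "C3")),
    n_inter = sum(x$clusters$source %in% c("C2", "C4")),
    n_significant_clusters = sum(x$clusters$significant),
    n_lof_significant = sum(x$lof$significant),
    delta = x$delta,
    n_modules = nrow(x$modules),
    n_significant_modules = sum(x$modules$significant)
  )
}

#' Generic tidy/glance (broom-compatible)
#'
#' Re-exported-style generics so `tidy()`/`glance()` work without loading
#' broom.
#' @param x Object.
#' @param ... Passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Plot method for pipeline results
#'
#' Volcano-style view of the scored clusters: observed/expected ratio
#' against the raw Poisson p-value, coloured by cluster family, with the
#' significance calls marked.
#'
#' @param object A `mutnet_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mutnet_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = log2((.data$O_C + 0.5) / (.data$E_C + 0.5)),
    y = -log10(pmax(.data$p, 1e-300)),
    colour = .data$source, shape = .data$significant
  )) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "log2 observed/expected", y = "-log10 p",
                  colour = "family", shape = "significant") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.mutnet_result
#' @export
autoplot <- function(object, ...) UseMethod("autoplot")

#' Plot module sizes and heats
#'
#' Bar chart of interconnected module sizes with the significance threshold
#' marked.
#'
#' @param result A `mutnet_result`.
#' @return A ggplot object.
#' @export
plot_modules <- function(result) {
  df <- result$modules %>%
    dplyr::mutate(module_id = factor(.data$module_id,
                                     levels = .data$module_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$module_id, y = .data$size,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(
      yintercept = result$params$module_size_threshold + 0.5,
      linetype = "dashed"
    ) +
    ggplot2::labs(x = "module", y = "proteins") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90))
}

#' Plot mutated residues and clusters along one protein
#'
#' Lollipop-style view: per-residue in-frame event counts with cluster
#' extents underneath.
#'
#' @param result A `mutnet_result`.
#' @param protein Protein id.
#' @return A ggplot object.
#' @export
plot_protein_clusters <- function(result, protein) {
  mut <- result$mutated %>%
    dplyr::filter(.data$protein_id == protein) %>%
    dplyr::count(.data$residue, name = "events")
  cl <- result$clusters %>%
    dplyr::filter(.data$protein_u == protein |
                    (!is.na(.data$protein_v) & .data$protein_v == protein))
  spans <- purrr::pmap(
    list(cl$cluster_id, cl$source, cl$protein_u, cl$residues_u,
         cl$residues_v),
    function(id, src, pu, ru, rv) {
      res <- if (pu == protein) ru else rv
      if (length(res) == 0) return(NULL)
      tibble::tibble(cluster_id = id, source = src,
                     from = min(res), to = max(res))
    }
  ) %>% dplyr::bind_rows()
  p <- ggplot2::ggplot(mut, ggplot2::aes(x = .data$residue,
                                         y = .data$events)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$residue, yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::labs(title = protein, x = "residue",
                  y = "in-frame events") +
    ggplot2::theme_minimal()
  if (nrow(spans) > 0) {
    p <- p + ggplot2::geom_segment(
      data = spans,
      ggplot2::aes(x = .data$from, xend = .data$to,
                   y = -0.5, yend = -0.5, colour = .data$source),
      inherit.aes = FALSE, linewidth = 2
    )
  }
  p
}

#' Write a JSON run summary
#'
#' @param result A `mutnet_result`.
#' @param path Output file.
#' @export
write_run_summary <- function(result, path) {
  g <- glance(result)
  jsonlite::write_json(
    c(as.list(g), result$params[c("beta", "w0", "cap", "seed", "baseline")]),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
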