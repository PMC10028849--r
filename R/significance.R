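# Cluster and protein-level significance: Poisson recurrence tests with
# family-wise Bonferroni correction.

#' One-sided Poisson upper-tail probability
#'
#' `P(X >= O)` for `X ~ Poisson(E)`: the probability of observing at least
#' `O` events under the background expectation. `O = 0` returns exactly 1.
#' Computed via the regularized survival function, stable for large `O`/`E`.
#'
#' @param o Observed count (non-negative integer, vectorized).
#' @param e Expected count (positive, vectorized).
#' @return p-value in (0, 1].
#' @export
poisson_upper_tail <- function(o, e) {
  stopifnot(all(o >= 0), all(o == floor(o)))
  if (any(e <= 0)) stop("poisson_upper_tail: expected count must be > 0")
  ifelse(o == 0, 1, stats::ppois(o - 1, e, lower.tail = FALSE))
}

#' Expected in-frame mutation count of a 3D cluster
#'
#' Intra-protein: `E_C = E_u * (k / l_u) * n_p`. Inter-protein (`C2`/`C4`):
#' `E_C = (E_u * k_u / l_u + E_v * k_v / l_v) * n_p`, where `E` values are
#' expected in-frame events per sample over the full protein, `l` protein
#' lengths and `n_p` the cohort size.
#'
#' @param clusters Cluster tibble (see [intra_clusters()] and friends).
#' @param protein_backgrounds Output of [expected_protein_counts()].
#' @param n_p Number of tumor samples in the preprocessed cohort.
#' @return The cluster tibble with an `E_C` column added.
#' @export
cluster_expected_count <- function(clusters, protein_backgrounds, n_p) {
  stopifnot(n_p >= 1)
  bg <- protein_backgrounds
  iu <- match(clusters$protein_u, bg$protein_id)
  iv <- match(clusters$protein_v, bg$protein_id)
  if (anyNA(iu) || anyNA(iv[!is.na(clusters$protein_v)])) {
    stop("cluster_expected_count: cluster protein missing from backgrounds")
  }
  l_u <- bg$length[iu]
  e_u <- bg$E_in_frame[iu]
  if (any(l_u == 0, na.rm = TRUE)) stop("protein length 0")
  term_u <- e_u * clusters$k_u / l_u
  term_v <- rep(0, nrow(clusters))
  has_v <- !is.na(clusters$protein_v) & clusters$k_v > 0
  if (any(has_v)) {
    l_v <- bg$length[iv[has_v]]
    if (any(l_v == 0)) stop("protein length 0")
    term_v[has_v] <- bg$E_in_frame[iv[has_v]] * clusters$k_v[has_v] / l_v
  }
  dplyr::mutate(clusters, E_C = (term_u + term_v) * n_p)
}

#' Score 3D clusters
#'
#' Computes raw Poisson upper-tail p-values for every cluster and applies
#' Bonferroni correction separately within the structure-derived family
#' (`C1`, `C2`, `C3` together) and the interface family (`C4`). A cluster is
#' significant when its adjusted p-value is below `alpha_level`.
#'
#' @param clusters Cluster tibble carrying `O_C` (all four sources may be
#'   mixed; rows are assigned to families by `source`).
#' @param protein_backgrounds Output of [expected_protein_counts()].
#' @param n_p Cohort size.
#' @param alpha_level Significance level on adjusted p-values.
#' @return Cluster tibble with `E_C`, `p`, `p_adj`, `significant` columns.
#' @export
score_clusters <- function(clusters, protein_backgrounds, n_p,
                           alpha_level = 0.05) {
  if (nrow(clusters) == 0) {
    return(dplyr::mutate(clusters, E_C = numeric(0), p = numeric(0),
                         p_adj = numeric(0), significant = logical(0)))
  }
  clusters <- cluster_expected_count(clusters, protein_backgrounds, n_p)
  clusters %>%
    dplyr::mutate(
      p = poisson_upper_tail(.data$O_C, .data$E_C),
      family = dplyr::if_else(.data$source == "C4", "interface", "structure")
    ) %>%
    dplyr::group_by(.data$family) %>%
    dplyr::mutate(p_adj = pmin(1, .data$p * dplyr::n())) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(significant = .data$p_adj < alpha_level) %>%
    dplyr::select(-"family")
}

#' Protein-level loss-of-function enrichment
#'
#' For each protein, tests the observed LOF mutation count over the full
#' sequence against `E_u^LOF * n_p` with a Poisson upper tail; Bonferroni
#' correction is applied across all tested proteins.
#'
#' @param lof_counts Tibble with columns `protein_id`, `O_u` (observed LOF
#'   events across the cohort). Proteins in `protein_backgrounds` absent
#'   from this table are tested with `O_u = 0`.
#' @param protein_backgrounds Output of [expected_protein_counts()].
#' @param n_p Cohort size.
#' @param alpha_level Significance level on adjusted p-values.
#' @return Tibble: `protein_id`, `O_u`, `E_u`, `p`, `p_adj`, `significant`.
#' @export
lof_enrichment <- function(lof_counts, protein_backgrounds, n_p,
                           alpha_level = 0.05) {
  stopifnot(n_p >= 1)
  out <- protein_backgrounds %>%
    dplyr::left_join(lof_counts, by = "protein_id") %>%
    dplyr::mutate(
      O_u = dplyr::coalesce(.data$O_u, 0L),
      E_u = .data$E_lof * n_p,
      p = poisson_upper_tail(.data$O_u, .data$E_u)
    )
  m <- nrow(out)
  out %>%
    dplyr::mutate(p_adj = pmin(1, .data$p * m),
                  significant = .data$p_adj < alpha_level) %>%
    dplyr::select("protein_id", "O_u", "E_u", "p", "p_adj", "significant")
}

#' Count observed LOF events per protein
#'
#' @param records Mutation tibble; rows with `consequence_class == "lof"`
#'   are counted.
#' @return Tibble `protein_id`, `O_u`.
#' @export
count_lof <- function(records) {
  records %>%
    dplyr::filter(.data$consequence_class == "lof") %>%
    dplyr::count(.data$protein_id, name = "O_u") %>%
    dplyr::mutate(O_u = as.integer(.data$O_u))
}

#' Write a scored cluster table
#'
#' Serializes the cluster tibble to a tab-delimited file with residue sets
#' as comma-joined strings and deterministic row order.
#'
#' @param clusters Scored cluster tibble.
#' @param path Output path.
#' @export
write_cluster_table <- function(clusters, path) {
  out <- clusters %>%
    dplyr::mutate(
      residues_u = purrr::map_chr(.data$residues_u, paste, collapse = ","),
      residues_v = purrr::map_chr(.data$residues_v, paste, collapse = ","),
      mutation_ids = purrr::map_chr(.data$mutation_ids, paste, collapse = ",")
    ) %>%
    dplyr::arrange(.data$source, .data$cluster_id)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
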