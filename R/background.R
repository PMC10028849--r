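# Covariate-aware local background mutation model.
#
# Each gene's background mutation rate (BMR) is estimated from its own
# silent/noncoding mutations and, if those are too few, from its nearest
# neighbors in a 5-dimensional covariate space (expression, replication
# timing, chromatin compartment, GC content, gene density). Counts x are
# events; opportunities X are base.sample units, so BMR is per base per
# sample and expected counts are events per sample over the full gene.

.COVARIATE_COLS <- c("expression", "replication_timing", "chromatin",
                     "gc_content", "gene_density")

#' Read the per-gene covariate / coverage table
#'
#' Tab-delimited columns: `gene_id`, the five covariates (`expression`,
#' `replication_timing`, `chromatin`, `gc_content`, `gene_density`),
#' `N_coding`, `A_missense`, `A_nonsense`, `A_splice` (substitution-type
#' probabilities; may instead be derived from a per-base consequence table
#' via [mutation_type_fractions()]), `covered_bases_SNV`,
#' `covered_bases_indel` (per-sample opportunity lengths), `x_SNV`,
#' `x_indel` (background event counts over the cohort).
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_covariates <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = "c", .default = "d"
  ), progress = FALSE)
}

#' Nearest-neighbor pool in covariate space
#'
#' Z-scores each covariate across genes (missing values imputed to the
#' covariate median), then expands a pool around the focal gene — itself
#' first, then nearest neighbors by euclidean distance in z-space, ties
#' broken by gene id — until the pooled background SNV count reaches
#' `min_background_count` or every gene is included.
#'
#' @param gene_id Focal gene.
#' @param covariates Covariate tibble (see [read_covariates()]); must
#'   contain `x_SNV`.
#' @param min_background_count Minimum pooled silent/noncoding SNV count.
#' @return Character vector of gene ids, focal gene first, in inclusion
#'   order.
#' @export
neighbor_pool <- function(gene_id, covariates, min_background_count = 50) {
  stopifnot(gene_id %in% covariates$gene_id)
  m <- as.matrix(covariates[, .COVARIATE_COLS])
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    v[is.na(v)] <- stats::median(v, na.rm = TRUE)
    m[, j] <- v
  }
  z <- scale(m)
  z[!is.finite(z)] <- 0 # constant covariate: zero variance
  i <- match(gene_id, covariates$gene_id)
  d <- sqrt(colSums((t(z) - z[i, ])^2))
  ord <- order(d, covariates$gene_id)
  ord <- c(i, setdiff(ord, i))
  cum <- cumsum(covariates$x_SNV[ord])
  n_take <- if (any(cum >= min_background_count)) {
    which(cum >= min_background_count)[1]
  } else {
    length(ord)
  }
  covariates$gene_id[ord[seq_len(n_take)]]
}

#' Pooled background mutation rates
#'
#' `BMR_SNV = sum(x_SNV) / sum(X_SNV)` and `BMR_indel = sum(x_indel) /
#' sum(X_indel)` over the pool, where `X = covered_bases * n_samples`
#' (base.sample units), making rates per base per sample.
#'
#' @param pool Character vector of gene ids.
#' @param covariates Covariate tibble.
#' @param n_samples Number of tumor samples contributing the background
#'   counts.
#' @return Named list with `bmr_snv` and `bmr_indel`.
#' @export
compute_bmr <- function(pool, covariates, n_samples) {
  rows <- covariates[match(pool, covariates$gene_id), ]
  X_snv <- sum(rows$covered_bases_SNV) * n_samples
  X_indel <- sum(rows$covered_bases_indel) * n_samples
  if (X_snv <= 0 || X_indel <= 0) {
    stop("compute_bmr: zero background opportunity (missing coverage input)")
  }
  list(bmr_snv = sum(rows$x_SNV) / X_snv,
       bmr_indel = sum(rows$x_indel) / X_indel)
}

#' Substitution-type fractions from a per-base consequence table
#'
#' Each covered coding base has three possible substitutions; the base
#' contributes `n_t / 3` to mutation type `t` for each of its substitutions
#' of that type (a base with two missense and one nonsense substitution
#' contributes 2/3 and 1/3). `A_t = N_t / N_coding`.
#'
#' @param base_table Tibble with one row per covered coding base and columns
#'   `n_missense`, `n_nonsense`, `n_splice` (counts among the base's three
#'   substitutions; the remainder is silent).
#' @param n_coding Coding length of the gene in base pairs (defaults to the
#'   number of rows).
#' @return Named list with `N_missense`, `N_nonsense`, `N_splice`,
#'   `N_coding`, `A_missense`, `A_nonsense`, `A_splice`.
#' @export
mutation_type_fractions <- function(base_table, n_coding = nrow(base_table)) {
  if (n_coding == 0) stop("mutation_type_fractions: N_coding is zero")
  stopifnot(all(base_table$n_missense + base_table$n_nonsense +
                  base_table$n_splice <= 3))
  N_missense <- sum(base_table$n_missense) / 3
  N_nonsense <- sum(base_table$n_nonsense) / 3
  N_splice <- sum(base_table$n_splice) / 3
  list(
    N_missense = N_missense, N_nonsense = N_nonsense, N_splice = N_splice,
    N_coding = n_coding,
    A_missense = N_missense / n_coding,
    A_nonsense = N_nonsense / n_coding,
    A_splice = N_splice / n_coding
  )
}

#' Expected in-frame and LOF mutation counts per gene
#'
#' For every gene: pools neighbors ([neighbor_pool()]), computes pooled
#' rates ([compute_bmr()]), then
#' `E_in_frame = N_coding * A_missense * (BMR_SNV + alpha * BMR_indel)` and
#' `E_lof = N_coding * (A_nonsense + A_splice) * (BMR_SNV + (1 - alpha) *
#' BMR_indel)`, events per sample over the full gene. After all genes are
#' computed, each family of expectations is floored at its cohort-wide
#' `floor_quantile` quantile to avoid false positives driven by vanishing
#' local rates.
#'
#' @param covariates Covariate tibble (see [read_covariates()]).
#' @param n_samples Number of tumor samples behind the background counts.
#' @param alpha Fraction of coding indels that are in-frame (default 0.09).
#' @param floor_quantile Quantile used as the lower threshold (default
#'   0.01).
#' @param min_background_count Passed to [neighbor_pool()].
#' @return Tibble with one row per gene: `gene_id`, `bmr_snv`, `bmr_indel`,
#'   `E_in_frame`, `E_lof`, `pool_size`, plus the raw (pre-floor) values.
#' @export
expected_gene_counts <- function(covariates, n_samples, alpha = 0.09,
                                 floor_quantile = 0.01,
                                 min_background_count = 50) {
  stopifnot(alpha >= 0, alpha <= 1)
  rows <- purrr::map(covariates$gene_id, function(g) {
    pool <- neighbor_pool(g, covariates, min_background_count)
    bmr <- compute_bmr(pool, covariates, n_samples)
    gi <- covariates[match(g, covariates$gene_id), ]
    tibble::tibble(
      gene_id = g,
      bmr_snv = bmr$bmr_snv, bmr_indel = bmr$bmr_indel,
      pool_size = length(pool),
      E_in_frame_raw = gi$N_coding * gi$A_missense *
        (bmr$bmr_snv + alpha * bmr$bmr_indel),
      E_lof_raw = gi$N_coding * (gi$A_nonsense + gi$A_splice) *
        (bmr$bmr_snv + (1 - alpha) * bmr$bmr_indel)
    )
  })
  out <- dplyr::bind_rows(rows)
  floor_if <- stats::quantile(out$E_in_frame_raw, floor_quantile, names = FALSE)
  floor_lof <- stats::quantile(out$E_lof_raw, floor_quantile, names = FALSE)
  out %>%
    dplyr::mutate(E_in_frame = pmax(.data$E_in_frame_raw, floor_if),
                  E_lof = pmax(.data$E_lof_raw, floor_lof)) %>%
    dplyr::select("gene_id", "bmr_snv", "bmr_indel", "pool_size",
                  "E_in_frame_raw", "E_lof_raw", "E_in_frame", "E_lof")
}

#' Expected counts per protein
#'
#' Sums gene-level expectations over the genes encoding each protein;
#' proteins with no encoding gene in the background table fall back to the
#' median gene-level expectation.
#'
#' @param proteins Tibble with columns `protein_id`, `length` (amino
#'   acids).
#' @param gene_map Tibble with columns `protein_id`, `gene_id` (a protein
#'   may be encoded by several genes).
#' @param gene_backgrounds Output of [expected_gene_counts()].
#' @return Tibble: `protein_id`, `length`, `E_in_frame`, `E_lof`,
#'   `n_genes`.
#' @export
expected_protein_counts <- function(proteins, gene_map, gene_backgrounds) {
  med_if <- stats::median(gene_backgrounds$E_in_frame)
  med_lof <- stats::median(gene_backgrounds$E_lof)
  sums <- gene_map %>%
    dplyr::inner_join(gene_backgrounds, by = "gene_id") %>%
    dplyr::group_by(.data$protein_id) %>%
    dplyr::summarise(E_in_frame = sum(.data$E_in_frame),
                     E_lof = sum(.data$E_lof),
                     n_genes = dplyr::n(), .groups = "drop")
  proteins %>%
    dplyr::left_join(sums, by = "protein_id") %>%
    dplyr::mutate(
      n_genes = dplyr::coalesce(.data$n_genes, 0L),
      E_in_frame = dplyr::coalesce(.data$E_in_frame, med_if),
      E_lof = dplyr::coalesce(.data$E_lof, med_lof)
    ) %>%
    dplyr::select("protein_id", "length", "E_in_frame", "E_lof", "n_genes")
}
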