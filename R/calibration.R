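# Simulation studies: statistical calibration of the cluster test and
# end-to-end module-detection scenarios on synthetic data.
#
# Study conditions (fixed): cohorts of n_p = 1000 tumor samples over 50
# proteins of 200 residues each, clustered on the predicted-structure
# contact graph of the synthetic coil geometry. The null study uses the
# generator's default background rates; the detection study raises the
# background so that a 5-residue patch has an expected cluster count
# E_C = 1 over the cohort, then plants a 10-fold rate elevation on it.

#' Study conditions for the calibration simulations
#'
#' @param n_proteins,protein_length,n_samples Cohort geometry.
#' @return List with the protein table, the predicted contact graph
#'   (built once; geometry is seed-independent) and the cohort size.
#' @export
calibration_conditions <- function(n_proteins = 50, protein_length = 200,
                                   n_samples = 1000) {
  proteins <- tibble::tibble(
    protein_id = sprintf("P%03d", seq_len(n_proteins)),
    gene_id = sprintf("G%03d", seq_len(n_proteins)),
    length = as.integer(protein_length)
  )
  st <- synth_structurome(proteins)
  g3 <- build_predicted_graph(unname(st$chain_snapshots))
  list(proteins = proteins, g3 = g3, n_samples = n_samples)
}

# one synthetic cohort -> scored intra-protein (C3) clusters
.calibrate_one <- function(cond, seed, bmr_snv, bmr_indel, planted) {
  co <- synth_cohort(cond$proteins, n_samples = cond$n_samples,
                     bmr_snv = bmr_snv, bmr_indel = bmr_indel,
                     planted = planted, seed = seed)
  mutated <- expand_to_residues(
    co$mutations, dplyr::select(cond$proteins, "protein_id", "length")
  )
  clusters <- intra_clusters(cond$g3, mutated)
  gene_bg <- expected_gene_counts(co$covariates, cond$n_samples)
  protein_bg <- expected_protein_counts(
    dplyr::select(cond$proteins, "protein_id", "length"),
    dplyr::select(cond$proteins, "protein_id", "gene_id"), gene_bg
  )
  score_clusters(clusters, protein_bg, cond$n_samples)
}

#' Family-wise error rate of the cluster test under a uniform background
#'
#' Simulates cohorts with no planted clusters at the generator's default
#' background rates and reports, per seed, whether any Bonferroni-adjusted
#' cluster p-value fell below the significance level.
#'
#' @param n_seeds Number of simulated cohorts.
#' @param seed Base seed; cohort `i` uses `seed + i`.
#' @param cond Study conditions from [calibration_conditions()].
#' @return Tibble: `seed`, `n_clusters`, `any_significant`.
#' @export
run_null_calibration <- function(n_seeds = 200, seed = 0,
                                 cond = calibration_conditions()) {
  purrr::map(seq_len(n_seeds), function(i) {
    scored <- .calibrate_one(cond, seed + i, bmr_snv = 2e-6,
                             bmr_indel = 2e-7, planted = NULL)
    tibble::tibble(seed = seed + i, n_clusters = nrow(scored),
                   any_significant = any(scored$significant))
  }) %>% dplyr::bind_rows()
}

#' Detection power for a planted 10-fold hotspot patch
#'
#' Raises the background so the expected in-frame count per protein is 0.04
#' events per sample (a 5-residue patch then has E_C = 1 over the cohort),
#' plants a 10-fold rate elevation on residues 48-52 of the first protein,
#' and reports per seed whether a significant cluster overlaps the patch.
#'
#' @inheritParams run_null_calibration
#' @param multiplier Planted rate multiplier (default 10).
#' @return Tibble: `seed`, `n_clusters`, `detected`.
#' @export
run_detection_calibration <- function(n_seeds = 200, seed = 0,
                                      multiplier = 10,
                                      cond = calibration_conditions()) {
  # E_u = N_coding * A_missense * (bmr_snv + alpha * bmr_indel) = 0.04
  # with bmr_indel = bmr_snv / 10, alpha = 0.09, A_missense = 0.7:
  bmr_snv <- 0.04 / (3 * 200 * 0.7 * (1 + 0.09 / 10))
  patch <- tibble::tibble(protein_id = cond$proteins$protein_id[1],
                          res_start = 48, res_end = 52,
                          multiplier = multiplier)
  purrr::map(seq_len(n_seeds), function(i) {
    scored <- .calibrate_one(cond, seed + i, bmr_snv = bmr_snv,
                             bmr_indel = bmr_snv / 10, planted = patch)
    hit <- scored %>%
      dplyr::filter(.data$significant,
                    .data$protein_u == cond$proteins$protein_id[1]) %>%
      dplyr::mutate(overlap = purrr::map_lgl(
        .data$residues_u, function(r) any(r %in% 48:52)
      )) %>%
      dplyr::filter(.data$overlap)
    tibble::tibble(seed = seed + i, n_clusters = nrow(scored),
                   detected = nrow(hit) > 0)
  }) %>% dplyr::bind_rows()
}

#' Hub-and-leaves diffusion scenario
#'
#' End-to-end synthetic configuration with one strongly mutated hub protein
#' whose neighbors carry only background mutations: the hub exports heat
#' but receives none back, so no interconnected module should exceed the
#' size threshold.
#'
#' @param n_leaves Number of cold leaf proteins attached to the hub.
#' @param n_samples Cohort size.
#' @param seed Seed for the cohort.
#' @return A `mutnet_result`.
#' @export
demo_hub_scenario <- function(n_leaves = 8, n_samples = 300, seed = 1) {
  proteins <- tibble::tibble(
    protein_id = c("HUB", sprintf("L%02d", seq_len(n_leaves))),
    gene_id = c("HUBG", sprintf("LG%02d", seq_len(n_leaves))),
    length = 200L
  )
  st <- synth_structurome(proteins)
  g3 <- build_predicted_graph(unname(st$chain_snapshots))
  net <- tibble::tibble(protein_a = "HUB",
                        protein_b = sprintf("L%02d", seq_len(n_leaves))) %>%
    dplyr::mutate(protein_a = pmin(.data$protein_a, .data$protein_b),
                  protein_b = pmax(.data$protein_a, .data$protein_b))
  co <- synth_cohort(
    proteins, n_samples = n_samples, seed = seed,
    planted = tibble::tibble(protein_id = "HUB", res_start = 50,
                             res_end = 54, multiplier = 2000)
  )
  mutnet_run(co$mutations, net, proteins, co$covariates, g3 = g3,
             n_p = n_samples, n_random = 10, seed = seed)
}

#' Mutually-hot clique diffusion scenario
#'
#' End-to-end synthetic configuration with a 6-protein clique in which
#' every protein carries a strongly mutated patch and every pairwise
#' interaction has a mutated interface cluster, embedded in a background
#' network of cold proteins: the clique should surface as exactly one
#' significant interconnected module of size 6.
#'
#' @param n_background Number of cold background proteins.
#' @param n_samples Cohort size.
#' @param seed Seed for the cohort and background network.
#' @return A `mutnet_result`.
#' @export
demo_clique_scenario <- function(n_background = 24, n_samples = 300,
                                 seed = 1) {
  clique <- sprintf("HOT%d", 1:6)
  bg <- sprintf("B%02d", seq_len(n_background))
  proteins <- tibble::tibble(
    protein_id = c(clique, bg),
    gene_id = paste0(c(clique, bg), "G"),
    length = 200L
  )
  pairs <- utils::combn(clique, 2)
  interactions <- tibble::tibble(
    protein_a = pairs[1, ], protein_b = pairs[2, ],
    center_a = 50, center_b = 50, gap = 5
  )
  st <- synth_structurome(proteins, interactions)
  g3 <- build_predicted_graph(unname(st$chain_snapshots))
  net <- synth_network(c(clique, bg), edge_prob = 0.12, clique = clique,
                       seed = seed)
  co <- synth_cohort(
    proteins, n_samples = n_samples, seed = seed,
    planted = tibble::tibble(protein_id = clique, res_start = 48,
                             res_end = 52, multiplier = 2000)
  )
  mutnet_run(co$mutations, net, proteins, co$covariates, g3 = g3,
             interfaces = st$interfaces, n_p = n_samples, n_random = 10,
             seed = seed)
}
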