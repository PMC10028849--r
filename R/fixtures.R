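# Deterministic synthetic-data generators.
#
# Every stage of the pipeline can be exercised with no external downloads:
# toy backbone coordinates (so contact-graph code paths run on real
# geometry), Poisson cohorts with planted clusters consistent with the
# background model, and seeded random PPI networks with optional planted
# cliques. Structure geometry is a pure function of its parameters; all
# randomness in cohorts/networks flows from an explicit seed.

#' Synthetic single-chain backbone coordinates
#'
#' Residues are placed on a compact zigzag coil, one C-alpha atom per
#' residue: consecutive residues sit `spacing` Angstrom apart (default 3.8,
#' the C-alpha virtual bond length) and the chain rises `rise` Angstrom per
#' residue, so with the defaults the i/i+1 distance is 3.8 and the i/i+2
#' distance 5.8 — both within the 6 Angstrom intra-chain cutoff, as in real
#' folded backbones — while residues three or more apart exceed it
#' (i/i+3 is about 9.0).
#'
#' @param protein_id Protein accession.
#' @param length Number of residues.
#' @param spacing Consecutive-residue distance in Angstrom.
#' @param rise Axial rise per residue in Angstrom (must be < `spacing`).
#' @param chain Chain identifier.
#' @param structure_id Structure identifier.
#' @return A snapshot tibble (see [read_structure()] for columns).
#' @export
synth_chain <- function(protein_id, length, spacing = 3.8, rise = 2.9,
                        chain = "A",
                        structure_id = paste0("synth_", protein_id)) {
  stopifnot(rise < spacing)
  i <- seq_len(length)
  lateral <- sqrt(spacing^2 - rise^2)
  tibble::tibble(
    structure_id = structure_id, model = 1L, chain = chain,
    author_resid = i,
    protein_id = protein_id, protein_resid = i,
    x = lateral * (i %% 2), y = 0, z = rise * (i - 1)
  )
}

#' Synthetic structurome: chains, complexes and interface annotations
#'
#' Generates one single-chain snapshot per protein (used for both the
#' experimental intra-chain graph and the predicted graph) and, for each
#' requested interaction, a two-chain complex snapshot in which the two
#' backbones cross perpendicularly: chain A runs along z, chain B along x
#' at height `gap`, crossing above residue `center_a` of A and `center_b`
#' of B. With `gap = 5` the residues within 9 Angstrom of the partner chain
#' form a compact patch of a few residues per side; `gap > 9` yields no
#' inter-chain contact at all. Interface annotations
#' are derived from the same geometry (residues with any inter-chain
#' distance at most `interface_cutoff`) and labelled "very high".
#'
#' @param proteins Tibble with columns `protein_id`, `length`.
#' @param interactions Optional tibble with columns `protein_a`,
#'   `protein_b`, `center_a`, `center_b`, `gap`.
#' @param spacing Backbone spacing in Angstrom.
#' @param interface_cutoff Distance defining annotated interface residues.
#' @return List: `chain_snapshots` (one per protein), `complex_snapshots`
#'   (one per interaction), `interfaces` (annotation tibble).
#' @export
synth_structurome <- function(proteins, interactions = NULL, spacing = 3.8,
                              interface_cutoff = 9) {
  stopifnot(all(proteins$length >= 1))
  chains <- purrr::map2(proteins$protein_id, proteins$length, synth_chain,
                        spacing = spacing)
  names(chains) <- proteins$protein_id
  complexes <- list()
  interfaces <- list()
  if (!is.null(interactions) && nrow(interactions) > 0) {
    for (r in seq_len(nrow(interactions))) {
      a <- interactions$protein_a[r]; b <- interactions$protein_b[r]
      ca <- interactions$center_a[r]; cb <- interactions$center_b[r]
      gap <- interactions$gap[r]
      la <- proteins$length[proteins$protein_id == a]
      lb <- proteins$length[proteins$protein_id == b]
      stopifnot(length(la) == 1, length(lb) == 1, ca <= la, cb <= lb)
      sid <- paste0("synth_cx_", a, "_", b)
      rise <- 2.9
      lateral <- sqrt(spacing^2 - rise^2)
      snap_a <- synth_chain(a, la, spacing, rise, chain = "A",
                            structure_id = sid)
      center_xyz <- snap_a[ca, c("x", "y", "z")]
      j <- seq_len(lb)
      snap_b <- tibble::tibble(
        structure_id = sid, model = 1L, chain = "B",
        author_resid = j, protein_id = b, protein_resid = j,
        x = center_xyz$x + rise * (j - cb), y = gap,
        z = center_xyz$z + lateral * (j %% 2)
      )
      cx <- dplyr::bind_rows(snap_a, snap_b)
      complexes[[length(complexes) + 1]] <- cx
      # geometric interface: residues within cutoff of the partner chain
      d2 <- outer(snap_a$x, snap_b$x, "-")^2 + gap^2 +
        outer(snap_a$z, snap_b$z, "-")^2
      close <- d2 <= interface_cutoff^2
      res_a <- which(apply(close, 1, any))
      res_b <- which(apply(close, 2, any))
      if (length(res_a) > 0 || length(res_b) > 0) {
        interfaces[[length(interfaces) + 1]] <- tibble::tibble(
          protein_a = min(a, b), protein_b = max(a, b),
          protein = c(rep(a, length(res_a)), rep(b, length(res_b))),
          residue = as.integer(c(res_a, res_b)),
          confidence = "very high"
        )
      }
    }
  }
  list(
    chain_snapshots = chains,
    complex_snapshots = complexes,
    interfaces = if (length(interfaces)) dplyr::bind_rows(interfaces) else
      tibble::tibble(protein_a = character(), protein_b = character(),
                     protein = character(), residue = integer(),
                     confidence = character())
  )
}

#' Synthetic tumor cohort with planted 3D clusters
#'
#' Draws per-residue in-frame mutation counts as Poisson with cohort rate
#' `E_g^in-frame / l_g * n_samples` (so the generator and the background
#' model share one parameterization), multiplied inside planted regions by
#' their rate multiplier; LOF counts over whole genes analogously; and
#' silent/noncoding background counts at the same per-base rates. Also
#' emits an expression table (all genes expressed unless listed) and a
#' covariate/coverage table with substitution-type probabilities supplied
#' directly.
#'
#' @param proteins Tibble `protein_id`, `gene_id`, `length` (one gene per
#'   protein here; many-to-one maps can be built by hand).
#' @param n_samples Cohort size.
#' @param bmr_snv,bmr_indel True background rates per base per sample.
#' @param alpha In-frame fraction of coding indels.
#' @param a_missense,a_nonsense,a_splice Substitution-type probabilities.
#' @param planted Optional tibble `protein_id`, `res_start`, `res_end`,
#'   `multiplier` of planted in-frame rate elevations.
#' @param lof_multiplier Named numeric vector (by gene) of LOF rate
#'   multipliers, default 1 everywhere.
#' @param unexpressed_genes Genes emitted at FPKM below 1 in all samples.
#' @param n_expression_samples Samples per cancer type in the expression
#'   table.
#' @param cancer_type Cancer type label for all samples.
#' @param seed Integer seed; fully determines the output.
#' @return List: `mutations` (record tibble), `expression`, `covariates`,
#'   `true` (per-gene true expectations per sample).
#' @export
synth_cohort <- function(proteins, n_samples = 1000,
                         bmr_snv = 2e-6, bmr_indel = 2e-7, alpha = 0.09,
                         a_missense = 0.7, a_nonsense = 0.03,
                         a_splice = 0.01,
                         planted = NULL, lof_multiplier = NULL,
                         unexpressed_genes = character(),
                         n_expression_samples = 50,
                         cancer_type = "SYNTH", seed = 1) {
  set.seed(seed)
  n_g <- nrow(proteins)
  n_coding <- 3 * proteins$length
  e_inframe <- n_coding * a_missense * (bmr_snv + alpha * bmr_indel)
  e_lof <- n_coding * (a_nonsense + a_splice) *
    (bmr_snv + (1 - alpha) * bmr_indel)
  sample_ids <- sprintf("S%04d", seq_len(n_samples))

  records <- list()
  for (g in seq_len(n_g)) {
    l <- proteins$length[g]
    lam <- rep(e_inframe[g] / l * n_samples, l)
    if (!is.null(planted)) {
      pl <- planted[planted$protein_id == proteins$protein_id[g], ]
      for (r in seq_len(nrow(pl))) {
        idx <- pl$res_start[r]:pl$res_end[r]
        lam[idx] <- lam[idx] * pl$multiplier[r]
      }
    }
    counts <- stats::rpois(l, lam)
    tot <- sum(counts)
    if (tot > 0) {
      records[[length(records) + 1]] <- tibble::tibble(
        sample_id = sample(sample_ids, tot, replace = TRUE),
        gene_id = proteins$gene_id[g],
        protein_id = proteins$protein_id[g],
        residue_start = rep(seq_len(l), counts),
        residue_end = rep(seq_len(l), counts),
        consequence_term = "missense_variant"
      )
    }
    lof_mult <- if (!is.null(lof_multiplier) &&
                    proteins$gene_id[g] %in% names(lof_multiplier)) {
      lof_multiplier[[proteins$gene_id[g]]]
    } else 1
    n_lof <- stats::rpois(1, e_lof[g] * n_samples * lof_mult)
    if (n_lof > 0) {
      pos <- sample.int(l, n_lof, replace = TRUE)
      records[[length(records) + 1]] <- tibble::tibble(
        sample_id = sample(sample_ids, n_lof, replace = TRUE),
        gene_id = proteins$gene_id[g],
        protein_id = proteins$protein_id[g],
        residue_start = pos, residue_end = pos,
        consequence_term = "stop_gained"
      )
    }
  }
  mutations <- dplyr::bind_rows(records)
  if (nrow(mutations) == 0) {
    mutations <- tibble::tibble(
      sample_id = character(), gene_id = character(),
      protein_id = character(), residue_start = integer(),
      residue_end = integer(), consequence_term = character()
    )
  }
  mutations <- mutations %>%
    dplyr::mutate(
      cancer_type = cancer_type,
      consequence_class = classify_consequence(.data$consequence_term),
      population_af = NA_real_
    ) %>%
    dplyr::arrange(.data$protein_id, .data$residue_start, .data$sample_id) %>%
    dplyr::select("sample_id", "cancer_type", "gene_id", "protein_id",
                  "residue_start", "residue_end", "consequence_term",
                  "consequence_class", "population_af")

  # background (silent/noncoding) counts at the same per-base rates
  covered_snv <- n_coding
  covered_indel <- n_coding
  covariates <- tibble::tibble(
    gene_id = proteins$gene_id,
    expression = stats::rlnorm(n_g, log(10), 0.8),
    replication_timing = stats::rnorm(n_g),
    chromatin = stats::rnorm(n_g),
    gc_content = stats::runif(n_g, 0.35, 0.6),
    gene_density = stats::rlnorm(n_g, 0, 0.5),
    N_coding = n_coding,
    A_missense = a_missense, A_nonsense = a_nonsense, A_splice = a_splice,
    covered_bases_SNV = covered_snv,
    covered_bases_indel = covered_indel,
    x_SNV = stats::rpois(n_g, bmr_snv * covered_snv * n_samples),
    x_indel = stats::rpois(n_g, bmr_indel * covered_indel * n_samples)
  )

  expr_samples <- sprintf("E%03d", seq_len(n_expression_samples))
  expression <- tidyr::expand_grid(
    gene_id = proteins$gene_id, sample_id = expr_samples
  ) %>%
    dplyr::mutate(
      cancer_type = cancer_type,
      fpkm = dplyr::if_else(.data$gene_id %in% unexpressed_genes,
                            stats::runif(dplyr::n(), 0, 0.5),
                            stats::rlnorm(dplyr::n(), log(20), 0.5) + 1)
    ) %>%
    dplyr::select("gene_id", "cancer_type", "sample_id", "fpkm")

  list(
    mutations = mutations,
    expression = expression,
    covariates = covariates,
    true = tibble::tibble(gene_id = proteins$gene_id,
                          E_in_frame = e_inframe, E_lof = e_lof)
  )
}

#' Synthetic PPI network
#'
#' Seeded Erdos-Renyi graph over the given proteins with an optional
#' planted clique; simple and self-loop-free by construction.
#'
#' @param protein_ids Character vector of vertices.
#' @param edge_prob Edge probability.
#' @param clique Optional character vector of proteins forced into a
#'   clique.
#' @param seed Integer seed.
#' @return Edge tibble `protein_a`, `protein_b` (sorted within row, no
#'   duplicates).
#' @export
synth_network <- function(protein_ids, edge_prob = 0.05, clique = NULL,
                          seed = 1) {
  set.seed(seed)
  n <- length(protein_ids)
  pairs <- if (n >= 2) utils::combn(sort(protein_ids), 2) else
    matrix(character(), 2, 0)
  take <- stats::runif(ncol(pairs)) < edge_prob
  edges <- tibble::tibble(protein_a = pairs[1, take],
                          protein_b = pairs[2, take])
  if (!is.null(clique) && length(clique) >= 2) {
    cl <- utils::combn(sort(clique), 2)
    edges <- dplyr::bind_rows(
      edges, tibble::tibble(protein_a = cl[1, ], protein_b = cl[2, ])
    ) %>% dplyr::distinct()
  }
  dplyr::arrange(edges, .data$protein_a, .data$protein_b)
}

#' Write a snapshot as a minimal PDB file
#'
#' One C-alpha ATOM record per residue; useful for exercising the structure
#' reader on generated geometry. A companion residue-mapping tibble is
#' returned invisibly.
#'
#' @param snap Snapshot tibble.
#' @param path Output file.
#' @return Invisibly, the SIFTS-like mapping tibble for the snapshot.
#' @export
write_snapshot_pdb <- function(snap, path) {
  lines <- character(0)
  serial <- 0
  for (m in sort(unique(snap$model))) {
    sm <- snap[snap$model == m, ]
    if (length(unique(snap$model)) > 1) {
      lines <- c(lines, sprintf("MODEL     %4d", m))
    }
    for (r in seq_len(nrow(sm))) {
      serial <- serial + 1
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial, sm$chain[r], sm$author_resid[r], sm$x[r], sm$y[r], sm$z[r]
      ))
    }
    if (length(unique(snap$model)) > 1) lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  invisible(dplyr::distinct(snap, .data$structure_id, .data$chain,
                            .data$author_resid, .data$protein_id,
                            .data$protein_resid))
}

#' Write mutation records as a MAF-like file
#'
#' Emits the default MC3/VEP column dialect so the result round-trips
#' through [read_mutations()].
#'
#' @param records Mutation tibble.
#' @param path Output file.
#' @export
write_mutations_maf <- function(records, path) {
  out <- tibble::tibble(
    Hugo_Symbol = records$gene_id,
    Tumor_Sample_Barcode = records$sample_id,
    Cancer_Type = records$cancer_type,
    Consequence = records$consequence_term,
    Protein_position = ifelse(
      records$residue_start == records$residue_end,
      as.character(records$residue_start),
      paste0(records$residue_start, "-", records$residue_end)
    ),
    SWISSPROT = records$protein_id,
    gnomADe_AF = records$population_af
  )
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}
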