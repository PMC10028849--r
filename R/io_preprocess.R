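#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

# Controlled consequence vocabularies (VEP "Consequence" terms).
.IN_FRAME_TERMS <- c("missense_variant", "inframe_deletion", "inframe_insertion")
.LOF_TERMS <- c(
  "frameshift_variant", "stop_gained", "stop_lost", "start_lost",
  "splice_acceptor_variant", "splice_donor_variant",
  "splice_donor_5th_base_variant"
)
.BACKGROUND_TERMS <- c(
  "synonymous_variant", "stop_retained_variant", "start_retained_variant",
  "intron_variant", "5_prime_UTR_variant", "3_prime_UTR_variant",
  "upstream_gene_variant", "downstream_gene_variant", "intergenic_variant",
  "non_coding_transcript_exon_variant", "non_coding_transcript_variant"
)

#' Classify a VEP consequence term
#'
#' Maps a VEP-style consequence term onto the four classes the pipeline
#' distinguishes: `in_frame` (missense and in-frame indels, eligible for 3D
#' clustering), `lof` (truncating / splice-disrupting, used for
#' loss-of-function enrichment), `background` (silent and noncoding terms
#' usable for background mutation-rate estimation) and `excluded`
#' (everything else). Unknown terms map to `excluded`; the function is total.
#'
#' @param term Character vector of consequence terms.
#' @return Character vector of the same length with values in
#'   `c("in_frame", "lof", "background", "excluded")`.
#' @examples
#' classify_consequence(c("missense_variant", "frameshift_variant", "weird"))
#' @export
classify_consequence <- function(term) {
  stopifnot(is.character(term))
  out <- rep("excluded", length(term))
  out[term %in% .IN_FRAME_TERMS] <- "in_frame"
  out[term %in% .LOF_TERMS] <- "lof"
  out[term %in% .BACKGROUND_TERMS] <- "background"
  out
}

#' Default column mapping for MAF-like mutation tables
#'
#' Column names follow MC3/VEP conventions; override any entry to adapt to a
#' different dialect.
#'
#' @param ... Named overrides, e.g. `protein_id = "uniprot"`.
#' @return Named list mapping logical fields to file column names.
#' @export
mutation_dialect <- function(...) {
  dialect <- list(
    gene_id = "Hugo_Symbol",
    sample_id = "Tumor_Sample_Barcode",
    cancer_type = "Cancer_Type",
    consequence = "Consequence",
    protein_position = "Protein_position",
    protein_id = "SWISSPROT",
    population_af = "gnomADe_AF"
  )
  utils::modifyList(dialect, list(...))
}

# Parse VEP-style Protein_position strings ("42", "10-12", "42/500") into
# 1-based inclusive start/end. Returns NA on failure.
.parse_protein_position <- function(x) {
  x <- sub("/.*$", "", x)
  m <- regmatches(x, regexec("^([0-9]+)(?:-([0-9]+))?$", x))
  starts <- vapply(m, function(g) {
    if (length(g) == 0) NA_integer_ else suppressWarnings(as.integer(g[2]))
  }, integer(1))
  ends <- vapply(m, function(g) {
    if (length(g) == 0 || is.na(g[3]) || g[3] == "") NA_integer_
    else suppressWarnings(as.integer(g[3]))
  }, integer(1))
  ends[is.na(ends)] <- starts[is.na(ends)]
  list(start = starts, end = ends)
}

#' Read a MAF-like somatic mutation table
#'
#' Reads a tab-delimited, VEP-consequence-annotated mutation table that has
#' already been mapped to UniProt accessions and 1-based protein residue
#' coordinates, validates every row, classifies consequences and collapses
#' duplicate rows (same sample, protein, residue range and term).
#'
#' Rows that fail validation (unparseable or non-positive residue
#' coordinates, empty protein id) are dropped with a per-row message under
#' `strict = FALSE`, or abort the read under `strict = TRUE`. A missing
#' required column is always fatal.
#'
#' @param path Path to the tab-delimited file.
#' @param dialect Column mapping, see [mutation_dialect()].
#' @param strict If `TRUE`, any malformed row is an error; otherwise
#'   malformed rows are skipped with a summary message.
#' @return A tibble of mutation records with columns `sample_id`,
#'   `cancer_type`, `gene_id`, `protein_id`, `residue_start`, `residue_end`,
#'   `consequence_term`, `consequence_class`, `population_af`.
#' @export
read_mutations <- function(path, dialect = mutation_dialect(), strict = FALSE) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("sample_id", "consequence", "protein_id", "protein_position")
  for (field in required) {
    col <- dialect[[field]]
    if (!col %in% names(raw)) {
      stop("required column '", col, "' (", field, ") missing from ", path)
    }
  }
  get_col <- function(field, default = NA_character_) {
    col <- dialect[[field]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]]
    else rep(default, nrow(raw))
  }
  pos <- .parse_protein_position(get_col("protein_position"))
  af_raw <- get_col("population_af")
  records <- tibble::tibble(
    row = seq_len(nrow(raw)),
    sample_id = get_col("sample_id"),
    cancer_type = dplyr::coalesce(get_col("cancer_type"), "UNKNOWN"),
    gene_id = get_col("gene_id"),
    protein_id = get_col("protein_id"),
    residue_start = pos$start,
    residue_end = pos$end,
    consequence_term = get_col("consequence"),
    population_af = suppressWarnings(as.numeric(af_raw))
  )
  bad <- is.na(records$residue_start) | records$residue_start < 1 |
    records$residue_end < records$residue_start |
    is.na(records$protein_id) | records$protein_id == "" |
    is.na(records$sample_id) | records$sample_id == "" |
    (!is.na(records$population_af) &
       (records$population_af < 0 | records$population_af > 1))
  if (any(bad)) {
    msg <- paste0("rows failed validation: ",
                  paste(records$row[bad], collapse = ", "))
    if (strict) stop(msg) else message("read_mutations: skipped ", sum(bad),
                                       " malformed row(s) [", msg, "]")
  }
  records %>%
    dplyr::filter(!bad) %>%
    dplyr::mutate(consequence_class = classify_consequence(.data$consequence_term)) %>%
    dplyr::distinct(.data$sample_id, .data$protein_id, .data$residue_start,
                    .data$residue_end, .data$consequence_term,
                    .keep_all = TRUE) %>%
    dplyr::select("sample_id", "cancer_type", "gene_id", "protein_id",
                  "residue_start", "residue_end", "consequence_term",
                  "consequence_class", "population_af")
}

#' Remove putative germline variants
#'
#' Drops records with a non-zero population allele frequency (observed in a
#' population resource such as gnomAD). Records with a zero or absent allele
#' frequency are kept: absence means the variant was not seen in the
#' population resource.
#'
#' @param records Mutation tibble from [read_mutations()].
#' @return Filtered tibble.
#' @export
filter_germline <- function(records) {
  dplyr::filter(records, is.na(.data$population_af) | .data$population_af == 0)
}

#' The 18 known cancer genes exempt from the expression filter
#'
#' Well-known cancer genes with low transcript detection levels that are kept
#' regardless of measured expression.
#'
#' @return Character vector of gene symbols.
#' @export
expression_exempt_genes <- function() {
  c("AR", "CDH4", "EGFR", "EPHA3", "ERBB4", "FGFR2", "FLT3", "FOXA1",
    "FOXA2", "MECOM", "MIR142", "MSH4", "PDGFRA", "SOX1", "SOX9", "SOX17",
    "TBX3", "WT1")
}

# Per (gene, cancer_type): is the gene expressed (>= min_fpkm in >= min_frac
# of that type's samples)? Sample universe per type = distinct samples in the
# expression table for that type.
.expressed_table <- function(expr, min_fpkm = 1, min_frac = 0.8) {
  expr %>%
    dplyr::group_by(.data$cancer_type) %>%
    dplyr::mutate(.n_samples = dplyr::n_distinct(.data$sample_id)) %>%
    dplyr::group_by(.data$gene_id, .data$cancer_type) %>%
    dplyr::summarise(
      expressed = sum(.data$fpkm >= min_fpkm) >= min_frac * .data$.n_samples[1],
      .groups = "drop"
    )
}

#' Remove mutations in unexpressed genes
#'
#' A record is kept iff its gene is expressed in its cancer type (FPKM at or
#' above `min_fpkm` in at least `min_frac` of that type's tumor samples), or
#' the gene is on the exempt list, or the record's cancer type is `UNKNOWN`
#' and the gene is expressed in at least `min_frac` of the cancer types in
#' the expression table. Genes absent from the expression table are treated
#' as unexpressed (logged).
#'
#' @param records Mutation tibble.
#' @param expr Long expression tibble with columns `gene_id`, `cancer_type`,
#'   `sample_id`, `fpkm`.
#' @param exempt_genes Genes kept regardless of expression; defaults to
#'   [expression_exempt_genes()].
#' @param min_fpkm,min_frac Expression call thresholds.
#' @return Filtered tibble.
#' @export
filter_expression <- function(records, expr,
                              exempt_genes = expression_exempt_genes(),
                              min_fpkm = 1, min_frac = 0.8) {
  stopifnot(all(c("gene_id", "cancer_type", "sample_id", "fpkm") %in%
                  names(expr)))
  etab <- .expressed_table(expr, min_fpkm, min_frac)
  n_types <- dplyr::n_distinct(etab$cancer_type)
  # genes expressed in >= min_frac of cancer types (for UNKNOWN-type samples)
  pan <- etab %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(pan_expressed = sum(.data$expressed) >= min_frac * n_types,
                     .groups = "drop")
  out <- records %>%
    dplyr::left_join(etab, by = c("gene_id", "cancer_type")) %>%
    dplyr::left_join(pan, by = "gene_id") %>%
    dplyr::mutate(
      expressed = dplyr::coalesce(.data$expressed, FALSE),
      pan_expressed = dplyr::coalesce(.data$pan_expressed, FALSE),
      keep = .data$gene_id %in% exempt_genes |
        dplyr::if_else(.data$cancer_type == "UNKNOWN",
                       .data$pan_expressed, .data$expressed)
    )
  missing <- setdiff(unique(records$gene_id), unique(expr$gene_id))
  missing <- setdiff(missing, exempt_genes)
  if (length(missing) > 0) {
    message("filter_expression: ", length(missing),
            " gene(s) absent from expression table treated as unexpressed")
  }
  out %>%
    dplyr::filter(.data$keep) %>%
    dplyr::select(-"expressed", -"pan_expressed", -"keep")
}

#' Read a binary PPI edge list
#'
#' Reads a two-column tab-delimited edge list of protein identifiers into a
#' simple undirected graph: self-loops and duplicate edges (in either order)
#' are dropped with counts logged. When an expression table is supplied,
#' only edges whose both endpoints are expressed in at least one cancer type
#' (or exempt) are retained.
#'
#' @param path Path to the edge list (header optional; first two columns are
#'   used).
#' @param expr Optional expression tibble (see [filter_expression()]).
#' @param exempt_genes Genes considered expressed regardless of data.
#' @param min_fpkm,min_frac Expression call thresholds.
#' @return A tibble with columns `protein_a`, `protein_b`, one row per
#'   undirected edge, `protein_a < protein_b`.
#' @export
read_network <- function(path, expr = NULL,
                         exempt_genes = expression_exempt_genes(),
                         min_fpkm = 1, min_frac = 0.8) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0) stop("empty edge list: ", path)
  edges <- tibble::tibble(a = raw[[1]], b = raw[[2]])
  n0 <- nrow(edges)
  edges <- dplyr::filter(edges, .data$a != .data$b)
  n_loops <- n0 - nrow(edges)
  edges <- edges %>%
    dplyr::mutate(protein_a = pmin(.data$a, .data$b),
                  protein_b = pmax(.data$a, .data$b)) %>%
    dplyr::distinct(.data$protein_a, .data$protein_b)
  n_dupes <- n0 - n_loops - nrow(edges)
  if (n_loops + n_dupes > 0) {
    message("read_network: dropped ", n_loops, " self-loop(s) and ",
            n_dupes, " duplicate edge(s)")
  }
  if (!is.null(expr)) {
    etab <- .expressed_table(expr, min_fpkm, min_frac)
    expressed_any <- etab %>%
      dplyr::group_by(.data$gene_id) %>%
      dplyr::summarise(any_expr = any(.data$expressed), .groups = "drop") %>%
      dplyr::filter(.data$any_expr) %>%
      dplyr::pull("gene_id")
    ok <- union(expressed_any, exempt_genes)
    edges <- dplyr::filter(edges, .data$protein_a %in% ok,
                           .data$protein_b %in% ok)
  }
  edges
}

# igraph view of an edge tibble; vertices with degree 0 never appear.
.network_igraph <- function(edges) {
  igraph::graph_from_data_frame(
    edges[, c("protein_a", "protein_b")], directed = FALSE
  )
}
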