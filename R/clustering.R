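# 3D cluster identification.
#
# Clusters are connected components of mutated residues under a residue
# contact graph: C1 from the experimental intra-chain graph, C3 from the
# predicted-structure graph, C2 from per-PPI merged graphs containing at
# least one mutated inter-chain contact, and C4 from annotated interface
# residues. A residue may legitimately sit in one cluster of each family;
# families are scored independently.

#' Expand in-frame mutations to their residue footprints
#'
#' Missense mutations map to a single residue, in-frame deletions to every
#' residue of their range, in-frame insertions to the anchor residue(s) at
#' the insertion site. Residues beyond the protein length are dropped with a
#' warning; records on proteins of unknown length are skipped and logged.
#'
#' @param records Mutation tibble; only rows with
#'   `consequence_class == "in_frame"` are used.
#' @param protein_lengths Tibble with columns `protein_id`, `length` (amino
#'   acids).
#' @return Tibble with one row per (mutation, footprint residue):
#'   `mutation_id` (row index into the in-frame records), `protein_id`,
#'   `residue`, `sample_id`, `cancer_type`.
#' @export
expand_to_residues <- function(records, protein_lengths) {
  stopifnot(all(c("protein_id", "length") %in% names(protein_lengths)))
  inframe <- records %>%
    dplyr::filter(.data$consequence_class == "in_frame") %>%
    dplyr::mutate(mutation_id = dplyr::row_number())
  unknown <- setdiff(unique(inframe$protein_id), protein_lengths$protein_id)
  if (length(unknown) > 0) {
    message("expand_to_residues: skipped records on ", length(unknown),
            " protein(s) of unknown length")
  }
  inframe <- dplyr::inner_join(inframe, protein_lengths,
                               by = "protein_id")
  if (nrow(inframe) == 0) {
    return(tibble::tibble(mutation_id = integer(), protein_id = character(),
                          residue = integer(), sample_id = character(),
                          cancer_type = character()))
  }
  fp <- inframe %>%
    dplyr::mutate(
      res_from = dplyr::if_else(.data$consequence_term == "missense_variant",
                                .data$residue_start, .data$residue_start),
      res_to = dplyr::if_else(.data$consequence_term == "missense_variant",
                              .data$residue_start, .data$residue_end)
    ) %>%
    dplyr::rowwise() %>%
    dplyr::mutate(residue = list(seq(.data$res_from, .data$res_to))) %>%
    dplyr::ungroup() %>%
    tidyr::unnest("residue")
  n_oob <- sum(fp$residue > fp$length)
  if (n_oob > 0) {
    warning("expand_to_residues: dropped ", n_oob,
            " footprint residue(s) beyond protein length")
  }
  fp %>%
    dplyr::filter(.data$residue <= .data$length) %>%
    dplyr::select("mutation_id", "protein_id", "residue", "sample_id",
                  "cancer_type") %>%
    dplyr::arrange(.data$protein_id, .data$residue, .data$mutation_id)
}

.empty_clusters <- function() {
  tibble::tibble(
    cluster_id = character(), source = character(),
    protein_u = character(), protein_v = character(),
    residues_u = list(), residues_v = list(),
    k_u = integer(), k_v = integer(), k = integer(),
    O_C = integer(), mutation_ids = list()
  )
}

# Count mutation events (distinct mutation_id) touching a residue set.
.count_events <- function(mutated, protein_u, res_u, protein_v = NA,
                          res_v = integer()) {
  hit <- (mutated$protein_id == protein_u & mutated$residue %in% res_u)
  if (!is.na(protein_v)) {
    hit <- hit | (mutated$protein_id == protein_v & mutated$residue %in% res_v)
  }
  ids <- sort(unique(mutated$mutation_id[hit]))
  list(o = length(ids), ids = ids)
}

#' Intra-protein 3D clusters
#'
#' Extracts the subgraph of the contact graph induced by mutated residues;
#' connected components are the clusters. Mutated residues that are vertices
#' of the graph but have no mutated contact partner form singleton clusters;
#' mutated residues outside the graph's vertex set (no structural coverage)
#' are excluded from this family.
#'
#' @param graph A `contact_graph` of kind `intra_experimental` (clusters
#'   labelled `C1`) or `intra_predicted` (`C3`).
#' @param mutated Footprint tibble from [expand_to_residues()].
#' @return Cluster tibble (one row per cluster) with observed event counts
#'   `O_C` and member mutation ids.
#' @export
intra_clusters <- function(graph, mutated) {
  stopifnot(inherits(graph, "contact_graph"),
            graph$kind %in% c("intra_experimental", "intra_predicted"))
  source <- if (graph$kind == "intra_experimental") "C1" else "C3"
  mut_res <- dplyr::distinct(mutated, .data$protein_id, .data$residue)
  covered <- dplyr::semi_join(
    mut_res,
    dplyr::rename(graph$vertices, residue = "protein_resid"),
    by = c("protein_id", "residue")
  )
  if (nrow(covered) == 0) return(.empty_clusters())
  vkey <- paste(covered$protein_id, covered$residue, sep = "|")
  e <- graph$edges
  ekey_u <- paste(e$protein_u, e$res_u, sep = "|")
  ekey_v <- paste(e$protein_v, e$res_v, sep = "|")
  keep <- ekey_u %in% vkey & ekey_v %in% vkey
  g <- igraph::graph_from_data_frame(
    data.frame(from = ekey_u[keep], to = ekey_v[keep]),
    directed = FALSE,
    vertices = data.frame(name = vkey)
  )
  comp <- igraph::components(g)
  mem <- dplyr::mutate(covered, comp = unname(comp$membership))
  events <- mutated %>%
    dplyr::inner_join(mem, by = c("protein_id", "residue")) %>%
    dplyr::group_by(.data$comp) %>%
    dplyr::summarise(
      O_C = dplyr::n_distinct(.data$mutation_id),
      mutation_ids = list(sort(unique(.data$mutation_id))),
      .groups = "drop"
    )
  mem %>%
    dplyr::group_by(.data$comp) %>%
    dplyr::summarise(
      protein_u = .data$protein_id[1],
      residues_u = list(sort(.data$residue)),
      k_u = dplyr::n(), .groups = "drop"
    ) %>%
    dplyr::inner_join(events, by = "comp") %>%
    dplyr::mutate(
      cluster_id = paste(source, .data$protein_u,
                         purrr::map_int(.data$residues_u, 1), sep = ":"),
      source = source,
      protein_v = NA_character_,
      residues_v = list(integer()),
      k_v = 0L, k = .data$k_u,
      O_C = as.integer(.data$O_C)
    ) %>%
    dplyr::select("cluster_id", "source", "protein_u", "protein_v",
                  "residues_u", "residues_v", "k_u", "k_v", "k", "O_C",
                  "mutation_ids") %>%
    dplyr::arrange(.data$cluster_id)
}

#' Inter-protein 3D clusters from inter-chain contacts
#'
#' For each protein pair in the interaction set, merges the two proteins'
#' mutated intra-chain subgraphs with the mutated inter-chain contacts of
#' that pair; connected components containing at least one inter-chain edge
#' are reported as `C2` clusters. Components held together only by
#' intra-chain contacts are not reported here (they belong to `C1`).
#'
#' @param intra_graph The experimental intra-chain `contact_graph` (source
#'   of intra edges and coverage).
#' @param inter_graph The inter-chain `contact_graph`.
#' @param mutated Footprint tibble from [expand_to_residues()].
#' @param ppi Tibble of interactions with columns `protein_a`, `protein_b`;
#'   only these pairs are examined.
#' @return Cluster tibble with per-side residue sets (`k_u`, `k_v`).
#' @export
inter_clusters <- function(intra_graph, inter_graph, mutated, ppi) {
  stopifnot(inherits(inter_graph, "contact_graph"))
  mut_res <- dplyr::distinct(mutated, .data$protein_id, .data$residue)
  mut_key <- paste(mut_res$protein_id, mut_res$residue, sep = "|")
  ie <- inter_graph$edges
  ie_key_u <- paste(ie$protein_u, ie$res_u, sep = "|")
  ie_key_v <- paste(ie$protein_v, ie$res_v, sep = "|")
  ie_mut <- ie[ie_key_u %in% mut_key & ie_key_v %in% mut_key, ]
  ae <- intra_graph$edges
  ae_key_u <- paste(ae$protein_u, ae$res_u, sep = "|")
  ae_key_v <- paste(ae$protein_v, ae$res_v, sep = "|")
  ae_mut <- ae[ae_key_u %in% mut_key & ae_key_v %in% mut_key, ]
  cov_v <- dplyr::semi_join(
    mut_res,
    dplyr::rename(intra_graph$vertices, residue = "protein_resid"),
    by = c("protein_id", "residue")
  )
  out <- vector("list", nrow(ppi))
  for (r in seq_len(nrow(ppi))) {
    a <- min(ppi$protein_a[r], ppi$protein_b[r])
    b <- max(ppi$protein_a[r], ppi$protein_b[r])
    pe <- ie_mut[(ie_mut$protein_u == a & ie_mut$protein_v == b) |
                   (ie_mut$protein_u == b & ie_mut$protein_v == a), ]
    if (a == b) pe <- ie_mut[ie_mut$protein_u == a & ie_mut$protein_v == a, ]
    if (nrow(pe) == 0) next
    ia <- ae_mut[ae_mut$protein_u %in% c(a, b), ]
    verts <- unique(c(
      paste(cov_v$protein_id[cov_v$protein_id %in% c(a, b)],
            cov_v$residue[cov_v$protein_id %in% c(a, b)], sep = "|"),
      paste(pe$protein_u, pe$res_u, sep = "|"),
      paste(pe$protein_v, pe$res_v, sep = "|")
    ))
    edges <- dplyr::bind_rows(
      tibble::tibble(from = paste(ia$protein_u, ia$res_u, sep = "|"),
                     to = paste(ia$protein_v, ia$res_v, sep = "|"),
                     inter = FALSE),
      tibble::tibble(from = paste(pe$protein_u, pe$res_u, sep = "|"),
                     to = paste(pe$protein_v, pe$res_v, sep = "|"),
                     inter = TRUE)
    )
    edges <- edges[edges$from %in% verts & edges$to %in% verts, ]
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = data.frame(name = verts))
    comp <- igraph::components(g)
    # components containing >= 1 inter-chain edge
    ends <- igraph::ends(g, igraph::E(g), names = TRUE)
    inter_flag <- igraph::edge_attr(g, "inter")
    comp_with_inter <- unique(comp$membership[ends[inter_flag, 1]])
    for (cid in comp_with_inter) {
      members <- names(comp$membership)[comp$membership == cid]
      parts <- strsplit(members, "|", fixed = TRUE)
      prot <- vapply(parts, `[`, character(1), 1)
      res <- as.integer(vapply(parts, `[`, character(1), 2))
      res_u <- sort(res[prot == a])
      res_v <- sort(res[prot == b])
      if (a == b) res_v <- integer()
      ev <- .count_events(mutated, a, res_u,
                          if (a == b) NA else b, res_v)
      out[[length(out) + 1]] <- tibble::tibble(
        cluster_id = paste("C2", a, res_u[1], b,
                           if (length(res_v)) res_v[1] else res_u[1],
                           sep = ":"),
        source = "C2", protein_u = a, protein_v = b,
        residues_u = list(res_u), residues_v = list(res_v),
        k_u = length(res_u), k_v = length(res_v),
        k = length(res_u) + length(res_v),
        O_C = ev$o, mutation_ids = list(ev$ids)
      )
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) return(.empty_clusters())
  dplyr::arrange(res, .data$cluster_id)
}

#' Interface clusters from annotated PPI interface residues
#'
#' For each annotated interaction in the interaction set, the union of
#' mutated interface residues on both sides forms one `C4` cluster; pairs
#' with no mutated interface residue yield no cluster.
#'
#' @param annotations Interface annotation tibble from
#'   [load_interface_annotations()].
#' @param mutated Footprint tibble.
#' @param ppi Interaction tibble (`protein_a`, `protein_b`).
#' @return Cluster tibble.
#' @export
interface_clusters <- function(annotations, mutated, ppi) {
  mut_key <- paste(mutated$protein_id, mutated$residue, sep = "|")
  ppi_key <- paste(pmin(ppi$protein_a, ppi$protein_b),
                   pmax(ppi$protein_a, ppi$protein_b), sep = "|")
  ann <- annotations %>%
    dplyr::filter(paste(.data$protein_a, .data$protein_b, sep = "|")
                  %in% ppi_key) %>%
    dplyr::filter(paste(.data$protein, .data$residue, sep = "|") %in% mut_key)
  if (nrow(ann) == 0) return(.empty_clusters())
  ann %>%
    dplyr::group_by(.data$protein_a, .data$protein_b) %>%
    dplyr::group_modify(function(df, key) {
      res_u <- sort(unique(df$residue[df$protein == key$protein_a]))
      res_v <- sort(unique(df$residue[df$protein == key$protein_b]))
      ev <- .count_events(mutated, key$protein_a, res_u, key$protein_b, res_v)
      tibble::tibble(
        cluster_id = paste("C4", key$protein_a,
                           if (length(res_u)) res_u[1] else res_v[1],
                           key$protein_b,
                           if (length(res_v)) res_v[1] else res_u[1],
                           sep = ":"),
        source = "C4",
        residues_u = list(res_u), residues_v = list(res_v),
        k_u = length(res_u), k_v = length(res_v),
        k = length(res_u) + length(res_v),
        O_C = ev$o, mutation_ids = list(ev$ids)
      )
    }) %>%
    dplyr::ungroup() %>%
    dplyr::rename(protein_u = "protein_a", protein_v = "protein_b") %>%
    dplyr::select("cluster_id", "source", "protein_u", "protein_v",
                  "residues_u", "residues_v", "k_u", "k_v", "k", "O_C",
                  "mutation_ids") %>%
    dplyr::arrange(.data$cluster_id)
}

#' Remove predicted-structure clusters redundant with experimental ones
#'
#' Drops every `C3` cluster sharing at least one (protein, residue) with any
#' `C1` cluster. Overlap with `C2` or `C4` clusters does not trigger
#' removal.
#'
#' @param c3,c1 Cluster tibbles.
#' @return The filtered `C3` tibble.
#' @export
dedupe_predicted <- function(c3, c1) {
  if (nrow(c3) == 0 || nrow(c1) == 0) return(c3)
  c1_keys <- unique(unlist(purrr::map2(
    c1$protein_u, c1$residues_u,
    function(p, r) paste(p, r, sep = "|")
  )))
  keep <- purrr::map2_lgl(c3$protein_u, c3$residues_u, function(p, r) {
    !any(paste(p, r, sep = "|") %in% c1_keys)
  })
  c3[keep, ]
}
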