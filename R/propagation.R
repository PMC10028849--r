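# Insulated heat diffusion over the PPI network.
#
# Cluster and LOF evidence become node heats and edge weights; at steady
# state the exchanged-heat matrix E = F D_h (F the diffusion matrix) says
# how much of each protein's initial heat reaches every other protein.
# Thresholding E at delta yields a directed graph whose strongly connected
# components are the "interconnected modules"; requiring strong
# connectivity suppresses one-way star configurations around single hot
# hubs.

#' Initial node heats from cluster and LOF evidence
#'
#' `h_u = min(cap, -log10 min{p_C : C in C_u}) + min(cap, -log10 p_u)`,
#' where `C_u` is the set of scored 3D clusters (all families) containing at
#' least one residue of `u`, and `p_u` is the protein's LOF enrichment
#' p-value. An empty cluster set contributes 0; a protein without LOF
#' evidence has `p_u = 1` and contributes 0. Raw (not adjusted) p-values are
#' used.
#'
#' @param proteins Character vector of protein ids to assign heat to.
#' @param scored_clusters Scored cluster tibble (see [score_clusters()]).
#' @param lof_table LOF enrichment tibble (see [lof_enrichment()]).
#' @param cap Per-addend maximum (default 300), guarding against zero
#'   p-values.
#' @return Tibble: `protein_id`, `h_in_frame`, `h_lof`, `heat`.
#' @export
initial_heat <- function(proteins, scored_clusters, lof_table, cap = 300) {
  log_term <- function(p) pmin(cap, -log10(pmax(p, 1e-320)))
  cl_u <- dplyr::bind_rows(
    tibble::tibble(protein_id = scored_clusters$protein_u,
                   side_k = scored_clusters$k_u, p = scored_clusters$p),
    tibble::tibble(protein_id = scored_clusters$protein_v,
                   side_k = scored_clusters$k_v, p = scored_clusters$p)
  ) %>%
    dplyr::filter(!is.na(.data$protein_id), .data$side_k > 0)
  cl_u <- if (nrow(cl_u) == 0) {
    tibble::tibble(protein_id = character(), min_p = numeric())
  } else {
    cl_u %>%
      dplyr::group_by(.data$protein_id) %>%
      dplyr::summarise(min_p = min(.data$p), .groups = "drop")
  }
  tibble::tibble(protein_id = proteins) %>%
    dplyr::left_join(cl_u, by = "protein_id") %>%
    dplyr::left_join(lof_table[, c("protein_id", "p")], by = "protein_id") %>%
    dplyr::mutate(
      h_in_frame = dplyr::if_else(is.na(.data$min_p), 0, log_term(.data$min_p)),
      h_lof = dplyr::if_else(is.na(.data$p), 0, log_term(.data$p)),
      heat = .data$h_in_frame + .data$h_lof
    ) %>%
    dplyr::select("protein_id", "h_in_frame", "h_lof", "heat")
}

#' Heat-transfer weights per PPI edge
#'
#' `w_ij = min(cap, -log10 min{p_C : C in C_ij}) + w0` when the interaction
#' has at least one inter-protein cluster (`C2` or `C4`), else the baseline
#' `w0`. Weights are symmetric and strictly positive.
#'
#' @param edges Network edge tibble (`protein_a`, `protein_b`).
#' @param scored_clusters Scored cluster tibble; only `C2`/`C4` rows are
#'   consulted.
#' @param w0 Baseline weight (default 1).
#' @param cap Cap on the log term (default 300).
#' @return The edge tibble with a `weight` column.
#' @export
edge_weight <- function(edges, scored_clusters, w0 = 1, cap = 300) {
  inter <- dplyr::filter(scored_clusters, .data$source %in% c("C2", "C4"))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  best <- if (nrow(inter) == 0) {
    tibble::tibble(pair = character(), min_p = numeric())
  } else {
    inter %>%
      dplyr::mutate(pair = key(.data$protein_u,
                               dplyr::coalesce(.data$protein_v,
                                               .data$protein_u))) %>%
      dplyr::group_by(.data$pair) %>%
      dplyr::summarise(min_p = min(.data$p), .groups = "drop")
  }
  edges %>%
    dplyr::mutate(pair = key(.data$protein_a, .data$protein_b)) %>%
    dplyr::left_join(best, by = "pair") %>%
    dplyr::mutate(weight = dplyr::if_else(
      is.na(.data$min_p), w0,
      pmin(cap, -log10(pmax(.data$min_p, 1e-320))) + w0
    )) %>%
    dplyr::select(-"pair", -"min_p")
}

#' Column-stochastic transition matrix
#'
#' `W[i, j] = w_ij / sum_{k in Z_j} w_kj` for neighbors `i` of `j`, zero
#' otherwise; every column over the (degree >= 1) node set sums to 1.
#'
#' @param edges Weighted edge tibble (`protein_a`, `protein_b`, `weight`).
#' @return Dense matrix with dimnames = node ids (sorted).
#' @export
transition_matrix <- function(edges) {
  if (nrow(edges) == 0) stop("transition_matrix: empty network")
  stopifnot(all(edges$weight > 0))
  nodes <- sort(unique(c(edges$protein_a, edges$protein_b)))
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  ia <- match(edges$protein_a, nodes)
  ib <- match(edges$protein_b, nodes)
  W[cbind(ia, ib)] <- edges$weight
  W[cbind(ib, ia)] <- edges$weight
  csum <- colSums(W)
  if (any(csum == 0)) stop("transition_matrix: degree-0 vertex present")
  sweep(W, 2, csum, "/")
}

#' Diffusion and exchanged-heat matrices
#'
#' Solves `(I - (1 - beta) W) F = beta I` for the diffusion matrix `F` and
#' forms the exchanged-heat matrix `E = F D_h`: `E[i, j]` is the net heat
#' protein `i` receives from protein `j`'s initial heat `h_j`. Column sums
#' of `E` equal the input heats (heat conservation).
#'
#' @param W Column-stochastic transition matrix.
#' @param beta Insulating fraction retained per step, in (0, 1].
#' @param heats Named numeric vector of initial heats (names must cover
#'   `colnames(W)`).
#' @return List with `F` (diffusion matrix), `E` (exchanged heat), `nodes`.
#' @export
compute_exchanged_heat <- function(W, beta, heats) {
  stopifnot(beta > 0, beta <= 1)
  nodes <- colnames(W)
  h <- heats[nodes]
  stopifnot(!anyNA(h))
  n <- nrow(W)
  Fm <- beta * solve(diag(n) - (1 - beta) * W)
  dimnames(Fm) <- dimnames(W)
  E <- sweep(Fm, 2, h, "*")
  list(F = Fm, E = E, nodes = nodes)
}

#' Interconnected modules from the exchanged-heat matrix
#'
#' Builds the directed graph with an edge from `j` to `i` whenever
#' `E[i, j] > delta` (strict) and returns its strongly connected
#' components; components with more than `size_threshold` proteins are
#' significant.
#'
#' @param E Exchanged-heat matrix with dimnames.
#' @param delta Positive heat threshold.
#' @param size_threshold Modules must exceed this size to be significant
#'   (default 5).
#' @return Tibble: `module_id`, `proteins` (list column), `size`,
#'   `significant`.
#' @export
identify_modules <- function(E, delta, size_threshold = 5) {
  stopifnot(delta > 0)
  comp <- .scc_membership(E > delta, colnames(E))
  tibble::tibble(protein_id = names(comp), comp = comp) %>%
    dplyr::group_by(.data$comp) %>%
    dplyr::summarise(proteins = list(sort(.data$protein_id)),
                     size = dplyr::n(), .groups = "drop") %>%
    dplyr::arrange(dplyr::desc(.data$size),
                   purrr::map_chr(.data$proteins, 1)) %>%
    dplyr::mutate(module_id = paste0("M", dplyr::row_number()),
                  significant = .data$size > size_threshold) %>%
    dplyr::select("module_id", "proteins", "size", "significant")
}

# strongly connected component membership of adjacency matrix A
# (A[i, j] TRUE means directed edge j -> i)
.scc_membership <- function(A, nodes) {
  idx <- which(A, arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = nodes[idx[, 2]], to = nodes[idx[, 1]]),
    directed = TRUE, vertices = data.frame(name = nodes)
  )
  igraph::components(g, mode = "strong")$membership
}

# largest SCC size at threshold delta
.max_scc_size <- function(E, delta) {
  max(table(.scc_membership(E > delta, colnames(E))))
}

# minimum delta over the candidate grid (distinct positive entries of E)
# such that all SCCs have size <= size_threshold; Inf if no candidates.
.min_delta_for <- function(E, size_threshold) {
  cand <- sort(unique(E[E > 0]))
  if (length(cand) == 0) return(Inf)
  if (.max_scc_size(E, cand[length(cand)]) > size_threshold) {
    # even deleting every edge leaves an oversize SCC: impossible, since
    # thresholding at the max removes all edges
    stop("unreachable: empty graph has an oversize component")
  }
  lo <- 1L; hi <- length(cand)
  if (.max_scc_size(E, cand[1]) <= size_threshold) return(cand[1])
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (.max_scc_size(E, cand[mid]) <= size_threshold) hi <- mid else lo <- mid
  }
  cand[hi]
}

#' Degree-preserving randomization of an edge list
#'
#' Double-edge-swap rewiring (self-loops and multi-edges rejected), keeping
#' every vertex degree exactly; the weight multiset of the original edges is
#' randomly reassigned to the swapped edges. Uses R's RNG.
#'
#' @param edges Weighted edge tibble.
#' @param niter Number of attempted swaps (default `10 * nrow(edges)`).
#' @return Rewired weighted edge tibble.
#' @export
randomize_network <- function(edges, niter = 10 * nrow(edges)) {
  g <- igraph::graph_from_data_frame(edges[, c("protein_a", "protein_b")],
                                     directed = FALSE)
  g2 <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE, niter = niter))
  ends <- igraph::as_edgelist(g2)
  tibble::tibble(
    protein_a = pmin(ends[, 1], ends[, 2]),
    protein_b = pmax(ends[, 1], ends[, 2]),
    weight = sample(edges$weight)
  )
}

#' Select the exchanged-heat threshold delta on randomized networks
#'
#' For each replicate, the network is rewired degree-preservingly with heats
#' held fixed and the original weight multiset randomly reassigned; the
#' exchanged-heat matrix is recomputed and the smallest delta (over the grid
#' of its distinct positive entries, by binary search) leaving no strongly
#' connected component larger than `size_threshold` is recorded. The final
#' delta is the smallest across replicates. Replicate seeds are derived
#' deterministically from `seed`.
#'
#' @param edges Weighted edge tibble of the observed network.
#' @param heats Named heat vector.
#' @param beta Insulating fraction.
#' @param n_random Number of randomized replicates (default 20).
#' @param size_threshold Maximum tolerated module size on randomized data
#'   (default 5).
#' @param seed Integer seed driving all replicates.
#' @return List: `delta`, `replicate_deltas`, `replicates` (list of the
#'   randomized edge tibbles), `exchanged` (list of their E matrices).
#' @export
select_delta <- function(edges, heats, beta = 0.5, n_random = 20,
                         size_threshold = 5, seed = 1) {
  reps <- vector("list", n_random)
  exch <- vector("list", n_random)
  deltas <- rep(Inf, n_random)
  for (r in seq_len(n_random)) {
    set.seed(seed + r)
    re <- randomize_network(edges)
    W <- transition_matrix(re)
    E <- compute_exchanged_heat(W, beta, heats)$E
    reps[[r]] <- re
    exch[[r]] <- E
    deltas[r] <- .min_delta_for(E, size_threshold)
  }
  delta <- min(deltas)
  if (!is.finite(delta)) {
    message("select_delta: all randomized exchanged-heat matrices are zero; ",
            "falling back to machine epsilon")
    delta <- .Machine$double.eps
  }
  list(delta = delta, replicate_deltas = deltas, replicates = reps,
       exchanged = exch)
}

#' Potential driver mutations from significant modules
#'
#' For each protein in a significant module, takes the mutations of its
#' minimum-raw-p significant cluster (any family); for each interaction
#' with both endpoints inside one significant module, adds the mutations of
#' the minimum-raw-p significant inter-protein (`C2`/`C4`) cluster of that
#' interface. Significance gates (adjusted p) apply; ranking uses raw p.
#'
#' @param modules Module tibble from [identify_modules()].
#' @param scored_clusters Scored cluster tibble.
#' @param edges Network edge tibble.
#' @return Tibble: `mutation_id`, `via` (`protein` or `interface`),
#'   `anchor` (the protein or interaction key), `cluster_id`.
#' @export
extract_driver_mutations <- function(modules, scored_clusters, edges) {
  sig_prot <- unlist(modules$proteins[modules$significant])
  empty <- tibble::tibble(mutation_id = integer(), via = character(),
                          anchor = character(), cluster_id = character())
  if (length(sig_prot) == 0) return(empty)
  sig_cl <- dplyr::filter(scored_clusters, .data$significant)
  if (nrow(sig_cl) == 0) return(empty)
  per_protein <- purrr::map(sig_prot, function(u) {
    mine <- sig_cl[(sig_cl$protein_u == u & sig_cl$k_u > 0) |
                     (!is.na(sig_cl$protein_v) & sig_cl$protein_v == u &
                        sig_cl$k_v > 0), ]
    if (nrow(mine) == 0) return(NULL)
    best <- mine[order(mine$p, mine$cluster_id), ][1, ]
    tibble::tibble(mutation_id = best$mutation_ids[[1]], via = "protein",
                   anchor = u, cluster_id = best$cluster_id)
  })
  module_of <- stats::setNames(
    rep(modules$module_id[modules$significant],
        lengths(modules$proteins[modules$significant])),
    sig_prot
  )
  in_module <- edges$protein_a %in% sig_prot & edges$protein_b %in% sig_prot &
    module_of[edges$protein_a] == module_of[edges$protein_b]
  per_ppi <- purrr::map(which(in_module), function(r) {
    a <- min(edges$protein_a[r], edges$protein_b[r])
    b <- max(edges$protein_a[r], edges$protein_b[r])
    mine <- sig_cl[sig_cl$source %in% c("C2", "C4") &
                     sig_cl$protein_u == a &
                     !is.na(sig_cl$protein_v) & sig_cl$protein_v == b, ]
    if (nrow(mine) == 0) return(NULL)
    best <- mine[order(mine$p, mine$cluster_id), ][1, ]
    tibble::tibble(mutation_id = best$mutation_ids[[1]], via = "interface",
                   anchor = paste(a, b, sep = "|"),
                   cluster_id = best$cluster_id)
  })
  dplyr::bind_rows(c(per_protein, per_ppi)) %>%
    dplyr::distinct() %>%
    dplyr::arrange(.data$via, .data$anchor, .data$mutation_id)
}

#' Baseline (structure-blind) heats and weights
#'
#' Ablation mode: node heat is the number of distinct tumor samples carrying
#' any protein-altering mutation (in-frame or LOF) in the protein, and every
#' edge weight is 1. Downstream diffusion, delta selection and module calls
#' are unchanged.
#'
#' @param records Preprocessed mutation tibble.
#' @param edges Network edge tibble.
#' @return List: `heats` (tibble `protein_id`, `heat`), `edges` (with
#'   `weight = 1`).
#' @export
baseline_configuration <- function(records, edges) {
  heats <- records %>%
    dplyr::filter(.data$consequence_class %in% c("in_frame", "lof")) %>%
    dplyr::distinct(.data$protein_id, .data$sample_id) %>%
    dplyr::count(.data$protein_id, name = "heat") %>%
    dplyr::mutate(heat = as.numeric(.data$heat))
  list(heats = heats, edges = dplyr::mutate(edges, weight = 1))
}
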