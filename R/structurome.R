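# Structure snapshots and residue contact graphs.
#
# A "structure snapshot" is a flat atom table: one row per (non-hydrogen,
# non-water, polymer) atom carrying its chain, author residue index, mapped
# protein accession + protein residue index, and coordinates in Angstrom.
# Multi-model (NMR) files yield one snapshot per model, so the
# min-over-snapshots rule covers models automatically.

#' Minimum inter-residue atomic distance
#'
#' The 3D distance between two residues is the euclidean distance between
#' their closest atoms.
#'
#' @param res_a,res_b Numeric matrices with columns x, y, z (one row per
#'   atom).
#' @return Minimum distance in Angstrom.
#' @export
residue_min_distance <- function(res_a, res_b) {
  res_a <- as.matrix(res_a)
  res_b <- as.matrix(res_b)
  if (nrow(res_a) == 0 || nrow(res_b) == 0) {
    stop("residue_min_distance: unresolved residue (empty atom set)")
  }
  stopifnot(all(is.finite(res_a)), all(is.finite(res_b)))
  d2 <- outer(rowSums(res_a^2), rowSums(res_b^2), "+") -
    2 * tcrossprod(res_a, res_b)
  sqrt(max(0, min(d2)))
}

#' Read a structure file into one or more snapshots
#'
#' Parses a PDB or mmCIF file (via \pkg{bio3d}), keeps non-hydrogen,
#' non-water atoms of standard polymer residues, resolves alternate
#' locations to the highest-occupancy conformer (ties: first in file order),
#' splits models into separate snapshots, and attaches the residue-to-protein
#' mapping.
#'
#' @param path PDB (`.pdb`) or mmCIF (`.cif`) file.
#' @param mapping Tibble with columns `structure_id`, `chain`,
#'   `author_resid`, `protein_id`, `protein_resid` (a SIFTS-like table).
#'   Residues without a mapping row are retained with `protein_id = NA` and
#'   are ignored by graph construction.
#' @param structure_id Identifier used to look up rows in `mapping`;
#'   defaults to the file name without extension.
#' @return A list of snapshot tibbles (one per model) with columns
#'   `structure_id`, `model`, `chain`, `author_resid`, `protein_id`,
#'   `protein_resid`, `x`, `y`, `z`.
#' @export
read_structure <- function(path, mapping = NULL, structure_id = NULL) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("read_structure requires the bio3d package")
  }
  if (is.null(structure_id)) {
    structure_id <- sub("\\.[^.]*$", "", basename(path))
  }
  pdb <- if (grepl("\\.cif$", path, ignore.case = TRUE)) {
    bio3d::read.cif(path, verbose = FALSE)
  } else {
    bio3d::read.pdb(path, verbose = FALSE, multi = TRUE)
  }
  at <- tibble::as_tibble(pdb$atom)
  at$eleno_order <- seq_len(nrow(at))
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  n_models <- nrow(xyz)
  water <- c("HOH", "WAT", "DOD")
  keep <- at$type == "ATOM" & !at$resid %in% water &
    !(!is.na(at$elesy) & at$elesy %in% c("H", "D"))
  snapshots <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    mxyz <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
    snap <- at[keep, c("chain", "resno", "alt", "o", "eleno_order")]
    snap$x <- mxyz[keep, 1]; snap$y <- mxyz[keep, 2]; snap$z <- mxyz[keep, 3]
    # altloc: per residue keep the highest-occupancy altloc label
    snap <- snap %>%
      dplyr::group_by(.data$chain, .data$resno) %>%
      dplyr::group_modify(function(df, key) {
        alts <- unique(df$alt[!is.na(df$alt)])
        if (length(alts) <= 1) return(df)
        occ <- vapply(alts, function(a) {
          mean(df$o[df$alt == a], na.rm = TRUE)
        }, numeric(1))
        occ[is.na(occ)] <- 0
        best <- alts[order(-occ, vapply(alts, function(a) {
          min(df$eleno_order[df$alt == a])
        }, numeric(1)))][1]
        df[is.na(df$alt) | df$alt == best, ]
      }) %>%
      dplyr::ungroup()
    snap <- tibble::tibble(
      structure_id = structure_id, model = m,
      chain = snap$chain, author_resid = snap$resno,
      x = snap$x, y = snap$y, z = snap$z
    )
    snapshots[[m]] <- .apply_mapping(snap, mapping, structure_id)
  }
  snapshots
}

.apply_mapping <- function(snap, mapping, structure_id) {
  if (is.null(mapping)) {
    snap$protein_id <- NA_character_
    snap$protein_resid <- NA_integer_
    return(snap)
  }
  map <- mapping %>%
    dplyr::filter(.data$structure_id == !!structure_id) %>%
    dplyr::select("chain", "author_resid", "protein_id", "protein_resid")
  dplyr::left_join(snap, map, by = c("chain", "author_resid"))
}

#' Read a SIFTS-like residue mapping table
#'
#' @param path Tab-delimited file with columns `structure_id`, `chain`,
#'   `author_resid`, `protein_id`, `protein_resid`.
#' @return Tibble.
#' @export
read_residue_mapping <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    structure_id = "c", chain = "c", author_resid = "i",
    protein_id = "c", protein_resid = "i"
  ), progress = FALSE)
}

# Internal: per-snapshot residue pairs within cutoff.
# mode "intra": same chain; "inter": different chains.
# Returns tibble protein_u, res_u, protein_v, res_v, dist (canonical order).
.snapshot_contacts <- function(snap, cutoff, mode) {
  snap <- dplyr::filter(snap, !is.na(.data$protein_id),
                        !is.na(.data$protein_resid),
                        is.finite(.data$x), is.finite(.data$y),
                        is.finite(.data$z))
  if (nrow(snap) == 0) return(.empty_contacts())
  res <- snap %>%
    dplyr::group_by(.data$chain, .data$protein_id, .data$protein_resid) %>%
    dplyr::group_rows()
  meta <- snap %>%
    dplyr::group_by(.data$chain, .data$protein_id, .data$protein_resid) %>%
    dplyr::summarise(.groups = "drop")
  coords <- as.matrix(snap[, c("x", "y", "z")])
  n <- nrow(meta)
  if (n < 2) return(.empty_contacts())
  # coarse residue-level prefilter on centroids + radii, exact on survivors
  cent <- t(vapply(res, function(idx) colMeans(coords[idx, , drop = FALSE]),
                   numeric(3)))
  rad <- vapply(seq_len(n), function(i) {
    idx <- res[[i]]
    sqrt(max(rowSums((coords[idx, , drop = FALSE] -
                        matrix(cent[i, ], length(idx), 3, byrow = TRUE))^2)))
  }, numeric(1))
  out <- vector("list", n)
  for (i in seq_len(n - 1)) {
    js <- (i + 1):n
    if (mode == "intra") {
      js <- js[meta$chain[js] == meta$chain[i]]
    } else {
      js <- js[meta$chain[js] != meta$chain[i]]
    }
    if (length(js) == 0) next
    dc <- sqrt(colSums((t(cent[js, , drop = FALSE]) - cent[i, ])^2))
    js <- js[dc - rad[i] - rad[js] <= cutoff]
    if (length(js) == 0) next
    ai <- coords[res[[i]], , drop = FALSE]
    dists <- vapply(js, function(j) {
      residue_min_distance(ai, coords[res[[j]], , drop = FALSE])
    }, numeric(1))
    sel <- dists <= cutoff
    if (!any(sel)) next
    out[[i]] <- tibble::tibble(
      protein_u = meta$protein_id[i], res_u = meta$protein_resid[i],
      protein_v = meta$protein_id[js[sel]], res_v = meta$protein_resid[js[sel]],
      dist = dists[sel]
    )
  }
  pairs <- dplyr::bind_rows(out)
  if (nrow(pairs) == 0) return(.empty_contacts())
  .canonicalize_pairs(pairs)
}

.empty_contacts <- function() {
  tibble::tibble(protein_u = character(), res_u = integer(),
                 protein_v = character(), res_v = integer(),
                 dist = numeric())
}

# order endpoints (protein, residue) lexicographically and drop self-pairs
.canonicalize_pairs <- function(pairs) {
  flip <- pairs$protein_u > pairs$protein_v |
    (pairs$protein_u == pairs$protein_v & pairs$res_u > pairs$res_v)
  pairs[flip, c("protein_u", "res_u", "protein_v", "res_v")] <-
    pairs[flip, c("protein_v", "res_v", "protein_u", "res_u")]
  dplyr::filter(pairs, !(.data$protein_u == .data$protein_v &
                           .data$res_u == .data$res_v))
}

.new_contact_graph <- function(kind, vertices, edges) {
  structure(list(kind = kind, vertices = vertices, edges = edges),
            class = "contact_graph")
}

#' @export
print.contact_graph <- function(x, ...) {
  cat("<contact_graph>", x$kind, ":", nrow(x$vertices), "residues,",
      nrow(x$edges), "contacts\n")
  invisible(x)
}

# shared core for the three graph builders
.build_contact_graph <- function(snapshots, cutoff, mode, kind,
                                 all_vertices = TRUE) {
  if (length(snapshots) == 0) {
    warning("no snapshots supplied; returning an empty ", kind, " graph")
    return(.new_contact_graph(kind,
                              tibble::tibble(protein_id = character(),
                                             protein_resid = integer()),
                              .empty_contacts()))
  }
  edges <- purrr::map(snapshots, .snapshot_contacts, cutoff = cutoff,
                      mode = mode) %>%
    dplyr::bind_rows()
  edges <- if (nrow(edges) == 0) .empty_contacts() else {
    edges %>%
      dplyr::group_by(.data$protein_u, .data$res_u, .data$protein_v,
                      .data$res_v) %>%
      dplyr::summarise(dist = min(.data$dist), .groups = "drop") %>%
      dplyr::arrange(.data$protein_u, .data$res_u, .data$protein_v,
                     .data$res_v)
  }
  if (all_vertices) {
    vertices <- purrr::map(snapshots, function(s) {
      s %>%
        dplyr::filter(!is.na(.data$protein_id), !is.na(.data$protein_resid)) %>%
        dplyr::distinct(.data$protein_id, .data$protein_resid)
    }) %>%
      dplyr::bind_rows() %>%
      dplyr::distinct() %>%
      dplyr::arrange(.data$protein_id, .data$protein_resid)
  } else {
    vertices <- dplyr::bind_rows(
      tibble::tibble(protein_id = edges$protein_u,
                     protein_resid = edges$res_u),
      tibble::tibble(protein_id = edges$protein_v,
                     protein_resid = edges$res_v)
    ) %>%
      dplyr::distinct() %>%
      dplyr::arrange(.data$protein_id, .data$protein_resid)
  }
  .new_contact_graph(kind, vertices, edges)
}

#' Build the intra-chain contact graph from experimental structures
#'
#' Vertices are all mapped residues covered by at least one snapshot; an
#' edge joins two residues of the same chain whose minimum distance over all
#' snapshots is at most `cutoff` (default 6 Angstrom).
#'
#' @param snapshots List of snapshot tibbles (see [read_structure()]).
#' @param cutoff Contact cutoff in Angstrom.
#' @return A `contact_graph` of kind `intra_experimental`.
#' @export
build_intra_contact_graph <- function(snapshots, cutoff = 6) {
  .build_contact_graph(snapshots, cutoff, "intra", "intra_experimental",
                       all_vertices = TRUE)
}

#' Build the inter-chain contact graph from experimental structures
#'
#' Edges join residues in different chains (possibly of the same protein —
#' homomeric contacts are kept) with minimum distance over snapshots at most
#' `cutoff` (default 9 Angstrom). The vertex set is restricted to edge
#' endpoints.
#'
#' @inheritParams build_intra_contact_graph
#' @return A `contact_graph` of kind `inter_experimental`.
#' @export
build_inter_contact_graph <- function(snapshots, cutoff = 9) {
  .build_contact_graph(snapshots, cutoff, "inter", "inter_experimental",
                       all_vertices = FALSE)
}

#' Build the intra-protein contact graph from predicted structures
#'
#' Same rule as [build_intra_contact_graph()] applied to single-chain
#' predicted models; residues of every model-confidence level are used.
#' A snapshot with more than one chain is an error: predicted models cover
#' one protein each.
#'
#' @inheritParams build_intra_contact_graph
#' @return A `contact_graph` of kind `intra_predicted`.
#' @export
build_predicted_graph <- function(snapshots, cutoff = 6) {
  for (s in snapshots) {
    if (dplyr::n_distinct(s$chain) > 1) {
      stop("predicted snapshots must be single-chain (got a multi-chain file)")
    }
  }
  .build_contact_graph(snapshots, cutoff, "intra", "intra_predicted",
                       all_vertices = TRUE)
}

#' Load PPI interface-residue annotations
#'
#' Reads a tab-delimited table (`protein_a`, `protein_b`, `side`,
#' `residue`, `confidence`) of predicted interface residues, keeping rows at
#' or above `min_confidence`. Pair keys are unordered: rows for (A,B) and
#' (B,A) merge. A `side` naming a protein outside the pair rejects the row.
#'
#' @param path Tab-delimited annotation file.
#' @param min_confidence Minimum confidence label retained; the ordered
#'   ladder is `low < medium < high < very high`.
#' @return Tibble with columns `protein_a`, `protein_b` (sorted within
#'   row), `protein` (the side the residue lies on), `residue`,
#'   `confidence`.
#' @export
load_interface_annotations <- function(path, min_confidence = "very high") {
  ladder <- c("low", "medium", "high", "very high")
  stopifnot(min_confidence %in% ladder)
  raw <- readr::read_tsv(path, col_types = readr::cols(
    protein_a = "c", protein_b = "c", side = "c", residue = "i",
    confidence = "c"
  ), progress = FALSE)
  if (nrow(raw) == 0) {
    return(tibble::tibble(protein_a = character(), protein_b = character(),
                          protein = character(), residue = integer(),
                          confidence = character()))
  }
  bad_side <- raw$side != raw$protein_a & raw$side != raw$protein_b
  if (any(bad_side)) {
    message("load_interface_annotations: rejected ", sum(bad_side),
            " row(s) whose side is not in the pair")
    raw <- raw[!bad_side, ]
  }
  raw %>%
    dplyr::filter(match(.data$confidence, ladder) >=
                    match(min_confidence, ladder)) %>%
    dplyr::mutate(protein = .data$side,
                  pa = pmin(.data$protein_a, .data$protein_b),
                  pb = pmax(.data$protein_a, .data$protein_b)) %>%
    dplyr::transmute(protein_a = .data$pa, protein_b = .data$pb,
                     protein = .data$protein, residue = .data$residue,
                     confidence = .data$confidence) %>%
    dplyr::distinct(.data$protein_a, .data$protein_b, .data$protein,
                    .data$residue, .keep_all = TRUE) %>%
    dplyr::arrange(.data$protein_a, .data$protein_b, .data$protein,
                   .data$residue)
}

#' Write / read a contact graph as a tab-delimited edge list
#'
#' The cache format round-trips bit-exactly: distances are written with full
#' precision (`%.17g`), and the vertex set is stored alongside so isolated
#' vertices survive.
#'
#' @param graph A `contact_graph`.
#' @param path Output path (edge list; a companion `<path>.vertices` file
#'   stores the vertex set).
#' @return `write_contact_graph` returns `path` invisibly;
#'   `read_contact_graph` returns a `contact_graph`.
#' @export
write_contact_graph <- function(graph, path) {
  edges <- graph$edges
  edges$dist <- sprintf("%.17g", edges$dist)
  edges$kind <- graph$kind
  readr::write_tsv(edges, path, progress = FALSE)
  readr::write_tsv(graph$vertices, paste0(path, ".vertices"), progress = FALSE)
  invisible(path)
}

#' @rdname write_contact_graph
#' @export
read_contact_graph <- function(path) {
  edges <- readr::read_tsv(path, col_types = readr::cols(
    protein_u = "c", res_u = "i", protein_v = "c", res_v = "i",
    dist = "c", kind = "c"
  ), progress = FALSE)
  kind <- if (nrow(edges) > 0) edges$kind[1] else "intra_experimental"
  vpath <- paste0(path, ".vertices")
  vertices <- if (file.exists(vpath)) {
    readr::read_tsv(vpath, col_types = readr::cols(protein_id = "c",
                                                   protein_resid = "i"),
                    progress = FALSE)
  } else {
    dplyr::distinct(dplyr::bind_rows(
      tibble::tibble(protein_id = edges$protein_u, protein_resid = edges$res_u),
      tibble::tibble(protein_id = edges$protein_v, protein_resid = edges$res_v)
    ))
  }
  edges$dist <- as.numeric(edges$dist)
  edges$kind <- NULL
  .new_contact_graph(kind, vertices, edges)
}
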