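# Brute-force oracles, written independently of the implementation
# (no igraph, no ppois): reachability by breadth-first search, Poisson
# tails by direct series summation, distances by all-atom-pairs loops.

# Connected components of an undirected graph given as a two-column
# edge data.frame over `vertices`; returns a named membership vector.
oracle_components <- function(edges, vertices) {
  adj <- stats::setNames(vector("list", length(vertices)), vertices)
  for (r in seq_len(nrow(edges))) {
    a <- edges[[1]][r]; b <- edges[[2]][r]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  comp <- stats::setNames(rep(NA_integer_, length(vertices)), vertices)
  cur <- 0L
  for (v in vertices) {
    if (!is.na(comp[v])) next
    cur <- cur + 1L
    queue <- v
    comp[v] <- cur
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      for (w in adj[[u]]) {
        if (is.na(comp[w])) {
          comp[w] <- cur
          queue <- c(queue, w)
        }
      }
    }
  }
  comp
}

# Strongly connected components of a directed graph given as an adjacency
# matrix A (A[i, j] TRUE: edge j -> i), via boolean transitive closure.
oracle_scc <- function(A) {
  n <- nrow(A)
  reach <- t(A) | diag(TRUE, n) # reach[j, i]: j -> i in <= 1 step
  repeat {
    nxt <- (reach %*% reach) > 0
    if (all(nxt == reach)) break
    reach <- nxt
  }
  mutual <- reach & t(reach)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0) {
      cur <- cur + 1L
      comp[mutual[i, ]] <- cur
    }
  }
  comp
}

# Poisson upper tail P(X >= o) by direct series summation of the upper
# tail in log space, summed smallest-terms-first.
oracle_poisson_upper <- function(o, e) {
  if (o == 0) return(1)
  x <- o:(o + max(200, ceiling(10 * e) + 200))
  lt <- x * log(e) - e - lgamma(x + 1)
  m <- max(lt)
  exp(m) * sum(exp(sort(lt - m)))
}

# All-atom-pairs minimum distance, naive double loop.
oracle_min_dist <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- sqrt(sum((a[i, ] - b[j, ])^2))
      if (d < best) best <- d
    }
  }
  best
}

# All contact pairs of a snapshot by brute force; mode "intra"/"inter".
oracle_snapshot_contacts <- function(snap, cutoff, mode) {
  snap <- snap[!is.na(snap$protein_id), ]
  keys <- unique(paste(snap$chain, snap$protein_id, snap$protein_resid,
                       sep = "\r"))
  out <- list()
  for (i in seq_along(keys)) {
    ki <- strsplit(keys[i], "\r")[[1]]
    ai <- as.matrix(snap[snap$chain == ki[1] & snap$protein_id == ki[2] &
                           snap$protein_resid == as.integer(ki[3]),
                         c("x", "y", "z")])
    for (j in seq_along(keys)) {
      if (j <= i) next
      kj <- strsplit(keys[j], "\r")[[1]]
      same_chain <- ki[1] == kj[1]
      if (mode == "intra" && !same_chain) next
      if (mode == "inter" && same_chain) next
      aj <- as.matrix(snap[snap$chain == kj[1] & snap$protein_id == kj[2] &
                             snap$protein_resid == as.integer(kj[3]),
                           c("x", "y", "z")])
      d <- oracle_min_dist(ai, aj)
      if (d <= cutoff) {
        out[[length(out) + 1]] <- data.frame(
          protein_u = ki[2], res_u = as.integer(ki[3]),
          protein_v = kj[2], res_v = as.integer(kj[3]), dist = d
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(protein_u = character(), res_u = integer(),
                      protein_v = character(), res_v = integer(),
                      dist = numeric()))
  }
  pairs <- do.call(rbind, out)
  flip <- pairs$protein_u > pairs$protein_v |
    (pairs$protein_u == pairs$protein_v & pairs$res_u > pairs$res_v)
  pairs[flip, c("protein_u", "res_u", "protein_v", "res_v")] <-
    pairs[flip, c("protein_v", "res_v", "protein_u", "res_u")]
  pairs <- pairs[!(pairs$protein_u == pairs$protein_v &
                     pairs$res_u == pairs$res_v), ]
  # min over duplicate residue pairs
  key <- paste(pairs$protein_u, pairs$res_u, pairs$protein_v, pairs$res_v)
  agg <- tapply(pairs$dist, key, min)
  parts <- strsplit(names(agg), " ")
  data.frame(
    protein_u = vapply(parts, `[`, "", 1),
    res_u = as.integer(vapply(parts, `[`, "", 2)),
    protein_v = vapply(parts, `[`, "", 3),
    res_v = as.integer(vapply(parts, `[`, "", 4)),
    dist = as.numeric(agg), row.names = NULL
  )
}

# random snapshot for contact-graph oracle tests: n residues on 1-2 chains,
# 1-3 atoms each, coordinates in a box so some pairs fall under cutoffs
random_snapshot <- function(n = 12, chains = c("A", "B"), box = 15,
                            structure_id = "rnd") {
  rows <- list()
  for (i in seq_len(n)) {
    ch <- sample(chains, 1)
    natoms <- sample(1:3, 1)
    base <- stats::runif(3, 0, box)
    rows[[i]] <- tibble::tibble(
      structure_id = structure_id, model = 1L, chain = ch,
      author_resid = i,
      protein_id = paste0("P", ch), protein_resid = i,
      x = base[1] + stats::runif(natoms, -1, 1),
      y = base[2] + stats::runif(natoms, -1, 1),
      z = base[3] + stats::runif(natoms, -1, 1)
    )
  }
  dplyr::bind_rows(rows)
}
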