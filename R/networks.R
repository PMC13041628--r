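#' Map ordinal social-activity frequency to an offline degree target
#'
#' Monotone non-decreasing lookup; the default table is
#' `{1 -> 2, 2 -> 4, 3 -> 6, 4 -> 8, 5 -> 10}`, linear with mean near the
#' online layer's mean degree of 6 so the two layers are balanced.
#'
#' @param freq ordinal codes in `1..5` (vectorized).
#' @param table integer vector of length 5, must be non-decreasing.
#' @return integer degree targets.
#' @export
degree_from_social_activity <- function(freq, table = c(2L, 4L, 6L, 8L, 10L)) {
  if (any(diff(table) < 0)) stop("degree table must be non-decreasing")
  if (any(freq < 1L | freq > length(table) | freq != round(freq)))
    stop("social activity codes must be integers in 1..", length(table))
  table[freq]
}

#' Build the offline layer from per-agent degree targets
#'
#' Randomized stub matching with rejection of self-loops and multi-edges,
#' followed by bounded repair rounds that re-shuffle the unmatched stubs.
#' An odd total stub count is resolved by decrementing one random positive
#' target. Realized degrees track the targets closely (typically within
#' +/-1 when the sequence is graphical).
#'
#' @param degree_targets vector of non-negative integer targets.
#' @param seed optional seed.
#' @param max_rounds repair-round bound.
#' @return two-column integer matrix of undirected edges (1-based node
#'   ids), no self-loops, no duplicates.
#' @export
build_offline <- function(degree_targets, seed = NULL, max_rounds = 50L) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(degree_targets)
  if (n < 2L) stop("need at least 2 nodes")
  d <- as.integer(degree_targets)
  if (any(d < 0L)) stop("degree targets must be non-negative")
  if (all(d == 0L)) {
    warning("all degree targets zero: returning an empty graph")
    return(matrix(integer(0), 0L, 2L))
  }
  if (sum(d) %% 2L == 1L) {
    i <- sample(which(d > 0L), 1L)
    d[i] <- d[i] - 1L
  }
  edges_i <- integer(0); edges_j <- integer(0)
  keys <- numeric(0)           # (min-1)*n + max, unique per unordered pair
  remaining <- d
  for (round in seq_len(max_rounds)) {
    if (sum(remaining) < 2L) break
    stubs <- sample(rep.int(seq_len(n), remaining))
    m <- length(stubs) %/% 2L
    a <- stubs[seq_len(m)]
    b <- stubs[m + seq_len(m)]
    lo <- pmin(a, b); hi <- pmax(a, b)
    key <- (lo - 1) * n + hi
    ok <- lo != hi & !duplicated(key) & !(key %in% keys)
    if (!any(ok)) break
    edges_i <- c(edges_i, lo[ok]); edges_j <- c(edges_j, hi[ok])
    keys <- c(keys, key[ok])
    deg_now <- tabulate(c(edges_i, edges_j), nbins = n)
    remaining <- pmax(d - deg_now, 0L)
  }
  cbind(edges_i, edges_j, deparse.level = 0)
}

#' Build the online layer as a Watts-Strogatz small-world graph
#'
#' Starts from a ring lattice in which every node links to `k/2` neighbors
#' on each side; each lattice edge is then rewired with probability `p` to
#' a uniformly chosen target that creates neither a self-loop nor a
#' duplicate edge. The edge count is exactly `n * k / 2` for any `p`.
#'
#' @param n node count.
#' @param k even mean degree (default 6).
#' @param p rewiring probability (default 0.10).
#' @param seed optional seed.
#' @return two-column integer matrix of undirected edges (1-based).
#' @export
build_online_ws <- function(n, k = 6L, p = 0.10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (k %% 2L != 0L || k < 2L) stop("k must be a positive even integer")
  if (k >= n) stop("k must be smaller than n")
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  src <- rep(seq_len(n), each = k %/% 2L)
  off <- rep(seq_len(k %/% 2L), times = n)
  dst <- ((src - 1L + off) %% n) + 1L
  lo <- pmin(src, dst); hi <- pmax(src, dst)
  keys <- new.env(hash = TRUE, size = n * k)
  for (e in seq_along(lo)) assign(sprintf("%d_%d", lo[e], hi[e]), TRUE, envir = keys)
  rewire <- which(runif(length(lo)) < p)
  for (e in rewire) {
    old <- sprintf("%d_%d", lo[e], hi[e])
    for (try in seq_len(100L)) {
      tgt <- sample.int(n, 1L)
      if (tgt == src[e]) next
      a <- min(src[e], tgt); b <- max(src[e], tgt)
      kk <- sprintf("%d_%d", a, b)
      if (!is.null(keys[[kk]])) next
      rm(list = old, envir = keys)
      assign(kk, TRUE, envir = keys)
      lo[e] <- a; hi[e] <- b
      break
    }
  }
  cbind(lo, hi, deparse.level = 0)
}

#' Assemble a two-layer contact network
#'
#' Fixed node set across layers; the union neighborhood (deduplicated,
#' excluding self) is precomputed in compressed sparse form for the
#' simulation engine.
#'
#' @param n node count.
#' @param offline_edges,online_edges two-column edge matrices (1-based).
#' @return an object of class `"layered_network"`.
#' @export
layered_network <- function(n, offline_edges, online_edges) {
  check_simple <- function(e, layer) {
    if (nrow(e) == 0L) return(invisible())
    if (any(e < 1L | e > n)) stop("node id out of range in ", layer, " layer")
    if (any(e[, 1] == e[, 2])) stop("self-loop in ", layer, " layer")
    key <- (pmin(e[, 1], e[, 2]) - 1) * n + pmax(e[, 1], e[, 2])
    if (anyDuplicated(key)) stop("duplicate edge in ", layer, " layer")
  }
  check_simple(offline_edges, "offline")
  check_simple(online_edges, "online")
  all_e <- rbind(offline_edges, online_edges)
  if (nrow(all_e) > 0L) {
    key <- (pmin(all_e[, 1], all_e[, 2]) - 1) * n + pmax(all_e[, 1], all_e[, 2])
    all_e <- all_e[!duplicated(key), , drop = FALSE]
  }
  src <- c(all_e[, 1], all_e[, 2])
  dst <- c(all_e[, 2], all_e[, 1])
  o <- order(src, dst)
  src <- src[o]; dst <- dst[o]
  ptr <- c(0L, cumsum(tabulate(src, nbins = n)))
  structure(list(n = n,
                 offline_edges = offline_edges,
                 online_edges = online_edges,
                 adj_ptr = as.integer(ptr),
                 adj_nbr = as.integer(dst - 1L)),
            class = "layered_network")
}

#' Union neighborhood of a node
#'
#' @param net a `"layered_network"`.
#' @param i node id (1-based).
#' @return sorted integer vector of neighbors over both layers.
#' @export
union_neighbors <- function(net, i) {
  if (i < 1L || i > net$n) stop("node id out of range")
  a <- net$adj_ptr[i]; b <- net$adj_ptr[i + 1L]
  if (b <= a) return(integer(0))
  net$adj_nbr[(a + 1L):b] + 1L
}

#' @export
print.layered_network <- function(x, ...) {
  cat(sprintf("Two-layer network: %d nodes, %d offline edges, %d online edges\n",
              x$n, nrow(x$offline_edges), nrow(x$online_edges)))
  invisible(x)
}

# Build both layers for a set of agents from one seed.
build_layers <- function(degree_targets, seed, ws_k = 6L, ws_p = 0.10) {
  n <- length(degree_targets)
  offline <- build_offline(degree_targets, seed = seed)
  online <- build_online_ws(n, k = ws_k, p = ws_p, seed = seed + 1L)
  layered_network(n, offline, online)
}
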