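# Internal helpers shared across modules: seeded evaluation, adjacency lists,
# breadth-first reachability and a unit-capacity max-flow/min-cut.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Derive a stream of child seeds (< 2^31) from a master seed, reproducibly.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Adjacency lists as a list of integer vectors indexed by node.
# `edges` is an integer matrix with columns (from, to).
build_adj <- function(edges, n, mode = c("out", "in", "all")) {
  mode <- match.arg(mode)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  if (nrow(edges) > 0) {
    src <- switch(mode,
      out = edges[, 1], `in` = edges[, 2],
      all = c(edges[, 1], edges[, 2])
    )
    dst <- switch(mode,
      out = edges[, 2], `in` = edges[, 1],
      all = c(edges[, 2], edges[, 1])
    )
    sp <- split(dst, factor(src, levels = seq_len(n)))
    adj <- lapply(sp, function(v) unique(as.integer(v)))
  }
  adj
}

# Nodes reachable from `start` following `adj`, never entering `blocked` nodes.
# Returns a logical vector over nodes. `start` itself is reported reachable
# unless it is blocked.
bfs_reach <- function(adj, start, blocked = NULL) {
  n <- length(adj)
  seen <- logical(n)
  if (!is.null(blocked)) seen[blocked] <- NA  # NA marks forbidden
  if (is.na(seen[start])) {
    return(logical(n))
  }
  seen[start] <- TRUE
  frontier <- start
  while (length(frontier) > 0) {
    nxt <- unlist(adj[frontier], use.names = FALSE)
    if (length(nxt) == 0) break
    keep <- !is.na(seen[nxt]) & !seen[nxt]
    nxt <- unique(nxt[keep])
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  seen[is.na(seen)] <- FALSE
  seen
}

# Single-source shortest path lengths (unweighted, directed) from `start`;
# Inf where unreachable.
bfs_dist <- function(adj, start) {
  n <- length(adj)
  d <- rep(Inf, n)
  d[start] <- 0
  frontier <- start
  lev <- 0
  while (length(frontier) > 0) {
    lev <- lev + 1
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[is.infinite(d[nxt])]
    if (length(nxt) == 0) break
    d[nxt] <- lev
    frontier <- nxt
  }
  d
}

# Minimum edge cut with unit capacities on the listed edges, from `source` to
# any node in `sinks` (a super-sink is implied). Edmonds-Karp on an explicit
# residual structure; graphs here are small (tens of nodes).
#
# edges: integer matrix (from, to). Returns integer vector of edge row indices
# forming a minimum cut (possibly empty).
min_edge_cut <- function(edges, n, source, sinks) {
  m <- nrow(edges)
  if (m == 0 || length(sinks) == 0) return(integer(0))
  sink <- n + 1L
  # Residual arcs: each original edge (cap 1) + sink arcs (cap Inf) + reverses.
  from <- c(edges[, 1], sinks)
  to <- c(edges[, 2], rep(sink, length(sinks)))
  cap <- c(rep(1, m), rep(Inf, length(sinks)))
  nf <- length(from)
  # add reverse arcs with zero capacity; arc i's reverse is arc i + nf
  from <- c(from, to)
  to <- c(to, from[seq_len(nf)])
  cap <- c(cap, rep(0, nf))
  out_arcs <- build_arc_index(from, n + 1L)
  repeat {
    # BFS for augmenting path in residual graph
    prev_arc <- rep(NA_integer_, n + 1L)
    seen <- logical(n + 1L)
    seen[source] <- TRUE
    frontier <- source
    found <- FALSE
    while (length(frontier) > 0 && !found) {
      new_frontier <- integer(0)
      for (u in frontier) {
        for (a in out_arcs[[u]]) {
          v <- to[a]
          if (!seen[v] && cap[a] > 0) {
            seen[v] <- TRUE
            prev_arc[v] <- a
            if (v == sink) {
              found <- TRUE
              break
            }
            new_frontier <- c(new_frontier, v)
          }
        }
        if (found) break
      }
      frontier <- new_frontier
    }
    if (!found) break
    # augment by 1 (unit capacities on original arcs bound the bottleneck)
    v <- sink
    while (v != source) {
      a <- prev_arc[v]
      cap[a] <- cap[a] - 1
      rev <- if (a <= nf) a + nf else a - nf
      cap[rev] <- cap[rev] + 1
      v <- from[a]
    }
  }
  # Min cut: original edges from the residual-reachable side to the rest.
  seen <- logical(n + 1L)
  seen[source] <- TRUE
  frontier <- source
  while (length(frontier) > 0) {
    new_frontier <- integer(0)
    for (u in frontier) {
      for (a in out_arcs[[u]]) {
        v <- to[a]
        if (!seen[v] && cap[a] > 0) {
          seen[v] <- TRUE
          new_frontier <- c(new_frontier, v)
        }
      }
    }
    frontier <- new_frontier
  }
  which(seen[edges[, 1]] & !seen[edges[, 2]])
}

build_arc_index <- function(from, n) {
  idx <- vector("list", n)
  for (i in seq_len(n)) idx[[i]] <- integer(0)
  sp <- split(seq_along(from), factor(from, levels = seq_len(n)))
  lapply(sp, as.integer)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
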