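# Independent oracles and instance generators used across the suite.
# Oracles go through igraph (or plain set arithmetic) so they share no code
# path with the package's own BFS/flow primitives.

# Criticality oracle: drop the gene, test receptor -> reporter reachability
# with igraph.
oracle_is_critical <- function(net, gene) {
  if (gene %in% c(net$receptor, net$reporter)) {
    return(TRUE)
  }
  g <- as_igraph(net)
  if (!is.finite(igraph::distances(g, v = net$receptor, to = net$reporter, mode = "out")[1, 1])) {
    return(TRUE) # vacuous: no path at all
  }
  g2 <- igraph::delete_vertices(g, gene)
  !is.finite(igraph::distances(g2, v = net$receptor, to = net$reporter, mode = "out")[1, 1])
}

oracle_critical_set <- function(net) {
  net$genes[vapply(net$genes, function(g) oracle_is_critical(net, g), logical(1))]
}

# Mutual-reachability oracle for SCC membership.
oracle_same_scc <- function(net) {
  d <- igraph::distances(as_igraph(net), mode = "out")
  is.finite(d) & is.finite(t(d))
}

# Any path between nonconsecutive ordered criticals whose interior genes are
# all noncritical? (violation predicate for the deletion step)
oracle_has_violation <- function(edges, genes, oi) {
  n <- length(genes)
  m2 <- length(oi)
  noncrit <- setdiff(seq_len(n), oi)
  for (i in seq_len(max(m2 - 2, 0))) {
    for (j in (i + 2):m2) {
      allowed <- c(noncrit, oi[i], oi[j])
      inside <- logical(n)
      inside[allowed] <- TRUE
      keep <- inside[edges[, 1]] & inside[edges[, 2]] & edges[, 1] != oi[j]
      sub <- edges[keep, , drop = FALSE]
      if (nrow(sub) == 0) next
      g <- igraph::graph_from_edgelist(
        cbind(genes[sub[, 1]], genes[sub[, 2]]),
        directed = TRUE
      )
      nm <- igraph::V(g)$name
      if (!(genes[oi[i]] %in% nm) || !(genes[oi[j]] %in% nm)) next
      if (is.finite(igraph::distances(g, v = genes[oi[i]], to = genes[oi[j]], mode = "out")[1, 1])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# Smallest number of edge deletions removing every violation, by subset
# enumeration in increasing cardinality.
oracle_min_deletions <- function(net, ordering) {
  oi <- match(ordering, net$genes)
  e <- net$edges
  m <- nrow(e)
  if (!oracle_has_violation(e, net$genes, oi)) {
    return(0L)
  }
  for (k in seq_len(m)) {
    for (comb in utils::combn(m, k, simplify = FALSE)) {
      if (!oracle_has_violation(e[-comb, , drop = FALSE], net$genes, oi)) {
        return(k)
      }
    }
  }
  m
}

# Smallest edit distance (deletions + insertions) to any network consistent
# with `cons`, found by enumerating edit scripts in increasing total size.
# `cap` bounds the search; returns NA when the optimum exceeds it.
oracle_min_edit_distance <- function(ref, cons, cap = 4L) {
  e <- ref$edges
  m <- nrow(e)
  n <- length(ref$genes)
  keys <- (e[, 1] - 1) * n + e[, 2]
  diag_keys <- seq(1, n * n, by = n + 1)
  comp <- setdiff(setdiff(seq_len(n * n), diag_keys), keys)
  mk_net <- function(dl, il) {
    ne <- e[setdiff(seq_len(m), dl), , drop = FALSE]
    if (length(il) > 0) {
      kk <- comp[il]
      add <- cbind(((kk - 1) %/% n) + 1L, ((kk - 1) %% n) + 1L)
      ne <- rbind(ne, add)
    }
    net2 <- ref
    net2$edges <- ne
    net2
  }
  for (d in 0:cap) {
    for (kd in 0:d) {
      ki <- d - kd
      if (kd > m || ki > length(comp)) next
      dels <- if (kd == 0) list(integer(0)) else utils::combn(m, kd, simplify = FALSE)
      inss <- if (ki == 0) list(integer(0)) else utils::combn(length(comp), ki, simplify = FALSE)
      for (dl in dels) {
        for (il in inss) {
          if (is_consistent(mk_net(dl, il), cons)) {
            return(d)
          }
        }
      }
    }
  }
  NA_integer_
}

# One synthetic inference instance at the small-study scale: a scale-free
# target, ideal-screen constraints with `n_unknown` masked, and a shuffled
# reference at `rate` noise.
make_instance <- function(seed, size = 12L, density = 3L, n_unknown = 6L, rate = 0.15) {
  net <- make_target(size, density, seed = seed)
  cons <- derive_constraints(net)
  masked <- mask_unknown(cons, net, n_unknown, seed = seed + 7919L)
  ref <- shuffle_edges(net, rate, seed = seed + 104729L)
  list(target = net, constraints = masked, reference = ref)
}
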