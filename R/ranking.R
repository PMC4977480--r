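# Critical-gene ranking: the order in which the signal is assumed to visit
# the critical genes on its way from receptor to reporter. Two strategies:
# Sloan profile reduction (degree + distance-to-reporter priority) and
# TopSoG, a topological sort for general graphs that condenses strongly
# connected components and guides a depth-first traversal by how close a
# node is to the receptor and how far from the reporter.
#
# Both strategies rank ALL nodes of the network (independently of which
# genes are constrained critical) and then restrict the total order to the
# critical genes, so optimizers can cache the total ranking per reference.

#' Sloan node ranking of a network
#'
#' Classic Sloan profile-reduction ordering over all nodes, run on the
#' undirected view of the network from the receptor towards the reporter.
#' Node priority is `-W1 * degree + W2 * dist(node, reporter)` with the
#' standard weights W1 = 1, W2 = 2; the highest-priority eligible
#' (preactive/active) node is numbered next, and numbering or activating a
#' node raises its neighbours' priorities by W1. Ties break by stable gene
#' order. Nodes in components never touched by the front are started afresh
#' from the best remaining node.
#'
#' @param network a `gene_network`.
#' @return character vector: all genes in Sloan order.
#' @seealso [sloan_order()] for the restriction to critical genes.
#' @export
sloan_ranking <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  w1 <- 1
  w2 <- 2
  n <- length(network$genes)
  adj <- build_adj(network$edges, n, "all") # undirected view
  deg <- lengths(adj)
  t <- match(network$reporter, network$genes)
  s <- match(network$receptor, network$genes)
  d <- bfs_dist(adj, t)
  d[is.infinite(d)] <- 0 # unreachable nodes carry no distance bonus
  p <- -w1 * deg + w2 * d
  # status: 0 inactive, 1 preactive, 2 active, 3 postactive (numbered)
  status <- integer(n)
  status[s] <- 1L
  order_out <- integer(0)
  pick <- function() {
    elig <- which(status == 1L | status == 2L)
    if (length(elig) == 0) return(NA_integer_)
    elig[which.max(p[elig])] # which.max takes the first max: stable tie-break
  }
  while (length(order_out) < n) {
    v <- pick()
    if (is.na(v)) {
      # restart on an untouched component
      rem <- which(status == 0L)
      v <- rem[which.max(p[rem])]
      status[v] <- 1L
    }
    if (status[v] == 1L) { # assembling a preactive node frees its edges
      for (w in adj[[v]]) {
        p[w] <- p[w] + w1
        if (status[w] == 0L) status[w] <- 1L
      }
    }
    status[v] <- 3L
    order_out <- c(order_out, v)
    for (w in adj[[v]]) {
      if (status[w] == 1L) { # neighbour joins the active front
        status[w] <- 2L
        p[w] <- p[w] + w1
        for (x in adj[[w]]) {
          if (status[x] < 3L) {
            p[x] <- p[x] + w1
            if (status[x] == 0L) status[x] <- 1L
          }
        }
      }
    }
  }
  network$genes[order_out]
}

#' Order the critical genes with the Sloan strategy
#'
#' Restricts the Sloan ranking of all nodes (see [sloan_ranking()]) to the
#' given critical genes. The receptor is forced to the front and the reporter
#' to the back so the result is always a valid receptor-to-reporter ordering.
#'
#' @param network a `gene_network`.
#' @param criticals character vector of genes constrained critical; must
#'   contain the receptor and reporter.
#' @return character vector: the critical genes, receptor first, reporter
#'   last.
#' @export
sloan_order <- function(network, criticals) {
  restrict_ordering(network, sloan_ranking(network), criticals)
}

# Restrict a total node ranking to the criticals and enforce the endpoint
# invariants (receptor first, reporter last).
restrict_ordering <- function(network, ranking, criticals) {
  stopifnot(inherits(network, "gene_network"))
  gene_index(network, criticals) # validates membership
  if (!all(c(network$receptor, network$reporter) %in% criticals)) {
    stop("criticals must contain the receptor and reporter", call. = FALSE)
  }
  ord <- ranking[ranking %in% criticals]
  ord <- c(network$receptor, setdiff(ord, c(network$receptor, network$reporter)), network$reporter)
  ord
}

# ---- strongly connected components -----------------------------------------

#' Strongly connected components of a network
#'
#' Components are maximal sets of mutually reachable genes; acyclic parts of
#' the network yield singleton components.
#'
#' @param network a `gene_network`.
#' @return a list with `membership` (integer vector over genes, stable gene
#'   order), `components` (list of character vectors) and `entrances`
#'   (initially `NULL`; see [select_entrance()]).
#' @export
find_sccs <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  g <- as_igraph(network)
  memb <- igraph::components(g, mode = "strong")$membership
  comps <- split(network$genes, memb)
  list(
    membership = as.integer(memb),
    components = unname(comps),
    entrances = NULL
  )
}

#' Entrance gene of a strongly connected component
#'
#' The entry points of a component are its members that receive an edge from
#' outside the component. Among them, only *first-contact* entry points —
#' those a signal from the receptor can reach without previously touching
#' the component — can actually be where signal flow enters, so the
#' candidate set is restricted to them whenever any exist (an entry point
#' fed only by genes downstream of the component would start the
#' within-component ordering against the direction of signal flow). The
#' entrance is then the candidate whose sum of shortest-path distances,
#' inside the component's induced subnetwork, to all other entry points is
#' smallest (ties break by stable gene order). A component containing the
#' receptor uses the receptor; one with no entry point at all uses the
#' member with the best receptor/reporter priority score. Singleton
#' components return their sole gene.
#'
#' @param network a `gene_network`.
#' @param component character vector: the members of one strongly connected
#'   component of `network`.
#' @return a gene identifier.
#' @export
select_entrance <- function(network, component) {
  stopifnot(inherits(network, "gene_network"))
  ci <- gene_index(network, component)
  if (length(ci) == 1) return(component[[1]])
  n <- length(network$genes)
  inside <- logical(n)
  inside[ci] <- TRUE
  ri <- match(network$receptor, network$genes)
  if (inside[ri]) {
    return(network$receptor) # the signal starts inside this component
  }
  e <- network$edges
  incoming <- e[!inside[e[, 1]] & inside[e[, 2]], , drop = FALSE]
  entry <- sort(unique(incoming[, 2]))
  if (length(entry) == 0) {
    sc <- priority_scores(network)
    cand <- sc[sc$gene %in% component, ]
    return(cand$gene[[which.max(cand$score)]])
  }
  if (length(entry) == 1) return(network$genes[entry])
  # restrict to first-contact entry points: some outside predecessor is
  # reachable from the receptor without passing through the component
  adj_full <- build_adj(e, n, "out")
  outside_reach <- bfs_reach(adj_full, ri, blocked = ci)
  first_contact <- entry[vapply(entry, function(v) {
    preds <- incoming[incoming[, 2] == v, 1]
    any(outside_reach[preds])
  }, logical(1))]
  candidates <- if (length(first_contact) > 0) first_contact else entry
  if (length(candidates) == 1) return(network$genes[candidates])
  # distances within the induced subnetwork; sums run over every entry point
  keep <- inside[e[, 1]] & inside[e[, 2]]
  sub <- e[keep, , drop = FALSE]
  local <- match(seq_len(n), ci) # n -> local index or NA
  sub_local <- cbind(local[sub[, 1]], local[sub[, 2]])
  adj <- build_adj(sub_local, length(ci), "out")
  entry_local <- local[entry]
  sums <- vapply(local[candidates], function(v) {
    d <- bfs_dist(adj, v)
    sum(d[setdiff(entry_local, v)])
  }, numeric(1))
  network$genes[candidates[which.min(sums)]] # which.min: first = stable gene order
}

#' Condense the strongly connected components of a network
#'
#' Each multi-gene component is replaced by a single super node; edges
#' crossing a component boundary are redirected to/from the super node and
#' duplicates collapsed. The result is acyclic.
#'
#' @param network a `gene_network`.
#' @param decomposition the result of [find_sccs()] on `network`.
#' @return a list with `graph` (a `gene_network` whose receptor/reporter are
#'   the condensed nodes containing the originals), `node_of` (map gene ->
#'   condensed node name) and `members` (map condensed node name -> character
#'   vector of original genes).
#' @export
condense_sccs <- function(network, decomposition) {
  stopifnot(inherits(network, "gene_network"))
  memb <- decomposition$membership
  comps <- decomposition$components
  sizes <- lengths(comps)
  # condensed node names: the gene itself for singletons, scc super node else
  cname <- character(length(comps))
  for (i in seq_along(comps)) {
    cname[i] <- if (sizes[i] == 1) comps[[i]] else paste0("..scc", i, "..")
  }
  node_of <- stats::setNames(cname[memb], network$genes)
  e <- network$edges
  cf <- cname[memb[e[, 1]]]
  ct <- cname[memb[e[, 2]]]
  keep <- cf != ct
  edges <- unique(tibble::tibble(from = cf[keep], to = ct[keep]))
  # condensed node order follows first appearance of a member in gene order
  first_member <- vapply(comps, function(g) min(match(g, network$genes)), integer(1))
  cond_genes <- cname[order(first_member)]
  crec <- unname(node_of[network$receptor])
  crep <- unname(node_of[network$reporter])
  if (identical(crec, crep)) {
    # receptor and reporter share an SCC; the condensed terminals are only
    # traversal anchors, so park the reporter on any other condensed node
    others <- setdiff(cond_genes, crec)
    if (length(others) == 0) {
      others <- "..lone.."
      cond_genes <- c(cond_genes, others)
    }
    crep <- others[[1]]
  }
  graph <- gene_network(
    edges,
    receptor = crec,
    reporter = crep,
    genes = cond_genes
  )
  members <- stats::setNames(comps, cname)
  list(graph = graph, node_of = node_of, members = members)
}

# ---- guided DFS -------------------------------------------------------------

#' Receptor/reporter priority scores
#'
#' For each gene, `d_s` is the shortest directed path length from the
#' receptor to the gene, `d_t` the shortest directed path length from the
#' gene to the reporter (both `Inf` when unreachable, with the convention
#' 1/Inf = 0), and the score is `1/d_s - 1/d_t`: large for genes close to the
#' receptor but far from the reporter, which is the direction a signal-order
#' traversal should prefer.
#'
#' @param network a `gene_network`; distances are measured in this network.
#' @return a tibble with columns `gene`, `d_s`, `d_t`, `score`.
#' @export
priority_scores <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  n <- length(network$genes)
  adj <- build_adj(network$edges, n, "out")
  radj <- build_adj(network$edges, n, "in")
  s <- match(network$receptor, network$genes)
  t <- match(network$reporter, network$genes)
  d_s <- bfs_dist(adj, s)
  d_t <- bfs_dist(radj, t)
  inv <- function(x) ifelse(is.infinite(x), 0, 1 / x)
  tibble::tibble(
    gene = network$genes,
    d_s = d_s,
    d_t = d_t,
    score = inv(d_s) - inv(d_t)
  )
}

#' Depth-first traversal guided by priority scores
#'
#' Depth-first traversal from `start`; whenever several unvisited successors
#' are available the one with the largest score is taken next (ties break by
#' stable gene order). Returns genes in first-visit order. Nodes unreachable
#' from `start` are appended afterwards, sorted by score descending then
#' stable gene order, so the traversal is always total.
#'
#' @param network a `gene_network`.
#' @param start gene identifier to start from.
#' @param scores a tibble as from [priority_scores()]; scores may be computed
#'   against a different (e.g. uncondensed) network and matched by gene name.
#' @return character vector of all genes in visit order.
#' @export
guided_dfs <- function(network, start, scores) {
  stopifnot(inherits(network, "gene_network"))
  n <- length(network$genes)
  sc <- scores$score[match(network$genes, scores$gene)]
  if (anyNA(sc)) {
    stop("scores missing for gene(s): ",
      paste(network$genes[is.na(sc)], collapse = ", "),
      call. = FALSE
    )
  }
  adj <- build_adj(network$edges, n, "out")
  visited <- logical(n)
  out <- integer(0)
  visit <- function(v) {
    stack <- v
    while (length(stack) > 0) {
      u <- stack[[length(stack)]]
      if (!visited[u]) {
        visited[u] <<- TRUE
        out <<- c(out, u)
      }
      succ <- adj[[u]]
      succ <- succ[!visited[succ]]
      if (length(succ) == 0) {
        stack <- stack[-length(stack)]
      } else {
        nxt <- succ[which.max(sc[succ])]
        stack <- c(stack, nxt)
      }
    }
  }
  visit(gene_index(network, start))
  if (any(!visited)) {
    rest <- which(!visited)
    rest <- rest[order(-sc[rest], rest)]
    out <- c(out, rest)
  }
  network$genes[out]
}

#' TopSoG node ranking of a network
#'
#' Topological Sorting for General Graphs: (1) find the strongly connected
#' components; (2) pick an entrance for every multi-gene component; (3)
#' condense components into super nodes, yielding a DAG; (4) traverse the DAG
#' depth-first from the node containing the receptor, guided by the
#' `1/d_s - 1/d_t` priority score measured in the original network (a super
#' node scores as its entrance); (5) expand each super node in place by the
#' guided traversal of the component's induced subnetwork started at its
#' entrance. The result ranks every gene of the network in putative
#' signal-flow order.
#'
#' @param network a `gene_network`.
#' @return character vector: all genes in TopSoG order.
#' @seealso [topsog_order()] for the restriction to critical genes.
#' @export
topsog_ranking <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  dec <- find_sccs(network)
  cond <- condense_sccs(network, dec)
  sc <- priority_scores(network)
  entrances <- lapply(cond$members, function(m) {
    if (length(m) == 1) m else select_entrance(network, m)
  })
  # a super node carries its entrance's score; singletons their own
  cond_nodes <- network_genes(cond$graph)
  cond_scores <- tibble::tibble(
    gene = cond_nodes,
    score = vapply(cond_nodes, function(nm) {
      ent <- entrances[[nm]]
      if (is.null(ent)) -Inf else sc$score[match(ent, sc$gene)]
    }, numeric(1))
  )
  cond_ranking <- guided_dfs(cond$graph, cond$graph$receptor, cond_scores)
  # expand super nodes in place
  expanded <- lapply(cond_ranking, function(nm) {
    m <- cond$members[[nm]]
    if (is.null(m)) {
      return(character(0)) # placeholder node, no members
    }
    if (length(m) == 1) {
      return(m)
    }
    sub <- induced_network(network, m, entrances[[nm]])
    guided_dfs(sub, entrances[[nm]], sc)
  })
  unlist(expanded, use.names = FALSE)
}

# Induced subnetwork over `members`; receptor/reporter are placeholders for
# traversal only (`start` and an arbitrary distinct member).
induced_network <- function(network, members, start) {
  mi <- gene_index(network, members)
  inside <- logical(length(network$genes))
  inside[mi] <- TRUE
  e <- network$edges
  keep <- inside[e[, 1]] & inside[e[, 2]]
  other <- setdiff(members, start)[[1]]
  gene_network(
    tibble::tibble(
      from = network$genes[e[keep, 1]],
      to = network$genes[e[keep, 2]]
    ),
    receptor = start, reporter = other, genes = members
  )
}

#' Order the critical genes with the TopSoG strategy
#'
#' Restricts the TopSoG ranking of all nodes (see [topsog_ranking()]) to the
#' given critical genes, receptor first and reporter last.
#'
#' @inheritParams sloan_order
#' @return character vector: the critical genes, receptor first, reporter
#'   last.
#' @export
topsog_order <- function(network, criticals) {
  restrict_ordering(network, topsog_ranking(network), criticals)
}

#' Total node ranking for a given strategy
#'
#' @param network a `gene_network`.
#' @param ranking `"topsog"` or `"sloan"`.
#' @return character vector of all genes in rank order.
#' @export
node_ranking <- function(network, ranking = c("topsog", "sloan")) {
  ranking <- match.arg(ranking)
  switch(ranking,
    topsog = topsog_ranking(network),
    sloan = sloan_ranking(network)
  )
}
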