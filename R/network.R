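#' Build a gene network
#'
#' A `gene_network` is a simple directed graph over named genes with a
#' designated receptor (signal entry) and reporter (signal readout) gene.
#' It is the container every other function in the package operates on.
#'
#' Gene identifiers are case-sensitive opaque strings. The order of the gene
#' set is the order of first appearance (file order), which downstream
#' algorithms use for reproducible tie-breaking. Duplicate edges are collapsed
#' with a warning; self-loops are an error.
#'
#' @param edges a data frame (or tibble) with character columns `from` and
#'   `to`, one directed edge per row. A two-column matrix is also accepted.
#' @param receptor,reporter gene identifiers of the receptor and reporter.
#'   Must be distinct.
#' @param genes optional character vector fixing the gene set (and its order).
#'   Defaults to the genes seen in `edges` plus receptor and reporter.
#' @return an object of class `gene_network`.
#' @examples
#' net <- gene_network(
#'   data.frame(from = c("s", "a"), to = c("a", "t")),
#'   receptor = "s", reporter = "t"
#' )
#' net
#' @export
gene_network <- function(edges, receptor, reporter, genes = NULL) {
  if (is.matrix(edges)) {
    edges <- data.frame(from = as.character(edges[, 1]), to = as.character(edges[, 2]))
  }
  stopifnot(is.data.frame(edges))
  if (nrow(edges) == 0) {
    ef <- character(0)
    et <- character(0)
  } else {
    ef <- as.character(edges$from %||% edges[[1]])
    et <- as.character(edges$to %||% edges[[2]])
  }
  if (!is.character(receptor) || !is.character(reporter) ||
    length(receptor) != 1 || length(reporter) != 1) {
    stop("receptor and reporter must be single gene identifiers", call. = FALSE)
  }
  if (identical(receptor, reporter)) {
    stop("receptor and reporter must be distinct", call. = FALSE)
  }
  if (is.null(genes)) {
    genes <- unique(c(receptor, reporter, as.vector(rbind(ef, et))))
  } else {
    genes <- as.character(genes)
    if (anyDuplicated(genes)) stop("duplicate gene identifiers in `genes`", call. = FALSE)
    missing <- setdiff(c(receptor, reporter, ef, et), genes)
    if (length(missing) > 0) {
      stop(
        "edge endpoints or terminals not in `genes`: ",
        paste(missing, collapse = ", "),
        call. = FALSE
      )
    }
  }
  if (any(ef == et)) {
    bad <- unique(ef[ef == et])
    stop("self-loops are not allowed (gene ", paste(bad, collapse = ", "), ")", call. = FALSE)
  }
  fi <- match(ef, genes)
  ti <- match(et, genes)
  key <- (fi - 1) * length(genes) + ti
  if (anyDuplicated(key)) {
    warning("duplicate edges collapsed", call. = FALSE)
    keep <- !duplicated(key)
    fi <- fi[keep]
    ti <- ti[keep]
  }
  structure(
    list(
      genes = genes,
      edges = cbind(from = as.integer(fi), to = as.integer(ti)),
      receptor = receptor,
      reporter = reporter
    ),
    class = "gene_network"
  )
}

#' @export
print.gene_network <- function(x, ...) {
  cat(
    "<gene_network> ", length(x$genes), " genes, ", nrow(x$edges), " edges; ",
    "receptor = ", x$receptor, ", reporter = ", x$reporter, "\n",
    sep = ""
  )
  invisible(x)
}

#' Edge list of a network as a tibble
#'
#' @param x a `gene_network`.
#' @param ... unused.
#' @return a tibble with character columns `from`, `to`.
#' @export
network_edges <- function(x, ...) {
  stopifnot(inherits(x, "gene_network"))
  tibble::tibble(
    from = x$genes[x$edges[, 1]],
    to = x$genes[x$edges[, 2]]
  )
}

#' @method as_tibble gene_network
#' @export
as_tibble.gene_network <- function(x, ...) network_edges(x)

#' Genes of a network
#' @param x a `gene_network`.
#' @return character vector of gene identifiers in stable (file) order.
#' @export
network_genes <- function(x) {
  stopifnot(inherits(x, "gene_network"))
  x$genes
}

# ---- internal index helpers -------------------------------------------------

gene_index <- function(net, gene) {
  i <- match(gene, net$genes)
  if (anyNA(i)) {
    stop("unknown gene identifier: ", paste(gene[is.na(i)], collapse = ", "), call. = FALSE)
  }
  i
}

edge_keys <- function(net) {
  (net$edges[, 1] - 1) * length(net$genes) + net$edges[, 2]
}

# Replace the edge set (integer matrix) of a network, keeping genes/terminals.
set_edges <- function(net, edges) {
  net$edges <- edges
  net
}

as_igraph_impl <- function(net) {
  g <- igraph::graph_from_edgelist(
    cbind(net$genes[net$edges[, 1]], net$genes[net$edges[, 2]]),
    directed = TRUE
  )
  missing <- setdiff(net$genes, igraph::V(g)$name)
  if (length(missing) > 0) g <- igraph::add_vertices(g, length(missing), name = missing)
  igraph::permute(g, match(igraph::V(g)$name, net$genes))
}

#' Convert a gene network to an igraph object
#'
#' Vertices carry the gene names in stable order; the receptor and reporter
#' are recorded as graph attributes.
#'
#' @param net a `gene_network`.
#' @return a directed `igraph` graph.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  if (nrow(net$edges) == 0) {
    g <- igraph::make_empty_graph(n = length(net$genes), directed = TRUE)
    g <- igraph::set_vertex_attr(g, "name", value = net$genes)
  } else {
    g <- as_igraph_impl(net)
  }
  g <- igraph::set_graph_attr(g, "receptor", net$receptor)
  igraph::set_graph_attr(g, "reporter", net$reporter)
}

# ---- criticality, consistency, distance ------------------------------------

#' Is a gene critical for signal transduction?
#'
#' A gene is critical when every directed path from the receptor to the
#' reporter passes through it; knocking it down severs signal flow.
#' Equivalently, deleting the gene (with its incident edges) leaves the
#' reporter unreachable from the receptor. The receptor and reporter are
#' always critical. If the network has no receptor-to-reporter path at all,
#' the defining condition is vacuously true for every gene and all genes are
#' reported critical; constructed (inferred) networks always contain such a
#' path, so this arises only on raw inputs.
#'
#' @param network a `gene_network`.
#' @param gene a gene identifier.
#' @return `TRUE` or `FALSE`.
#' @seealso [critical_genes()] for all critical genes at once.
#' @export
is_critical <- function(network, gene) {
  stopifnot(inherits(network, "gene_network"))
  gi <- gene_index(network, gene)
  s <- match(network$receptor, network$genes)
  t <- match(network$reporter, network$genes)
  if (gi == s || gi == t) return(TRUE)
  adj <- build_adj(network$edges, length(network$genes), "out")
  if (!bfs_reach(adj, s)[t]) return(TRUE) # vacuous: no path at all
  !bfs_reach(adj, s, blocked = gi)[t]
}

#' All critical genes of a network
#'
#' @param network a `gene_network`.
#' @return character vector of critical genes in stable gene order; always
#'   contains the receptor and reporter.
#' @export
critical_genes <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  n <- length(network$genes)
  s <- match(network$receptor, network$genes)
  t <- match(network$reporter, network$genes)
  adj <- build_adj(network$edges, n, "out")
  radj <- build_adj(network$edges, n, "in")
  fwd <- bfs_reach(adj, s)
  if (!fwd[t]) {
    return(network$genes) # vacuously, every gene is critical
  }
  bwd <- bfs_reach(radj, t)
  on_path <- fwd & bwd
  crit <- logical(n)
  crit[c(s, t)] <- TRUE
  for (v in which(on_path)) {
    if (v == s || v == t) next
    crit[v] <- !bfs_reach(adj, s, blocked = v)[t]
  }
  network$genes[crit]
}

#' Check a network against RNAi constraints
#'
#' RNAi constraints assign each gene 1 (knockdown blocks signal flow: the gene
#' must be critical), 0 (it does not: the gene must be noncritical) or -1
#' (experiment missing: no requirement). A network is consistent with a
#' constraint vector when every 1-gene is critical and every 0-gene is not.
#'
#' @param network a `gene_network`.
#' @param constraints a constraint tibble as returned by [constraints()], or
#'   any data frame with columns `gene` and `value`.
#' @return `TRUE` or `FALSE`.
#' @export
is_consistent <- function(network, constraints) {
  cv <- constraint_values(network, constraints)
  crit <- network$genes %in% critical_genes(network)
  all(crit[cv == 1L]) && !any(crit[cv == 0L])
}

#' Edit distance between two networks on the same gene set
#'
#' The number of directed edges present in exactly one of the two networks
#' (the size of the symmetric difference of the edge sets). This is the edit
#' cost that the constructor minimizes against the reference network.
#'
#' @param network_a,network_b `gene_network`s built on the same gene set.
#' @return a nonnegative integer.
#' @export
network_distance <- function(network_a, network_b) {
  stopifnot(inherits(network_a, "gene_network"), inherits(network_b, "gene_network"))
  if (!setequal(network_a$genes, network_b$genes)) {
    stop("networks are not built on the same gene set", call. = FALSE)
  }
  ka <- paste(network_a$genes[network_a$edges[, 1]], network_a$genes[network_a$edges[, 2]], sep = "\r")
  kb <- paste(network_b$genes[network_b$edges[, 1]], network_b$genes[network_b$edges[, 2]], sep = "\r")
  length(setdiff(ka, kb)) + length(setdiff(kb, ka))
}

# ---- constraint vectors -----------------------------------------------------

#' Create an RNAi constraint vector
#'
#' Returns a tibble with one row per gene of `network` (in stable gene order)
#' and a `value` column in \{1, 0, -1\}: critical, noncritical, unknown. The
#' receptor and reporter are always critical by definition, so a value of 0
#' on either is rejected; they default to 1.
#'
#' @param network a `gene_network`.
#' @param values named vector or list giving values for a subset of genes;
#'   unlisted genes get `default`.
#' @param default value for genes not named in `values` (default -1, unknown).
#' @return a tibble with columns `gene` (character) and `value` (integer).
#' @export
constraints <- function(network, values = NULL, default = -1L) {
  stopifnot(inherits(network, "gene_network"))
  v <- rep(as.integer(default), length(network$genes))
  names(v) <- network$genes
  if (!is.null(values)) {
    values <- unlist(values)
    gene_index(network, names(values)) # validates
    v[names(values)] <- as.integer(values)
  }
  v[network$receptor] <- if (v[network$receptor] == 0L) {
    stop("receptor cannot be constrained noncritical", call. = FALSE)
  } else {
    1L
  }
  v[network$reporter] <- if (v[network$reporter] == 0L) {
    stop("reporter cannot be constrained noncritical", call. = FALSE)
  } else {
    1L
  }
  if (!all(v %in% c(1L, 0L, -1L))) {
    stop("constraint values must be 1, 0 or -1", call. = FALSE)
  }
  tibble::tibble(gene = network$genes, value = unname(v))
}

# Validate a constraint table against a network and return the integer values
# aligned to stable gene order.
constraint_values <- function(network, constraints) {
  stopifnot(is.data.frame(constraints), all(c("gene", "value") %in% names(constraints)))
  extra <- setdiff(constraints$gene, network$genes)
  miss <- setdiff(network$genes, constraints$gene)
  if (length(extra) > 0 || length(miss) > 0) {
    stop(
      "constraint domain does not match gene set",
      if (length(miss) > 0) paste0("; missing: ", paste(miss, collapse = ", ")),
      if (length(extra) > 0) paste0("; extra: ", paste(extra, collapse = ", ")),
      call. = FALSE
    )
  }
  v <- as.integer(constraints$value[match(network$genes, constraints$gene)])
  if (!all(v %in% c(1L, 0L, -1L))) stop("constraint values must be 1, 0 or -1", call. = FALSE)
  rr <- match(c(network$receptor, network$reporter), network$genes)
  if (any(v[rr] == 0L)) {
    stop("receptor/reporter cannot be constrained noncritical", call. = FALSE)
  }
  v
}

#' Derive the complete constraint vector a network satisfies
#'
#' Every gene on all receptor-to-reporter paths is labelled critical (1) and
#' every other gene noncritical (0); this is the constraint vector an ideal,
#' noise-free RNAi screen of the network would produce. The result never
#' contains unknowns and the network is always consistent with it.
#'
#' @param network a `gene_network` with a receptor-to-reporter path.
#' @return a constraint tibble (columns `gene`, `value`).
#' @export
derive_constraints <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  crit <- network$genes %in% critical_genes(network)
  tibble::tibble(gene = network$genes, value = ifelse(crit, 1L, 0L))
}
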