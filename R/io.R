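# Readers and writers for the plain-text formats the tool exchanges:
# edge-list TSV (with optional #receptor=/#reporter= header comments),
# a minimal SIF dialect, GraphML (via igraph), and constraint TSV.

#' Read a network from an edge-list TSV file
#'
#' One edge per line as `source<TAB>target`. Lines starting with `#` are
#' comments; the special comments `#receptor=<id>` and `#reporter=<id>` may
#' designate the terminals, otherwise pass them explicitly (arguments win
#' over header comments).
#'
#' @param path file path.
#' @param receptor,reporter optional gene identifiers overriding the header.
#' @return a `gene_network`.
#' @export
read_network_tsv <- function(path, receptor = NULL, reporter = NULL) {
  lines <- readLines(path, warn = FALSE)
  hdr <- function(key) {
    m <- grep(paste0("^#", key, "="), lines, value = TRUE)
    if (length(m) == 0) NULL else sub(paste0("^#", key, "="), "", m[[1]])
  }
  receptor <- receptor %||% hdr("receptor")
  reporter <- reporter %||% hdr("reporter")
  if (is.null(receptor) || is.null(reporter)) {
    stop("receptor/reporter not given and not found in header comments", call. = FALSE)
  }
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(body) == 0) {
    edges <- tibble::tibble(from = character(0), to = character(0))
  } else {
    parts <- strsplit(body, "\t", fixed = TRUE)
    bad <- lengths(parts) < 2
    if (any(bad)) stop("malformed edge line(s): ", paste(body[bad], collapse = "; "), call. = FALSE)
    edges <- tibble::tibble(
      from = vapply(parts, `[[`, "", 1),
      to = vapply(parts, `[[`, "", 2)
    )
  }
  gene_network(edges, receptor = receptor, reporter = reporter)
}

#' Write a network to an edge-list TSV file
#'
#' Terminals are recorded as `#receptor=`/`#reporter=` header comments so the
#' file round-trips through [read_network_tsv()] unaided.
#'
#' @param network a `gene_network`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(network, path) {
  stopifnot(inherits(network, "gene_network"))
  e <- network_edges(network)
  writeLines(
    c(
      paste0("#receptor=", network$receptor),
      paste0("#reporter=", network$reporter),
      if (nrow(e) > 0) paste(e$from, e$to, sep = "\t")
    ),
    path
  )
  invisible(path)
}

#' Read/write a network in SIF format
#'
#' A minimal SIF dialect: `source<TAB>relation<TAB>target`. The relation
#' token is ignored on read and written as `activates`. SIF carries no
#' terminal designation, so receptor and reporter must be supplied.
#'
#' @param path file path.
#' @param receptor,reporter gene identifiers.
#' @return `read_network_sif()` returns a `gene_network`;
#'   `write_network_sif()` returns `path` invisibly.
#' @export
read_network_sif <- function(path, receptor, reporter) {
  lines <- readLines(path, warn = FALSE)
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(body) == 0) {
    edges <- tibble::tibble(from = character(0), to = character(0))
  } else {
    parts <- strsplit(body, "\t", fixed = TRUE)
    bad <- lengths(parts) < 3
    if (any(bad)) stop("malformed SIF line(s): ", paste(body[bad], collapse = "; "), call. = FALSE)
    edges <- tibble::tibble(
      from = vapply(parts, `[[`, "", 1),
      to = vapply(parts, `[[`, "", 3)
    )
  }
  gene_network(edges, receptor = receptor, reporter = reporter)
}

#' @rdname read_network_sif
#' @param network a `gene_network`.
#' @export
write_network_sif <- function(network, path) {
  stopifnot(inherits(network, "gene_network"))
  e <- network_edges(network)
  writeLines(
    if (nrow(e) > 0) paste(e$from, "activates", e$to, sep = "\t") else character(0),
    path
  )
  invisible(path)
}

#' Read/write a network in GraphML format
#'
#' The receptor and reporter travel as graph attributes; an optional integer
#' node attribute `constraint` round-trips an RNAi constraint vector.
#'
#' @param path file path.
#' @param receptor,reporter optional overrides for terminals stored in the
#'   file's graph attributes.
#' @return `read_network_graphml()` returns a `gene_network`; if the file
#'   carries a `constraint` node attribute the constraint tibble is attached
#'   as attribute `"constraints"`. `write_network_graphml()` returns `path`
#'   invisibly.
#' @export
read_network_graphml <- function(path, receptor = NULL, reporter = NULL) {
  g <- igraph::read_graph(path, format = "graphml")
  receptor <- receptor %||% igraph::graph_attr(g, "receptor")
  reporter <- reporter %||% igraph::graph_attr(g, "reporter")
  if (is.null(receptor) || is.null(reporter)) {
    stop("receptor/reporter not given and not stored in the GraphML file", call. = FALSE)
  }
  genes <- igraph::V(g)$name
  el <- igraph::as_edgelist(g, names = TRUE)
  net <- gene_network(
    tibble::tibble(from = el[, 1], to = el[, 2]),
    receptor = receptor, reporter = reporter, genes = genes
  )
  cons <- igraph::vertex_attr(g, "constraint")
  if (!is.null(cons)) {
    attr(net, "constraints") <- tibble::tibble(gene = genes, value = as.integer(cons))
  }
  net
}

#' @rdname read_network_graphml
#' @param network a `gene_network`.
#' @param constraints optional constraint tibble to store as the `constraint`
#'   node attribute.
#' @export
write_network_graphml <- function(network, path, constraints = NULL) {
  g <- as_igraph(network)
  if (!is.null(constraints)) {
    v <- constraint_values(network, constraints)
    g <- igraph::set_vertex_attr(g, "constraint", value = v)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read/write RNAi constraints as TSV
#'
#' Two tab-separated columns, `gene<TAB>value`, value in \{1, 0, -1\}. Genes
#' of the network absent from the file default to -1 (unknown) with a
#' warning.
#'
#' @param path file path.
#' @param network the `gene_network` the constraints belong to.
#' @return `read_constraints_tsv()` returns a constraint tibble;
#'   `write_constraints_tsv()` returns `path` invisibly.
#' @export
read_constraints_tsv <- function(path, network) {
  stopifnot(inherits(network, "gene_network"))
  tab <- utils::read.table(path,
    sep = "\t", header = FALSE, comment.char = "#",
    col.names = c("gene", "value"), colClasses = c("character", "integer")
  )
  extra <- setdiff(tab$gene, network$genes)
  if (length(extra) > 0) {
    stop("constraint file names unknown gene(s): ", paste(extra, collapse = ", "), call. = FALSE)
  }
  miss <- setdiff(network$genes, tab$gene)
  if (length(miss) > 0) {
    warning(
      length(miss), " gene(s) absent from constraint file set to unknown (-1)",
      call. = FALSE
    )
  }
  v <- stats::setNames(tab$value, tab$gene)
  constraints(network, values = v, default = -1L)
}

#' @rdname read_constraints_tsv
#' @param constraints a constraint tibble (columns `gene`, `value`).
#' @export
write_constraints_tsv <- function(constraints, path) {
  stopifnot(is.data.frame(constraints), all(c("gene", "value") %in% names(constraints)))
  writeLines(paste(constraints$gene, constraints$value, sep = "\t"), path)
  invisible(path)
}
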