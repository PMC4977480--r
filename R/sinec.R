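# The SiNeC-style constructor: given a reference network and a COMPLETE
# constraint vector (no unknowns), edit the reference with few edge
# deletions/insertions so the result is consistent with the constraints.
#
# Three steps: (i) rank the critical genes (ranking module); (ii) delete
# edges that let a signal bypass a critical gene — i.e. sever every path
# between nonconsecutive critical genes whose interior is all noncritical;
# (iii) insert the direct edge between consecutive critical genes where no
# admissible path remains, or where some noncritical gene sits on all of
# them (which would wrongly make it critical).

#' Segment assignment of noncritical genes
#'
#' Given a critical-gene ordering `g_0 .. g_{m+1}` (receptor to reporter),
#' a noncritical gene serves segment `i` when it is reachable from `g_i` and
#' can reach `g_{i+1}` via paths whose interior genes are all noncritical.
#' Genes qualifying for several segments keep every index; genes serving no
#' segment are off-path. Mostly a diagnostic view of the constructor's
#' bookkeeping.
#'
#' @param network a `gene_network`.
#' @param ordering character vector: critical genes from receptor to
#'   reporter (as from [sloan_order()] or [topsog_order()]).
#' @return a list with `segments` (tibble `gene`, `segment` with one row per
#'   qualifying gene/segment pair, segments indexed from 0) and `off_path`
#'   (character vector).
#' @export
assign_segments <- function(network, ordering) {
  stopifnot(inherits(network, "gene_network"))
  oi <- gene_index(network, ordering)
  n <- length(network$genes)
  noncrit <- setdiff(seq_len(n), oi)
  rows <- list()
  for (i in seq_len(length(oi) - 1)) {
    gi <- oi[i]
    gj <- oi[i + 1]
    allowed <- c(noncrit, gi, gj)
    sub <- subgraph_edges_within(network, allowed)
    adj <- build_adj(sub, n, "out")
    radj <- build_adj(sub, n, "in")
    fwd <- bfs_reach(adj, gi)
    bwd <- bfs_reach(radj, gj)
    serves <- intersect(noncrit, which(fwd & bwd))
    if (length(serves) > 0) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        gene = network$genes[serves], segment = i - 1L
      )
    }
  }
  seg <- if (length(rows) > 0) dplyr::bind_rows(rows) else {
    tibble::tibble(gene = character(0), segment = integer(0))
  }
  list(
    segments = seg,
    off_path = setdiff(network$genes[noncrit], seg$gene)
  )
}

# Edge matrix restricted to edges with both endpoints in `allowed` (integer
# node indices); matrix keeps original node indexing.
subgraph_edges_within <- function(network, allowed) {
  inside <- logical(length(network$genes))
  inside[allowed] <- TRUE
  e <- network$edges
  e[inside[e[, 1]] & inside[e[, 2]], , drop = FALSE]
}

#' Delete edges conflicting with a critical-gene ordering
#'
#' After deletion no path whose interior genes are all noncritical connects
#' two nonconsecutive critical genes: a signal can no longer sneak from
#' `g_i` past `g_{i+1}` to a later critical gene. For each consecutive pair
#' the deleted edges form a minimum unit-capacity edge cut separating `g_i`
#' from all later critical genes `g_{i+2}, ..., reporter` in the subnetwork
#' whose interior is the noncritical genes (`g_{i+1}` and the other critical
#' genes removed). Cuts are computed sequentially on the progressively
#' deleted network and unioned. Backward edges (towards earlier segments)
#' are never deleted: they cannot complete a receptor-to-reporter path that
#' skips a critical gene.
#'
#' @param network a `gene_network`.
#' @param ordering critical genes from receptor to reporter.
#' @return an `edit_script` with deletions only (see [sinec_construct()]).
#' @export
delete_conflicting_edges <- function(network, ordering) {
  stopifnot(inherits(network, "gene_network"))
  oi <- gene_index(network, ordering)
  n <- length(network$genes)
  noncrit <- setdiff(seq_len(n), oi)
  m2 <- length(oi) # number of critical genes incl. terminals
  cur <- network$edges
  deleted <- cur[0, , drop = FALSE]
  for (i in seq_len(max(m2 - 2, 0))) {
    gi <- oi[i]
    later <- oi[(i + 2):m2]
    allowed <- c(noncrit, gi, later)
    inside <- logical(n)
    inside[allowed] <- TRUE
    # later criticals are pure sinks here: a path continuing through one of
    # them has a critical interior gene and is no violation
    keep <- inside[cur[, 1]] & inside[cur[, 2]] & !(cur[, 1] %in% later)
    sub <- cur[keep, , drop = FALSE]
    cut_local <- min_edge_cut(sub, n, source = gi, sinks = later)
    if (length(cut_local) > 0) {
      cut_rows <- which(keep)[cut_local]
      deleted <- rbind(deleted, cur[cut_rows, , drop = FALSE])
      cur <- cur[-cut_rows, , drop = FALSE]
    }
  }
  new_edit_script(network, deleted = deleted, inserted = cur[0, , drop = FALSE])
}

#' Insert edges required by the constraints
#'
#' Runs after [delete_conflicting_edges()]. For each consecutive critical
#' pair `(g_i, g_{i+1})` the direct edge is inserted when (case 1) no path
#' with all-noncritical interior connects them, or (case 2) some noncritical
#' gene lies on every such path and no direct edge exists — left alone that
#' gene would itself become critical, contradicting its constraint. The
#' result is verified against the full constraint vector; failure raises an
#' error naming the offending genes (a guard: it indicates a bug, not a
#' property of the input).
#'
#' @param network a `gene_network` (already past the deletion step).
#' @param ordering critical genes from receptor to reporter.
#' @param constraints complete constraint tibble (no -1 entries).
#' @return an `edit_script` with insertions only.
#' @export
insert_required_edges <- function(network, ordering, constraints) {
  stopifnot(inherits(network, "gene_network"))
  oi <- gene_index(network, ordering)
  n <- length(network$genes)
  noncrit <- setdiff(seq_len(n), oi)
  cur <- network$edges
  keys <- (cur[, 1] - 1) * n + cur[, 2]
  ins <- list()
  for (i in seq_len(length(oi) - 1)) {
    gi <- oi[i]
    gj <- oi[i + 1]
    direct <- ((gi - 1) * n + gj) %in% keys
    sub <- subgraph_edges_within(network, c(noncrit, gi, gj))
    # paths gi -> gj must not re-enter gi or leave gj; interior noncritical
    adj <- build_adj(sub, n, "out")
    reach <- bfs_reach(adj, gi)
    need <- FALSE
    if (!reach[gj]) {
      need <- TRUE # case 1: no admissible path at all
    } else if (!direct) {
      # case 2: a noncritical gene on ALL admissible paths?
      interior <- intersect(noncrit, which(reach))
      for (x in interior) {
        if (!bfs_reach(adj, gi, blocked = x)[gj]) {
          need <- TRUE
          break
        }
      }
    }
    if (need && !direct) ins[[length(ins) + 1]] <- c(gi, gj)
  }
  inserted <- if (length(ins) > 0) {
    do.call(rbind, ins)
  } else {
    cur[0, , drop = FALSE]
  }
  es <- new_edit_script(network, deleted = cur[0, , drop = FALSE], inserted = inserted)
  verify_consistency(es$network, constraints)
  es
}

verify_consistency <- function(network, constraints) {
  cv <- constraint_values(network, constraints)
  crit <- network$genes %in% critical_genes(network)
  bad <- (cv == 1L & !crit) | (cv == 0L & crit)
  if (any(bad)) {
    stop(
      "construction failure: constraints violated for gene(s) ",
      paste(network$genes[bad], collapse = ", "),
      call. = FALSE
    )
  }
  invisible(TRUE)
}

# ---- edit scripts -----------------------------------------------------------

# deleted/inserted are integer edge matrices in `base`'s gene indexing;
# the resulting network applies both to `base`.
new_edit_script <- function(base, deleted, inserted) {
  e <- base$edges
  n <- length(base$genes)
  keys <- (e[, 1] - 1) * n + e[, 2]
  if (nrow(deleted) > 0) {
    dk <- (deleted[, 1] - 1) * n + deleted[, 2]
    stopifnot(all(dk %in% keys))
    e <- e[!(keys %in% dk), , drop = FALSE]
  }
  if (nrow(inserted) > 0) {
    ik <- (inserted[, 1] - 1) * n + inserted[, 2]
    stopifnot(!any(ik %in% keys))
    e <- rbind(e, inserted)
  }
  res <- set_edges(base, e)
  structure(
    list(
      deleted = edge_tibble(base, deleted),
      inserted = edge_tibble(base, inserted),
      network = res
    ),
    class = "edit_script"
  )
}

edge_tibble <- function(net, e) {
  tibble::tibble(from = net$genes[e[, 1]], to = net$genes[e[, 2]])
}

#' @export
print.edit_script <- function(x, ...) {
  cat(
    "<edit_script> ", nrow(x$deleted), " deletion(s), ",
    nrow(x$inserted), " insertion(s)\n",
    sep = ""
  )
  invisible(x)
}

#' Number of edits in an edit script
#' @param x an `edit_script`.
#' @return integer: deletions plus insertions.
#' @export
edit_count <- function(x) {
  stopifnot(inherits(x, "edit_script"))
  nrow(x$deleted) + nrow(x$inserted)
}

# Merge a deletions-only and an insertions-only script against `base`.
merge_edit_scripts <- function(base, del_script, ins_script) {
  gi <- function(tb) {
    cbind(
      match(tb$from, base$genes),
      match(tb$to, base$genes)
    )
  }
  del <- gi(del_script$deleted)
  ins <- gi(ins_script$inserted)
  storage.mode(del) <- "integer"
  storage.mode(ins) <- "integer"
  new_edit_script(base, deleted = del, inserted = ins)
}

#' Construct a consistent network close to a reference
#'
#' The full constructor: ranks the critical genes on the reference network
#' with the chosen strategy, deletes the edges that conflict with the
#' ordering, then inserts the edges the constraints require. The output
#' network is consistent with the (complete) constraint vector; its distance
#' to the reference equals the number of edits. Deterministic for fixed
#' inputs and strategy.
#'
#' @param reference a `gene_network` (the reference topology).
#' @param constraints complete constraint tibble: every gene 1 or 0, no
#'   unknowns (resolve unknowns first with the optimizers, see
#'   [infer_holistic()]).
#' @param ranking `"topsog"` (default) or `"sloan"`.
#' @param ranking_total optional precomputed total node ranking of
#'   `reference` (see [node_ranking()]); supplied by the optimizers to avoid
#'   recomputing it for every constraint assignment.
#' @return an `edit_script`: tibbles `deleted` and `inserted`, and `network`,
#'   the constructed `gene_network`.
#' @examples
#' ref <- gene_network(
#'   data.frame(from = c("s", "a", "s"), to = c("a", "t", "t")),
#'   receptor = "s", reporter = "t"
#' )
#' cs <- constraints(ref, c(a = 1, t = 1, s = 1))
#' sinec_construct(ref, cs)
#' @export
sinec_construct <- function(reference, constraints,
                            ranking = c("topsog", "sloan"),
                            ranking_total = NULL) {
  ranking <- match.arg(ranking)
  cv <- constraint_values(reference, constraints)
  if (any(cv == -1L)) {
    stop(
      "constraint vector is incomplete (unknown genes: ",
      paste(reference$genes[cv == -1L], collapse = ", "),
      "); resolve unknowns with an optimizer first",
      call. = FALSE
    )
  }
  criticals <- reference$genes[cv == 1L]
  # a reference already consistent with the constraints needs no edits: the
  # empty edit script is the exact optimum, so never let an unlucky ordering
  # manufacture edits here
  if (is_consistent(reference, constraints)) {
    out <- new_edit_script(reference,
      deleted = reference$edges[0, , drop = FALSE],
      inserted = reference$edges[0, , drop = FALSE]
    )
    attr(out, "ordering") <- NULL
    return(out)
  }
  if (is.null(ranking_total)) ranking_total <- node_ranking(reference, ranking)
  ordering <- restrict_ordering(reference, ranking_total, criticals)
  del <- delete_conflicting_edges(reference, ordering)
  ins <- insert_required_edges(del$network, ordering, constraints)
  out <- merge_edit_scripts(reference, del, ins)
  attr(out, "ordering") <- ordering
  out
}
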