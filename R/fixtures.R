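#' The motivating ranking fixture
#'
#' A small hypothetical signaling network with receptor `vs`, reporter `vt`
#' and two genes `va`, `vb` constrained critical, built so that the two
#' ranking strategies disagree on their order: `va` feeds `vb` directly and
#' both sit one step from the reporter, so signal-flow causality puts `va`
#' first (TopSoG does), while `vb` carries the larger degree and a cloud of
#' feeder genes adjacent to the receptor, which the degree-and-distance
#' driven Sloan front reaches first (Sloan ranks `vb` before `va`).
#'
#' The construction is verified programmatically on creation: `va` and `vb`
#' each lie on a receptor-to-reporter path, `va` reaches `vb`,
#' `deg(vb) > deg(va)`, and both have the same shortest directed distance to
#' the reporter. The feeders (`x1..x4`) point into the receptor, so they are
#' adjacent to it in Sloan's undirected view but invisible to a forward
#' traversal; `va`'s private successors (`q*`, `r*`) keep part of its
#' neighbourhood un-activated at the moment Sloan chooses between `va` and
#' `vb`.
#'
#' @return a `gene_network` with attribute `"criticals"` = `c("vs", "va",
#'   "vb", "vt")`.
#' @export
fig1_network <- function() {
  edges <- tibble::tribble(
    ~from, ~to,
    "vs", "va",
    "va", "vb",
    "va", "vt",
    "vb", "vt",
    "x1", "vb", "x1", "vs",
    "x2", "vb", "x2", "vs",
    "x3", "vb", "x3", "vs",
    "x4", "vb", "x4", "vs",
    "va", "q1",
    "va", "q2",
    "q1", "r11", "q1", "r12", "q1", "r13",
    "q2", "r21", "q2", "r22", "q2", "r23"
  )
  net <- gene_network(edges, receptor = "vs", reporter = "vt")
  # programmatic contract of the fixture
  deg <- function(g) {
    sum(net$edges == match(g, net$genes))
  }
  sc <- priority_scores(net)
  adj <- build_adj(net$edges, length(net$genes), "out")
  on_path <- function(g) {
    gi <- match(g, net$genes)
    s <- match("vs", net$genes)
    t <- match("vt", net$genes)
    bfs_reach(adj, s)[gi] && bfs_reach(adj, gi)[t]
  }
  stopifnot(
    on_path("va"), on_path("vb"),
    bfs_reach(adj, match("va", net$genes))[match("vb", net$genes)],
    deg("vb") > deg("va"),
    sc$d_t[sc$gene == "va"] == sc$d_t[sc$gene == "vb"]
  )
  attr(net, "criticals") <- c("vs", "va", "vb", "vt")
  net
}

#' Random simple directed graph (fixed edge count)
#'
#' Uniformly samples `n_edges` distinct ordered pairs (no self-loops) over
#' `size` genes. Used as a neutral test bed for the graph predicates; for
#' benchmark networks use [generate_target()].
#'
#' @param size number of genes.
#' @param n_edges number of directed edges.
#' @param seed RNG seed.
#' @param receptor,reporter indices (in 1..size) of the terminals; default 1
#'   and `size`.
#' @return a `gene_network` with genes `g1..g<size>`.
#' @export
random_digraph <- function(size, n_edges, seed, receptor = 1L, reporter = size) {
  stopifnot(size >= 2, n_edges <= size * (size - 1))
  genes <- paste0("g", seq_len(size))
  with_seed(seed, {
    # linear indices of the size x size pair matrix, diagonal excluded
    pick <- sample(setdiff(seq_len(size * size), seq(1, size * size, by = size + 1)), n_edges)
    fr <- ((pick - 1) %% size) + 1
    to <- ((pick - 1) %/% size) + 1
    gene_network(
      tibble::tibble(from = genes[fr], to = genes[to]),
      receptor = genes[receptor], reporter = genes[reporter], genes = genes
    )
  })
}
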