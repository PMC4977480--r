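# Critical-gene ranking: Sloan, SCC machinery, guided DFS, TopSoG.

test_that("both strategies reproduce the unique order on a chain", {
  net <- gene_network(
    tibble::tibble(from = c("s", "a", "b"), to = c("a", "b", "t")),
    receptor = "s", reporter = "t"
  )
  crit <- c("s", "a", "b", "t")
  expect_identical(sloan_order(net, crit), crit)
  expect_identical(topsog_order(net, crit), crit)
})

test_that("the motivating fixture separates the two strategies", {
  net <- fig1_network()
  crit <- attr(net, "criticals")
  so <- sloan_order(net, crit)
  to <- topsog_order(net, crit)
  expect_lt(match("vb", so), match("va", so)) # Sloan: high-degree vb first
  expect_lt(match("va", to), match("vb", to)) # TopSoG: causal order va first
})

test_that("orderings are valid critical orderings on random instances", {
  for (seed in 1:6) {
    inst <- make_instance(seed, size = 14, n_unknown = 0)
    net <- inst$reference
    crit <- critical_genes(inst$target)
    for (ord in list(sloan_order(net, crit), topsog_order(net, crit))) {
      expect_setequal(ord, crit)
      expect_identical(anyDuplicated(ord), 0L)
      expect_identical(ord[[1]], net$receptor)
      expect_identical(ord[[length(ord)]], net$reporter)
    }
  }
})

test_that("strongly connected components agree with mutual reachability", {
  net <- gene_network(
    tibble::tibble(from = c("a", "b", "c", "c"), to = c("b", "c", "a", "d")),
    receptor = "a", reporter = "d"
  )
  dec <- find_sccs(net)
  expect_setequal(
    lapply(dec$components, sort),
    list(c("a", "b", "c"), "d")
  )
  dag <- gene_network(
    tibble::tibble(from = c("a", "a", "b"), to = c("b", "c", "c")),
    receptor = "a", reporter = "c"
  )
  expect_true(all(lengths(find_sccs(dag)$components) == 1))

  for (seed in c(3, 9, 27)) {
    net <- random_digraph(9, 20, seed = seed)
    dec <- find_sccs(net)
    same <- oracle_same_scc(net)
    for (i in seq_along(net$genes)) {
      for (j in seq_along(net$genes)) {
        expect_identical(
          dec$membership[i] == dec$membership[j],
          unname(same[i, j])
        )
      }
    }
  }
})

test_that("entrance selection minimizes distance sums to other entry points", {
  # 3-cycle a->b->c->a entered at a and b: within-cycle sums a:1, b:2
  net <- gene_network(
    tibble::tibble(
      from = c("s", "s", "a", "b", "c", "c"),
      to = c("a", "b", "b", "c", "a", "t")
    ),
    receptor = "s", reporter = "t"
  )
  expect_identical(select_entrance(net, c("a", "b", "c")), "a")
  expect_identical(select_entrance(net, "s"), "s")
  # single entry point
  net2 <- gene_network(
    tibble::tibble(from = c("s", "a", "b", "b"), to = c("a", "b", "a", "t")),
    receptor = "s", reporter = "t"
  )
  expect_identical(select_entrance(net2, c("a", "b")), "a")
  # component containing the receptor, no incoming edges
  net3 <- gene_network(
    tibble::tibble(from = c("s", "x", "x"), to = c("x", "s", "t")),
    receptor = "s", reporter = "t"
  )
  expect_identical(select_entrance(net3, c("s", "x")), "s")
})

test_that("condensation collapses cycles and is always acyclic", {
  net <- gene_network(
    tibble::tibble(from = c("s", "a", "b", "b"), to = c("a", "b", "a", "t")),
    receptor = "s", reporter = "t"
  )
  cond <- condense_sccs(net, find_sccs(net))
  expect_identical(length(network_genes(cond$graph)), 3L)
  expect_identical(nrow(network_edges(cond$graph)), 2L)
  expect_true(igraph::is_dag(as_igraph(cond$graph)))

  dag <- gene_network(
    tibble::tibble(from = c("s", "s", "a"), to = c("a", "b", "t")),
    receptor = "s", reporter = "t"
  )
  cond2 <- condense_sccs(dag, find_sccs(dag))
  expect_setequal(network_genes(cond2$graph), network_genes(dag))
  expect_identical(nrow(network_edges(cond2$graph)), nrow(network_edges(dag)))

  for (seed in c(2, 4, 8, 16)) {
    net <- random_digraph(10, 25, seed = seed)
    cond <- condense_sccs(net, find_sccs(net))
    expect_true(igraph::is_dag(as_igraph(cond$graph)))
  }
})

test_that("priority scores follow 1/d_s - 1/d_t with 1/Inf = 0", {
  net <- gene_network(
    tibble::tibble(
      from = c("s", "s", "x", "w", "y", "a"),
      to = c("x", "y", "w", "t", "t", "s")
    ),
    receptor = "s", reporter = "t"
  )
  sc <- priority_scores(net)
  # x: d_s=1, d_t=2 -> 0.5; y: d_s=1, d_t=1 -> 0; w: d_s=2, d_t=1 -> -0.5
  expect_equal(sc$score[sc$gene == "x"], 0.5)
  expect_equal(sc$score[sc$gene == "y"], 0)
  expect_equal(sc$score[sc$gene == "w"], -0.5)
  # a is unreachable from s (1/d_s = 0) but reaches t in 3 steps via s
  expect_equal(sc$score[sc$gene == "a"], -1 / 3)
  # guided DFS prefers the far-from-reporter branch: x before y
  ord <- guided_dfs(net, "s", sc)
  expect_lt(match("x", ord), match("y", ord))
  # unreachable node appended at the end
  expect_identical(ord[[length(ord)]], "a")
})

test_that("TopSoG equals guided DFS on DAGs and respects topological order", {
  dag <- gene_network(
    tibble::tibble(
      from = c("s", "s", "a", "b", "a"),
      to = c("a", "b", "c", "c", "t")
    ),
    receptor = "s", reporter = "t"
  )
  expect_identical(
    topsog_ranking(dag),
    guided_dfs(dag, "s", priority_scores(dag))
  )
  # on DAG inputs no later critical can reach an earlier one
  for (seed in 1:5) {
    net <- make_target(12, 2, seed = seed * 13)
    dec <- find_sccs(net)
    cond <- condense_sccs(net, dec)
    crit <- critical_genes(net)
    ord <- topsog_order(net, crit)
    cg <- as_igraph(cond$graph)
    cd <- igraph::distances(cg, mode = "out")
    cnode <- function(g) unname(cond$node_of[g])
    for (i in seq_along(ord)) {
      for (j in seq_len(i - 1)) {
        ni <- cnode(ord[[i]])
        nj <- cnode(ord[[j]])
        if (ni != nj && !(ord[[i]] %in% c(net$receptor, net$reporter)) &&
          !(ord[[j]] %in% c(net$receptor, net$reporter))) {
          expect_false(is.finite(cd[ni, nj]) && cd[ni, nj] > 0)
        }
      }
    }
  }
})
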