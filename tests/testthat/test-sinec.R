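# The constructor: segment assignment, deletion, insertion, full build.

bypass_net <- function() {
  gene_network(
    tibble::tibble(from = c("s", "a", "s"), to = c("a", "t", "t")),
    receptor = "s", reporter = "t"
  )
}

test_that("segment assignment places noncritical genes between critical pairs", {
  net <- gene_network(
    tibble::tibble(from = c("s", "a"), to = c("a", "t")),
    receptor = "s", reporter = "t", genes = c("s", "a", "t", "z")
  )
  seg <- assign_segments(net, c("s", "t"))
  expect_identical(seg$segments$gene, "a")
  expect_identical(seg$segments$segment, 0L)
  expect_identical(seg$off_path, "z")

  net2 <- gene_network(
    tibble::tibble(from = c("s", "a", "g1", "b"), to = c("a", "g1", "b", "t")),
    receptor = "s", reporter = "t"
  )
  seg2 <- assign_segments(net2, c("s", "g1", "t"))$segments
  expect_identical(seg2$segment[seg2$gene == "a"], 0L)
  expect_identical(seg2$segment[seg2$gene == "b"], 1L)
})

test_that("deletion removes exactly the bypass around a critical gene", {
  es <- delete_conflicting_edges(bypass_net(), c("s", "a", "t"))
  expect_identical(es$deleted, tibble::tibble(from = "s", to = "t"))
  expect_identical(nrow(es$inserted), 0L)

  # an already order-consistent network needs no deletions
  chain <- gene_network(
    tibble::tibble(from = c("s", "a"), to = c("a", "t")),
    receptor = "s", reporter = "t"
  )
  expect_identical(nrow(delete_conflicting_edges(chain, c("s", "a", "t"))$deleted), 0L)
})

test_that("deletion matches the subset-enumeration minimum on most instances", {
  n_match <- 0
  total <- 20
  for (i in seq_len(total)) {
    params <- withr::with_seed(i, list(n = sample(8:10, 1), m = sample(10:14, 1)))
    net <- random_digraph(params$n, params$m, seed = i * 17)
    mids <- withr::with_seed(
      i + 999,
      sample(setdiff(network_genes(net), c(net$receptor, net$reporter)), 2)
    )
    ord <- topsog_order(net, c(net$receptor, mids, net$reporter))
    del <- delete_conflicting_edges(net, ord)
    om <- oracle_min_deletions(net, ord)
    expect_gte(nrow(del$deleted), om)
    # deletions really remove every violation
    expect_false(oracle_has_violation(
      del$network$edges, net$genes, match(ord, net$genes)
    ))
    if (nrow(del$deleted) == om) n_match <- n_match + 1
  }
  expect_gte(n_match / total, 0.9)
})

test_that("insertion covers both the missing-path and forced-gene cases", {
  # case 1: no path between consecutive criticals at all
  net <- gene_network(
    tibble::tibble(from = "a", to = "t"),
    receptor = "s", reporter = "t", genes = c("s", "a", "t")
  )
  cons <- constraints(net, c(a = 1))
  es <- insert_required_edges(net, c("s", "a", "t"), cons)
  expect_identical(es$inserted, tibble::tibble(from = "s", to = "a"))

  # case 2: noncritical b sits on every s -> a path
  net2 <- gene_network(
    tibble::tibble(from = c("s", "b", "a"), to = c("b", "a", "t")),
    receptor = "s", reporter = "t"
  )
  cons2 <- constraints(net2, c(a = 1, b = 0))
  es2 <- insert_required_edges(net2, c("s", "a", "t"), cons2)
  expect_identical(es2$inserted, tibble::tibble(from = "s", to = "a"))
  expect_false(is_critical(es2$network, "b"))

  # consistent input needs nothing
  chain <- gene_network(
    tibble::tibble(from = c("s", "a"), to = c("a", "t")),
    receptor = "s", reporter = "t"
  )
  es3 <- insert_required_edges(chain, c("s", "a", "t"), constraints(chain, c(a = 1)))
  expect_identical(nrow(es3$inserted), 0L)
})

test_that("construct edits the bypass example minimally and reports the edit count", {
  net <- bypass_net()
  cons <- constraints(net, c(a = 1))
  es <- sinec_construct(net, cons)
  expect_identical(edit_count(es), 1L)
  expect_identical(network_distance(es$network, net), 1L)
  expect_identical(oracle_min_edit_distance(net, cons), 1L)

  # a network already consistent with its own constraints is untouched
  inst <- make_target(12, 3, seed = 21)
  es0 <- sinec_construct(inst, derive_constraints(inst))
  expect_identical(edit_count(es0), 0L)
  expect_identical(network_edges(es0$network), network_edges(inst))
})

test_that("construct is deterministic, idempotent and always consistent", {
  for (seed in 1:8) {
    inst <- make_instance(seed, size = 10, n_unknown = 0, rate = 0.25)
    cons <- inst$constraints
    ref <- inst$reference
    es1 <- sinec_construct(ref, cons)
    es2 <- sinec_construct(ref, cons)
    expect_identical(es1$deleted, es2$deleted)
    expect_identical(es1$inserted, es2$inserted)
    expect_true(is_consistent(es1$network, cons))
    expect_identical(
      network_distance(es1$network, ref),
      edit_count(es1)
    )
    # rebuilding from the constructed network changes nothing
    es3 <- sinec_construct(es1$network, cons)
    expect_identical(edit_count(es3), 0L)
  }
  # incomplete constraints are rejected
  inst <- make_instance(1)
  expect_error(sinec_construct(inst$reference, inst$constraints), "incomplete")
})

test_that("construct distance nearly matches the brute-force optimum on small instances", {
  n_eq <- 0
  n_checked <- 0
  for (i in 1:12) {
    net <- make_target(9, 2, seed = 100 + i) # 14 edges
    cons <- derive_constraints(net)
    ref <- shuffle_edges(net, 0.15, seed = 200 + i)
    es <- sinec_construct(ref, cons)
    d <- edit_count(es)
    expect_true(is_consistent(es$network, cons))
    opt <- oracle_min_edit_distance(ref, cons, cap = min(d, 4L))
    if (is.na(opt)) next # optimum beyond the enumeration cap; skip the comparison
    n_checked <- n_checked + 1
    expect_gte(d, opt)
    expect_lte(d - opt, 2)
    if (d == opt) n_eq <- n_eq + 1
  }
  expect_gte(n_eq / n_checked, 0.9)
})

test_that("the internal min cut agrees with igraph max-flow", {
  for (i in 1:25) {
    params <- withr::with_seed(i, list(n = sample(5:10, 1), m = sample(6:18, 1)))
    net <- random_digraph(params$n, params$m, seed = i * 31)
    e <- net$edges
    n <- params$n
    sinks <- withr::with_seed(i + 5000, sample(2:n, sample(1:2, 1)))
    cut <- sinecr:::min_edge_cut(e, n, 1L, sinks)
    el <- rbind(e, cbind(sinks, n + 1L))
    g <- igraph::graph_from_edgelist(el, directed = TRUE)
    caps <- c(rep(1, nrow(e)), rep(Inf, length(sinks)))
    mf <- igraph::max_flow(g, source = 1L, target = n + 1L, capacity = caps)
    expect_identical(length(cut), as.integer(mf$value))
    e2 <- if (length(cut)) e[-cut, , drop = FALSE] else e
    adj <- sinecr:::build_adj(e2, n, "out")
    expect_false(any(sinecr:::bfs_reach(adj, 1L)[sinks]))
  }
})
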