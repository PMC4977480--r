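# Unknown-constraint resolution: holistic / prioritized / exhaustive.

test_that("initialization flips exactly the unknown entries to noncritical", {
  net <- make_target(10, 2, seed = 2)
  full <- derive_constraints(net)
  expect_identical(initialize_noncritical(full), full) # nothing to do
  masked <- mask_unknown(full, net, 4, seed = 3)
  init <- initialize_noncritical(masked)
  expect_false(any(init$value == -1L))
  expect_identical(sum(init$value != masked$value), 4L)
})

test_that("with no unknowns every optimizer reduces to a single construction", {
  inst <- make_instance(4, n_unknown = 0)
  es <- sinec_construct(inst$reference, inst$constraints)
  for (method in c("holistic", "prioritized", "exhaustive")) {
    res <- infer_network(inst$reference, inst$constraints, method = method)
    expect_identical(res$constructor_calls, 1L)
    expect_identical(res$distance_to_reference, network_distance(es$network, inst$reference))
    expect_identical(nrow(res$trace), 0L)
  }
})

test_that("a reference consistent under all-noncritical unknowns accepts no flips", {
  net <- make_target(12, 3, seed = 6)
  cons <- derive_constraints(net)
  # mask only genes that really are noncritical: the all-noncritical start is
  # then already consistent with the target used as its own reference
  noncrit <- cons$gene[cons$value == 0L]
  cons$value[cons$gene %in% utils::head(noncrit, 5)] <- -1L
  res <- infer_holistic(net, cons)
  expect_identical(res$distance_to_reference, 0L)
  expect_identical(nrow(res$trace), 0L)
  expect_identical(res$constructor_calls, 1L) # 0 cannot be improved
})

test_that("exhaustive search counts constructor calls exactly and bounds the heuristics", {
  for (n in c(1L, 3L)) {
    inst <- make_instance(10 + n, n_unknown = n)
    res <- infer_exhaustive(inst$reference, inst$constraints)
    expect_identical(res$constructor_calls, as.integer(2^n))
  }
  expect_error(
    infer_exhaustive(make_instance(1)$reference, make_instance(1)$constraints, max_n = 2L),
    "max_n"
  )
})

test_that("heuristics never beat the exhaustive optimum and usually reach it", {
  n_eq_h <- 0
  n_eq_p <- 0
  calls_h <- 0
  calls_p <- 0
  total <- 15
  for (i in seq_len(total)) {
    inst <- make_instance(i, size = 11, n_unknown = 5)
    ex <- infer_exhaustive(inst$reference, inst$constraints)
    h <- infer_holistic(inst$reference, inst$constraints)
    p <- infer_prioritized(inst$reference, inst$constraints)
    expect_gte(h$distance_to_reference, ex$distance_to_reference)
    expect_gte(p$distance_to_reference, ex$distance_to_reference)
    # consistency with the resolved constraints, rechecked from scratch
    for (res in list(ex, h, p)) {
      expect_true(is_consistent(res$network, res$resolved_constraints))
      expect_identical(
        res$distance_to_reference,
        network_distance(res$network, inst$reference)
      )
    }
    # accepted-flip traces improve strictly monotonically
    for (res in list(h, p)) {
      if (nrow(res$trace) > 1) {
        expect_true(all(diff(res$trace$distance) < 0))
      }
    }
    if (h$distance_to_reference == ex$distance_to_reference) n_eq_h <- n_eq_h + 1
    if (p$distance_to_reference == ex$distance_to_reference) n_eq_p <- n_eq_p + 1
    calls_h <- calls_h + h$constructor_calls
    calls_p <- calls_p + p$constructor_calls
  }
  expect_gte(n_eq_h / total, 0.8)
  expect_gte(n_eq_p / total, 0.8)
  # in aggregate the grouped climber constructs fewer candidate networks
  expect_lte(calls_p, calls_h)
})

test_that("the prioritized trace replays an explicit simulation of the grouping rule", {
  inst <- make_instance(42, size = 10, n_unknown = 4)
  res <- infer_prioritized(inst$reference, inst$constraints)

  # independent replay with direct constructor calls
  ref <- inst$reference
  cv <- inst$constraints$value
  values <- ifelse(cv == -1L, 0L, cv)
  dist_of <- function(v) {
    cs <- tibble::tibble(gene = network_genes(ref), value = v)
    network_distance(sinec_construct(ref, cs)$network, ref)
  }
  best_v <- values
  best_d <- dist_of(values)
  unknown <- which(cv == -1L)
  probe <- vapply(unknown, function(g) {
    v <- values
    v[g] <- 1L
    dist_of(v)
  }, numeric(1))
  expect_identical(
    res$dist_table,
    tibble::tibble(gene = network_genes(ref)[unknown], dist = as.integer(probe))
  )
  trace <- list()
  for (d in sort(unique(probe))) {
    grp <- unknown[probe == d]
    repeat {
      grp <- grp[best_v[grp] == 0L]
      if (length(grp) == 0 || best_d == 0) break
      ds <- vapply(grp, function(g) {
        v <- best_v
        v[g] <- 1L
        dist_of(v)
      }, numeric(1))
      m <- which.min(ds)
      if (ds[m] < best_d) {
        best_v[grp[m]] <- 1L
        best_d <- ds[m]
        trace[[length(trace) + 1]] <- list(gene = network_genes(ref)[grp[m]], d = ds[m])
        grp <- grp[-m]
      } else {
        break
      }
    }
  }
  expect_identical(res$trace$gene, vapply(trace, `[[`, "", "gene"))
  expect_identical(res$distance_to_reference, as.integer(best_d))
})

test_that("tidy and glance summarize inference results", {
  inst <- make_instance(3, size = 10, n_unknown = 3)
  res <- infer_prioritized(inst$reference, inst$constraints)
  tr <- tidy(res)
  expect_s3_class(tr, "tbl_df")
  expect_named(tr, c("gene", "distance"))
  gl <- glance(res)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$method, "prioritized")
  expect_identical(gl$n_unknown, 3L)
  expect_identical(gl$flips_accepted, nrow(tr))
})
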