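# Synthetic benchmark: scale-free target networks, diameter-based
# receptor/reporter selection, ideal-screen constraints with a random subset
# masked unknown, and degree-preserving edge shuffling that turns a target
# into a noisy reference.

#' Generate a scale-free target network
#'
#' Preferential-attachment growth: starting from `density` isolated core
#' genes, each arriving gene attaches `density` edges to distinct existing
#' genes chosen with probability proportional to their current degree
#' (uniformly while all degrees are zero). Each attachment edge is oriented
#' new-to-old or old-to-new by a fair coin. The result is a simple digraph
#' with exactly `density * (size - density)` edges, deterministic per seed.
#'
#' @param size number of genes (must exceed `density`).
#' @param density edges attached per arriving gene (default 3).
#' @param seed RNG seed.
#' @return a `gene_network` with genes `g1..g<size>` and provisional
#'   terminals (use [select_receptor_reporter()] or [make_target()]).
#' @export
generate_target <- function(size, density = 3L, seed = 1L) {
  m <- as.integer(density)
  size <- as.integer(size)
  if (size <= m) stop("size must exceed density", call. = FALSE)
  if (m < 1) stop("density must be >= 1", call. = FALSE)
  genes <- paste0("g", seq_len(size))
  with_seed(seed, {
    deg <- numeric(size)
    from <- integer(m * (size - m))
    to <- integer(m * (size - m))
    k <- 0L
    for (v in (m + 1L):size) {
      existing <- seq_len(v - 1L)
      w <- deg[existing]
      targets <- if (all(w == 0)) {
        sample(existing, m)
      } else {
        sample_weighted_distinct(existing, w, m)
      }
      for (u in targets) {
        k <- k + 1L
        if (stats::runif(1) < 0.5) {
          from[k] <- v
          to[k] <- u
        } else {
          from[k] <- u
          to[k] <- v
        }
        deg[u] <- deg[u] + 1
        deg[v] <- deg[v] + 1
      }
    }
    gene_network(
      tibble::tibble(from = genes[from], to = genes[to]),
      receptor = genes[1], reporter = genes[size], genes = genes
    )
  })
}

# m distinct draws with probability proportional to weight (zero-weight items
# are drawable only after all positive weights are taken)
sample_weighted_distinct <- function(items, w, m) {
  out <- integer(m)
  w <- w + ifelse(w == 0, 1e-9, 0)
  for (i in seq_len(m)) {
    pick <- sample(seq_along(items), 1, prob = w)
    out[i] <- items[pick]
    items <- items[-pick]
    w <- w[-pick]
  }
  out
}

#' Choose receptor and reporter on the network diameter
#'
#' Computes all-pairs shortest directed path lengths; among pairs at finite
#' distance the maximum defines the diameter. The source of a diameter path
#' becomes the receptor and its sink the reporter; when several pairs tie,
#' one is chosen uniformly at random (seeded).
#'
#' @param network a `gene_network`.
#' @param seed RNG seed for tie-breaking.
#' @return the network with receptor/reporter reassigned; the chosen pair is
#'   also available via `$receptor`/`$reporter`. Errors if no directed path
#'   of length >= 1 exists.
#' @export
select_receptor_reporter <- function(network, seed = 1L) {
  stopifnot(inherits(network, "gene_network"))
  g <- as_igraph(network)
  d <- igraph::distances(g, mode = "out")
  d[!is.finite(d)] <- -1
  diag(d) <- -1
  dia <- max(d)
  if (dia < 1) stop("network has no directed path of length >= 1", call. = FALSE)
  hits <- which(d == dia, arr.ind = TRUE)
  pick <- with_seed(seed, hits[sample(nrow(hits), 1), ])
  network$receptor <- network$genes[pick[["row"]]]
  network$reporter <- network$genes[pick[["col"]]]
  network
}

#' Generate a benchmark target with terminals
#'
#' Convenience wrapper: [generate_target()] followed by
#' [select_receptor_reporter()]. If the generated graph has no directed path
#' at all (possible at tiny sizes), it is regenerated with a derived seed,
#' up to `retries` attempts.
#'
#' @inheritParams generate_target
#' @param retries maximum regeneration attempts.
#' @return a `gene_network` with diameter-based receptor and reporter.
#' @export
make_target <- function(size, density = 3L, seed = 1L, retries = 25L) {
  seeds <- c(seed, derive_seeds(seed, retries))
  for (s in seeds) {
    net <- generate_target(size, density, s)
    ok <- tryCatch(
      {
        net <- select_receptor_reporter(net, seed = s)
        TRUE
      },
      error = function(e) FALSE
    )
    if (ok) return(net)
  }
  stop("could not generate a target with a receptor-reporter path", call. = FALSE)
}

#' Mask constraints of randomly chosen genes as unknown
#'
#' Emulates an incomplete RNAi screen: exactly `n` genes, sampled without
#' replacement and never the receptor or reporter, have their constraint set
#' to -1.
#'
#' @param constraints a complete constraint tibble (see
#'   [derive_constraints()]).
#' @param network the `gene_network` the constraints belong to.
#' @param n number of genes to mask; at most `|genes| - 2`.
#' @param seed RNG seed.
#' @return the constraint tibble with `n` values replaced by -1.
#' @export
mask_unknown <- function(constraints, network, n, seed = 1L) {
  stopifnot(inherits(network, "gene_network"))
  constraint_values(network, constraints) # validates
  eligible <- setdiff(network$genes, c(network$receptor, network$reporter))
  if (n > length(eligible)) {
    stop("cannot mask ", n, " genes; only ", length(eligible), " eligible", call. = FALSE)
  }
  masked <- with_seed(seed, sample(eligible, n))
  dplyr::mutate(
    tibble::as_tibble(constraints),
    value = ifelse(.data$gene %in% masked, -1L, as.integer(.data$value))
  )
}

#' Degree-preserving edge shuffling
#'
#' Perturbs a target network into a reference: performs
#' `ceiling(rate * |E| / 2)` successful directed double-edge swaps — two
#' edges (a,b), (c,d) are replaced by (a,d), (c,b) — so `rate * |E|` edges
#' are rewired while every gene keeps its exact in- and out-degree. Swaps
#' that would create a self-loop, a duplicate edge, or change nothing are
#' rejected and retried; exhausting the attempt budget is an error reporting
#' the swaps completed.
#'
#' @param network a `gene_network`.
#' @param rate fraction of edges to rewire, in [0, 1).
#' @param seed RNG seed.
#' @param attempt_factor budget multiplier: at most
#'   `attempt_factor * swaps_needed` trials.
#' @return the shuffled `gene_network` (same genes and terminals).
#' @export
shuffle_edges <- function(network, rate, seed = 1L, attempt_factor = 200L) {
  stopifnot(inherits(network, "gene_network"), rate >= 0, rate < 1)
  e <- network$edges
  mE <- nrow(e)
  swaps_needed <- ceiling(rate * mE / 2)
  if (swaps_needed == 0) return(network)
  n <- length(network$genes)
  with_seed(seed, {
    keys <- new.env(hash = TRUE, parent = emptyenv())
    kstr <- function(a, b) paste0(a, ".", b)
    for (i in seq_len(mE)) assign(kstr(e[i, 1], e[i, 2]), TRUE, envir = keys)
    done <- 0L
    attempts <- 0L
    budget <- attempt_factor * swaps_needed
    while (done < swaps_needed) {
      attempts <- attempts + 1L
      if (attempts > budget) {
        stop(
          "edge shuffling stalled after ", done, " of ", swaps_needed,
          " swaps; the degree sequence admits too few rewirings",
          call. = FALSE
        )
      }
      ij <- sample.int(mE, 2)
      a <- e[ij[1], 1]; b <- e[ij[1], 2]
      cc <- e[ij[2], 1]; d <- e[ij[2], 2]
      if (a == d || cc == b) next # self-loop
      if (b == d || a == cc) next # no-op or duplicate of the partner edge
      if (exists(kstr(a, d), envir = keys) || exists(kstr(cc, b), envir = keys)) next
      rm(list = c(kstr(a, b), kstr(cc, d)), envir = keys)
      assign(kstr(a, d), TRUE, envir = keys)
      assign(kstr(cc, b), TRUE, envir = keys)
      e[ij[1], 2] <- d
      e[ij[2], 2] <- b
      done <- done + 1L
    }
    set_edges(network, e)
  })
}

#' Benchmark configuration
#'
#' The synthetic study grid: target sizes, edges-per-gene density, replicate
#' targets per size, the mutation (noise) rates at which references are
#' derived, and the number of genes masked unknown. The defaults are the
#' study grid of four sizes times ten replicates with seven noise levels and
#' 15 unknown genes; the default noise level for single-condition runs is
#' 15%.
#'
#' @param sizes integer vector of network sizes.
#' @param density edges per arriving gene.
#' @param replicates targets generated per size.
#' @param mutation_rates noise levels (fraction of edges rewired).
#' @param n_unknown genes masked unknown per target (capped at size - 2).
#' @param seed master seed; every artifact's seed derives from it.
#' @return a `benchmark_config` list.
#' @export
benchmark_config <- function(sizes = c(50L, 75L, 100L, 125L),
                             density = 3L,
                             replicates = 10L,
                             mutation_rates = seq(0.05, 0.35, by = 0.05),
                             n_unknown = 15L,
                             seed = 1L) {
  stopifnot(
    all(sizes > density), density >= 1,
    all(mutation_rates >= 0), all(mutation_rates < 1),
    all(n_unknown < sizes - 2)
  )
  structure(
    list(
      sizes = as.integer(sizes), density = as.integer(density),
      replicates = as.integer(replicates),
      mutation_rates = as.numeric(mutation_rates),
      n_unknown = as.integer(n_unknown), seed = as.integer(seed)
    ),
    class = "benchmark_config"
  )
}

#' Generate the full synthetic benchmark
#'
#' For every size and replicate: a scale-free target with diameter-based
#' terminals, its ideal-screen constraints, and a mask of unknown genes; for
#' every target and mutation rate: one degree-preserving shuffled reference.
#' All artifacts are written as edge-list/constraint TSV files under `dir`
#' together with `manifest.json` recording the per-item seeds, so the whole
#' dataset can be regenerated byte-identically.
#'
#' @param config a [benchmark_config()].
#' @param dir output directory (created if missing).
#' @return the manifest, invisibly, as a list (`config` plus a `targets`
#'   list; each target records its files, terminals, seeds and references).
#' @export
make_benchmark <- function(config, dir) {
  stopifnot(inherits(config, "benchmark_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n_targets <- length(config$sizes) * config$replicates
  seeds <- matrix(
    derive_seeds(config$seed, n_targets * 3 + n_targets * length(config$mutation_rates)),
    ncol = 1
  )
  si <- 0L
  next_seed <- function() {
    si <<- si + 1L
    seeds[si]
  }
  targets <- list()
  for (size in config$sizes) {
    for (rep in seq_len(config$replicates)) {
      id <- sprintf("target_s%d_r%02d", size, rep)
      gen_seed <- next_seed()
      mask_seed <- next_seed()
      rr_seed <- next_seed() # folded into make_target retries; kept for manifest
      net <- make_target(size, config$density, gen_seed)
      cons <- derive_constraints(net)
      masked <- mask_unknown(cons, net, min(config$n_unknown, size - 2L), mask_seed)
      net_path <- file.path(dir, paste0(id, ".tsv"))
      con_path <- file.path(dir, paste0(id, ".constraints.tsv"))
      write_network_tsv(net, net_path)
      write_constraints_tsv(masked, con_path)
      refs <- list()
      for (rate in config$mutation_rates) {
        ref_seed <- next_seed()
        ref <- shuffle_edges(net, rate, ref_seed)
        ref_path <- file.path(dir, sprintf("%s_ref_rate%03d.tsv", id, round(rate * 100)))
        write_network_tsv(ref, ref_path)
        refs[[length(refs) + 1]] <- list(
          rate = rate, seed = ref_seed, path = basename(ref_path)
        )
      }
      targets[[length(targets) + 1]] <- list(
        id = id, size = size, replicate = rep,
        seed = gen_seed, mask_seed = mask_seed, rr_seed = rr_seed,
        receptor = net$receptor, reporter = net$reporter,
        n_unknown = min(config$n_unknown, size - 2L),
        path = basename(net_path),
        constraints_path = basename(con_path),
        references = refs
      )
    }
  }
  manifest <- list(config = unclass(config), targets = targets)
  jsonlite::write_json(
    manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(manifest)
}
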