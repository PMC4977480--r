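# Resolving unknown RNAi constraints. Real screens rarely cover every gene;
# the genes with missing data (-1) can each be critical or not, and the best
# completion is the one whose constructed network stays closest to the
# reference. Holistic hill climbing sweeps all unknowns each round;
# prioritized hill climbing first probes each unknown alone, groups unknowns
# by the probe distance and climbs group by group (cheapest-looking genes
# first); the exhaustive baseline enumerates all 2^n completions.

#' Set every unknown constraint to noncritical
#'
#' The optimizers' shared starting point: real signaling networks have few
#' critical genes, so unknowns default to noncritical (0) before climbing.
#'
#' @param constraints a constraint tibble (columns `gene`, `value`).
#' @return the tibble with every -1 replaced by 0.
#' @export
initialize_noncritical <- function(constraints) {
  stopifnot(is.data.frame(constraints), all(c("gene", "value") %in% names(constraints)))
  dplyr::mutate(
    tibble::as_tibble(constraints),
    value = ifelse(.data$value == -1L, 0L, as.integer(.data$value))
  )
}

# Shared bookkeeping for one optimizer run. `construct1` builds and measures
# one completion, counting constructor calls. Completions are memoized by
# assignment, so re-examining an already-probed completion (e.g. the first
# sweep of a prioritized group, which coincides with its probes) is free —
# this is what makes the prioritized call count O(n + sum n_i^2) rather
# than O(n^2).
new_run_state <- function(reference, constraints, ranking) {
  cv <- constraint_values(reference, constraints)
  total <- node_ranking(reference, ranking) # criticals-independent, cached
  env <- new.env(parent = emptyenv())
  env$calls <- 0L
  env$cache <- new.env(hash = TRUE, parent = emptyenv())
  construct1 <- function(values) {
    key <- paste(values, collapse = "")
    hit <- get0(key, envir = env$cache)
    if (!is.null(hit)) {
      return(hit)
    }
    env$calls <- env$calls + 1L
    cs <- tibble::tibble(gene = reference$genes, value = values)
    es <- sinec_construct(reference, cs, ranking = ranking, ranking_total = total)
    res <- list(
      network = es$network,
      distance = network_distance(es$network, reference),
      values = values
    )
    assign(key, res, envir = env$cache)
    res
  }
  list(
    cv = cv,
    unknown = which(cv == -1L),
    construct1 = construct1,
    calls = function() env$calls
  )
}

finish_result <- function(reference, best, trace, state, method, ranking,
                          dist_table = NULL, groups = NULL) {
  resolved <- tibble::tibble(gene = reference$genes, value = best$values)
  # recompute the distance independently of the climbing bookkeeping
  dist <- network_distance(best$network, reference)
  stopifnot(is_consistent(best$network, resolved))
  structure(
    list(
      network = best$network,
      resolved_constraints = resolved,
      distance_to_reference = dist,
      constructor_calls = state$calls(),
      n_unknown = length(state$unknown),
      trace = trace,
      dist_table = dist_table,
      groups = groups,
      method = method,
      ranking = ranking,
      reference = reference
    ),
    class = "sinec_inference"
  )
}

empty_trace <- function() tibble::tibble(gene = character(0), distance = integer(0))

#' Holistic hill climbing over unknown constraints
#'
#' Starts from all unknowns noncritical, then repeatedly sweeps every
#' still-noncritical unknown gene: each is temporarily set critical, the
#' network is rebuilt, and the sweep's best strictly-improving flip is
#' accepted permanently. Stops when no single flip improves the distance.
#' Runs the constructor O(n^2) times for n unknowns. Flips are
#' one-directional (noncritical to critical) and never reverted.
#'
#' @param reference a `gene_network`.
#' @param constraints constraint tibble; -1 marks the unknown genes.
#' @param ranking `"topsog"` (default) or `"sloan"`.
#' @return a `sinec_inference`: the constructed network, the resolved
#'   constraint vector, its distance to the reference, the constructor-call
#'   count and the accepted-flip trace. See [tidy.sinec_inference()].
#' @export
infer_holistic <- function(reference, constraints, ranking = c("topsog", "sloan")) {
  ranking <- match.arg(ranking)
  state <- new_run_state(reference, constraints, ranking)
  values <- ifelse(state$cv == -1L, 0L, state$cv)
  best <- state$construct1(values)
  candidates <- state$unknown
  trace <- empty_trace()
  repeat {
    if (length(candidates) == 0 || best$distance == 0) break
    sweep <- lapply(candidates, function(g) {
      v <- best$values
      v[g] <- 1L
      state$construct1(v)
    })
    dists <- vapply(sweep, `[[`, numeric(1), "distance")
    m <- which.min(dists) # first minimum: stable gene-order tie-break
    if (dists[m] < best$distance) {
      best <- sweep[[m]]
      trace <- dplyr::bind_rows(trace, tibble::tibble(
        gene = reference$genes[candidates[m]],
        distance = as.integer(dists[m])
      ))
      candidates <- candidates[-m]
    } else {
      break
    }
  }
  finish_result(reference, best, trace, state, "holistic", ranking)
}

#' Prioritized hill climbing over unknown constraints
#'
#' Like [infer_holistic()] but cheaper: after the all-noncritical baseline,
#' each unknown gene alone is probed as critical and the resulting distance
#' recorded (`Dist[i]`). Unknowns are grouped by equal probe distance; a
#' smaller probe distance signals a higher likelihood of being critical, so
#' groups are climbed in increasing order, each with holistic-style sweeps
#' restricted to the group's still-noncritical genes until no flip improves,
#' before advancing to the next group. Constructor calls are the n probes
#' plus O(sum of squared group sizes).
#'
#' @inheritParams infer_holistic
#' @return a `sinec_inference`; additionally carries `dist_table` (the probe
#'   distances) and `groups` (the probe-distance grouping).
#' @export
infer_prioritized <- function(reference, constraints, ranking = c("topsog", "sloan")) {
  ranking <- match.arg(ranking)
  state <- new_run_state(reference, constraints, ranking)
  values <- ifelse(state$cv == -1L, 0L, state$cv)
  best <- state$construct1(values)
  trace <- empty_trace()
  unknown <- state$unknown
  # nothing to probe when there are no unknowns, and nothing can improve a
  # baseline that already matches the reference exactly
  if (length(unknown) == 0 || best$distance == 0) {
    return(finish_result(
      reference, best, trace, state, "prioritized", ranking,
      dist_table = tibble::tibble(gene = character(0), dist = integer(0)),
      groups = list()
    ))
  }
  probe <- vapply(unknown, function(g) {
    v <- values
    v[g] <- 1L
    state$construct1(v)$distance
  }, numeric(1))
  dist_table <- tibble::tibble(gene = reference$genes[unknown], dist = as.integer(probe))
  levels_sorted <- sort(unique(probe))
  groups <- lapply(levels_sorted, function(d) reference$genes[unknown[probe == d]])
  names(groups) <- as.character(levels_sorted)
  for (grp in groups) {
    candidates <- match(grp, reference$genes)
    repeat {
      candidates <- candidates[best$values[candidates] == 0L]
      if (length(candidates) == 0 || best$distance == 0) break
      sweep <- lapply(candidates, function(g) {
        v <- best$values
        v[g] <- 1L
        state$construct1(v)
      })
      dists <- vapply(sweep, `[[`, numeric(1), "distance")
      m <- which.min(dists)
      if (dists[m] < best$distance) {
        best <- sweep[[m]]
        trace <- dplyr::bind_rows(trace, tibble::tibble(
          gene = reference$genes[candidates[m]],
          distance = as.integer(dists[m])
        ))
        candidates <- candidates[-m]
      } else {
        break
      }
    }
    if (best$distance == 0) break
  }
  finish_result(reference, best, trace, state, "prioritized", ranking,
    dist_table = dist_table, groups = groups
  )
}

#' Exhaustive resolution of unknown constraints
#'
#' Enumerates every assignment of critical/noncritical to the n unknown
#' genes (2^n constructor calls exactly) and returns the completion whose
#' constructed network is closest to the reference. Ties prefer assignments
#' with fewer critical genes, then the lexicographically smallest assignment
#' bit-vector in stable gene order. The gold standard the hill climbers are
#' measured against; impractical beyond small n.
#'
#' @inheritParams infer_holistic
#' @param max_n refuse to enumerate more than `2^max_n` completions
#'   (default 20); raise explicitly for larger runs.
#' @return a `sinec_inference`.
#' @export
infer_exhaustive <- function(reference, constraints, ranking = c("topsog", "sloan"),
                             max_n = 20L) {
  ranking <- match.arg(ranking)
  state <- new_run_state(reference, constraints, ranking)
  unknown <- state$unknown
  n <- length(unknown)
  if (n > max_n) {
    stop(
      "refusing to enumerate 2^", n, " completions; raise `max_n` explicitly ",
      "if you really want this", call. = FALSE
    )
  }
  base_values <- ifelse(state$cv == -1L, 0L, state$cv)
  best <- NULL
  best_key <- NULL
  for (idx in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(idx)[seq_len(max(n, 1))])[seq_len(n)]
    v <- base_values
    v[unknown] <- bits
    res <- state$construct1(v)
    # tie-break key: distance, then #criticals, then lexicographic bits
    key <- c(res$distance, sum(bits), bits)
    if (is.null(best) || key_less(key, best_key)) {
      best <- res
      best_key <- key
    }
  }
  finish_result(reference, best, empty_trace(), state, "exhaustive", ranking)
}

# lexicographic comparison of equal-length numeric keys
key_less <- function(a, b) {
  d <- a - b
  nz <- which(d != 0)
  length(nz) > 0 && d[nz[1]] < 0
}

#' Run an optimizer by name
#'
#' @param reference a `gene_network`.
#' @param constraints constraint tibble; -1 marks unknowns.
#' @param method `"prioritized"` (default), `"holistic"` or `"exhaustive"`.
#' @param ranking `"topsog"` or `"sloan"`.
#' @param ... passed to the method (e.g. `max_n` for `"exhaustive"`).
#' @return a `sinec_inference`.
#' @export
infer_network <- function(reference, constraints,
                          method = c("prioritized", "holistic", "exhaustive"),
                          ranking = c("topsog", "sloan"), ...) {
  method <- match.arg(method)
  ranking <- match.arg(ranking)
  switch(method,
    holistic = infer_holistic(reference, constraints, ranking),
    prioritized = infer_prioritized(reference, constraints, ranking),
    exhaustive = infer_exhaustive(reference, constraints, ranking, ...)
  )
}

# ---- methods ---------------------------------------------------------------

#' @export
print.sinec_inference <- function(x, ...) {
  cat(
    "<sinec_inference> method = ", x$method, " (", x$ranking, " ranking)\n",
    "  distance to reference: ", x$distance_to_reference, "\n",
    "  constructor calls:     ", x$constructor_calls, "\n",
    "  genes set critical:    ", nrow(x$trace), "\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy an inference result
#'
#' `tidy()` returns the accepted-flip trace (one row per unknown gene fixed
#' critical, with the distance after accepting it); `glance()` returns a
#' one-row summary.
#'
#' @param x a `sinec_inference`.
#' @param ... unused.
#' @return a tibble.
#' @method tidy sinec_inference
#' @export
tidy.sinec_inference <- function(x, ...) {
  x$trace
}

#' @rdname tidy.sinec_inference
#' @method glance sinec_inference
#' @export
glance.sinec_inference <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    ranking = x$ranking,
    distance = x$distance_to_reference,
    constructor_calls = x$constructor_calls,
    n_unknown = x$n_unknown,
    flips_accepted = nrow(x$trace)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
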