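# Evaluation: edge-level F-score against the true topology, and the sweep
# driver that replays the benchmark grid through the optimizers.

#' Edge-level precision, recall and F-score
#'
#' Compares the directed edge sets of an inferred and a true network on the
#' same genes: TP are edges in both, FP inferred-only, FN truth-only;
#' precision = TP/(TP+FP), recall = TP/(TP+FN), F-score their harmonic mean.
#' Ratios with a zero denominator — and hence the F-score when TP = 0 — are
#' defined as 0.
#'
#' @param inferred,truth `gene_network`s on the same gene set.
#' @return a one-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f_score`.
#' @export
f_score <- function(inferred, truth) {
  stopifnot(inherits(inferred, "gene_network"), inherits(truth, "gene_network"))
  if (!setequal(inferred$genes, truth$genes)) {
    stop("networks are not built on the same gene set", call. = FALSE)
  }
  ki <- paste(inferred$genes[inferred$edges[, 1]], inferred$genes[inferred$edges[, 2]], sep = "\r")
  kt <- paste(truth$genes[truth$edges[, 1]], truth$genes[truth$edges[, 2]], sep = "\r")
  tp <- length(intersect(ki, kt))
  fp <- length(setdiff(ki, kt))
  fn <- length(setdiff(kt, ki))
  safe <- function(num, den) if (den == 0) 0 else num / den
  precision <- safe(tp, tp + fp)
  recall <- safe(tp, tp + fn)
  tibble::tibble(
    tp = tp, fp = fp, fn = fn,
    precision = precision, recall = recall,
    f_score = safe(2 * precision * recall, precision + recall)
  )
}

#' Run the inference sweep over a benchmark
#'
#' For every reference network in the manifest and every requested
#' method/ranking combination, resolves the masked constraints against the
#' reference and records the distance to the reference, the F-score against
#' the true target, and the constructor-call count. Per-item failures are
#' recorded (warning + NA row) and the sweep continues.
#'
#' @param manifest a manifest list from [make_benchmark()], or the path to a
#'   `manifest.json`.
#' @param dir directory holding the benchmark files (defaults to the
#'   manifest's directory when `manifest` is a path).
#' @param methods subset of `c("prioritized", "holistic", "exhaustive")`.
#' @param rankings subset of `c("topsog", "sloan")`.
#' @return a tibble of class `sinec_sweep`, one row per run: `target`,
#'   `size`, `rate`, `n_unknown`, `method`, `ranking`, `distance`,
#'   `f_score`, `constructor_calls`.
#' @export
run_sweep <- function(manifest, dir = NULL,
                      methods = "prioritized",
                      rankings = "topsog") {
  if (is.character(manifest)) {
    dir <- dir %||% dirname(manifest)
    manifest <- jsonlite::read_json(manifest)
  }
  stopifnot(!is.null(dir))
  methods <- match.arg(methods, c("prioritized", "holistic", "exhaustive"), several.ok = TRUE)
  rankings <- match.arg(rankings, c("topsog", "sloan"), several.ok = TRUE)
  rows <- list()
  for (tg in manifest$targets) {
    target_net <- read_network_tsv(file.path(dir, tg$path))
    cons <- suppressWarnings(
      read_constraints_tsv(file.path(dir, tg$constraints_path), target_net)
    )
    for (ref_info in tg$references) {
      reference <- read_network_tsv(file.path(dir, ref_info$path))
      for (method in methods) {
        for (ranking in rankings) {
          res <- tryCatch(
            infer_network(reference, cons, method = method, ranking = ranking),
            error = function(e) {
              warning(
                "sweep item failed (", tg$id, ", rate ", ref_info$rate, ", ",
                method, "/", ranking, "): ", conditionMessage(e),
                call. = FALSE
              )
              NULL
            }
          )
          rows[[length(rows) + 1]] <- tibble::tibble(
            target = tg$id,
            size = tg$size,
            rate = ref_info$rate,
            n_unknown = tg$n_unknown,
            method = method,
            ranking = ranking,
            distance = if (is.null(res)) NA_integer_ else res$distance_to_reference,
            f_score = if (is.null(res)) NA_real_ else f_score(res$network, target_net)$f_score,
            constructor_calls = if (is.null(res)) NA_integer_ else res$constructor_calls
          )
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sinec_sweep", class(out))
  out
}

#' Average sweep records per parameter cell
#'
#' Arithmetic means over the replicate targets in each
#' size/rate/n_unknown/method/ranking cell.
#'
#' @param records a sweep tibble from [run_sweep()].
#' @return a tibble with the cell means of distance, F-score and constructor
#'   calls, plus `n_runs`.
#' @export
summarize_sweep <- function(records) {
  records |>
    dplyr::group_by(
      .data$size, .data$rate, .data$n_unknown, .data$method, .data$ranking
    ) |>
    dplyr::summarize(
      mean_distance = mean(.data$distance, na.rm = TRUE),
      mean_f_score = mean(.data$f_score, na.rm = TRUE),
      mean_constructor_calls = mean(.data$constructor_calls, na.rm = TRUE),
      n_runs = dplyr::n(),
      .groups = "drop"
    )
}

#' Plot a sweep
#'
#' Mean distance to the reference against mutation rate, one line per
#' method/ranking combination, faceted by network size.
#'
#' @param object a `sinec_sweep` tibble from [run_sweep()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot sinec_sweep
#' @export
autoplot.sinec_sweep <- function(object, ...) {
  cells <- summarize_sweep(object)
  ggplot2::ggplot(
    cells,
    ggplot2::aes(
      x = .data$rate, y = .data$mean_distance,
      colour = interaction(.data$method, .data$ranking, sep = " / "),
      group = interaction(.data$method, .data$ranking)
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$size), labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = "mutation rate (fraction of edges rewired)",
      y = "mean distance to reference",
      colour = "method / ranking"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an inference trace
#'
#' Distance to the reference after each accepted critical-gene flip.
#'
#' @param object a `sinec_inference`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot sinec_inference
#' @export
autoplot.sinec_inference <- function(object, ...) {
  tr <- object$trace
  tr$step <- seq_len(nrow(tr))
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$step, y = .data$distance)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "accepted flip",
      y = "distance to reference",
      title = paste0(object$method, " optimization (", object$ranking, " ranking)")
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
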