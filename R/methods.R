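#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a study result
#'
#' A `lomax_study` is already a long tibble; `tidy()` strips the class and
#' attributes so the result composes with arbitrary dplyr pipelines.
#'
#' @param x a `lomax_study` (from [run_study()] or
#'   [expected_performance()]).
#' @param ... unused.
#' @return A plain tibble.
#' @export
tidy.lomax_study <- function(x, ...) {
  out <- x
  attr(out, "config") <- NULL
  attr(out, "study_type") <- NULL
  class(out) <- class(tibble::tibble())
  out
}

#' One-row summary of a study result
#'
#' @param x a `lomax_study`.
#' @param ... unused.
#' @return A one-row tibble: evaluation type, grid dimensions, replicates,
#'   seed, and the estimator attaining the smallest MASE summed over the
#'   grid, with that total.
#' @export
glance.lomax_study <- function(x, ...) {
  cfg <- attr(x, "config")
  totals <- x |>
    dplyr::group_by(label) |>
    dplyr::summarise(total_mase = sum(mase), .groups = "drop") |>
    dplyr::arrange(total_mase)
  tibble::tibble(
    type = attr(x, "study_type"),
    n_cells = dplyr::n_distinct(paste(x$beta, x$n)),
    n_estimators = dplyr::n_distinct(x$label),
    reps = cfg$reps,
    seed = cfg$seed,
    best_estimator = totals$label[1],
    best_total_mase = totals$total_mase[1]
  )
}

#' Plot estimator accuracy across the study grid
#'
#' MASE against sample size, one line per estimator column, faceted by the
#' true shape. Log scale on the y axis keeps the (roughly \eqn{1/n}) decay
#' legible.
#'
#' @param object a `lomax_study`.
#' @param metric `"mase"` (default) or `"ae"`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.lomax_study <- function(object, metric = c("mase", "ae"), ...) {
  metric <- match.arg(metric)
  dat <- tidy(object)
  p <- ggplot2::ggplot(
    dat,
    ggplot2::aes(x = n, y = .data[[metric]],
                 colour = label, linetype = method)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~beta, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "sample size n",
                  y = toupper(metric),
                  colour = "estimator", linetype = "method") +
    ggplot2::theme_minimal()
  if (metric == "mase") p <- p + ggplot2::scale_y_log10()
  if (metric == "ae") {
    p <- p + ggplot2::geom_hline(
      data = dplyr::distinct(dat, beta),
      mapping = ggplot2::aes(yintercept = beta),
      linetype = "dotted", colour = "grey40"
    )
  }
  p
}

#' @export
print.lomax_study <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("# Lomax shape estimation study (%s), %d cells x %d estimators\n",
              attr(x, "study_type"),
              dplyr::n_distinct(paste(x$beta, x$n)),
              dplyr::n_distinct(x$label)))
  if (!is.null(cfg) && attr(x, "study_type") == "monte-carlo") {
    cat(sprintf("# reps = %d, seed = %d\n", cfg$reps, cfg$seed))
  }
  NextMethod()
}
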