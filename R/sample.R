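#' Simulate Lomax lifetime samples
#'
#' Draws `reps` independent samples of `n_obs` lifetimes each from the Lomax
#' distribution, by inversion (see [rlomax()]), and returns them as a tidy
#' tibble with one row per lifetime.
#'
#' @param n_obs number of lifetimes per sample.
#' @param shape true shape parameter \eqn{\beta}.
#' @param scale known scale parameter \eqn{\sigma} (default 3).
#' @param reps number of replicate samples (default 1).
#'
#' @return A tibble with columns `replicate` (integer) and `lifetime`
#'   (nonnegative double), `reps * n_obs` rows.
#'
#' @examples
#' set.seed(1)
#' sim <- simulate_lifetimes(25, shape = 1, scale = 3)
#' summarise_lifetimes(sim, scale = 3)
#' @export
simulate_lifetimes <- function(n_obs, shape, scale = 3, reps = 1) {
  stopifnot(n_obs >= 1, reps >= 1)
  tibble::tibble(
    replicate = rep(seq_len(reps), each = n_obs),
    lifetime = rlomax(n_obs * reps, shape, scale)
  )
}

#' Sufficient statistic of a Lomax sample with known scale
#'
#' With \eqn{\sigma} known, the log-likelihood of the shape depends on the
#' data only through \eqn{\gamma = \sum_i \log(1 + x_i/\sigma)}. Under the
#' model, \eqn{\gamma} is Gamma-distributed with shape `n` and rate
#' \eqn{\beta}, which makes every estimator in this package a function of
#' \eqn{(n, \gamma)} alone.
#'
#' @param x numeric vector of nonnegative lifetimes.
#' @param scale known scale parameter \eqn{\sigma > 0}.
#'
#' @return The scalar \eqn{\gamma \ge 0} (0 iff all lifetimes are 0).
#' @examples
#' lomax_suffstat(c(9, 9), scale = 3)  # 2 * log(4)
#' @export
lomax_suffstat <- function(x, scale) {
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0) {
    stop("`scale` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop("lifetimes must be finite and nonnegative", call. = FALSE)
  }
  sum(log1p(x / scale))
}

#' Summarise a lifetime sample for shape estimation
#'
#' Reduces a tidy table of lifetimes to the summaries every estimator needs:
#' the sample size `n`, the sufficient statistic `gamma_stat`
#' (see [lomax_suffstat()]) and the maximum likelihood estimate
#' \eqn{\hat\beta = n/\gamma}. Grouped by `replicate` if that column is
#' present, so the output of [simulate_lifetimes()] with `reps > 1`
#' summarises to one row per replicate.
#'
#' @param data a data frame with a `lifetime` column (override with the
#'   `lifetime` argument) and optionally a `replicate` column.
#' @param scale known scale parameter \eqn{\sigma}.
#' @param lifetime tidy-selected column holding the lifetimes.
#'
#' @return A tibble with columns `n`, `gamma_stat` and `mle`
#'   (plus `replicate` when grouping applies).
#' @export
summarise_lifetimes <- function(data, scale, lifetime = lifetime) {
  x <- dplyr::pull(data, {{ lifetime }})
  if ("replicate" %in% names(data)) {
    data |>
      dplyr::group_by(replicate) |>
      dplyr::summarise(
        n = dplyr::n(),
        gamma_stat = lomax_suffstat({{ lifetime }}, scale),
        .groups = "drop"
      ) |>
      dplyr::mutate(mle = mle_shape(n, gamma_stat))
  } else {
    tibble::tibble(
      n = length(x),
      gamma_stat = lomax_suffstat(x, scale),
      mle = mle_shape(length(x), lomax_suffstat(x, scale))
    )
  }
}

#' Maximum likelihood estimate of the Lomax shape
#'
#' The unique root of the score equation with known scale: \eqn{n/\gamma}.
#'
#' @param n sample size(s).
#' @param gamma_stat sufficient statistic(s) \eqn{\gamma > 0}.
#'
#' @return Numeric vector of MLEs.
#' @examples
#' mle_shape(25, 25)
#' @export
mle_shape <- function(n, gamma_stat) {
  stopifnot(n >= 1)
  if (any(gamma_stat <= 0)) {
    stop("degenerate sample: gamma_stat must be positive (all-zero lifetimes carry no information on the shape)",
         call. = FALSE)
  }
  n / gamma_stat
}

#' Read and write lifetime samples as plain text
#'
#' One nonnegative lifetime per line; lines starting with `#` are comments.
#'
#' @param path file path.
#' @param data a data frame with a `lifetime` column.
#'
#' @return `read_lifetimes()` returns a tibble with a `lifetime` column;
#'   `write_lifetimes()` returns `data` invisibly.
#' @export
read_lifetimes <- function(path) {
  out <- readr::read_table(path, col_names = "lifetime",
                           col_types = readr::cols(lifetime = readr::col_double()),
                           comment = "#")
  if (any(out$lifetime < 0)) stop("negative lifetime in ", path, call. = FALSE)
  out
}

#' @rdname read_lifetimes
#' @export
write_lifetimes <- function(data, path) {
  readr::write_lines(format(data$lifetime, trim = TRUE, digits = 15), path)
  invisible(data)
}
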