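#' The Lomax (Pareto type II) distribution
#'
#' Density, distribution function, quantile function, random generation and
#' reliability (survival) function for the Lomax distribution with shape
#' `shape` (\eqn{\beta > 0}) and scale `scale` (\eqn{\sigma > 0}):
#' \deqn{f(x) = (\beta/\sigma)\,(1 + x/\sigma)^{-(\beta + 1)}, \quad x \ge 0.}
#'
#' `rlomax()` draws by inversion of the distribution function,
#' \eqn{x = \sigma[(1 - u)^{-1/\beta} - 1]} with \eqn{u} uniform on (0, 1)
#' (R's uniform generator never returns the endpoints, so the draw is always
#' finite). The heavy upper tail means moments of order \eqn{\ge \beta} do
#' not exist.
#'
#' @param x,q vector of quantiles (values below 0 have zero density and zero
#'   probability mass below them).
#' @param p vector of probabilities in `[0, 1)`.
#' @param n number of draws.
#' @param shape shape parameter \eqn{\beta}, positive.
#' @param scale scale parameter \eqn{\sigma}, positive, in the units of the
#'   data.
#' @param log,log.p logical; if `TRUE`, probabilities/densities are returned
#'   on the log scale.
#' @param lower.tail logical; if `TRUE` (default), probabilities are
#'   \eqn{P(X \le x)}, otherwise the survival probability \eqn{P(X > x)}.
#'
#' @return A numeric vector: densities for `dlomax()`, probabilities for
#'   `plomax()` and `lomax_reliability()`, quantiles for `qlomax()`, draws
#'   for `rlomax()`.
#'
#' @examples
#' dlomax(0, shape = 2, scale = 3)        # beta / sigma = 2/3
#' plomax(9, shape = 1, scale = 3)        # 0.75
#' lomax_reliability(9, shape = 1, scale = 3)
#' x <- rlomax(100, shape = 1.5, scale = 3)
#' @name lomax
NULL

check_lomax_params <- function(shape, scale) {
  if (!is.numeric(shape) || any(!is.finite(shape)) || any(shape <= 0)) {
    stop("`shape` must be a positive finite numeric", call. = FALSE)
  }
  if (!is.numeric(scale) || any(!is.finite(scale)) || any(scale <= 0)) {
    stop("`scale` must be a positive finite numeric", call. = FALSE)
  }
  invisible(NULL)
}

#' @rdname lomax
#' @export
dlomax <- function(x, shape, scale, log = FALSE) {
  check_lomax_params(shape, scale)
  ld <- log(shape) - log(scale) - (shape + 1) * log1p(x / scale)
  ld[x < 0] <- -Inf
  if (log) ld else exp(ld)
}

#' @rdname lomax
#' @export
plomax <- function(q, shape, scale, lower.tail = TRUE, log.p = FALSE) {
  check_lomax_params(shape, scale)
  q <- pmax(q, 0)
  lsurv <- -shape * log1p(q / scale)
  if (lower.tail) {
    p <- -expm1(lsurv)
    if (log.p) log(p) else p
  } else {
    if (log.p) lsurv else exp(lsurv)
  }
}

#' @rdname lomax
#' @export
qlomax <- function(p, shape, scale) {
  check_lomax_params(shape, scale)
  if (any(p < 0 | p >= 1)) stop("`p` must lie in [0, 1)", call. = FALSE)
  scale * expm1(-log1p(-p) / shape)
}

#' @rdname lomax
#' @export
rlomax <- function(n, shape, scale) {
  check_lomax_params(shape, scale)
  u <- stats::runif(n)
  scale * ((1 - u)^(-1 / shape) - 1)
}

#' @rdname lomax
#' @param t vector of nonnegative mission times.
#' @export
lomax_reliability <- function(t, shape, scale) {
  if (any(t < 0)) stop("`t` must be nonnegative", call. = FALSE)
  plomax(t, shape, scale, lower.tail = FALSE)
}
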