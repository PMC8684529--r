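#' Conjugate gamma prior for the Lomax shape
#'
#' A Gamma(`shape`, rate = `rate`) prior on \eqn{\beta} is conjugate to the
#' Lomax likelihood with known scale. The prior density is decreasing in
#' \eqn{\beta} iff `shape < 1`; that restriction matters only when the prior
#' feeds the E-Bayesian hyperprior construction, so it is recorded but not
#' enforced here.
#'
#' @param shape prior shape \eqn{z > 0} (default 0.6).
#' @param rate prior rate \eqn{k > 0} (default 0.5).
#'
#' @return An object of class `"gamma_prior"` with fields `shape`, `rate`
#'   and `decreasing` (`TRUE` iff `shape < 1`).
#' @examples
#' gamma_prior(0.6, 0.5)
#' @export
gamma_prior <- function(shape = 0.6, rate = 0.5) {
  stopifnot(shape > 0, rate > 0)
  structure(list(shape = shape, rate = rate, decreasing = shape < 1),
            class = "gamma_prior")
}

#' @export
print.gamma_prior <- function(x, ...) {
  cat(sprintf("<gamma_prior> Gamma(shape = %g, rate = %g)%s\n",
              x$shape, x$rate,
              if (x$decreasing) " [decreasing density]" else ""))
  invisible(x)
}

#' Gamma posterior of the Lomax shape
#'
#' Conjugate update: a Gamma(\eqn{z, k}) prior combined with a sample of
#' size `n` and sufficient statistic \eqn{\gamma} yields the posterior
#' Gamma(\eqn{n + z}, rate \eqn{\gamma + k}). An empty sample (`n = 0`,
#' `gamma_stat = 0`) returns the prior.
#'
#' @param n sample size (nonnegative integer).
#' @param gamma_stat sufficient statistic \eqn{\gamma \ge 0}
#'   (see [lomax_suffstat()]).
#' @param prior a [gamma_prior()].
#'
#' @return An object of class `"posterior_gamma"` with fields `shape` and
#'   `rate`.
#' @examples
#' posterior_gamma(25, 25, gamma_prior(0.6, 0.5))  # Gamma(25.6, 25.5)
#' @export
posterior_gamma <- function(n, gamma_stat, prior = gamma_prior()) {
  stopifnot(inherits(prior, "gamma_prior"), n >= 0, gamma_stat >= 0)
  if (gamma_stat + prior$rate <= 0) stop("improper posterior", call. = FALSE)
  structure(list(shape = n + prior$shape, rate = gamma_stat + prior$rate),
            class = "posterior_gamma")
}

#' @export
print.posterior_gamma <- function(x, ...) {
  cat(sprintf("<posterior_gamma> Gamma(shape = %g, rate = %g), mean %.6g\n",
              x$shape, x$rate, x$shape / x$rate))
  invisible(x)
}

#' Closed-form Bayes estimators of the Lomax shape
#'
#' Posterior-risk minimisers under the six supported losses, for a gamma
#' posterior with parameters `shape` (\eqn{s}) and `rate` (\eqn{r}).
#' All are vectorised over `shape`/`rate`:
#'
#' * `bayes_self()` — posterior mean \eqn{s/r};
#' * `bayes_linex()` — \eqn{(s/c)\log(1 + c/r)}, needs \eqn{r + c > 0};
#' * `bayes_asym()` — \eqn{\sqrt{(s-1)s}/r}, needs \eqn{s > 1};
#' * `bayes_entropy()` — \eqn{(s-1)/r}, needs \eqn{s > 1};
#' * `bayes_cllf()` — \eqn{(s/2c)\log\{(r+c)/(r-c)\}}, needs \eqn{r > c};
#' * `bayes_wcllf()` — \eqn{(s/2c)\log\{(r+\omega+c)/(r+\omega-c)\}},
#'   needs \eqn{r + \omega > c}; reduces to `bayes_cllf()` at
#'   \eqn{\omega = 0}.
#'
#' The domain guards raise errors rather than clamping: at the sample sizes
#' this package targets the inequalities hold with overwhelming probability,
#' and silent clamping would bias a simulation study.
#'
#' @param shape,rate posterior gamma parameters, or a
#'   [posterior_gamma()] object in `shape` (then `rate` is taken from it).
#' @param c loss constant (nonzero for LINEX, positive for the composite
#'   families).
#' @param omega weight decay \eqn{\omega \ge 0} of the weighted composite
#'   LINEX loss.
#'
#' @return Numeric vector of estimates.
#' @examples
#' post <- posterior_gamma(25, 25, gamma_prior(0.6, 0.5))
#' bayes_self(post)
#' bayes_wcllf(post, c = 0.5, omega = 0.5)
#' @name bayes_estimators
NULL

unpack_posterior <- function(shape, rate) {
  if (inherits(shape, "posterior_gamma")) {
    list(s = shape$shape, r = shape$rate)
  } else {
    stopifnot(is.numeric(shape), is.numeric(rate))
    list(s = shape, r = rate)
  }
}

#' @rdname bayes_estimators
#' @export
bayes_self <- function(shape, rate = NULL) {
  p <- unpack_posterior(shape, rate)
  p$s / p$r
}

#' @rdname bayes_estimators
#' @export
bayes_linex <- function(shape, rate = NULL, c) {
  p <- unpack_posterior(shape, rate)
  if (c == 0) stop("LINEX requires c != 0", call. = FALSE)
  if (any(p$r + c <= 0)) {
    stop("LINEX estimator undefined: need posterior rate + c > 0", call. = FALSE)
  }
  (p$s / c) * log1p(c / p$r)
}

#' @rdname bayes_estimators
#' @export
bayes_asym <- function(shape, rate = NULL) {
  p <- unpack_posterior(shape, rate)
  if (any(p$s <= 1)) {
    stop("asymmetric-loss estimator needs posterior shape > 1", call. = FALSE)
  }
  sqrt((p$s - 1) * p$s) / p$r
}

#' @rdname bayes_estimators
#' @export
bayes_entropy <- function(shape, rate = NULL) {
  p <- unpack_posterior(shape, rate)
  if (any(p$s <= 1)) {
    stop("entropy-loss estimator needs posterior shape > 1", call. = FALSE)
  }
  (p$s - 1) / p$r
}

#' @rdname bayes_estimators
#' @export
bayes_cllf <- function(shape, rate = NULL, c) {
  p <- unpack_posterior(shape, rate)
  if (c <= 0) stop("composite LINEX requires c > 0", call. = FALSE)
  if (any(p$r <= c)) {
    stop("composite LINEX estimator undefined: need posterior rate (gamma + k) > c",
         call. = FALSE)
  }
  (p$s / (2 * c)) * log((p$r + c) / (p$r - c))
}

#' @rdname bayes_estimators
#' @export
bayes_wcllf <- function(shape, rate = NULL, c, omega = 0) {
  p <- unpack_posterior(shape, rate)
  if (c <= 0) stop("weighted composite LINEX requires c > 0", call. = FALSE)
  if (omega < 0) stop("`omega` must be nonnegative", call. = FALSE)
  if (any(p$r + omega <= c)) {
    stop("weighted composite LINEX estimator undefined: need rate + omega > c",
         call. = FALSE)
  }
  (p$s / (2 * c)) * log((p$r + omega + c) / (p$r + omega - c))
}

#' Bayes estimate under an arbitrary loss specification
#'
#' Dispatches a [loss_spec()] to the matching closed form in
#' [bayes_estimators].
#'
#' @param posterior a [posterior_gamma()].
#' @param spec a [loss_spec()].
#' @return Scalar estimate.
#' @export
bayes_shape <- function(posterior, spec) {
  stopifnot(inherits(spec, "loss_spec"))
  switch(spec$family,
    self = bayes_self(posterior),
    linex = bayes_linex(posterior, c = spec$c),
    asymmetric = bayes_asym(posterior),
    entropy = bayes_entropy(posterior),
    cllf = bayes_cllf(posterior, c = spec$c),
    wcllf = bayes_wcllf(posterior, c = spec$c, omega = spec$omega)
  )
}
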