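#' Specify a loss function for shape estimation
#'
#' The package supports six loss families for an estimate \eqn{\hat\beta} of
#' the shape \eqn{\beta}, writing \eqn{\Delta = \hat\beta - \beta}:
#'
#' * `"self"` — squared error, \eqn{\Delta^2};
#' * `"linex"` — LINEX, \eqn{e^{c\Delta} - c\Delta - 1}, `c != 0`;
#' * `"asymmetric"` — precautionary ratio loss,
#'   \eqn{\beta/\hat\beta + \hat\beta/\beta - 2};
#' * `"entropy"` — \eqn{\hat\beta/\beta - \log(\hat\beta/\beta) - 1};
#' * `"cllf"` — composite LINEX, the sum of LINEX losses at \eqn{+c} and
#'   \eqn{-c}: \eqn{e^{-c\Delta} + e^{c\Delta} - 2}, `c > 0`;
#' * `"wcllf"` — weighted composite LINEX,
#'   \eqn{e^{-\omega\beta}(e^{-c\Delta} + e^{c\Delta} - 2)}, `c > 0`,
#'   `omega >= 0`; the weight discounts errors made at large true shapes,
#'   and `omega = 0` recovers `"cllf"` exactly.
#'
#' @param family one of `"self"`, `"linex"`, `"asymmetric"`, `"entropy"`,
#'   `"cllf"`, `"wcllf"` (the acronyms SELF, LLF, ASLF, ENLF, CLLF, WCLLF
#'   are also accepted).
#' @param c loss asymmetry constant; required nonzero for `"linex"`,
#'   positive for `"cllf"` and `"wcllf"`, ignored otherwise.
#' @param omega weight decay \eqn{\omega \ge 0}; `"wcllf"` only.
#'
#' @return An object of class `"loss_spec"`.
#' @examples
#' loss_spec("wcllf", c = 0.5, omega = 0.5)
#' @export
loss_spec <- function(family, c = NULL, omega = NULL) {
  aliases <- c(self = "self", llf = "linex", linex = "linex",
               aslf = "asymmetric", asymmetric = "asymmetric",
               enlf = "entropy", entropy = "entropy",
               cllf = "cllf", wcllf = "wcllf")
  key <- aliases[tolower(family)]
  if (is.na(key)) {
    stop("unknown loss family: ", family, call. = FALSE)
  }
  family <- unname(key)
  if (family == "linex") {
    if (is.null(c) || c == 0) stop("LINEX loss requires c != 0", call. = FALSE)
  }
  if (family %in% c("cllf", "wcllf")) {
    if (is.null(c) || c <= 0) {
      stop("composite LINEX losses require c > 0", call. = FALSE)
    }
  }
  if (family == "wcllf") {
    if (is.null(omega)) omega <- 0
    if (omega < 0) stop("`omega` must be nonnegative", call. = FALSE)
  } else {
    omega <- NULL
  }
  if (!family %in% c("linex", "cllf", "wcllf")) c <- NULL
  structure(list(family = family, c = c, omega = omega), class = "loss_spec")
}

#' @export
print.loss_spec <- function(x, ...) {
  cat("<loss_spec>", x$family,
      if (!is.null(x$c)) paste0("c = ", x$c),
      if (!is.null(x$omega)) paste0("omega = ", x$omega), "\n")
  invisible(x)
}

#' Evaluate a loss function
#'
#' Vectorised over `estimate` and `parameter`. Every family is nonnegative
#' and zero exactly when `estimate == parameter`.
#'
#' @param spec a [loss_spec()].
#' @param estimate candidate estimate(s) \eqn{\hat\beta}; must be positive
#'   for the ratio-based families.
#' @param parameter true/parameter value(s) \eqn{\beta > 0}.
#'
#' @return Numeric vector of losses.
#' @examples
#' loss_value(loss_spec("cllf", c = 0.5), estimate = 2, parameter = 1)
#' @export
loss_value <- function(spec, estimate, parameter) {
  stopifnot(inherits(spec, "loss_spec"))
  if (any(parameter <= 0)) stop("`parameter` must be positive", call. = FALSE)
  delta <- estimate - parameter
  switch(spec$family,
    self = delta^2,
    linex = exp(spec$c * delta) - spec$c * delta - 1,
    asymmetric = {
      if (any(estimate <= 0)) stop("`estimate` must be positive for the asymmetric loss", call. = FALSE)
      parameter / estimate + estimate / parameter - 2
    },
    entropy = {
      if (any(estimate <= 0)) stop("`estimate` must be positive for the entropy loss", call. = FALSE)
      r <- estimate / parameter
      r - log(r) - 1
    },
    cllf = exp(-spec$c * delta) + exp(spec$c * delta) - 2,
    wcllf = exp(-spec$omega * parameter) *
      (exp(-spec$c * delta) + exp(spec$c * delta) - 2)
  )
}

# Exponential tilt introduced by the loss: the posterior-risk integrand
# contains exp(-beta * (rate + tilt)) terms; each tilt must keep rate + tilt
# positive for the integral to converge.
risk_tilts <- function(spec) {
  switch(spec$family,
    self = 0,
    asymmetric = 0,
    entropy = 0,
    linex = spec$c,
    cllf = c(-spec$c, spec$c),
    wcllf = c(spec$omega - spec$c, spec$omega + spec$c)
  )
}

check_risk_domain <- function(spec, posterior) {
  bad <- risk_tilts(spec) + posterior$rate <= 0
  if (any(bad)) {
    t <- risk_tilts(spec)[bad][1]
    stop(sprintf(
      "posterior risk diverges: need posterior rate > %g for the %s loss (rate = %g)",
      -t, spec$family, posterior$rate), call. = FALSE)
  }
  invisible(NULL)
}

#' Posterior expected loss of a candidate estimate
#'
#' Integrates the loss against a gamma posterior for the shape by adaptive
#' quadrature. This is the package's independent numerical oracle: no
#' closed-form estimator expression enters the computation.
#'
#' @param spec a [loss_spec()].
#' @param estimate candidate estimate \eqn{\hat\beta > 0} (scalar).
#' @param posterior a [posterior_gamma()] object (or any list with `shape`
#'   and `rate`).
#'
#' @return The scalar posterior risk.
#' @examples
#' post <- posterior_gamma(25, 25, gamma_prior(0.6, 0.5))
#' posterior_risk(loss_spec("self"), 1, post)  # variance + bias^2
#' @export
posterior_risk <- function(spec, estimate, posterior) {
  stopifnot(inherits(spec, "loss_spec"), length(estimate) == 1L, estimate > 0)
  check_risk_domain(spec, posterior)
  s <- posterior$shape
  r <- posterior$rate
  # integrate over the union of the posterior bulk and its tilted images;
  # the exponential tilts e^{+c beta} shift the effective mode to
  # shape / (rate + tilt)
  rates <- r + risk_tilts(spec)
  lo <- min(stats::qgamma(1e-13, s, rate = max(rates)))
  hi <- max(stats::qgamma(1e-13, s, rate = min(rates), lower.tail = FALSE))
  val <- stats::integrate(
    function(b) loss_value(spec, estimate, b) * stats::dgamma(b, s, rate = r),
    lower = lo, upper = hi,
    rel.tol = 1e-11, abs.tol = 1e-13, subdivisions = 500L
  )
  val$value
}

#' Numerically minimise the posterior risk
#'
#' Derivative-free scalar minimisation of [posterior_risk()] over the
#' bracket `(0, 10 * posterior mean]`. Used throughout the test suite as the
#' independent oracle against which every closed-form Bayes estimator is
#' checked; it never calls the closed forms itself.
#'
#' @inheritParams posterior_risk
#'
#' @return The risk-minimising estimate (scalar).
#' @examples
#' post <- posterior_gamma(25, 25, gamma_prior(0.6, 0.5))
#' argmin_risk(loss_spec("self"), post)  # = posterior mean
#' @export
argmin_risk <- function(spec, posterior) {
  check_risk_domain(spec, posterior)
  mean_post <- posterior$shape / posterior$rate
  opt <- stats::optimize(
    function(b) posterior_risk(spec, b, posterior),
    interval = c(mean_post * 1e-4, mean_post * 10),
    tol = mean_post * 1e-10
  )
  if (opt$minimum <= mean_post * 2e-4 || opt$minimum >= mean_post * 9.99) {
    stop("risk minimiser hit the bracket boundary at ", opt$minimum, call. = FALSE)
  }
  opt$minimum
}
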