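# Catalogue of the thirteen estimator columns of the simulation study, as
# vectorised functions of (gamma_stat, n). c-dependent families get one
# entry per value of c; all entries share the same sample, so a single gamma
# vector evaluates every column (common random numbers).
estimator_set <- function(prior = gamma_prior(), v = 1,
                          c_values = c(0.5, 1.5), omega = 0.5) {
  z <- prior$shape
  k <- prior$rate
  fixed <- tibble::tibble(
    method = c("mle", rep("bayes", 3), rep("ebayes", 3)),
    family = c("mle", "self", "asymmetric", "entropy",
               "self", "asymmetric", "entropy"),
    c = NA_real_,
    fn = list(
      function(g, n) mle_shape(n, g),
      function(g, n) bayes_self(n + z, g + k),
      function(g, n) bayes_asym(n + z, g + k),
      function(g, n) bayes_entropy(n + z, g + k),
      function(g, n) ebayes_self(n, g, v),
      function(g, n) ebayes_asym(n, g, v),
      function(g, n) ebayes_entropy(n, g, v)
    )
  )
  varying <- tidyr::expand_grid(
    method = c("bayes", "ebayes"),
    family = c("linex", "cllf", "wcllf"),
    c = c_values
  )
  varying$fn <- purrr::pmap(varying, function(method, family, c) {
    force(c)
    if (method == "bayes") {
      switch(family,
        linex = function(g, n) bayes_linex(n + z, g + k, c = c),
        cllf  = function(g, n) bayes_cllf(n + z, g + k, c = c),
        wcllf = function(g, n) bayes_wcllf(n + z, g + k, c = c, omega = omega)
      )
    } else {
      switch(family,
        linex = function(g, n) ebayes_linex(n, g, v, c = c),
        cllf  = function(g, n) ebayes_cllf(n, g, v, c = c),
        wcllf = function(g, n) ebayes_wcllf(n, g, v, c = c, omega = omega)
      )
    }
  })
  out <- dplyr::bind_rows(fixed, varying)
  out$omega <- ifelse(out$family == "wcllf", omega, NA_real_)
  out$label <- paste0(
    ifelse(out$method == "ebayes", "eb_", ifelse(out$method == "bayes", "b_", "")),
    out$family,
    ifelse(is.na(out$c), "", paste0("_c", out$c))
  )
  out[, c("label", "method", "family", "c", "omega", "fn")]
}

#' Estimate the Lomax shape by all thirteen estimators
#'
#' Computes, from one sample of lifetimes with known scale, the maximum
#' likelihood estimate and the Bayes and E-Bayesian estimates under the six
#' supported losses (the loss families with a constant `c` are evaluated at
#' every value supplied). All estimates are functions of the sample only
#' through the sufficient statistic \eqn{\gamma}.
#'
#' @param data a data frame with a `lifetime` column (see
#'   [simulate_lifetimes()], [read_lifetimes()]).
#' @param scale known scale parameter \eqn{\sigma > 0}.
#' @param prior a [gamma_prior()] for the Bayes columns.
#' @param v upper bound of the uniform hyperprior on the prior rate, for the
#'   E-Bayes columns.
#' @param c values of the LINEX/composite-LINEX constant to evaluate.
#' @param omega weight decay of the weighted composite LINEX loss.
#' @param lifetime tidy-selected column holding the lifetimes.
#'
#' @return A tibble with one row per estimator: `label`, `method`
#'   (`"mle"`, `"bayes"`, `"ebayes"`), `family`, `c`, `omega`, `estimate`,
#'   plus the sample summaries `n` and `gamma_stat`.
#'
#' @examples
#' set.seed(7)
#' simulate_lifetimes(25, shape = 1, scale = 3) |>
#'   estimate_shape(scale = 3)
#' @export
estimate_shape <- function(data, scale, prior = gamma_prior(), v = 1,
                           c = base::c(0.5, 1.5), omega = 0.5,
                           lifetime = lifetime) {
  x <- dplyr::pull(data, {{ lifetime }})
  n <- length(x)
  g <- lomax_suffstat(x, scale)
  set <- estimator_set(prior = prior, v = v, c_values = c, omega = omega)
  set |>
    dplyr::mutate(estimate = purrr::map_dbl(fn, function(f) f(g, n)),
                  n = n, gamma_stat = g) |>
    dplyr::select(-fn)
}
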