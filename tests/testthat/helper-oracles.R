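# Independent oracles used across the suite. None of these call the
# closed-form expressions they are used to check.

# Average a Bayes estimator over the uniform hyperprior z ~ U(0,1),
# k ~ U(0, v) by a 2-D Gauss-Legendre product rule. `bayes_fn(shape, rate)`
# is the closed-form Bayes estimator; the averaging itself is generic.
hyperprior_average <- function(bayes_fn, n, gamma_stat, v, order = 48) {
  glz <- pracma::gaussLegendre(order, 0, 1)
  glk <- pracma::gaussLegendre(order, 0, v)
  acc <- 0
  for (i in seq_len(order)) {
    acc <- acc + glz$w[i] * sum(glk$w * bayes_fn(n + glz$x[i], gamma_stat + glk$x))
  }
  acc / v  # joint density is 1/v on (0,1) x (0,v)
}

# random admissible posteriors for oracle-equivalence checks
random_posteriors <- function(n_draws, seed) {
  set.seed(seed)
  tibble::tibble(
    shape = runif(n_draws, 2, 60),
    c = runif(n_draws, 0.1, 1.5),
    omega = runif(n_draws, 0, 1)
  ) |>
    dplyr::mutate(rate = c + runif(n_draws, 1, 50))
}

paper_settings <- function(reps = 10000, seed = 1L) {
  study_config(n = c(25, 50, 75, 100), beta = c(1, 1.5, 2), sigma = 3,
               v = 1, c = c(0.5, 1.5), prior_shape = 0.6, prior_rate = 0.5,
               omega = 0.5, reps = reps, seed = seed)
}

study_cell <- function(study, beta, n, label, col) {
  row <- dplyr::filter(study, .data$beta == !!beta, .data$n == !!n,
                       .data$label == !!label)
  stopifnot(nrow(row) == 1L)
  row[[col]]
}
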