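test_that("E-Bayes closed forms reproduce the worked n = 25, gamma = 25, v = 1 example", {
  expect_equal(ebayes_self(25, 25, v = 1), 25.5 * log(26 / 25))
  expect_equal(ebayes_self(25, 25, v = 1), 1.0001282, tolerance = 1e-6)
  expect_equal(ebayes_entropy(25, 25, v = 1), 24.5 * log(26 / 25))
  expect_equal(ebayes_entropy(25, 25, v = 1), 0.9609075, tolerance = 1e-6)
  # the asymmetric-loss estimate is bracketed by the two closed forms above
  eb_as <- ebayes_asym(25, 25, v = 1)
  expect_gt(eb_as, ebayes_entropy(25, 25, v = 1))
  expect_lt(eb_as, ebayes_self(25, 25, v = 1))
})

test_that("every E-Bayes form equals the 2-D hyperprior quadrature of its Bayes counterpart", {
  set.seed(11)
  cases <- tibble::tibble(
    n = sample(c(5, 25, 60, 100), 12, replace = TRUE),
    gamma_stat = runif(12, 4, 90),
    v = runif(12, 0.3, 2),
    c = runif(12, 0.1, 1.5),
    omega = runif(12, 0, 1)
  )
  for (i in seq_len(nrow(cases))) {
    n <- cases$n[i]; g <- cases$gamma_stat[i]; v <- cases$v[i]
    cc <- min(cases$c[i], g - 0.5); om <- cases$omega[i]
    expect_equal(ebayes_self(n, g, v),
                 hyperprior_average(bayes_self, n, g, v), tolerance = 1e-8)
    expect_equal(ebayes_linex(n, g, v, c = cc),
                 hyperprior_average(function(s, r) bayes_linex(s, r, c = cc), n, g, v),
                 tolerance = 1e-8)
    expect_equal(ebayes_asym(n, g, v),
                 hyperprior_average(bayes_asym, n, g, v), tolerance = 1e-8)
    expect_equal(ebayes_entropy(n, g, v),
                 hyperprior_average(bayes_entropy, n, g, v), tolerance = 1e-8)
    expect_equal(ebayes_cllf(n, g, v, c = cc),
                 hyperprior_average(function(s, r) bayes_cllf(s, r, c = cc), n, g, v),
                 tolerance = 1e-8)
    expect_equal(ebayes_wcllf(n, g, v, c = cc, omega = om),
                 hyperprior_average(function(s, r) bayes_wcllf(s, r, c = cc, omega = om),
                                    n, g, v),
                 tolerance = 1e-8)
  }
})

test_that("E-Bayes LINEX also matches a Monte Carlo average over hyperprior draws", {
  set.seed(21)
  n <- 25; g <- 25; v <- 1; cc <- 0.5
  z <- runif(2e5); k <- runif(2e5, 0, v)
  draws <- bayes_linex(n + z, g + k, c = cc)
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(ebayes_linex(n, g, v, c = cc) - mean(draws)), 3 * se)
})

test_that("hyperprior and loss-constant limits collapse to the simpler estimators", {
  n <- 25; g <- 25
  # v -> 0+: the k-average collapses to k = 0, z-average to z = 1/2
  expect_equal(ebayes_self(n, g, v = 1e-6), (n + 0.5) / g, tolerance = 1e-5)
  # c -> 0: LINEX and composite LINEX become the squared-error estimate
  expect_equal(ebayes_linex(n, g, v = 1, c = 1e-6), ebayes_self(n, g, v = 1),
               tolerance = 1e-5)
  expect_equal(ebayes_cllf(n, g, v = 1, c = 1e-6), ebayes_self(n, g, v = 1),
               tolerance = 1e-5)
  # omega = 0: weighted composite reduces exactly
  expect_identical(ebayes_wcllf(n, g, v = 1, c = 1.2, omega = 0),
                   ebayes_cllf(n, g, v = 1, c = 1.2))
})

test_that("entropy-to-squared-error ratio is (2n - 1)/(2n + 1) exactly", {
  for (n in c(2, 25, 80)) {
    g <- runif(1, 5, 50)
    expect_equal(ebayes_entropy(n, g) / ebayes_self(n, g),
                 (2 * n - 1) / (2 * n + 1))
  }
})

test_that("E-Bayes estimates lie inside the hyperprior corner range of the Bayes estimates", {
  set.seed(31)
  for (i in 1:8) {
    n <- sample(c(10, 25, 60), 1)
    g <- runif(1, 8, 60)
    v <- runif(1, 0.5, 1.5)
    cc <- runif(1, 0.1, 1.2)
    om <- runif(1, 0, 1)
    corners <- function(f) {
      vals <- c(f(n + 1e-9, g + 1e-12), f(n + 1, g + 1e-12),
                f(n + 1e-9, g + v), f(n + 1, g + v))
      range(vals)
    }
    checks <- list(
      list(ebayes_self(n, g, v), corners(function(s, r) bayes_self(s, r))),
      list(ebayes_linex(n, g, v, c = cc),
           corners(function(s, r) bayes_linex(s, r, c = cc))),
      list(ebayes_asym(n, g, v), corners(function(s, r) bayes_asym(s, r))),
      list(ebayes_entropy(n, g, v), corners(function(s, r) bayes_entropy(s, r))),
      list(ebayes_cllf(n, g, v, c = cc),
           corners(function(s, r) bayes_cllf(s, r, c = cc))),
      list(ebayes_wcllf(n, g, v, c = cc, omega = om),
           corners(function(s, r) bayes_wcllf(s, r, c = cc, omega = om)))
    )
    for (ch in checks) {
      expect_gt(ch[[1]], ch[[2]][1])
      expect_lt(ch[[1]], ch[[2]][2])
    }
  }
})

test_that("E-Bayes weighted composite LINEX is strictly decreasing in omega", {
  omegas <- seq(0, 2, by = 0.25)
  for (g in c(10, 25, 70)) {
    vals <- vapply(omegas, function(om) ebayes_wcllf(25, g, v = 1, c = 0.5, omega = om),
                   numeric(1))
    expect_true(all(diff(vals) < 0))
  }
})

test_that("E-Bayes domain guards reject degenerate statistics", {
  expect_error(ebayes_self(25, 0), "gamma_stat > 0")
  expect_error(ebayes_cllf(25, 1, c = 1.5), "gamma_stat > c")
  expect_error(ebayes_wcllf(25, 0.8, c = 1.5, omega = 0.5), "omega > c")
})
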