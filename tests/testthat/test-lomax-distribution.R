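test_that("density, distribution and reliability functions agree with the closed forms", {
  expect_equal(dlomax(0, shape = 2, scale = 3), 2 / 3)
  expect_equal(dlomax(-1, shape = 2, scale = 3), 0)
  expect_equal(dlomax(3, shape = 1, scale = 3), 1 / 12)

  expect_equal(plomax(0, shape = 1, scale = 3), 0)
  expect_equal(plomax(9, shape = 1, scale = 3), 0.75)
  expect_equal(plomax(1e12, shape = 1, scale = 3), 1, tolerance = 1e-10)

  expect_equal(lomax_reliability(0, shape = 1, scale = 3), 1)
  expect_equal(lomax_reliability(9, shape = 1, scale = 3), 0.25)

  # complement identity and monotonicity on a grid
  for (b in c(0.7, 1, 2.5)) {
    x <- seq(0, 40, length.out = 101)
    p <- plomax(x, b, 3)
    expect_equal(lomax_reliability(x, b, 3) + p, rep(1, length(x)))
    expect_true(all(diff(p) > 0))
  }

  expect_error(dlomax(1, shape = -1, scale = 3), "shape")
  expect_error(plomax(1, shape = 1, scale = 0), "scale")
})

test_that("the density integrates to the distribution function", {
  grid <- expand.grid(shape = c(0.8, 1, 2), scale = c(1, 3), x = c(0.5, 3, 12))
  for (i in seq_len(nrow(grid))) {
    with(grid[i, ], {
      num <- integrate(dlomax, 0, x, shape = shape, scale = scale,
                       rel.tol = 1e-12)$value
      expect_equal(num, plomax(x, shape, scale), tolerance = 1e-8)
    })
  }
})

test_that("quantile function inverts the distribution function", {
  p <- c(0, 0.1, 0.5, 0.75, 0.99)
  expect_equal(plomax(qlomax(p, 1.3, 3), 1.3, 3), p)
  expect_equal(qlomax(0.75, 1, 3), 9)  # inverse of the cdf example
})

test_that("sampling by inversion matches the analytic transform and is reproducible", {
  # x = sigma * ((1 - U)^(-1/beta) - 1) applied to known uniforms
  set.seed(99)
  u <- runif(5)
  set.seed(99)
  x <- rlomax(5, shape = 1, scale = 3)
  expect_equal(x, 3 * ((1 - u)^(-1) - 1))
  expect_equal(qlomax(0.75, 1, 3), 9)   # U = 0.75 worked example
  expect_equal(qlomax(0, 1, 3), 0)      # U = 0 lower endpoint

  set.seed(7)
  a <- rlomax(10, 1.5, 3)
  set.seed(7)
  expect_identical(a, rlomax(10, 1.5, 3))
})

test_that("draws pass a Kolmogorov-Smirnov check against the model cdf", {
  # D_n below the 1% critical value 1.628/sqrt(n) in nearly all seeded runs
  crit <- 1.628 / sqrt(10000)
  set.seed(123)
  passes <- vapply(1:20, function(i) {
    x <- rlomax(10000, shape = 1.2, scale = 3)
    d <- suppressWarnings(ks.test(x, plomax, shape = 1.2, scale = 3)$statistic)
    d < crit
  }, logical(1))
  expect_gte(sum(passes), 18)
})

test_that("log-lifetimes ln(1 + x/sigma) are exponential with rate beta", {
  set.seed(5)
  x <- rlomax(10000, shape = 1, scale = 3)
  y <- log1p(x / 3)
  se <- sd(y) / sqrt(length(y))
  expect_lt(abs(mean(y) - 1), 3 * se)
  # and the sufficient statistic is Gamma(n, rate beta): KS on replicates
  set.seed(6)
  g <- replicate(2000, lomax_suffstat(rlomax(10, 2, 3), 3))
  ks <- suppressWarnings(ks.test(g, pgamma, shape = 10, rate = 2))
  expect_gt(ks$p.value, 0.001)
})

test_that("sufficient statistic is exact on worked examples and validates input", {
  expect_equal(lomax_suffstat(c(0, 0, 0), 3), 0)
  expect_equal(lomax_suffstat(3 * (exp(1) - 1), 3), 1)
  expect_equal(lomax_suffstat(c(9, 9), 3), 2 * log(4))
  expect_error(lomax_suffstat(c(1, -1), 3), "nonnegative")
  expect_error(lomax_suffstat(1, -3), "positive")
})

test_that("the shape MLE is n/gamma, scale-free, and rejects degenerate samples", {
  expect_equal(mle_shape(1, 1), 1)
  expect_equal(mle_shape(25, 25), 1)
  expect_error(mle_shape(3, 0), "degenerate")

  # doubling data and scale together leaves gamma and the MLE unchanged
  x <- c(1.2, 5, 0.3, 8)
  g1 <- lomax_suffstat(x, 3)
  g2 <- lomax_suffstat(2 * x, 6)
  expect_equal(g1, g2)
  expect_equal(mle_shape(4, g1), mle_shape(4, g2))

  # E[n/gamma] = n beta / (n - 1) since gamma ~ Gamma(n, beta)
  set.seed(31)
  sims <- summarise_lifetimes(simulate_lifetimes(25, 1, 3, reps = 4000), scale = 3)
  se <- sd(sims$mle) / sqrt(nrow(sims))
  expect_lt(abs(mean(sims$mle) - 25 / 24), 3 * se)
})

test_that("tidy sample helpers and text round trip preserve the data", {
  set.seed(2)
  sim <- simulate_lifetimes(10, 1, 3, reps = 3)
  expect_equal(nrow(sim), 30)
  smry <- summarise_lifetimes(sim, scale = 3)
  expect_equal(nrow(smry), 3)
  expect_equal(smry$mle, 10 / smry$gamma_stat)

  path <- withr::local_tempfile(fileext = ".txt")
  one <- dplyr::filter(sim, replicate == 1)
  write_lifetimes(one, path)
  # comments are ignored on read
  writeLines(c("# lifetimes, known scale 3", readLines(path)), path)
  back <- read_lifetimes(path)
  expect_equal(back$lifetime, one$lifetime, tolerance = 1e-12)
})
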