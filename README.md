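# lomaxbayes

Bayesian and E-Bayesian estimation of the shape parameter of the Lomax
(Pareto type II) lifetime distribution under six loss functions, including
the weighted composite LINEX loss, with a fully vectorised Monte Carlo
study comparing all thirteen resulting estimators.

## The problem

The Lomax distribution is a heavy-tailed lifetime model used in
reliability, life testing, queueing and survival analysis, with density

```
f(x; β, σ) = (β/σ) (1 + x/σ)^-(β+1),   x ≥ 0,  β, σ > 0,
```

survival function `R(t) = (1 + t/σ)^-β`, scale σ (treated as known
throughout) and shape β, the estimand. With σ known, the log-likelihood of
a sample x₁, …, xₙ depends on the data only through the sufficient
statistic

```
γ = Σᵢ log(1 + xᵢ/σ)  ~  Gamma(n, rate β),
```

so every estimator here is a function of (n, γ), and the MLE is
`β̂ = n/γ`.

For asymmetric decision problems a point estimate should minimise the
posterior expectation of a loss `L(β̂, β)`. Under the conjugate
Gamma(z, k) prior the posterior is Gamma(n + z, γ + k), and the package
provides closed-form posterior-risk minimisers for six losses
(Δ = β̂ − β):

| loss | L(β̂, β) | Bayes estimator |
|---|---|---|
| SELF (squared error) | Δ² | (n+z)/(γ+k) |
| LINEX | e^{cΔ} − cΔ − 1 | ((n+z)/c) log(1 + c/(γ+k)) |
| ASLF (asymmetric ratio) | β/β̂ + β̂/β − 2 | √((n+z−1)(n+z))/(γ+k) |
| ENLF (entropy) | β̂/β − log(β̂/β) − 1 | (n+z−1)/(γ+k) |
| CLLF (composite LINEX) | e^{−cΔ} + e^{cΔ} − 2 | ((n+z)/2c) log((γ+k+c)/(γ+k−c)) |
| WCLLF (weighted composite LINEX) | e^{−ωβ} (e^{−cΔ} + e^{cΔ} − 2) | ((n+z)/2c) log((γ+k+ω+c)/(γ+k+ω−c)) |

The WCLLF multiplies the symmetric composite LINEX loss by the weight
`w(β) = e^{−ωβ}`, discounting errors made at large true shapes; at ω = 0
it reduces to the CLLF exactly.

The **E-Bayesian** estimators average each Bayes estimator over a
hyperprior on the prior hyperparameters — z uniform on (0, 1) (the range
where the gamma prior density is decreasing in β) and k uniform on (0, v),
independent — and are available in closed form for five of the six losses
(the ratio loss needs a one-dimensional Gauss–Legendre quadrature in z).

Every closed form is verified in the test suite against independent
numerical oracles: an adaptive-quadrature posterior-risk minimiser for the
Bayes estimators and a two-dimensional Gauss–Legendre hyperprior average
for the E-Bayesian ones.

## Worked example

```r
library(lomaxbayes)

set.seed(42)
sample_tbl <- simulate_lifetimes(25, shape = 1, scale = 3)
summarise_lifetimes(sample_tbl, scale = 3)
#> # A tibble: 1 × 4
#>   replicate     n gamma_stat   mle
#>       <int> <int>      <dbl> <dbl>
#> 1         1    25       36.6 0.682

estimate_shape(sample_tbl, scale = 3) |>
  dplyr::select(label, method, family, c, estimate)
#> # A tibble: 19 × 5
#>    label         method family         c estimate
#>    <chr>         <chr>  <chr>      <dbl>    <dbl>
#>  1 mle           mle    mle         NA      0.682
#>  2 b_self        bayes  self        NA      0.689
#>  3 b_asymmetric  bayes  asymmetric  NA      0.676
#>  4 b_entropy     bayes  entropy     NA      0.662
#>  5 eb_self       ebayes self        NA      0.687
#>  ...
#> 12 b_wcllf_c0.5  bayes  wcllf        0.5    0.680
#> 19 eb_wcllf_c1.5 ebayes wcllf        1.5    0.678
```

This sample happened to draw a large γ (36.6 where E γ = 25), so all
estimators sit below the true β = 1; the Bayes and E-Bayes columns shrink
the MLE towards the prior, and the weighted/asymmetric losses shrink
hardest.

The Monte Carlo study compares all thirteen estimator columns by their
average estimate (AE) and mean averaged squared error
(MASE = mean of (β̂ᵢ − β)² across replicates):

```r
cfg <- study_config(n = c(25, 100), beta = 1, reps = 10000, seed = 1)
s <- run_study(cfg)
study_tables(s)$mase_bayes
#> # A tibble: 2 × 12
#>    beta     n    mle b_self b_asymmetric b_entropy b_linex_c0.5 b_linex_c1.5 ...
#> 1     1    25 0.0486 0.0469       0.0437    0.0415       0.0441       0.0396
#> 2     1   100 0.0105 0.0104       0.0102    0.0101       0.0103       0.01
```

At n = 25 the Bayes columns all beat the MLE (0.0486), and the losses that
shrink the estimate (entropy, LINEX with c = 1.5, weighted composite
LINEX) beat squared error; by n = 100 the prior washes out and the columns
agree to three decimals. `expected_performance(cfg)` computes the same
table deterministically, integrating each estimator against the exact
Gamma(n, β) distribution of γ instead of simulating. `tidy()`, `glance()`
and `autoplot()` work on both results.

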