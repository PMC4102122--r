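flat <- analytic_pmf("custom", list(fn = function(z) rep(0, length(z))),
                     domain = c(-12, 12))
kT310 <- kT_from_temperature(310)

test_that("flat PMF with harmonic bias gives the Gaussian window law", {
  wins <- gen_umbrella_samples(flat, centers = c(-3, 0, 3), k_bias = 10,
                               kT = kT310, n_per_window = 5000, seed = 99)
  sd_expected <- sqrt(kT310 / 10)
  for (i in seq_along(wins)) {
    w <- wins[[i]]
    expect_lt(abs(mean(w$samples) - w$center), 3 * sd_expected / sqrt(w$n))
    expect_lt(abs(var(w$samples) / sd_expected^2 - 1), 3 * sqrt(2 / w$n))
  }
})

test_that("window samples follow the analytic biased density (KS p > 0.01)", {
  pmf <- analytic_pmf("gaussian_barrier",
                      list(height = 5, center = 0, width = 2),
                      domain = c(-12, 12))
  win <- gen_umbrella_samples(pmf, centers = 1.5, k_bias = 10, kT = kT310,
                              n_per_window = 10000, seed = 22)[[1]]
  cdf <- biased_cdf(pmf, 1.5, 10, kT310)
  ks <- suppressWarnings(stats::ks.test(win$samples, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("KS distance to the analytic CDF shrinks as n grows", {
  pmf <- analytic_pmf("double_well",
                      list(height = 3, center = 0, half_sep = 5),
                      domain = c(-12, 12))
  cdf <- biased_cdf(pmf, 0, 10, kT310)
  d <- vapply(c(100, 1000, 10000), function(n) {
    w <- gen_umbrella_samples(pmf, 0, 10, kT310, n_per_window = n,
                              seed = 23)[[1]]
    suppressWarnings(stats::ks.test(w$samples, cdf)$statistic)
  }, numeric(1))
  expect_true(all(diff(d) < 0))
})

test_that("sampling is deterministic and validates inputs", {
  a <- gen_umbrella_samples(flat, c(-1, 1), 10, kT310, 100, seed = 24)
  b <- gen_umbrella_samples(flat, c(-1, 1), 10, kT310, 100, seed = 24)
  expect_identical(lapply(a, `[[`, "samples"), lapply(b, `[[`, "samples"))
  expect_error(gen_umbrella_samples(flat, 99, 10, kT310, 10, seed = 1),
               "domain")
  expect_error(gen_umbrella_samples(flat, 0, -1, kT310, 10, seed = 1),
               "non-negative")
})

test_that("AR(1) thinning keeps the marginal but adds autocorrelation", {
  pmf <- analytic_pmf("harmonic", list(kappa = 0.5, center = 0),
                      domain = c(-8, 8))
  iid <- gen_umbrella_samples(pmf, 0, 0, kT310, 5000, seed = 25)[[1]]
  ar <- gen_umbrella_samples(pmf, 0, 0, kT310, 5000, seed = 25, rho = 0.9)[[1]]
  r1 <- function(x) cor(x[-1], x[-length(x)])
  expect_lt(abs(r1(iid$samples)), 0.1)
  expect_gt(r1(ar$samples), 0.5)
  cdf <- biased_cdf(pmf, 0, 0, kT310)
  expect_gt(suppressWarnings(stats::ks.test(ar$samples, cdf))$p.value, 0.01)
})
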