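kT310 <- kT_from_temperature(310)
flat <- analytic_pmf("custom", list(fn = function(z) rep(0, length(z))),
                     domain = c(-13, 13))

test_that("harmonic bias energy is a half k x squared displacement", {
  w <- umbrella_window(center = 2, k = 10, kT = kT310, samples = 0)
  expect_equal(bias_energy(w, 2), 0)
  expect_equal(bias_energy(w, 3), 5)     # k = 10 kJ/mol/A^2 at 1 A
  expect_equal(bias_energy(w, 4), 4 * bias_energy(w, 3))
})

test_that("umbrella windows round trip through TSV + sidecar", {
  w <- umbrella_window(center = -3.5, k = 10, kT = kT310,
                       samples = c(-3.1, -3.9, -3.5), time_ps = c(0, 0.02, 0.04))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_umbrella_window(w, f)
  back <- read_umbrella_window(f)
  expect_equal(back$center, w$center)
  expect_equal(back$k, w$k)
  expect_equal(back$kT, w$kT)
  expect_equal(back$samples, w$samples, tolerance = 1e-9)
})

test_that("windows sampling a flat PMF reconstruct a flat profile", {
  wins <- gen_umbrella_samples(flat, centers = seq(-12, 12, 1), k_bias = 10,
                               kT = kT310, n_per_window = 10000, seed = 61)
  sol <- wham(wins)
  expect_true(sol$converged)
  expect_equal(sum(sol$P), 1, tolerance = 1e-12)
  pmf <- to_pmf(sol)
  # interior bins only: the outermost bins carry few samples
  inner <- pmf$z > -12 & pmf$z < 12 & !is.na(pmf$G)
  dev <- pmf$G[inner] - median(pmf$G[inner])
  expect_lt(sqrt(mean(dev^2)), 0.1)
})

test_that("single unbiased window reduces to Boltzmann inversion", {
  pmf_true <- analytic_pmf("gaussian_barrier",
                           list(height = 2, center = 0, width = 3),
                           domain = c(-10, 10))
  win <- gen_umbrella_samples(pmf_true, 0, k_bias = 0, kT = kT310,
                              n_per_window = 50000, seed = 62)[[1]]
  sol <- wham(list(win))
  est <- to_pmf(sol)
  ok <- which(sol$n_ib[, 1] >= 100)
  direct <- -log(sol$n_ib[ok, 1] / sum(sol$n_ib[, 1]) / sol$bin_width)
  # WHAM with one k=0 window IS the normalized histogram
  expect_equal(est$G[ok] - mean(est$G[ok]), direct - mean(direct),
               tolerance = 1e-9)
  truth <- pmf_value(pmf_true, est$z[ok])
  resid <- (est$G[ok] - truth) - mean(est$G[ok] - truth)
  expect_lt(sqrt(mean(resid^2)), 0.15)
})

test_that("to_pmf applies the reference convention", {
  sol <- structure(list(bin_centers = c(0, 1), P = c(0.7, 0.3),
                        F = 0, mask = c(TRUE, TRUE), kT = kT310,
                        bin_width = 1), class = "wham_solution")
  pmf <- to_pmf(sol)
  expect_equal(pmf$G, c(0, log(7 / 3)))
  solu <- structure(list(bin_centers = 1:4, P = rep(0.25, 4), F = 0,
                         mask = rep(TRUE, 4), kT = kT310, bin_width = 1),
                    class = "wham_solution")
  expect_equal(to_pmf(solu)$G, rep(0, 4))
  sol2 <- sol; sol2$P <- c(0.3, 0.7)
  expect_equal(to_pmf(sol2, reference = "minimum")$G, c(log(7 / 3), 0))
  # bulk_mean zeroes the average over the cytoplasmic window
  bm <- to_pmf(sol, reference = "bulk_mean", bulk_width = 2)
  expect_equal(mean(bm$G), 0)
  expect_equal(diff(bm$G), log(7 / 3))
})

test_that("WHAM is invariant to window order and has monotone tail residuals", {
  pmf_true <- analytic_pmf("gaussian_barrier",
                           list(height = 3, center = 0, width = 2),
                           domain = c(-13, 13))
  wins <- gen_umbrella_samples(pmf_true, seq(-12, 12, 1), 10, kT310,
                               n_per_window = 2000, seed = 63)
  a <- wham(wins)
  b <- wham(rev(wins))
  ga <- to_pmf(a)$G
  gb <- to_pmf(b)$G
  expect_lt(max(abs(ga - gb), na.rm = TRUE), 1e-3)
  tail_res <- utils::tail(a$residuals, 100)
  expect_true(all(diff(tail_res) <= 1e-12))
})

test_that("halving the bin width barely moves the recovered barrier", {
  pmf_true <- analytic_pmf("gaussian_barrier",
                           list(height = 5, center = 0, width = 2),
                           domain = c(-13, 13))
  wins <- gen_umbrella_samples(pmf_true, seq(-12, 12, 1), 10, kT310,
                               n_per_window = 4000, seed = 64)
  barrier <- function(bw) {
    g <- to_pmf(wham(wins, bin_width = bw))$G
    max(g, na.rm = TRUE) - min(g, na.rm = TRUE)
  }
  expect_lt(abs(barrier(0.2) - barrier(0.1)), 0.1)
})

test_that("pathological window sets are reported", {
  # two tightly biased windows with no histogram overlap
  w1 <- umbrella_window(0, 50, kT310, rnorm(100, 0, 0.1))
  w2 <- umbrella_window(10, 50, kT310, rnorm(100, 10, 0.1))
  expect_error(wham(list(w1, w2)), "share no histogram bins")
  # empty interior bins are masked with a warning
  w3 <- umbrella_window(0, 0, kT310, c(rep(0.05, 50), rep(1.05, 50)))
  expect_warning(sol <- wham(list(w3), bin_width = 0.1), "empty bin")
  expect_false(all(sol$mask))
  # iteration cap flags non-convergence
  pmf_true <- analytic_pmf("gaussian_barrier",
                           list(height = 3, center = 0, width = 2),
                           domain = c(-13, 13))
  wins <- gen_umbrella_samples(pmf_true, seq(-12, 12, 2), 10, kT310,
                               n_per_window = 500, seed = 65)
  expect_warning(sol2 <- wham(wins, max_iter = 3), "did not converge")
  expect_false(sol2$converged)
})

test_that("PMF comparison reports uniform offsets as rectangles", {
  z <- seq(-10, 9.9, by = 0.1) + 0.05
  base <- pmf_profile(z, rep(1, length(z)))
  ident <- compare_pmfs(base, base)
  expect_equal(ident$delta_G, rep(0, length(z)))
  expect_equal(ident$area_positive, 0)
  lifted <- pmf_profile(z, base$G + ifelse(z >= -5 & z < 5, 4, 0))
  cmp <- compare_pmfs(lifted, base, region = c(-5, 5))
  expect_equal(cmp$peak, 4)
  expect_equal(cmp$area_positive, 40, tolerance = 1e-9)
  # antisymmetry under swapping the systems
  swapped <- compare_pmfs(base, lifted, region = c(-5, 5))
  expect_equal(swapped$delta_G, -cmp$delta_G)
  # disjoint domains are refused
  far <- pmf_profile(z + 100, base$G)
  expect_error(compare_pmfs(base, far), "disjoint")
})
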