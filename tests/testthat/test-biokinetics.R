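# Macro-to-micro kinetics: bi-exponential fitting, TRC integration,
# extrapolation factors, component combination.

biexp_points <- function(A, mu, times = c(6, 12, 24, 48, 96, 168, 240, 336)) {
  tibble::tibble(time_h = times,
                 dose_rate_mGy_h = A[1] * exp(-mu[1] * times) +
                   A[2] * exp(-mu[2] * times))
}

test_that("noiseless bi-exponential data are recovered to high accuracy", {
  fit <- fit_biexponential(biexp_points(c(50, 10), c(0.1, 0.005)))
  expect_equal(sort(fit$amplitudes, decreasing = TRUE), c(50, 10),
               tolerance = 1e-3)
  expect_equal(sort(fit$rates, decreasing = TRUE), c(0.1, 0.005),
               tolerance = 1e-3)
  expect_lt(fit$sse, 1e-8)
  td <- tidy(fit)
  expect_equal(td$term, c("A1", "mu1", "A2", "mu2"))
  expect_gt(glance(fit)$r.squared, 0.99999)
})

test_that("mono-exponential truth collapses the second component", {
  pts <- biexp_points(c(40, 0), c(0.02, 0.5))
  fit <- fit_biexponential(pts)
  grid <- seq(0, 300, by = 10)
  truth <- 40 * exp(-0.02 * grid)
  expect_lt(max(abs(trc_rate(fit, grid) - truth) / truth), 0.005)
  expect_error(fit_biexponential(pts[1:3, ]), class = "alphadose3d_design_error")
})

test_that("TRC integration matches closed forms and quadrature", {
  fit <- fit_biexponential(biexp_points(c(40, 0), c(0.02, 0.5)))
  # single exponential: A/lambda at infinite horizon
  expect_equal(integrate_trc(fit, horizon_h = 1e7), 40 / 0.02, tolerance = 1e-3)
  # six half-lives of the single rate: A/lambda (1 - 2^-6)
  h6 <- 6 * log(2) / 0.02
  expect_equal(integrate_trc(fit, horizon_h = h6),
               40 / 0.02 * (1 - 2^-6), tolerance = 1e-3)
  # adaptive-quadrature oracle on random bi-exponentials
  set.seed(13)
  for (rep in 1:20) {
    A <- runif(2, 1, 100); mu <- sort(10^runif(2, -3, -0.5), decreasing = TRUE)
    fit2 <- fit_biexponential(biexp_points(A, mu))
    h <- runif(1, 100, 2000)
    want <- integrate(function(t) trc_rate(fit2, t), 0, h,
                      rel.tol = 1e-12)$value
    expect_equal(integrate_trc(fit2, horizon_h = h), want, tolerance = 1e-8)
  }
  # monotone in horizon, additive over components
  expect_lt(integrate_trc(fit, horizon_h = 100),
            integrate_trc(fit, horizon_h = 200))
})

test_that("the default horizon is six parent half-lives", {
  expect_equal(default_horizon_h(test_chain()), 6 * 9.9 * 24)
})

test_that("extrapolation factors match the physical-decay closed form", {
  lam <- log(2) / (9.9 * 24) # pure physical decay, 1/h
  fit <- fit_biexponential(biexp_points(c(80, 0), c(lam, 1)))
  h6 <- 6 * log(2) / lam
  cf <- extrapolation_factor(fit, c(24, 168), horizon_h = h6)
  closed <- exp(lam * c(24, 168)) * (1 - 2^-6) / lam
  expect_equal(cf$c, closed, tolerance = 1e-6)
  # c is monotone increasing in reference time for a decaying curve
  cs <- extrapolation_factor(fit, c(12, 24, 96, 168), horizon_h = h6)$c
  expect_true(all(diff(cs) > 0))
  # bounds bracket the central value
  expect_true(all(cf$c_lower <= cf$c & cf$c <= cf$c_upper))
})

test_that("bound curves bracket the central curve", {
  set.seed(3)
  pts <- biexp_points(c(50, 10), c(0.1, 0.005))
  pts$dose_rate_mGy_h <- pts$dose_rate_mGy_h * (1 + 0.05 * rnorm(nrow(pts)))
  fit <- fit_biexponential(pts)
  grid <- seq(0, default_horizon_h(test_chain()), length.out = 100)
  expect_true(all(trc_rate(fit, grid, "upper") >=
                    trc_rate(fit, grid, "central") - 1e-9))
  expect_true(all(trc_rate(fit, grid, "lower") <=
                    trc_rate(fit, grid, "central") + 1e-9))
})

test_that("dose-map scaling propagates bounds and preserves ordering", {
  rate <- array(runif(27), c(3, 3, 3))
  cf <- tibble::tibble(c = 1, c_lower = 0.8, c_upper = 1.3)
  d1 <- scale_dose_map(rate, cf)
  expect_equal(d1$dose, rate) # c = 1 is the identity
  cf2 <- tibble::tibble(c = 250, c_lower = 200, c_upper = 320)
  d2 <- scale_dose_map(rate, cf2)
  expect_equal(d2$dose, rate * 250)
  expect_true(all(d2$lower <= d2$dose & d2$dose <= d2$upper))
  expect_error(scale_dose_map(rate, tibble::tibble(c = -1, c_lower = -1,
                                                   c_upper = -1)),
               class = "alphadose3d_contract_error")
})

test_that("component combination follows the dose-ratio algebra", {
  expect_equal(combine_components(5, 0)$total_Gy, 5)
  expect_equal(combine_components(5, 0)$fraction_bi, 0)
  expect_equal(combine_components(1.6, 3)$fraction_bi, 0.75)
  # ratio derived from two synthetic TRCs equals the integral ratio
  fit_ac <- fit_biexponential(biexp_points(c(30, 5), c(0.05, 0.004)))
  fit_bi <- fit_biexponential(biexp_points(c(90, 10), c(0.08, 0.006)))
  D_ac <- integrate_trc(fit_ac)
  D_bi <- integrate_trc(fit_bi)
  comb <- combine_components(D_ac, D_bi / D_ac)
  expect_equal(comb$total_Gy, D_ac + D_bi, tolerance = 1e-10)
  expect_equal(comb$fraction_bi, D_bi / (D_ac + D_bi), tolerance = 1e-10)
})

test_that("synthetic cohorts give nearly unbiased integrated dose", {
  truth <- list(amplitudes = c(60, 15), rates = c(0.08, 0.003))
  D_true <- 60 / 0.08 * (1 - exp(-0.08 * default_horizon_h(test_chain()))) +
    15 / 0.003 * (1 - exp(-0.003 * default_horizon_h(test_chain())))
  times <- c(24, 48, 96, 168)
  Ds <- vapply(1:200, function(i) {
    cohort <- simulate_biod_cohort(truth, times, n_subjects = 17,
                                   inter_subject_cv = 0.2, seed = 5000 + i)
    integrate_trc(fit_biexponential(cohort))
  }, numeric(1))
  expect_lt(abs(mean(Ds) / D_true - 1), 0.05)
  # median relative error of the extrapolation factor stays under 10%
  c_true <- D_true / (60 * exp(-0.08 * 24) + 15 * exp(-0.003 * 24))
  cs <- vapply(1:50, function(i) {
    cohort <- simulate_biod_cohort(truth, times, n_subjects = 17,
                                   inter_subject_cv = 0.2, seed = 7000 + i)
    extrapolation_factor(fit_biexponential(cohort), 24)$c
  }, numeric(1))
  expect_lt(median(abs(cs - c_true) / c_true), 0.10)
})
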