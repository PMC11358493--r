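# Decay-chain kinetics: ratio evolution, inversion, fitting, free-daughter
# quantification, frame-coincidence correction.

chain <- test_chain()
la <- chain_lambda(chain, "Ac-225")
lb <- chain_lambda(chain, "Bi-213")
k_eq <- lb / (lb - la)

test_that("chain constants and construction contracts hold", {
  expect_equal(chain$half_life_s[chain$name == "Ac-225"], 9.9 * 86400)
  expect_equal(chain$half_life_s[chain$name == "Bi-213"], 45.6 * 60)
  expect_equal(chain$half_life_s[chain$name == "At-217"], 0.032)
  expect_equal(chain$half_life_s[chain$name == "Fr-221"], 4.8 * 60)
  expect_equal(sum(chain$alpha_yield), 4, tolerance = 1e-6)
  # per-primary alpha branching fractions
  expect_equal(chain$alpha_yield / 4,
               c(0.25, 0.25, 0.25, 0.00525, 0.24475), tolerance = 1e-6)
  expect_error(
    decay_chain(rbind(nuclide("A", "1 d", 5, 1), nuclide("B", "2 d", 5, 1)),
                parent = "A", daughter = "B", alphas_per_chain = 2),
    class = "alphadose3d_domain_error" # parent must be longest-lived
  )
  expect_error(nuclide("X", "-1 s"), class = "alphadose3d_domain_error")
})

test_that("ratio evolution matches identities and its fixed point", {
  expect_equal(ratio_at_time(5, 0, chain), 5)
  for (t in c(0, 60, 3600, 86400)) {
    expect_equal(ratio_at_time(k_eq, t, chain), k_eq, tolerance = 1e-12)
  }
  expect_error(ratio_at_time(5, -1, chain), class = "alphadose3d_domain_error")
  expect_error(ratio_at_time(-1, 1, chain), class = "alphadose3d_domain_error")
})

test_that("ratio evolution and inversion agree with a Bateman ODE oracle", {
  skip_if_not_installed("deSolve")
  # frozen oracle value: ratio_at_time(14.7, 3600 s) for the Ac-225/Bi-213
  # pair, computed by numerical integration of the two-nuclide system
  sol <- bateman_ode(10, 147, la, lb, c(0, 3600))
  oracle <- sol[2, "Ab"] / sol[2, "Aa"]
  expect_equal(ratio_at_time(14.7, 3600, chain), unname(oracle),
               tolerance = 1e-6)
  # random instances, both directions
  set.seed(41)
  for (rep in 1:25) {
    la_r <- 10^runif(1, -7, -5)
    lb_r <- la_r * 10^runif(1, 0.5, 3)
    nucs <- rbind(
      nuclide("P", log(2) / la_r, 5, 1),
      nuclide("D", log(2) / lb_r, 6, 1)
    )
    ch <- decay_chain(nucs, "P", "D", alphas_per_chain = 2)
    Aa0 <- runif(1, 1, 100); Ab0 <- runif(1, 0, 500)
    t_end <- runif(1, 0.1, 3) / lb_r
    sol <- bateman_ode(Aa0, Ab0, la_r, lb_r, c(0, t_end))
    expect_equal(ratio_at_time(Ab0 / Aa0, t_end, ch),
                 unname(sol[2, "Ab"] / sol[2, "Aa"]), tolerance = 1e-6)
    expect_equal(
      initial_daughter_activity(unname(sol[2, "Ab"]), unname(sol[2, "Aa"]),
                                t_end, ch),
      Ab0, tolerance = 1e-6
    )
  }
})

test_that("forward ratio and inversion are exact algebraic inverses", {
  expect_equal(initial_daughter_activity(42, 10, 0, chain), 42)
  set.seed(7)
  for (rep in 1:50) {
    Aa0 <- runif(1, 1, 100)
    r0 <- runif(1, 0, 20)
    t <- runif(1, 0, 6 * 3600)
    Aa_t <- Aa0 * exp(-la * t)
    Ab_t <- ratio_at_time(r0, t, chain) * Aa_t
    expect_equal(initial_daughter_activity(Ab_t, Aa_t, t, chain),
                 r0 * Aa0, tolerance = 1e-10)
  }
})

test_that("ratio relaxes to the transient-equilibrium asymptote", {
  t20 <- 20 * chain$half_life_s[chain$name == "Bi-213"]
  # the transient decays as ~2^-20 per excess unit of r0
  expect_lt(abs(ratio_at_time(1, t20, chain) - k_eq), 1e-6)
  t40 <- 2 * t20
  for (r0 in c(0, 2, 14.7, 100)) {
    expect_lt(abs(ratio_at_time(r0, t40, chain) - k_eq), 1e-6)
  }
  # the near-1 equilibrium constant, selectable as exactly 1
  expect_equal(k_eq, 1.0032, tolerance = 1e-4)
  expect_equal(ratio_at_time(1, 1e9, chain, equilibrium_one = TRUE), 1)
})

test_that("initial-ratio fitting recovers truth", {
  times <- c(1800, 3600, 5400, 7200)
  exact <- tibble::tibble(time_s = times, ratio = ratio_at_time(14.7, times, chain))
  fit <- fit_initial_ratio(exact, chain)
  expect_equal(fit$r0, 14.7, tolerance = 1e-8)
  expect_equal(fit$r2, 1.0, tolerance = 1e-9)

  const <- tibble::tibble(time_s = times, ratio = rep(k_eq, 4))
  expect_equal(fit_initial_ratio(const, chain)$r0, k_eq, tolerance = 1e-10)

  expect_error(
    fit_initial_ratio(tibble::tibble(time_s = c(10, 10), ratio = c(1, 2)), chain),
    class = "alphadose3d_design_error"
  )

  # 1% multiplicative noise, 4 points, 200 replicates: mean recovery
  # within 2% of truth
  r0s <- vapply(1:200, function(i) {
    s <- simulate_ratio_series(14.7, times, counting_error_cv = 0.01,
                               chain = chain, seed = 1000 + i)
    fit_initial_ratio(s, chain)$r0
  }, numeric(1))
  expect_lt(abs(mean(r0s) / 14.7 - 1), 0.02)
})

test_that("free-daughter excess clamps, subtracts and flags equilibrium", {
  eq <- free_daughter_excess(10, 10)
  expect_equal(eq$excess_Bq, 0)
  expect_true(eq$equilibrium)
  expect_equal(free_daughter_excess(14.7 * 10, 10)$excess_Bq, 137)
  deficit <- free_daughter_excess(6.2, 10)
  expect_equal(deficit$excess_Bq, 0)
  expect_true(deficit$deficit)
  expect_false(deficit$equilibrium)
})

test_that("frame-coincidence factor matches its model and limits", {
  expect_equal(round(frame_coincidence_factor(0.040, 0.032, 4), 2), 1.09)
  expect_equal(frame_coincidence_factor(1e-6, 0.032, 4), 1, tolerance = 1e-4)
  # instantaneous daughter: every parent loses one of 4 alphas
  expect_equal(frame_coincidence_factor(0.040, 1e-9, 4), 4 / 3, tolerance = 1e-6)
  # monotone in frame period and in daughter decay rate; always >= 1
  periods <- c(0.001, 0.01, 0.04, 0.2, 1)
  f_per <- frame_coincidence_factor(periods, 0.032, 4)
  expect_true(all(diff(f_per) > 0))
  expect_true(all(f_per >= 1))
  hls <- c(1, 0.1, 0.032, 0.01, 0.001)
  f_hl <- frame_coincidence_factor(0.040, hls, 4)
  expect_true(all(diff(f_hl) > 0))
})

test_that("Monte Carlo of parent/daughter pairs matches the analytic P", {
  p_analytic <- frame_coincidence_probability(0.040, 0.032)
  set.seed(11)
  n <- 2e5
  u <- runif(n, 0, 0.040)
  delay <- rexp(n, rate = log(2) / 0.032)
  p_mc <- mean(u + delay < 0.040) # daughter decays within the parent frame
  expect_lt(abs(p_mc - p_analytic), 3 * sqrt(p_analytic * (1 - p_analytic) / n))
})

test_that("decay correction follows the half-life definition", {
  expect_equal(decay_correct(7, 0, 100), 7)
  expect_equal(decay_correct(7, 100, 100), 14)
  t_hl <- 9.9 * 86400
  expect_equal(decay_correct(1, t_hl, t_hl),
               exp(log(2) / t_hl * t_hl), tolerance = 1e-12)
  expect_equal(decay_correct(8, -100, 100), 4) # forward correction
})

test_that("duration parsing requires explicit units and converts exactly", {
  expect_equal(parse_duration("9.9 d"), 9.9 * 86400)
  expect_equal(parse_duration(c("45.6 min", "32 ms")), c(2736, 0.032))
  expect_equal(parse_duration(5), 5)
  expect_error(parse_duration("10 fortnights"), class = "alphadose3d_unit_error")
  expect_equal(seconds_to(7200, "h"), 2)
})
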