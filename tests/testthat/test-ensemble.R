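# a hand-built ensemble_result for the analytic fixtures
fixture_result <- function(t, F, N = 100) {
  structure(list(N = N, t = t, F = F,
                 first_transition_times = rep(NA_real_, N),
                 params = canonical_params(gamma = 1.0),
                 protocol = stim_noisy_constant(0.06, 0.01),
                 base_seed = 1L, rule = "first_passage", threshold = 0.5,
                 meta = list(scheme = "fixture", dt = 0.01, sigma2 = 0.01)),
            class = "ensemble_result")
}

test_that("the stochastic integrator reduces exactly to RK4 at zero noise", {
  p <- canonical_params(gamma = 1.0)
  x0 <- c(0.5, 0.5)
  tr_d <- integrate_rk4(x0, p, stim_constant(0.06), t_end = 20, dt = 0.002)
  tr_s <- integrate_srk4(x0, p, stim_noisy_constant(0.06, 0), t_end = 20,
                         dt = 0.002, seed = 1)
  expect_identical(tr_s$phi, tr_d$phi)
  expect_identical(tr_s$mu, tr_d$mu)
})

test_that("the linear submodel reproduces the Ornstein-Uhlenbeck stationary variance", {
  # kappa = 0: dphi = (alpha - phi) dt + sigma dW, stationary var sigma^2/2
  p <- dimensionless_params(alpha = 0.5, kappa = 0, gamma = 0,
                            epsilon = 0.1, alpha_range = c(0, 1))
  s2 <- 0.002
  tr <- integrate_srk4(c(0.5, 0.7), p, stim_noisy_constant(0.5, s2),
                       t_end = 2000, dt = 0.002, thin = 5L, seed = 42)
  v <- var(tr$phi[tr$t > 100])
  expect_equal(v, s2 / 2, tolerance = 0.05)
  expect_equal(tr$meta$clamp_count, 0)
})

test_that("trajectory distribution matches a fine-step Euler-Maruyama oracle", {
  p <- canonical_params(gamma = 1.0, alpha = 0.06, epsilon = 0.2)
  on <- solve_steady_states(p)$states[[3]]
  x0 <- c(on$phi_star, on$mu_star)
  s2 <- 0.01
  t_end <- 2
  n_cells <- 1500
  phi_srk <- vapply(seq_len(n_cells), function(i) {
    tr <- integrate_srk4(x0, p, stim_noisy_constant(0.06, s2),
                         t_end = t_end, dt = 0.002, thin = 1000L,
                         seed = 5000 + i)
    tr$phi[length(tr$phi)]
  }, 0)
  # independent vectorised Euler-Maruyama at dt/50 across all cells
  dt_em <- 0.002 / 50
  n_steps <- round(t_end / dt_em)
  set.seed(999)
  phi <- rep(x0[1], n_cells); mu <- rep(x0[2], n_cells)
  sn <- sqrt(s2 * dt_em)
  for (i in seq_len(n_steps)) {
    D <- 1 + phi^2 + p$gamma * mu
    dphi <- 0.06 + p$kappa * phi^2 / D - phi
    dmu <- p$epsilon * (p$beta + phi - mu)
    phi <- pmax(phi + dphi * dt_em + sn * rnorm(n_cells), 0)
    mu <- pmax(mu + dmu * dt_em, 0)
  }
  ks <- suppressWarnings(ks.test(phi_srk, phi))
  expect_gt(ks$p.value, 0.01)
})

test_that("no noise means no escape, overwhelming noise empties the on-state", {
  p <- canonical_params(gamma = 1.0, alpha = 0.06, epsilon = 0.02)
  res0 <- run_ensemble(20, p, stim_noisy_constant(0.06, 0), t_end = 30,
                       base_seed = 3)
  expect_true(all(res0$F == 0))
  big <- run_ensemble(20, p, stim_noisy_constant(0.06, 1), t_end = 50,
                      base_seed = 3)
  expect_equal(big$F_s, 1)
})

test_that("the fraction curve is monotone, bounded, and matches crossing times", {
  p <- canonical_params(gamma = 1.0, alpha = 0.06, epsilon = 0.02)
  res <- run_ensemble(60, p, stim_noisy_constant(0.06, 0.02), t_end = 60,
                      base_seed = 10)
  expect_true(all(diff(res$F) >= 0))
  expect_true(all(res$F >= 0 & res$F <= 1))
  # F(t) is exactly the empirical CDF of the per-cell first crossings
  ft <- res$first_transition_times
  at <- c(10, 30, 60)
  expect_equal(vapply(at, function(tt)
    mean(!is.na(ft) & ft <= tt), 0),
    res$F[match(at, res$t)])
})

test_that("plateau fraction and response time behave on analytic fixtures", {
  # all-escaped and none-escaped step fixtures
  t <- seq(0, 100, by = 0.5)
  expect_equal(steady_fraction(fixture_result(t, rep(1, length(t))))$F_s, 1)
  expect_equal(steady_fraction(fixture_result(t, rep(0, length(t))))$F_s, 0)
  # hand-enumerated 4-cell crossing times: F hits the midpoint exactly at
  # the t = 20 sample, so that sample's time is returned un-interpolated
  F4 <- (findInterval(t, c(10, 20, 30, 40))) / 4
  res4 <- fixture_result(t, F4, N = 4)
  expect_equal(steady_fraction(res4)$F_s, 1)
  expect_equal(response_time(res4), 20)
  # hand-enumerated 3-cell crossing times: the midpoint falls between
  # samples and is linearly interpolated within the jump
  F3 <- (findInterval(t, c(10, 20, 40))) / 3
  res3 <- fixture_result(t, F3, N = 3)
  expect_equal(response_time(res3), 19.75)
  # exponential saturation on a fine grid: midpoint at ln 2
  tf <- seq(0, 20, by = 0.01)
  rexp_fix <- fixture_result(tf, 1 - exp(-tf))
  rexp_fix$F_s <- 1
  expect_equal(response_time(rexp_fix), log(2), tolerance = 1e-4)
  # a curve that never rises is an error
  expect_error(response_time(fixture_result(t, rep(0, length(t)))),
               "undefined")
})

test_that("ensembles are reproducible and the rules differ as documented", {
  p <- canonical_params(gamma = 1.0, alpha = 0.06, epsilon = 0.02)
  proto <- stim_noisy_constant(0.06, 0.02)
  r1 <- run_ensemble(25, p, proto, t_end = 40, base_seed = 77)
  r2 <- run_ensemble(25, p, proto, t_end = 40, base_seed = 77)
  expect_identical(r1$F, r2$F)
  expect_identical(r1$first_transition_times, r2$first_transition_times)
  # occupancy counts cells currently below threshold, so it can decrease
  ro <- run_ensemble(25, p, proto, t_end = 40, base_seed = 77,
                     rule = "occupancy")
  expect_true(all(ro$F <= 1) && all(ro$F >= 0))
  expect_gte(max(r1$F - ro$F), 0)  # first-passage dominates occupancy
})

test_that("a parameter sweep is deterministic and sampling error shrinks with N", {
  p <- canonical_params(gamma = 1.0, alpha = 0.06, epsilon = 0.02)
  proto <- stim_noisy_constant(0.06, 0.02)
  tab1 <- sweep_ensemble("epsilon", c(0.02, 0.2), p, proto, N = 25,
                         t_end = 40, base_seed = 5)
  tab2 <- sweep_ensemble("epsilon", c(0.02, 0.2), p, proto, N = 25,
                         t_end = 40, base_seed = 5)
  expect_identical(tab1, tab2)
  # two ensemble sizes agree within the binomial 99% interval
  rsmall <- run_ensemble(100, p, proto, t_end = 40, base_seed = 11)
  rbig <- run_ensemble(400, p, proto, t_end = 40, base_seed = 2000)
  se <- sqrt(rbig$F_s * (1 - rbig$F_s) * (1 / 100 + 1 / 400))
  expect_lt(abs(rsmall$F_s - rbig$F_s), 2.58 * se + 1e-12)
})

test_that("the transition threshold tracks the separatrix proxy", {
  p <- canonical_params(gamma = 1.0, alpha = 0.06)
  ss <- solve_steady_states(p)$states
  expect_equal(transition_threshold(p), ss[[2]]$phi_star)
  # without a middle branch the off/on midpoint is used
  pf <- canonical_params(gamma = 0, alpha = 0.02)
  ssf <- solve_steady_states(pf)$states
  expect_length(ssf, 3)
  # single fixed point: threshold undefined
  pm <- dimensionless_params(alpha = 0.2, kappa = 1)
  expect_error(transition_threshold(pm), "undefined")
})
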