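test_that("a monostable sweep has one branch and no bifurcation points", {
  p <- dimensionless_params(alpha = 0.02, kappa = 1.0, gamma = 1.0)
  d <- sweep_alpha(p, seq(0, 0.25, length.out = 60))
  counts <- vapply(d$sets, function(s) length(s$states), 0L)
  expect_true(all(counts == 1))
  expect_length(d$saddle_nodes, 0)
  expect_length(d$hopf_points, 0)
  expect_identical(d$switch_character, "monostable")
})

test_that("saddle-node pairs enclose the three-root interval and match a dense scan", {
  p <- canonical_params(gamma = 1.5, epsilon = 0.5)
  d <- sweep_alpha(p)
  expect_length(d$saddle_nodes, 2)
  sn <- sort(vapply(d$saddle_nodes, function(b) b$alpha_at, 0))
  counts <- vapply(d$sets, function(s) length(s$states), 0L)
  inside <- d$alpha_grid > sn[1] & d$alpha_grid < sn[2]
  expect_true(all(counts[inside] == 3))
  expect_true(all(counts[!inside] == 1))
  expect_true(all(vapply(d$saddle_nodes, function(b) b$bracket_width, 0)
                  <= 1e-8))
  # independent dense scan of the root count
  dense <- seq(0, 0.25, length.out = 1e4)
  nd <- vapply(dense, function(a)
    length(solve_steady_states(p, a)$states), 0L)
  changes <- dense[which(diff(nd) != 0)]
  expect_equal(sort(changes), sn, tolerance = 1e-3)
  # the Jacobian is singular at the merging pair
  for (b in d$saddle_nodes) {
    mu <- mu_of_phi_steady(b$phi_at, p)
    J <- model_jacobian(c(b$phi_at, mu),
                        dimensionless_params(alpha = b$alpha_at,
                                             beta = p$beta, kappa = p$kappa,
                                             gamma = p$gamma,
                                             epsilon = p$epsilon))
    expect_lt(abs(det(J)), 1e-3)
  }
})

test_that("Hopf pairs are found on complex branches and match a dense eigenvalue scan", {
  p <- canonical_params(gamma = 1.6)
  d <- sweep_alpha(p)
  expect_length(d$hopf_points, 2)
  hb <- sort(vapply(d$hopf_points, function(b) b$alpha_at, 0))
  # dense scan of the leading real part on the unique branch
  dense <- seq(0.1365, 0.25, length.out = 1e4)
  re <- vapply(dense, function(a) {
    ss <- solve_steady_states(p, a)$states
    if (length(ss) != 1) return(NA_real_)
    max(Re(ss[[1]]$eigenvalues))
  }, 0)
  cross <- dense[which(diff(sign(re)) != 0)]
  expect_equal(hb[2], cross[length(cross)], tolerance = 1e-3)
  # no Hopf without the miRNA loop
  d0 <- sweep_alpha(canonical_params(gamma = 0))
  expect_length(d0$hopf_points, 0)
})

test_that("switch character distinguishes one-way, bistable and monostable", {
  expect_identical(switch_character(canonical_params(gamma = 0)),
                   "one_way_switch")
  expect_identical(switch_character(canonical_params(gamma = 1.0)),
                   "one_way_switch")
  expect_identical(switch_character(canonical_params(gamma = 1.5)),
                   "bistable_switch")
  expect_identical(
    switch_character(dimensionless_params(alpha = 0.02, kappa = 1.0)),
    "monostable")
})

test_that("increasing positive feedback stages monostable -> bistable -> one-way", {
  kappas <- seq(1, 6, length.out = 26)
  labs <- vapply(kappas, function(k)
    switch_character(dimensionless_params(alpha = 0.02, kappa = k,
                                          gamma = 1.5)), "")
  stages <- rle(labs)$values
  expect_identical(stages,
                   c("monostable", "bistable_switch", "one_way_switch"))
})

test_that("miRNA inhibition widens the bistable-switch window in kappa", {
  kappas <- seq(1, 6, length.out = 101)
  width <- function(gamma) {
    labs <- vapply(kappas, function(k)
      switch_character(dimensionless_params(alpha = 0.02, kappa = k,
                                            gamma = gamma)), "")
    sum(labs == "bistable_switch")
  }
  expect_gt(width(1.5), width(0))
})

test_that("regime classification covers the four behaviours", {
  expect_identical(pointwise_regime(canonical_params(gamma = 1.0)),
                   "bistable")
  expect_identical(pointwise_regime(canonical_params(gamma = 1.2)),
                   "excitable")
  expect_identical(pointwise_regime(canonical_params(gamma = 1.6,
                                                     alpha = 0.15)),
                   "oscillatory")
  expect_identical(pointwise_regime(dimensionless_params(alpha = 0.1,
                                                         kappa = 0)),
                   "monostable")
})

test_that("regime labels agree with a multi-start simulation oracle", {
  set.seed(202)
  tested <- 0
  for (p in random_params(40)) {
    if (tested >= 15) break
    lab <- pointwise_regime(p)
    if (lab == "unclassified") next
    # long integrations from scattered initial conditions plus a start near
    # each stable fixed point (scattered starts alone can all fall into one
    # basin)
    starts <- list(c(0, 0), c(0.5, 0.5), c(3, 1), c(1, 3), c(5, 5))
    for (s in solve_steady_states(p)$states)
      if (startsWith(s$stability, "stable"))
        starts <- c(starts, list(c(s$phi_star, s$mu_star) + 1e-3))
    finals <- vapply(starts,
                     function(x0) {
                       tr <- integrate_rk4(x0, p, stim_constant(p$alpha),
                                           t_end = 400, dt = 0.01,
                                           thin = 100L)
                       tr$phi[length(tr$phi)]
                     }, 0)
    n_attract <- length(unique(round(finals, 2)))
    if (lab == "bistable") expect_gte(n_attract, 2)
    if (lab == "monostable") {
      # all starts converge to fixed points (possibly the same one)
      ssphi <- vapply(solve_steady_states(p)$states,
                      function(s) s$phi_star, 0)
      expect_true(all(vapply(finals, function(f)
        min(abs(f - ssphi)) < 1e-2, TRUE)))
    }
    tested <- tested + 1
  }
  expect_gte(tested, 10)
})

test_that("two-parameter maps are label-consistent and gamma = 0 rows are switch-only", {
  # kappa-alpha plane without the miRNA loop: no excitable or oscillatory
  # cells anywhere
  pd <- phase_diagram("alpha", "kappa",
                      seq(0.001, 0.25, length.out = 40),
                      seq(0.5, 5, length.out = 40),
                      canonical_params(gamma = 0), boundaries = TRUE)
  expect_false(any(pd$labels %in% c("excitable", "oscillatory")))
  expect_true(all(pd$labels %in% c("monostable", "bistable")))
  # every boundary point separates two distinct labels
  if (nrow(pd$boundary_points))
    expect_true(all(pd$boundary_points$label_low !=
                      pd$boundary_points$label_high))
})

test_that("hysteresis jumps bracket the folds and vanish without bistability", {
  # bistable switch: jump locations within 2% of the fold locations
  p <- canonical_params(gamma = 1.5, epsilon = 0.5)
  d <- sweep_alpha(p)
  sn <- sort(vapply(d$saddle_nodes, function(b) b$alpha_at, 0))
  hl <- hysteresis_loop(p)
  expect_lt(abs(hl$jump_up_alpha - sn[2]) / sn[2], 0.02)
  expect_lt(abs(hl$jump_down_alpha - sn[1]) / sn[1], 0.02)
  # monostable: traces coincide, no jumps
  pm <- dimensionless_params(alpha = 0.02, kappa = 1.0)
  hm <- hysteresis_loop(pm, rate = 5e-5)
  expect_true(is.na(hm$jump_up_alpha) && is.na(hm$jump_down_alpha))
  expect_lt(max(abs(hm$up$phi - rev(hm$down$phi))), 1e-3)
  # one-way switch: the down sweep never returns within the physical range
  po <- canonical_params(gamma = 0)
  ho <- hysteresis_loop(po, rate = 5e-5)
  expect_false(is.na(ho$jump_up_alpha))
  expect_true(is.na(ho$jump_down_alpha))
})
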