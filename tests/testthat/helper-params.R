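# Canonical parameter sets used across the suite.  The package defaults
# (kappa = 3.5, beta = 0.2, epsilon = 0.1, alpha in [0, 0.25]) are the
# worked-example conditions of the package; gamma is the knob that moves the
# system through one-way switch, bistable, excitable and oscillatory
# behaviour.
canonical_params <- function(gamma, alpha = 0.02, epsilon = 0.1, ...) {
  dimensionless_params(alpha = alpha, gamma = gamma, epsilon = epsilon, ...)
}

# random valid parameter draws for property-style tests; ranges stay inside
# the physically sensible windows (kappa below the strongly one-way regime
# cap, modest gamma, epsilon away from 0)
random_params <- function(n, alpha_max = 0.25) {
  lapply(seq_len(n), function(i) {
    dimensionless_params(alpha = runif(1, 0, alpha_max),
                         beta = runif(1, 0, 1),
                         kappa = runif(1, 0, 5),
                         gamma = runif(1, 0, 2),
                         epsilon = runif(1, 0.05, 1),
                         alpha_range = c(0, alpha_max))
  })
}

# independent dense-grid bracketing oracle for the fixed points: sign
# changes of the scalar steady-state function h(phi) on a fine grid, with
# bisection refinement of each bracket
oracle_roots <- function(p, alpha = p$alpha, n_grid = 1e5) {
  h <- function(phi) {
    mu <- phi + p$beta
    alpha + p$kappa * phi^2 / (1 + phi^2 + p$gamma * mu) - phi
  }
  phi_cap <- 10 * max(p$alpha_range[2], p$kappa, 1)
  grid <- seq(0, phi_cap, length.out = n_grid)
  hv <- h(grid)
  roots <- numeric(0)
  if (abs(hv[1]) < 1e-12) roots <- c(roots, grid[1])
  idx <- which(hv[-1] * hv[-n_grid] < 0)
  for (i in idx) {
    lo <- grid[i]; hi <- grid[i + 1]
    for (k in 1:60) {
      mid <- (lo + hi) / 2
      if (h(lo) * h(mid) <= 0) hi <- mid else lo <- mid
    }
    roots <- c(roots, (lo + hi) / 2)
  }
  sort(roots)
}
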