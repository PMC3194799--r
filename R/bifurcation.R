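#' One-parameter bifurcation sweep along the stimulus axis
#'
#' Re-solves the full fixed-point problem at every grid value of the
#' stimulus \eqn{\alpha} (the steady-state problem is a scalar cubic, so a
#' global dense re-solve is cheap and cannot lose branches), links branches
#' between adjacent grid points by nearest-\eqn{\phi} matching, then locates
#' saddle-node and Hopf bifurcations by bisection and attaches the switch
#' character of the parameter set.
#'
#' @param p a \code{\link{dimensionless_params}} object.
#' @param alpha_grid ascending stimulus grid with at least 50 points;
#'   defaults to 201 points over \code{p$alpha_range}.  Values outside the
#'   physical range are allowed (and needed to diagnose one-way switches).
#' @return A \code{"branch_diagram"} object with the per-\eqn{\alpha} root
#'   sets (long-format data frame), the located \code{"bifurcation_point"}
#'   list, and the switch-character label.
#' @examples
#' sweep_alpha(dimensionless_params(gamma = 1.6))
#' @export
sweep_alpha <- function(p, alpha_grid = NULL) {
  stopifnot(inherits(p, "dimensionless_params"))
  if (is.null(alpha_grid))
    alpha_grid <- seq(p$alpha_range[1], p$alpha_range[2], length.out = 201)
  if (length(alpha_grid) < 50 || is.unsorted(alpha_grid, strictly = TRUE))
    stop("'alpha_grid' must be ascending with >= 50 points", call. = FALSE)
  sets <- lapply(alpha_grid, function(a) solve_steady_states(p, alpha = a))
  tab <- do.call(rbind, lapply(sets, as.data.frame))
  d <- structure(list(alpha_grid = alpha_grid, sets = sets, table = tab,
                      params = p),
                 class = "branch_diagram")
  d$saddle_nodes <- locate_saddle_nodes(d)
  d$hopf_points <- locate_hopf(d)
  d$switch_character <- switch_character(p)
  d
}

#' @export
print.branch_diagram <- function(x, ...) {
  cat(sprintf("Branch diagram over alpha in [%g, %g] (%d points)\n",
              min(x$alpha_grid), max(x$alpha_grid), length(x$alpha_grid)))
  cat(sprintf("  switch character: %s\n", x$switch_character))
  cat(sprintf("  saddle-node points: %d; Hopf points: %d\n",
              length(x$saddle_nodes), length(x$hopf_points)))
  for (b in c(x$saddle_nodes, x$hopf_points))
    cat(sprintf("    %s at alpha = %.6g (phi = %.6g)\n", b$kind, b$alpha_at,
                b$phi_at))
  invisible(x)
}

new_bif_point <- function(kind, alpha_at, phi_at, bracket_width)
  structure(list(kind = kind, alpha_at = alpha_at, phi_at = phi_at,
                 bracket_width = bracket_width), class = "bifurcation_point")

root_count <- function(p, alpha) length(solve_steady_states(p, alpha)$states)

#' Locate saddle-node bifurcations of a sweep
#'
#' Each change in fixed-point count between adjacent grid values is
#' bracketed and bisected on \eqn{\alpha} to an interval of at most
#' \code{1e-8}; the merging root pair gives the fold's \eqn{\phi} location,
#' at which the Jacobian is singular.
#'
#' @param d a \code{"branch_diagram"} from \code{\link{sweep_alpha}}.
#' @return List of \code{"bifurcation_point"} objects of kind
#'   \code{"saddle_node"}.
#' @export
locate_saddle_nodes <- function(d) {
  stopifnot(inherits(d, "branch_diagram"))
  p <- d$params
  counts <- vapply(d$sets, function(s) length(s$states), 0L)
  out <- list()
  for (i in which(diff(counts) != 0)) {
    lo <- d$alpha_grid[i]; hi <- d$alpha_grid[i + 1]
    n_lo <- counts[i]
    while (hi - lo > 1e-8) {
      mid <- (lo + hi) / 2
      if (root_count(p, mid) == n_lo) lo <- mid else hi <- mid
    }
    side <- if (counts[i] > counts[i + 1]) lo else hi
    roots <- vapply(solve_steady_states(p, side)$states,
                    function(s) s$phi_star, 0)
    phi_at <- if (length(roots) >= 2)
      mean(roots[order(diff(roots))[1] + 0:1]) else roots[1]
    out <- c(out, list(new_bif_point("saddle_node", (lo + hi) / 2, phi_at,
                                     hi - lo)))
  }
  out
}

# max real part of the eigenvalue pair of the branch point nearest phi_near,
# plus its imaginary part and phi; used for Hopf tracking along a branch
branch_eig <- function(p, alpha, phi_near) {
  ss <- solve_steady_states(p, alpha)$states
  phis <- vapply(ss, function(s) s$phi_star, 0)
  s <- ss[[which.min(abs(phis - phi_near))]]
  i <- which.max(Re(s$eigenvalues))
  list(re = Re(s$eigenvalues[i]), im = abs(Im(s$eigenvalues[i])),
       phi = s$phi_star)
}

#' Locate Hopf bifurcations of a sweep
#'
#' Follows each linked branch across the grid and bisects every sign change
#' of the maximal real part of a complex-conjugate eigenvalue pair to an
#' \eqn{\alpha} interval of at most \code{1e-8}.  Crossings whose imaginary
#' part is below \code{1e-6} (degenerate real crossings) are excluded.
#'
#' @param d a \code{"branch_diagram"} from \code{\link{sweep_alpha}}.
#' @return List of \code{"bifurcation_point"} objects of kind \code{"hopf"}.
#' @export
locate_hopf <- function(d) {
  stopifnot(inherits(d, "branch_diagram"))
  p <- d$params
  out <- list()
  for (i in seq_len(length(d$alpha_grid) - 1)) {
    s_lo <- d$sets[[i]]$states
    for (s in s_lo) {
      e_lo <- branch_eig(p, d$alpha_grid[i], s$phi_star)
      e_hi <- branch_eig(p, d$alpha_grid[i + 1], e_lo$phi)
      if (!(e_lo$im > 1e-12 || e_hi$im > 1e-12)) next
      if (sign(e_lo$re) == sign(e_hi$re) || e_lo$re == 0) next
      lo <- d$alpha_grid[i]; hi <- d$alpha_grid[i + 1]
      phi_track <- e_lo$phi
      re_lo <- e_lo$re
      while (hi - lo > 1e-8) {
        mid <- (lo + hi) / 2
        e_mid <- branch_eig(p, mid, phi_track)
        if (sign(e_mid$re) == sign(re_lo)) {
          lo <- mid; phi_track <- e_mid$phi; re_lo <- e_mid$re
        } else hi <- mid
      }
      e_at <- branch_eig(p, (lo + hi) / 2, phi_track)
      if (e_at$im > 1e-6)
        out <- c(out, list(new_bif_point("hopf", (lo + hi) / 2, e_at$phi,
                                         hi - lo)))
    }
  }
  # the same crossing can be reached from both branch endpoints; de-duplicate
  if (length(out) > 1) {
    keep <- !duplicated(round(vapply(out, function(b) b$alpha_at, 0), 6))
    out <- out[keep]
  }
  out
}

#' Switch character of a parameter set
#'
#' Scans the stimulus over an extended window (reaching below the physical
#' minimum, where the deactivating fold of a one-way switch hides) for the
#' interval enclosed by the two saddle-nodes, where three fixed-point
#' branches coexist.  No such interval gives
#' \code{monostable}; an interval whose lower (deactivating) fold lies at or
#' above the physical minimum gives \code{bistable_switch} (a fold exactly
#' at the boundary counts as bistable, the documented tie-break); a
#' deactivating fold below the physical minimum gives
#' \code{one_way_switch}: within the admissible stimulus range the on-state
#' can never be exited.
#'
#' @param p a \code{\link{dimensionless_params}} object (its
#'   \code{alpha_range} defines the physical window).
#' @param n_scan scan resolution.
#' @return One of \code{"monostable"}, \code{"bistable_switch"},
#'   \code{"one_way_switch"}.
#' @export
switch_character <- function(p, n_scan = 400) {
  stopifnot(inherits(p, "dimensionless_params"))
  amin <- p$alpha_range[1]; amax <- p$alpha_range[2]
  # the fold structure is diagnosed on the raw steady-state curve, without
  # the physicality clamp: the off-root crossing phi = 0 is not a fold, and
  # the deactivating fold of a one-way switch lies at negative stimulus
  # where the off-root is unphysical.  The switch taxonomy is fold-based:
  # the bistable interval is the stimulus window enclosed by the two
  # saddle-nodes (three coexisting branches), independent of whether a Hopf
  # instability additionally affects the upper branch.
  three_roots <- function(a) {
    if (p$kappa == 0) return(FALSE)
    length(cubic_real_roots(steady_poly_coef(p, a))) >= 3
  }
  ext <- max(5 * (amax - amin), 1)
  grid <- seq(amin - ext, amax, length.out = n_scan)
  bist <- vapply(grid, three_roots, TRUE)
  if (!any(bist)) return("monostable")
  i_first <- which(bist)[1]
  if (i_first == 1) return("one_way_switch")  # still bistable at scan edge
  # bisect the deactivating fold between the last monostable and first
  # bistable grid point
  lo <- grid[i_first - 1]; hi <- grid[i_first]
  while (hi - lo > 1e-8) {
    mid <- (lo + hi) / 2
    if (three_roots(mid)) hi <- mid else lo <- mid
  }
  fold_lo <- (lo + hi) / 2
  if (fold_lo >= amin - 1e-8) "bistable_switch" else "one_way_switch"
}

#' Dynamical regime at a fixed stimulus
#'
#' Classifies the regime at the configured stimulus \code{p$alpha}: two
#' stable fixed points give \code{bistable}; one stable plus two unstable
#' fixed points where a standard test pulse (rectangular, amplitude 0.16
#' above base, 5 time units) elicits a large excursion above the unstable
#' middle branch followed by recovery to within \code{1e-3} of rest gives
#' \code{excitable}; no stable fixed point with a verified sustained limit
#' cycle gives \code{oscillatory}; otherwise \code{monostable}.  A
#' simulation probe that fails to settle within the time cap returns
#' \code{unclassified} rather than a silent guess.
#'
#' @param p a \code{\link{dimensionless_params}} object.
#' @param pulse_amplitude test-pulse height for the excitability probe.
#' @param pulse_duration test-pulse duration (time units).
#' @param t_settle post-pulse settling window for the excitability probe;
#'   \code{NULL} (default) scales it with the off-state's relaxation time
#'   (capped at 5000 time units), so weakly damped rest states near the
#'   oscillatory boundary are given time to ring down.
#' @param t_osc integration span of the oscillation probe (the first half is
#'   discarded; at least 3 peaks with period dispersion below 5% and
#'   amplitude above \code{1e-3} are required).
#' @param dt integrator step.
#' @return One of \code{"monostable"}, \code{"bistable"},
#'   \code{"excitable"}, \code{"oscillatory"}, \code{"unclassified"}.
#' @export
pointwise_regime <- function(p, pulse_amplitude = 0.16, pulse_duration = 5,
                             t_settle = NULL, t_osc = 1200, dt = 0.01) {
  stopifnot(inherits(p, "dimensionless_params"))
  ss <- solve_steady_states(p)
  ns <- n_stable(ss)
  nn <- length(ss$states)
  if (ns >= 2) return("bistable")
  if (ns == 1 && nn == 3) {
    # excitability requires the single stable state to be the off branch;
    # when only the on-state is stable the system just relaxes upward
    stable_idx <- which(vapply(ss$states, function(s)
      startsWith(s$stability, "stable"), TRUE))
    if (stable_idx != 1L) return("monostable")
    # pulse probe from the off-state rest
    rest <- c(ss$states[[1]]$phi_star, ss$states[[1]]$mu_star)
    if (is.null(t_settle)) {
      decay <- abs(max(Re(ss$states[[1]]$eigenvalues)))
      t_settle <- min(5000, max(600, 14 / max(decay, 1e-6)))
    }
    proto <- stim_pulse(p$alpha, pulse_amplitude, t_on = 20,
                        t_off = 20 + pulse_duration)
    tr <- integrate_rk4(rest, p, proto, t_end = 20 + pulse_duration +
                          t_settle, dt = dt, thin = 10L)
    phi_mid <- ss$states[[2]]$phi_star
    n <- length(tr$phi)
    tail_win <- tr$phi[tr$t >= max(tr$t) - 20]
    settled <- diff(range(tail_win)) < 1e-4
    excursion <- max(tr$phi) > phi_mid
    recovered <- abs(tr$phi[n] - rest[1]) < 1e-3
    if (!settled) {
      # near the oscillatory border a stable limit cycle can coexist with
      # the weakly stable rest state; a pulse then leaves the system in
      # sustained spiking rather than returning to rest.  Label such cells
      # by their verified post-pulse behaviour.
      om <- try(oscillation_metrics_core(tr$t[tr$t > 25], tr$phi[tr$t > 25],
                                         dispersion_tol = 0.25),
                silent = TRUE)
      if (!inherits(om, "try-error") && isTRUE(om$sustained))
        return("oscillatory")
      return("unclassified")
    }
    if (excursion && recovered) return("excitable")
    return("monostable")
  }
  if (ns == 0) {
    # candidate oscillatory: integrate from a nudge off the unique fixed
    # point, large enough that a weakly unstable focus near a Hopf boundary
    # still reaches its limit cycle within the probe span
    s1 <- ss$states[[1]]
    x0 <- c(s1$phi_star * 1.05 + 0.05, s1$mu_star)
    tr <- integrate_rk4(x0, p, stim_constant(p$alpha), t_end = t_osc,
                        dt = dt, thin = 10L)
    om <- try(oscillation_metrics_core(tr$t, tr$phi), silent = TRUE)
    if (!inherits(om, "try-error") && isTRUE(om$sustained))
      return("oscillatory")
    return("unclassified")
  }
  "monostable"
}

#' Two-parameter regime map
#'
#' Evaluates \code{\link{pointwise_regime}} (or
#' \code{\link{switch_character}}) on a rectangular grid in any two model
#' parameters and extracts regime-boundary points by per-column bisection
#' between cells of differing label.
#'
#' @param x_param,y_param parameter names (one of \code{"alpha"},
#'   \code{"beta"}, \code{"kappa"}, \code{"gamma"}, \code{"epsilon"}).
#' @param x_grid,y_grid ascending grids, at least 40 points each.
#' @param fixed a \code{\link{dimensionless_params}} object providing the
#'   remaining parameters.
#' @param classifier \code{"regime"} (four dynamical regimes) or
#'   \code{"switch"} (monostable / bistable switch / one-way switch).
#' @param boundaries logical: extract boundary curves by bisection.
#' @param ... passed to the pointwise classifier.
#' @return A \code{"phase_diagram2d"} object: label matrix (rows = y,
#'   columns = x), grids, fixed parameters, and a data frame of boundary
#'   points.
#' @export
phase_diagram <- function(x_param, y_param, x_grid, y_grid, fixed,
                          classifier = c("regime", "switch"),
                          boundaries = TRUE, ...) {
  classifier <- match.arg(classifier)
  stopifnot(inherits(fixed, "dimensionless_params"))
  pnames <- c("alpha", "beta", "kappa", "gamma", "epsilon")
  if (!x_param %in% pnames || !y_param %in% pnames || x_param == y_param)
    stop("'x_param' and 'y_param' must be distinct model parameter names",
         call. = FALSE)
  if (length(x_grid) < 40 || length(y_grid) < 40)
    stop("grids must have at least 40 points", call. = FALSE)
  clf <- function(x, y) {
    p <- fixed
    p[[x_param]] <- x
    p[[y_param]] <- y
    if (classifier == "regime") pointwise_regime(p, ...)
    else switch_character(p, ...)
  }
  lab <- matrix(NA_character_, nrow = length(y_grid), ncol = length(x_grid))
  for (j in seq_along(x_grid))
    for (i in seq_along(y_grid))
      lab[i, j] <- clf(x_grid[j], y_grid[i])
  bpts <- NULL
  if (boundaries) {
    rows <- list()
    for (j in seq_along(x_grid)) {
      for (i in seq_len(length(y_grid) - 1)) {
        l1 <- lab[i, j]; l2 <- lab[i + 1, j]
        if (identical(l1, l2)) next
        lo <- y_grid[i]; hi <- y_grid[i + 1]
        for (k in 1:12) {
          mid <- (lo + hi) / 2
          if (identical(clf(x_grid[j], mid), l1)) lo <- mid else hi <- mid
        }
        kind <- if (any(c(l1, l2) == "oscillatory")) "hopf" else "saddle_node"
        rows[[length(rows) + 1]] <-
          data.frame(x = x_grid[j], y = (lo + hi) / 2, label_low = l1,
                     label_high = l2, kind = kind)
      }
    }
    bpts <- if (length(rows)) do.call(rbind, rows) else
      data.frame(x = numeric(0), y = numeric(0), label_low = character(0),
                 label_high = character(0), kind = character(0))
  }
  structure(list(x_param = x_param, y_param = y_param, x_grid = x_grid,
                 y_grid = y_grid, fixed = fixed, labels = lab,
                 boundary_points = bpts, classifier = classifier),
            class = "phase_diagram2d")
}

#' @export
print.phase_diagram2d <- function(x, ...) {
  cat(sprintf("Regime map: %s x %s (%d x %d grid), classifier '%s'\n",
              x$x_param, x$y_param, length(x$x_grid), length(x$y_grid),
              x$classifier))
  print(table(x$labels))
  invisible(x)
}

#' Quasi-static hysteresis sweep
#'
#' Ramps the stimulus linearly up across the physical window and back down,
#' slowly relative to both relaxation timescales, and reports the stimulus
#' values at which the occupied branch jumps.  In a bistable-switch regime
#' the up and down transitions differ and bracket the two fold locations;
#' in a one-way switch the down-sweep never returns within the physical
#' window; in a monostable regime the two traces coincide.
#'
#' @param p a \code{\link{dimensionless_params}} object.
#' @param rate ramp speed (stimulus units per time unit); the default is
#'   slow enough that fold passage delays stay well under 2% of the fold
#'   location.
#' @param dt integrator step.
#' @return A list with the up/down \code{"trajectory"}-like data frames and
#'   \code{jump_up_alpha} / \code{jump_down_alpha} (NA when no jump occurs).
#' @export
hysteresis_loop <- function(p, rate = 1e-5, dt = 0.01) {
  stopifnot(inherits(p, "dimensionless_params"))
  amin <- p$alpha_range[1]; amax <- p$alpha_range[2]
  t_ramp <- (amax - amin) / rate
  x0 <- rest_state(p, amin)
  up <- integrate_ramp_cpp(x0[1], x0[2], p$beta, p$kappa, p$gamma, p$epsilon,
                           amin, amax, t_ramp, dt, 100L)
  nu <- length(up$t)
  dn <- integrate_ramp_cpp(up$phi[nu], up$mu[nu], p$beta, p$kappa, p$gamma,
                           p$epsilon, amax, amin, t_ramp, dt, 100L)
  # a branch jump shows up as a fast change of phi between successive
  # samples; quasi-static drift along a branch scales with the ramp rate and
  # is orders of magnitude slower, so the detection threshold scales with it
  jump_tol <- max(0.02, 1000 * rate * dt * 100)
  find_jump <- function(alpha, phi) {
    idx <- which(abs(diff(phi)) > jump_tol)
    if (!length(idx)) return(NA_real_)
    alpha[idx[1]]
  }
  list(up = data.frame(t = up$t, alpha = up$alpha, phi = up$phi, mu = up$mu),
       down = data.frame(t = dn$t, alpha = dn$alpha, phi = dn$phi,
                         mu = dn$mu),
       jump_up_alpha = find_jump(up$alpha, up$phi),
       jump_down_alpha = find_jump(dn$alpha, dn$phi))
}
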