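#' Stochastic fixed-step integration under stimulus noise
#'
#' Integrates the model under a noisy stimulus protocol: the deterministic
#' drift advances with the classical fourth-order Runge-Kutta stages while
#' the Gaussian stimulus fluctuation enters the protein equation as an
#' additive increment \eqn{\sigma\sqrt{dt}\,z_i} per step (exact sampling of
#' the Wiener contribution for additive noise).  With zero noise variance
#' the scheme reduces bitwise to \code{\link{integrate_rk4}}.  Transiently
#' negative states are clamped at zero and counted; the fluctuating input
#' itself is never clipped.
#'
#' @inheritParams integrate_rk4
#' @param protocol a noisy \code{\link{stimulus_protocol}}
#'   (\code{stim_noisy_step} or \code{stim_noisy_constant}); deterministic
#'   protocols are accepted and integrate deterministically.
#' @param dt step size; the stochastic default is 0.002.
#' @param seed integer seed for the noise stream (defaults to the
#'   protocol's).
#' @return A \code{"trajectory"} object (metadata records scheme, dt, seed,
#'   noise variance and clamp count).
#' @export
integrate_srk4 <- function(initial, p, protocol, t_end, dt = 0.002,
                           thin = 1L, seed = protocol$seed) {
  stopifnot(inherits(p, "dimensionless_params"),
            inherits(protocol, "stimulus_protocol"))
  run_integrator(initial, p, protocol, t_end, dt, thin,
                 sigma2 = protocol$noise_variance, seed = seed)
}

#' Transition threshold for noise-induced switching
#'
#' A cell counts as having switched off when its protein level first falls
#' below the unstable middle-branch fixed point at the deterministic
#' operating stimulus (a separatrix proxy); when no middle branch exists
#' the midpoint of the off- and on-state protein levels is used instead.
#'
#' @param p a \code{\link{dimensionless_params}} object.
#' @param alpha operating stimulus (defaults to \code{p$alpha}).
#' @return The threshold protein level.
#' @export
transition_threshold <- function(p, alpha = p$alpha) {
  ss <- solve_steady_states(p, alpha)$states
  if (length(ss) == 3) return(ss[[2]]$phi_star)
  if (length(ss) >= 2) return((ss[[1]]$phi_star +
                                 ss[[length(ss)]]$phi_star) / 2)
  stop("transition threshold undefined: single fixed point at the ",
       "operating stimulus", call. = FALSE)
}

#' Stochastic ensemble of cells under a common noisy stimulus
#'
#' Runs \code{N} independent realisations ("cells"), all started at the
#' on-state fixed point of the operating stimulus, each with its own noise
#' stream (seed \code{base_seed + cell index}).  The fraction of transition
#' \eqn{F(t)} is the share of cells whose protein level has crossed the
#' transition threshold at least once by time \eqn{t} (first-passage
#' definition, so \eqn{F} is nondecreasing); the instantaneous-occupancy
#' variant is available via \code{rule = "occupancy"}.
#'
#' @param N number of cells, >= 1.
#' @param p a \code{\link{dimensionless_params}} object; the operating
#'   stimulus must admit an on-state.
#' @param protocol a noisy \code{\link{stimulus_protocol}}.
#' @param t_end,dt integration settings (stochastic default dt = 0.002).
#' @param base_seed integer; cell \eqn{i} uses \code{base_seed + i}.
#' @param rule \code{"first_passage"} (default) or \code{"occupancy"}.
#' @param f_grid_dt spacing of the time grid on which \eqn{F(t)} is
#'   reported.
#' @return An \code{"ensemble_result"}: \code{t}, \code{F}, per-cell
#'   \code{first_transition_times} (NA when never), plateau fraction
#'   \code{F_s} with convergence flag, and response time \code{T_R}.
#' @examples
#' \donttest{
#' p <- dimensionless_params(alpha = 0.06, gamma = 0.6)
#' res <- run_ensemble(50, p, stim_noisy_constant(0.06, 0.004), t_end = 50)
#' res
#' }
#' @export
run_ensemble <- function(N, p, protocol, t_end, dt = 0.002, base_seed = 1L,
                         rule = c("first_passage", "occupancy"),
                         f_grid_dt = 0.5) {
  rule <- match.arg(rule)
  stopifnot(N >= 1, inherits(p, "dimensionless_params"),
            inherits(protocol, "stimulus_protocol"))
  ss <- solve_steady_states(p, protocol$base_level)$states
  on <- Filter(function(s) s$branch == "on" &&
                 startsWith(s$stability, "stable"), ss)
  if (!length(on))
    stop("no stable on-state at the operating stimulus; ensemble protocol ",
         "requires a bistable configuration", call. = FALSE)
  x0 <- c(on[[1]]$phi_star, on[[1]]$mu_star)
  thr <- transition_threshold(p, protocol$base_level)
  t_grid <- seq(0, t_end, by = f_grid_dt)
  thin_occ <- max(1L, as.integer(round(f_grid_dt / dt)))
  first_cross <- numeric(N)
  occ <- if (rule == "occupancy")
    matrix(0, nrow = N, ncol = length(t_grid)) else NULL
  for (i in seq_len(N)) {
    tr <- run_integrator(x0, p, protocol, t_end, dt, thin = thin_occ,
                         sigma2 = protocol$noise_variance,
                         seed = base_seed + i, threshold = thr,
                         track_cross = TRUE)
    first_cross[i] <- tr$meta$first_cross
    if (rule == "occupancy")
      occ[i, ] <- approx(tr$t, tr$phi, xout = t_grid, rule = 2)$y < thr
  }
  first_cross[first_cross < 0] <- NA_real_
  Fcurve <- if (rule == "first_passage")
    vapply(t_grid, function(tt) mean(!is.na(first_cross) &
                                       first_cross <= tt), 0)
  else colMeans(occ)
  res <- structure(list(N = N, t = t_grid, F = Fcurve,
                        first_transition_times = first_cross,
                        params = p, protocol = protocol,
                        base_seed = as.integer(base_seed), rule = rule,
                        threshold = thr,
                        meta = list(scheme = "srk4-additive", dt = dt,
                                    sigma2 = protocol$noise_variance)),
                   class = "ensemble_result")
  sf <- steady_fraction(res)
  res$F_s <- sf$F_s
  res$plateau_converged <- sf$converged
  res$T_R <- tryCatch(response_time(res), error = function(e) NA_real_)
  res
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("Stochastic ensemble: N = %d cells, t_end = %g, sigma2 = %g\n",
              x$N, max(x$t), x$meta$sigma2))
  cat(sprintf("  transition rule: %s (threshold phi = %.4g)\n", x$rule,
              x$threshold))
  cat(sprintf("  F_s = %.3f%s, T_R = %s, %d/%d cells transitioned\n", x$F_s,
              if (x$plateau_converged) "" else " (plateau not converged)",
              if (is.na(x$T_R)) "NA" else sprintf("%.2f", x$T_R),
              sum(!is.na(x$first_transition_times)), x$N))
  invisible(x)
}

#' Fraction-of-transition curve
#'
#' @param result an \code{"ensemble_result"}.
#' @return Data frame with columns \code{t} and \code{F}.
#' @export
fraction_curve <- function(result) {
  stopifnot(inherits(result, "ensemble_result"))
  data.frame(t = result$t, F = result$F)
}

#' Plateau value of the fraction of transition
#'
#' The steady fraction \eqn{F_s} is the mean of \eqn{F(t)} over the final
#' 10% of the run; a plateau is accepted when the fitted slope over that
#' window is below \code{1e-4} per time unit, otherwise the value is
#' reported with a non-convergence flag.
#'
#' @param result an \code{"ensemble_result"}.
#' @return List with \code{F_s} and logical \code{converged}.
#' @export
steady_fraction <- function(result) {
  stopifnot(inherits(result, "ensemble_result"))
  n <- length(result$t)
  win <- result$t >= max(result$t) * 0.9
  Fw <- result$F[win]; tw <- result$t[win]
  slope <- if (length(Fw) > 2 && sd(tw) > 0)
    unname(stats::coef(stats::lm.fit(cbind(1, tw), Fw))[2]) else 0
  list(F_s = mean(Fw), converged = abs(slope) < 1e-4)
}

#' Response time of the ensemble
#'
#' The first time at which \eqn{F(t)} reaches the midpoint between its
#' initial and plateau values, linearly interpolated between samples.
#'
#' @param result an \code{"ensemble_result"} with \eqn{F_s > F(0)}.
#' @return The response time \eqn{T_R}.
#' @export
response_time <- function(result) {
  stopifnot(inherits(result, "ensemble_result"))
  F0 <- result$F[1]
  Fs <- if (!is.null(result$F_s)) result$F_s else steady_fraction(result)$F_s
  if (!(Fs > F0))
    stop("response time undefined: F never rises above its initial value",
         call. = FALSE)
  target <- (F0 + Fs) / 2
  idx <- which(result$F >= target)
  if (!length(idx))
    stop("F(t) never reaches the midpoint of its initial and plateau values",
         call. = FALSE)
  i <- idx[1]
  if (i == 1 || result$F[i] == target) return(result$t[i])
  t0 <- result$t[i - 1]; t1 <- result$t[i]
  F0i <- result$F[i - 1]; F1i <- result$F[i]
  t0 + (target - F0i) / (F1i - F0i) * (t1 - t0)
}

#' Ensemble statistics along a parameter grid
#'
#' Repeats \code{\link{run_ensemble}} at each value of one model parameter,
#' keeping the stimulus protocol fixed and offsetting the seed block per
#' grid point, and tabulates \eqn{F_s} and \eqn{T_R}.
#'
#' @param param parameter name to sweep (e.g. \code{"gamma"},
#'   \code{"epsilon"}).
#' @param grid parameter values.
#' @param fixed a \code{\link{dimensionless_params}} object for the
#'   remaining parameters.
#' @param protocol a noisy \code{\link{stimulus_protocol}}.
#' @param N cells per grid point.
#' @param t_end,dt integration settings.
#' @param base_seed integer; grid point \eqn{j} uses seed block
#'   \code{base_seed + (j-1) * N}.
#' @return Data frame with columns \code{param}, \code{value}, \code{F_s},
#'   \code{T_R}, \code{N}, \code{sigma2}, \code{seed}.
#' @export
sweep_ensemble <- function(param, grid, fixed, protocol, N = 200,
                           t_end = 100, dt = 0.002, base_seed = 1L) {
  stopifnot(inherits(fixed, "dimensionless_params"))
  rows <- lapply(seq_along(grid), function(j) {
    p <- fixed
    proto_j <- protocol
    if (param == "alpha") {
      # the operating stimulus is swept: the protocol must follow it
      if (!protocol$kind %in% c("constant", "noisy_constant"))
        stop("sweeping 'alpha' requires a constant-type protocol",
             call. = FALSE)
      proto_j$base_level <- proto_j$level <- grid[j]
    }
    p[[param]] <- grid[j]
    seed_j <- base_seed + (j - 1L) * N
    res <- run_ensemble(N, p, proto_j, t_end = t_end, dt = dt,
                        base_seed = seed_j)
    data.frame(param = param, value = grid[j], F_s = res$F_s,
               T_R = res$T_R, N = N, sigma2 = protocol$noise_variance,
               seed = seed_j)
  })
  do.call(rbind, rows)
}
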