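#' Deterministic fixed-step integration
#'
#' Integrates the dimensionless model with the classical fourth-order
#' Runge-Kutta scheme under a stimulus protocol.  The stimulus is evaluated
#' at the RK4 stage times with the protocol's right-continuous convention at
#' discontinuities.  State components pushed below zero are clamped and the
#' events counted in the trajectory metadata.
#'
#' @param initial numeric pair \code{c(phi, mu)}, or \code{NULL} to start at
#'   rest: the off-state fixed point at the protocol's base level.
#' @param p a \code{\link{dimensionless_params}} object.
#' @param protocol a \code{\link{stimulus_protocol}} with zero noise
#'   variance (use \code{\link{integrate_srk4}} for noisy protocols).
#' @param t_end final time, > 0.
#' @param dt step size, > 0; the default 0.01 changes desk-scale
#'   trajectories by less than 1e-6 when halved.
#' @param thin record every \code{thin}-th step.
#' @return A \code{"trajectory"} object: data columns \code{t},
#'   \code{alpha}, \code{phi}, \code{mu}, plus protocol and integrator
#'   metadata.
#' @examples
#' p <- dimensionless_params(alpha = 0.02, gamma = 1.0)
#' tr <- integrate_rk4(NULL, p, stim_pulse(0.02, 0.14, 20, 25), t_end = 100)
#' tr
#' @export
integrate_rk4 <- function(initial, p, protocol, t_end, dt = 0.01, thin = 1L) {
  stopifnot(inherits(p, "dimensionless_params"),
            inherits(protocol, "stimulus_protocol"))
  if (protocol$noise_variance > 0)
    stop("protocol carries noise; use integrate_srk4()", call. = FALSE)
  run_integrator(initial, p, protocol, t_end, dt, thin, sigma2 = 0,
                 seed = NULL)
}

run_integrator <- function(initial, p, protocol, t_end, dt, thin, sigma2,
                           seed, threshold = -1, track_cross = FALSE) {
  if (t_end <= 0 || dt <= 0) stop("'t_end' and 'dt' must be positive",
                                  call. = FALSE)
  if (is.null(initial)) initial <- rest_state(p, protocol$base_level)
  if (length(initial) != 2L || any(!is.finite(initial)) || any(initial < 0))
    stop("'initial' must be a non-negative pair c(phi, mu)", call. = FALSE)
  n_steps <- round(t_end / dt)
  z <- if (sigma2 > 0) noise_increments(n_steps, dt, sigma2, seed) else
    numeric(0)
  out <- integrate_core_cpp(initial[1], initial[2], p$beta, p$kappa, p$gamma,
                            p$epsilon, protocol_kind_code(protocol),
                            protocol$base_level, protocol$level,
                            protocol$t_on, protocol$t_off, t_end, dt,
                            sqrt(sigma2), z, as.integer(thin), threshold,
                            track_cross)
  structure(list(t = out$t, alpha = out$alpha, phi = out$phi, mu = out$mu,
                 protocol = protocol, params = p,
                 meta = list(scheme = if (sigma2 > 0) "srk4-additive" else
                   "rk4", dt = dt, thin = as.integer(thin),
                   seed = if (sigma2 > 0) as.integer(seed) else NULL,
                   sigma2 = sigma2, clamp_count = out$clamp_count,
                   first_cross = out$first_cross)),
            class = "trajectory")
}

# off-state fixed point at a given stimulus level ("rest at basal stimulus")
rest_state <- function(p, alpha = p$alpha) {
  ss <- solve_steady_states(p, alpha = alpha)$states[[1]]
  c(ss$phi_star, ss$mu_star)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d samples over [0, %g], scheme %s (dt = %g)\n",
              length(x$t), max(x$t), x$meta$scheme, x$meta$dt))
  cat(sprintf("  protocol: %s; final state phi = %.4g, mu = %.4g\n",
              x$protocol$kind, x$phi[length(x$phi)], x$mu[length(x$mu)]))
  if (x$meta$clamp_count > 0)
    cat(sprintf("  %d negative-state clamp event(s)\n", x$meta$clamp_count))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...)
  data.frame(t = x$t, alpha_t = x$alpha, phi = x$phi, mu = x$mu)

#' Classify the signal-response behaviour of a trajectory
#'
#' Labels a simulated response: \code{irreversible_switch} if, after the
#' stimulus returns to base, the system ends within tolerance of the
#' on-branch fixed point; \code{excitable_pulse} if a single large excursion
#' (peak \eqn{\phi} above the unstable middle-branch level) returns within
#' \code{1e-3} of the initial rest state; \code{sustained_oscillation} if
#' periodic peaks persist to the end of the run; \code{no_switch} otherwise;
#' \code{unclassified} when the trajectory has not settled.
#'
#' @param traj a \code{"trajectory"}.
#' @param p parameters used for branch references (defaults to the
#'   trajectory's own).
#' @return A single character label.
#' @export
classify_response <- function(traj, p = traj$params) {
  stopifnot(inherits(traj, "trajectory"))
  n <- length(traj$t)
  phi <- traj$phi
  base <- traj$protocol$base_level
  ss <- solve_steady_states(p, alpha = base)
  stable <- Filter(function(s) startsWith(s$stability, "stable"), ss$states)
  phi_stable <- vapply(stable, function(s) s$phi_star, 0)
  # oscillation first: sustained periodicity in the final half
  om <- try(oscillation_metrics_core(traj$t, phi), silent = TRUE)
  if (!inherits(om, "try-error") && om$sustained)
    return("sustained_oscillation")
  final <- phi[n]
  settle_win <- phi[traj$t >= max(traj$t) - 0.05 * max(traj$t)]
  if (diff(range(settle_win)) > 1e-3) return("unclassified")
  rest0 <- phi[1]
  mid <- Filter(function(s) s$branch == "middle", ss$states)
  phi_mid <- if (length(mid)) mid[[1]]$phi_star else NA_real_
  on <- Filter(function(s) s$branch == "on", ss$states)
  phi_on <- if (length(on)) on[[1]]$phi_star else NA_real_
  if (!is.na(phi_on) && abs(final - phi_on) < 1e-3 &&
      abs(rest0 - phi_on) > 1e-3)
    return("irreversible_switch")
  excursion <- !is.na(phi_mid) && max(phi) > phi_mid
  if (excursion && abs(final - rest0) < 1e-3) return("excitable_pulse")
  "no_switch"
}

# peak-based cycle detection shared by classify_response and
# oscillation_metrics; operates on the last half of the series
oscillation_metrics_core <- function(t, phi, min_cycles = 3,
                                     dispersion_tol = 0.05,
                                     amplitude_tol = 1e-3) {
  keep <- t >= max(t) / 2
  t <- t[keep]; phi <- phi[keep]
  n <- length(phi)
  if (n < 5) stop("series too short", call. = FALSE)
  up <- diff(phi) > 0
  peaks <- which(up[-length(up)] & !up[-1]) + 1
  troughs <- which(!up[-length(up)] & up[-1]) + 1
  amp <- if (length(peaks) && length(troughs))
    mean(phi[peaks]) - mean(phi[troughs]) else 0
  if (length(peaks) < min_cycles || amp < amplitude_tol)
    return(list(sustained = FALSE))
  periods <- diff(t[peaks])
  # judge regularity on the last cycles: an orbit still winding onto the
  # limit cycle carries period drift in its early cycles
  late <- utils::tail(periods, 5)
  dispersion <- sd(late) / mean(late)
  list(sustained = is.finite(dispersion) && dispersion < dispersion_tol,
       peaks = peaks, troughs = troughs, periods = periods,
       t = t, phi = phi, amplitude = amp)
}

#' Period, amplitude and waveform asymmetry of a limit cycle
#'
#' Measured on the last five complete cycles after discarding the first half
#' of the run as transient.  The rise time is the trough-to-peak duration
#' and the fall time the peak-to-trough duration; in the relaxation regime
#' the concentration builds up slowly and collapses quickly, so the
#' rise/fall ratio exceeds one.
#'
#' @param traj a \code{"trajectory"} classified as sustained oscillation.
#' @return A list with \code{period}, \code{amplitude} (peak-to-trough) and
#'   \code{rise_fall_ratio}.
#' @export
oscillation_metrics <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  om <- oscillation_metrics_core(traj$t, traj$phi)
  if (!isTRUE(om$sustained) || length(om$peaks) < 4)
    stop("fewer than 3 complete cycles detected", call. = FALSE)
  peaks <- utils::tail(om$peaks, 6)
  t <- om$t; phi <- om$phi
  troughs <- om$troughs
  rises <- falls <- numeric(0)
  for (pk in peaks) {
    tb <- troughs[troughs < pk]
    ta <- troughs[troughs > pk]
    if (length(tb)) rises <- c(rises, t[pk] - t[max(tb)])
    if (length(ta)) falls <- c(falls, t[min(ta)] - t[pk])
  }
  list(period = mean(utils::tail(diff(t[peaks]), 5)),
       amplitude = om$amplitude,
       rise_fall_ratio = mean(rises) / mean(falls))
}

#' Phase-plane orbits from a set of initial conditions
#'
#' Integrates the autonomous system (constant stimulus at \code{p$alpha})
#' from each initial condition and returns the orbits in the
#' \eqn{(\phi,\mu)} plane.  In steady regimes orbits terminate near a fixed
#' point; in oscillatory regimes they wind onto the limit cycle.
#'
#' @param p a \code{\link{dimensionless_params}} object.
#' @param initials list of numeric pairs \code{c(phi, mu)}.
#' @param t_end,dt integration settings.
#' @return A list of \code{"trajectory"} objects.
#' @export
phase_portrait <- function(p, initials, t_end = 500, dt = 0.01) {
  stopifnot(inherits(p, "dimensionless_params"))
  lapply(initials, function(x0)
    integrate_rk4(x0, p, stim_constant(p$alpha), t_end = t_end, dt = dt,
                  thin = 10L))
}

#' Sample moments of the protein response in a window
#'
#' @param traj a \code{"trajectory"}.
#' @param window time window \code{c(from, to)} within the trajectory span.
#' @return A list with \code{mean} and \code{sd} of \eqn{\phi} over the
#'   window.
#' @export
response_stats <- function(traj, window) {
  stopifnot(inherits(traj, "trajectory"), length(window) == 2L)
  keep <- traj$t >= window[1] & traj$t <= window[2]
  if (!any(keep)) stop("empty window", call. = FALSE)
  list(mean = mean(traj$phi[keep]), sd = sd(traj$phi[keep]))
}
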