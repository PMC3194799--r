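#' Stimulus protocols
#'
#' Constructors for the stimulus time courses that drive the protein input
#' \eqn{\alpha(t)}: a constant level, a rectangular pulse, a step, and their
#' noisy variants where zero-mean Gaussian white noise of variance
#' \eqn{\sigma^2} rides on the deterministic part
#' (\eqn{\alpha_n(t) = \alpha(t) + \xi(t)}).  Noise enters the model only
#' through the stimulus, producing additive noise in the \eqn{\phi} equation;
#' the fluctuating input is deliberately not clipped at zero (the state is
#' clamped instead) so the stated zero mean is not biased.
#'
#' Protocols are right-continuous at their discontinuities: a pulse holds its
#' elevated level on \eqn{[t_{on}, t_{off})} and a step holds its target from
#' \eqn{t_{on}} on.
#'
#' @param base_level baseline stimulus (dimensionless alpha units), >= 0.
#' @param amplitude pulse height above \code{base_level}.
#' @param target post-step stimulus level.
#' @param t_on,t_off protocol switch times (dimensionless time),
#'   \code{t_on < t_off} where both apply.
#' @param noise_variance Gaussian white-noise variance \eqn{\sigma^2 \ge 0}.
#' @param seed integer seed for the noise stream.
#' @return An object of class \code{"stimulus_protocol"}.
#' @examples
#' evaluate_stimulus(stim_pulse(0.02, amplitude = 0.14, t_on = 20, t_off = 25), 22)
#' @name stimulus_protocol
NULL

new_protocol <- function(kind, base_level, level = base_level, t_on = Inf,
                         t_off = Inf, noise_variance = 0, seed = 1L) {
  if (base_level < 0) stop("'base_level' must be non-negative", call. = FALSE)
  if (noise_variance < 0) stop("'noise_variance' must be >= 0", call. = FALSE)
  if (is.finite(t_on) && is.finite(t_off) && t_on >= t_off)
    stop("'t_on' must be earlier than 't_off'", call. = FALSE)
  structure(list(kind = kind, base_level = base_level, level = level,
                 t_on = t_on, t_off = t_off,
                 noise_variance = noise_variance, seed = as.integer(seed)),
            class = "stimulus_protocol")
}

#' @rdname stimulus_protocol
#' @export
stim_constant <- function(base_level) new_protocol("constant", base_level)

#' @rdname stimulus_protocol
#' @export
stim_pulse <- function(base_level, amplitude, t_on, t_off)
  new_protocol("pulse", base_level, base_level + amplitude, t_on, t_off)

#' @rdname stimulus_protocol
#' @export
stim_step <- function(base_level, target, t_on)
  new_protocol("step", base_level, target, t_on)

#' @rdname stimulus_protocol
#' @export
stim_noisy_step <- function(base_level, target, t_on, noise_variance,
                            seed = 1L)
  new_protocol("noisy_step", base_level, target, t_on,
               noise_variance = noise_variance, seed = seed)

#' @rdname stimulus_protocol
#' @export
stim_noisy_constant <- function(base_level, noise_variance, seed = 1L)
  new_protocol("noisy_constant", base_level,
               noise_variance = noise_variance, seed = seed)

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf("Stimulus protocol: %s\n", x$kind))
  cat(sprintf("  base level %g", x$base_level))
  if (x$kind %in% c("pulse", "step", "noisy_step"))
    cat(sprintf(", level %g on [%g, %s)", x$level, x$t_on,
                if (x$kind == "pulse") format(x$t_off) else "Inf"))
  cat("\n")
  if (x$noise_variance > 0)
    cat(sprintf("  Gaussian white noise: variance %g, seed %d\n",
                x$noise_variance, x$seed))
  invisible(x)
}

# integer code for the C++ integrator (noise handled separately)
protocol_kind_code <- function(protocol) {
  switch(protocol$kind,
         constant = 0L, noisy_constant = 0L,
         pulse = 1L,
         step = 2L, noisy_step = 2L,
         stop("unknown protocol kind: ", protocol$kind, call. = FALSE))
}

#' Deterministic stimulus level at a time point
#'
#' Pure piecewise-constant evaluation of a protocol's deterministic part;
#' noise never enters here (it is regenerated from the seed inside the
#' stochastic integrator).
#'
#' @param protocol a \code{\link{stimulus_protocol}}.
#' @param t time point(s), >= 0; vectorised.
#' @return Stimulus value(s).
#' @export
evaluate_stimulus <- function(protocol, t) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  if (any(t < 0)) stop("'t' must be non-negative", call. = FALSE)
  kind <- protocol_kind_code(protocol)
  if (kind == 0L) rep(protocol$base_level, length(t))
  else if (kind == 1L) ifelse(t >= protocol$t_on & t < protocol$t_off,
                              protocol$level, protocol$base_level)
  else ifelse(t >= protocol$t_on, protocol$level, protocol$base_level)
}

#' Gaussian white-noise increments for the stochastic integrator
#'
#' Standard-normal draws scaled by \eqn{\sigma\sqrt{dt}} so that the
#' continuous-time stimulus fluctuation has variance parameter
#' \eqn{\sigma^2}: over a step the integrated noise contribution is
#' \eqn{\sigma \Delta W \sim N(0, \sigma^2 dt)}.  The same seed always
#' reproduces the identical array; arrays are never stored, only
#' \code{(seed, sigma2)} are persisted in run metadata.
#'
#' @param n_steps number of increments.
#' @param dt time step, > 0.
#' @param sigma2 noise variance \eqn{\sigma^2 \ge 0}.
#' @param seed integer seed.
#' @return Numeric vector of length \code{n_steps}.
#' @export
noise_increments <- function(n_steps, dt, sigma2, seed) {
  if (dt <= 0) stop("'dt' must be positive", call. = FALSE)
  if (sigma2 < 0) stop("'sigma2' must be >= 0", call. = FALSE)
  if (sigma2 == 0) return(numeric(n_steps))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  sqrt(sigma2 * dt) * rnorm(n_steps)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}

# serialisable representation (used by configs and metadata)
protocol_to_list <- function(protocol) {
  out <- unclass(protocol)
  out[vapply(out, function(v) is.numeric(v) && !is.finite(v) &&
               length(v) == 1, TRUE)] <- NULL
  out
}

protocol_from_list <- function(x) {
  known <- c("kind", "base_level", "level", "amplitude", "target", "t_on",
             "t_off", "noise_variance", "seed")
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop("unknown protocol key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(x$kind)) stop("protocol block needs a 'kind'", call. = FALSE)
  switch(x$kind,
         constant = stim_constant(x$base_level),
         pulse = stim_pulse(x$base_level,
                            amplitude = if (!is.null(x$amplitude)) x$amplitude
                            else x$level - x$base_level,
                            t_on = x$t_on, t_off = x$t_off),
         step = stim_step(x$base_level,
                          target = if (!is.null(x$target)) x$target else
                            x$level, t_on = x$t_on),
         noisy_step = stim_noisy_step(x$base_level,
                                      target = if (!is.null(x$target))
                                        x$target else x$level,
                                      t_on = x$t_on,
                                      noise_variance = x$noise_variance,
                                      seed = if (is.null(x$seed)) 1L else
                                        x$seed),
         noisy_constant = stim_noisy_constant(x$base_level,
                                              noise_variance =
                                                x$noise_variance,
                                              seed = if (is.null(x$seed)) 1L
                                              else x$seed),
         stop("unknown protocol kind: ", x$kind, call. = FALSE))
}
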