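#' Dimensionless model right-hand side
#'
#' Evaluates \eqn{d\phi/d\tau = \alpha + \kappa\phi^2/(1+\phi^2+\Gamma\mu) -
#' \phi} and \eqn{d\mu/d\tau = \epsilon(\beta + \phi - \mu)} at a state.
#' With \code{gamma = 0} the \eqn{\mu} dependence of the \eqn{\phi} equation
#' vanishes; with \code{kappa = 0} the \eqn{\phi} equation reduces to
#' \eqn{\alpha - \phi}.
#'
#' @param state numeric vector \code{c(phi, mu)}, non-negative.
#' @param p a \code{\link{dimensionless_params}} object.
#' @param alpha_override optional scalar replacing \code{p$alpha}, the hook
#'   through which time-varying stimulus protocols drive the system.
#' @return Numeric vector \code{c(dphi, dmu)}.
#' @export
rhs_dimensionless <- function(state, p, alpha_override = NULL) {
  stopifnot(inherits(p, "dimensionless_params"))
  if (length(state) != 2L || any(!is.finite(state)))
    stop("'state' must be a finite pair c(phi, mu)", call. = FALSE)
  a <- if (is.null(alpha_override)) p$alpha else alpha_override
  # a fluctuating stimulus may transiently be negative; only finiteness is
  # required here
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a))
    stop("'alpha_override' must be a single finite number", call. = FALSE)
  out <- rhs_dimless_cpp(state[1], state[2], a, p$beta, p$kappa, p$gamma,
                         p$epsilon)
  names(out) <- c("dphi", "dmu")
  out
}

#' Dimensional model right-hand side
#'
#' Evaluates \eqn{dP/dt = a + k P^2/(K_1 + K_2 P^2 + L m) - \gamma_p P} and
#' \eqn{dm/dt = b + c P - \gamma_m m}.
#'
#' @param state numeric vector \code{c(P, m)} of concentrations.
#' @param p a \code{\link{dimensional_params}} object.
#' @return Numeric vector \code{c(dP, dm)}.
#' @export
rhs_dimensional <- function(state, p) {
  stopifnot(inherits(p, "dimensional_params"))
  if (length(state) != 2L || any(!is.finite(state)))
    stop("'state' must be a finite pair c(P, m)", call. = FALSE)
  P <- state[1]; m <- state[2]
  denom <- p$saturation_consts[1] + p$saturation_consts[2] * P^2 +
    p$mirna_inhibition_const * m
  dP <- p$basal_protein_rate + p$autocatalysis_const * P^2 / denom -
    p$protein_degradation_rate * P
  dm <- p$basal_mirna_rate + p$protein_driven_mirna_rate * P -
    p$mirna_degradation_rate * m
  c(dP = dP, dm = dm)
}

#' Jacobian of the dimensionless model
#'
#' Closed-form partial derivatives of the dimensionless vector field, used
#' for stability classification and Hopf detection.  Writing
#' \eqn{D = 1 + \phi^2 + \Gamma\mu},
#' \deqn{\partial_\phi \dot\phi = 2\kappa\phi(1+\Gamma\mu)/D^2 - 1, \quad
#'       \partial_\mu \dot\phi = -\kappa\phi^2\Gamma/D^2,}
#' \deqn{\partial_\phi \dot\mu = \epsilon, \quad
#'       \partial_\mu \dot\mu = -\epsilon.}
#'
#' @inheritParams rhs_dimensionless
#' @return A 2x2 numeric matrix.
#' @export
model_jacobian <- function(state, p, alpha_override = NULL) {
  stopifnot(inherits(p, "dimensionless_params"))
  if (length(state) != 2L || any(!is.finite(state)))
    stop("'state' must be a finite pair c(phi, mu)", call. = FALSE)
  phi <- state[1]; mu <- state[2]
  D <- 1 + phi^2 + p$gamma * mu
  matrix(c(2 * p$kappa * phi * (1 + p$gamma * mu) / D^2 - 1,
           -p$kappa * phi^2 * p$gamma / D^2,
           p$epsilon, -p$epsilon),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("dphi", "dmu"), c("phi", "mu")))
}
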