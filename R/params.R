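#' Dimensionless model parameters
#'
#' Construct the five-parameter dimensionless configuration of the
#' Myc/E2F/miR-17-92 model,
#' \deqn{d\phi/d\tau = \alpha + \kappa\,\phi^2 / (1 + \phi^2 + \Gamma\mu) - \phi,}
#' \deqn{d\mu/d\tau  = \epsilon\,(\beta + \phi - \mu).}
#'
#' @param alpha constitutive protein input (stimulus), dimensionless, >= 0.
#' @param beta constitutive miRNA transcription, dimensionless, >= 0.
#' @param kappa strength of the autocatalytic positive feedback, >= 0.
#' @param gamma strength of the miRNA inhibition of protein expression
#'   (written Gamma in the model); 0 switches the inhibition off entirely.
#' @param epsilon timescale ratio of the miRNA and protein degradation rates
#'   (miRNA is typically more stable, so epsilon < 1); must be > 0.
#' @param alpha_range physically admissible stimulus window
#'   \code{c(alpha_min, alpha_max)} used by sweeps and switch classification.
#' @return An object of class \code{"dimensionless_params"}.
#' @examples
#' p <- dimensionless_params(alpha = 0.02, gamma = 1.2)
#' p
#' @export
dimensionless_params <- function(alpha = 0.02, beta = 0.2, kappa = 3.5,
                                 gamma = 1.0, epsilon = 0.1,
                                 alpha_range = c(0, 0.25)) {
  for (nm in c("alpha", "beta", "kappa", "gamma", "epsilon")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
    if (v < 0) stop("'", nm, "' must be non-negative", call. = FALSE)
  }
  if (epsilon <= 0) stop("'epsilon' must be strictly positive", call. = FALSE)
  if (!is.numeric(alpha_range) || length(alpha_range) != 2L ||
      any(!is.finite(alpha_range)) || alpha_range[1] >= alpha_range[2])
    stop("'alpha_range' must be an increasing pair of finite numbers",
         call. = FALSE)
  if (alpha < alpha_range[1] - 1e-12 || alpha > alpha_range[2] + 1e-12)
    stop("'alpha' lies outside 'alpha_range'", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, kappa = kappa, gamma = gamma,
                 epsilon = epsilon, alpha_range = as.numeric(alpha_range)),
            class = "dimensionless_params")
}

#' @export
print.dimensionless_params <- function(x, ...) {
  cat("Dimensionless Myc/E2F/miR-17-92 parameters\n")
  cat(sprintf("  alpha = %g  (physical range [%g, %g])\n", x$alpha,
              x$alpha_range[1], x$alpha_range[2]))
  cat(sprintf("  beta = %g, kappa = %g, gamma = %g, epsilon = %g\n",
              x$beta, x$kappa, x$gamma, x$epsilon))
  invisible(x)
}

#' Dimensional model parameters
#'
#' Parameters of the model in concentration/time units,
#' \deqn{dP/dt = a + k P^2 / (K_1 + K_2 P^2 + L\,m) - \gamma_p P,}
#' \deqn{dm/dt = b + c P - \gamma_m m,}
#' where \eqn{P} is the Myc/E2F protein-module concentration and \eqn{m} the
#' miR-17-92 concentration.
#'
#' @param basal_protein_rate \eqn{a}, constitutive protein production
#'   (concentration/time).
#' @param autocatalysis_const \eqn{k}, scale of the autocatalytic term
#'   (concentration/time).
#' @param saturation_consts \eqn{c(K_1, K_2)}: the two saturation constants of
#'   the autocatalytic term (\eqn{K_1} in concentration^2, \eqn{K_2}
#'   dimensionless in this parameterisation).
#' @param mirna_inhibition_const \eqn{L}, the miRNA inhibition constant
#'   (concentration).
#' @param basal_mirna_rate \eqn{b}, constitutive miRNA transcription
#'   (concentration/time).
#' @param protein_driven_mirna_rate \eqn{c}, protein-proportional miRNA
#'   transcription rate (1/time).
#' @param protein_degradation_rate \eqn{\gamma_p > 0} (1/time).
#' @param mirna_degradation_rate \eqn{\gamma_m > 0} (1/time).
#' @return An object of class \code{"dimensional_params"}.
#' @export
dimensional_params <- function(basal_protein_rate,
                               autocatalysis_const,
                               saturation_consts,
                               mirna_inhibition_const,
                               basal_mirna_rate,
                               protein_driven_mirna_rate,
                               protein_degradation_rate,
                               mirna_degradation_rate) {
  vals <- list(basal_protein_rate = basal_protein_rate,
               autocatalysis_const = autocatalysis_const,
               saturation_consts = saturation_consts,
               mirna_inhibition_const = mirna_inhibition_const,
               basal_mirna_rate = basal_mirna_rate,
               protein_driven_mirna_rate = protein_driven_mirna_rate,
               protein_degradation_rate = protein_degradation_rate,
               mirna_degradation_rate = mirna_degradation_rate)
  if (length(saturation_consts) != 2L)
    stop("'saturation_consts' must hold the two constants c(K1, K2)",
         call. = FALSE)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0))
      stop("'", nm, "' must be finite and non-negative", call. = FALSE)
  }
  if (protein_degradation_rate <= 0 || mirna_degradation_rate <= 0)
    stop("degradation rates must be strictly positive", call. = FALSE)
  structure(vals, class = "dimensional_params")
}

#' @export
print.dimensional_params <- function(x, ...) {
  cat("Dimensional Myc/E2F/miR-17-92 parameters\n")
  for (nm in names(x)) cat(sprintf("  %s = %s\n", nm,
                                   paste(format(x[[nm]]), collapse = ", ")))
  invisible(x)
}

#' Map dimensional parameters to the dimensionless model
#'
#' Rescales protein by \eqn{P_0 = \sqrt{K_1/K_2}}, miRNA by
#' \eqn{m_0 = c P_0 / \gamma_m}, and time by \eqn{1/\gamma_p}, giving
#' \eqn{\alpha = a/(\gamma_p P_0)}, \eqn{\kappa = k P_0/(\gamma_p K_1)},
#' \eqn{\Gamma = L m_0 / K_1}, \eqn{\beta = b/(c P_0)}, and the timescale
#' ratio \eqn{\epsilon = \gamma_m/\gamma_p}.  Simulating the dimensional
#' system and rescaling states and time reproduces the dimensionless
#' trajectory; when \eqn{\gamma_m = \gamma_p} the two equations carry equal
#' time constants (\eqn{\epsilon = 1}).
#'
#' @param p a \code{\link{dimensional_params}} object.
#' @param alpha_range physical stimulus window for the resulting
#'   dimensionless configuration (dimensionless units).
#' @return A list with elements \code{params}
#'   (\code{\link{dimensionless_params}}), \code{protein_scale},
#'   \code{mirna_scale} and \code{time_scale}.
#' @export
nondimensionalize <- function(p, alpha_range = NULL) {
  stopifnot(inherits(p, "dimensional_params"))
  if (p$protein_degradation_rate <= 0 || p$mirna_degradation_rate <= 0)
    stop("degradation rates must be strictly positive", call. = FALSE)
  if (any(p$saturation_consts <= 0) || p$protein_driven_mirna_rate <= 0)
    stop("saturation constants and the protein-driven miRNA rate must be ",
         "positive to define the concentration scales", call. = FALSE)
  P0 <- sqrt(p$saturation_consts[1] / p$saturation_consts[2])
  m0 <- p$protein_driven_mirna_rate * P0 / p$mirna_degradation_rate
  alpha <- p$basal_protein_rate / (p$protein_degradation_rate * P0)
  kappa <- p$autocatalysis_const * P0 /
    (p$protein_degradation_rate * p$saturation_consts[1])
  gamma <- p$mirna_inhibition_const * m0 / p$saturation_consts[1]
  beta <- p$basal_mirna_rate / (p$protein_driven_mirna_rate * P0)
  epsilon <- p$mirna_degradation_rate / p$protein_degradation_rate
  if (is.null(alpha_range))
    alpha_range <- c(0, max(0.25, 2 * alpha))
  list(params = dimensionless_params(alpha = alpha, beta = beta,
                                     kappa = kappa, gamma = gamma,
                                     epsilon = epsilon,
                                     alpha_range = alpha_range),
       protein_scale = P0, mirna_scale = m0,
       time_scale = 1 / p$protein_degradation_rate)
}

# internal: replace alpha (used by sweeps); skips the range check so that
# bifurcation points just outside the physical window can be diagnosed
set_alpha <- function(p, alpha) {
  p$alpha <- alpha
  p
}
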