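#' Steady-state miRNA level implied by a protein level
#'
#' At any fixed point the miRNA balance \eqn{\epsilon(\beta + \phi - \mu) = 0}
#' pins \eqn{\mu^* = \phi^* + \beta}: an affine relation with unit slope whose
#' offset is the constitutive miRNA transcription \eqn{\beta}.  The protein
#' and miRNA steady states therefore differ only by a parameter-determined
#' constant, on every branch.
#'
#' @param phi protein steady-state level(s), vectorised.
#' @param p a \code{\link{dimensionless_params}} object.
#' @return \eqn{\mu} value(s), same length as \code{phi}.
#' @export
mu_of_phi_steady <- function(phi, p) {
  stopifnot(inherits(p, "dimensionless_params"))
  phi + p$beta
}

# cubic coefficients (ascending) of the steady-state polynomial in phi:
# substituting mu = beta + phi into the phi balance and clearing the
# denominator 1 + phi^2 + Gamma*(beta + phi) gives
#   -phi^3 + (alpha - Gamma + kappa) phi^2
#          + (alpha Gamma - (1 + Gamma beta)) phi + alpha (1 + Gamma beta) = 0
steady_poly_coef <- function(p, alpha = p$alpha) {
  c0 <- 1 + p$gamma * p$beta
  c(alpha * c0, alpha * p$gamma - c0, alpha - p$gamma + p$kappa, -1)
}

# real roots of a cubic (ascending coefficients) via the eigenvalues of the
# companion matrix, then a bounded Newton polish on the exact polynomial
cubic_real_roots <- function(cf, tol = 1e-12, imag_tol = 1e-7) {
  stopifnot(length(cf) == 4L, cf[4] != 0)
  a <- cf / cf[4]                       # monic: x^3 + a3 x^2 + a2 x + a1... wait
  comp <- matrix(0, 3, 3)
  comp[2, 1] <- 1; comp[3, 2] <- 1
  comp[, 3] <- -a[1:3]
  ev <- eigen(comp, only.values = TRUE)$values
  re <- Re(ev[abs(Im(ev)) <= imag_tol * pmax(1, abs(ev))])
  if (!length(re)) return(numeric(0))
  pol <- function(x) cf[1] + cf[2] * x + cf[3] * x^2 + cf[4] * x^3
  dpol <- function(x) cf[2] + 2 * cf[3] * x + 3 * cf[4] * x^2
  polish <- function(x) {
    for (i in 1:50) {
      d <- dpol(x)
      if (abs(d) < 1e-14) break
      step <- pol(x) / d
      if (!is.finite(step)) break
      x <- x - step
      if (abs(step) < tol * max(1, abs(x))) break
    }
    x
  }
  sort(vapply(re, polish, 0))
}

#' Solve for all physical fixed points
#'
#' Substitutes the steady-state relation \eqn{\mu = \phi + \beta} into the
#' protein balance, clears the denominator to a cubic in \eqn{\phi}, finds
#' all real roots globally via the companion matrix (so no branch can be
#' missed), polishes each by Newton iteration, keeps roots with
#' \eqn{\phi \ge -10^{-9}} (clamped to 0), de-duplicates within \code{1e-7},
#' and attaches eigenvalues and a stability label to each fixed point.
#'
#' @param p a \code{\link{dimensionless_params}} object.
#' @param alpha optional stimulus value overriding \code{p$alpha}.
#' @return An object of class \code{"steady_state_set"}: a list of fixed
#'   points sorted by \eqn{\phi^*}, each with fields \code{phi_star},
#'   \code{mu_star}, \code{eigenvalues}, \code{stability}
#'   (\code{stable_node}, \code{stable_focus}, \code{saddle},
#'   \code{unstable_node}, \code{unstable_focus}), \code{marginal} flag,
#'   \code{fold_degenerate} flag, and \code{branch} (\code{off},
#'   \code{middle}, \code{on} by \eqn{\phi^*} rank).
#' @examples
#' solve_steady_states(dimensionless_params(alpha = 0.02, gamma = 1.2))
#' @export
solve_steady_states <- function(p, alpha = NULL) {
  stopifnot(inherits(p, "dimensionless_params"))
  a <- if (is.null(alpha)) p$alpha else alpha
  dup <- FALSE
  if (p$kappa == 0) {
    roots <- a                           # linear system: phi* = alpha
  } else {
    roots <- cubic_real_roots(steady_poly_coef(p, a))
    roots <- roots[roots >= -1e-9]
    roots[roots < 0] <- 0
    if (length(roots) > 1) {             # de-duplicate, flag fold degeneracy
      keep <- c(TRUE, diff(roots) > 1e-7)
      dup <- any(!keep)
      roots <- roots[keep]
    }
  }
  if (!length(roots))
    stop("internal error: no physical steady state found", call. = FALSE)
  n <- length(roots)
  branches <- if (n == 1) "off" else if (n == 2) c("off", "on") else
    c("off", "middle", "on")
  ss <- lapply(seq_len(n), function(i) {
    phi <- roots[i]
    mu <- mu_of_phi_steady(phi, p)
    ev <- eigen(model_jacobian(c(phi, mu), set_alpha(p, a)),
                only.values = TRUE)$values
    st <- structure(list(phi_star = phi, mu_star = mu, eigenvalues = ev,
                         branch = branches[i], fold_degenerate = dup),
                    class = "steady_state")
    cls <- classify_stability(st, p)
    st$stability <- cls$stability
    st$marginal <- cls$marginal
    st
  })
  structure(list(states = ss, alpha = a, params = p),
            class = "steady_state_set")
}

#' Linear stability label of a fixed point
#'
#' Labels a fixed point from the signs of the real parts of its Jacobian
#' eigenvalues: both negative is stable (node if real, focus if complex),
#' opposite signs is a saddle, both positive is unstable (node/focus).  A
#' real part within \code{1e-10} of zero is flagged marginal rather than
#' silently classified.
#'
#' @param ss a \code{"steady_state"} (from \code{\link{solve_steady_states}})
#'   or a numeric pair \code{c(phi, mu)} at a fixed point.
#' @param p a \code{\link{dimensionless_params}} object.
#' @param alpha optional stimulus override.
#' @return A list with \code{stability} (character label) and
#'   \code{marginal} (logical).
#' @export
classify_stability <- function(ss, p, alpha = NULL) {
  stopifnot(inherits(p, "dimensionless_params"))
  a <- if (is.null(alpha)) p$alpha else alpha
  ev <- if (inherits(ss, "steady_state")) ss$eigenvalues else
    eigen(model_jacobian(as.numeric(ss)[1:2], set_alpha(p, a)),
          only.values = TRUE)$values
  re <- Re(ev)
  complex_pair <- any(abs(Im(ev)) > 1e-12)
  marginal <- any(abs(re) < 1e-10)
  stability <-
    if (all(re < 0)) if (complex_pair) "stable_focus" else "stable_node"
    else if (all(re > 0)) if (complex_pair) "unstable_focus" else
      "unstable_node"
    else "saddle"
  list(stability = stability, marginal = marginal)
}

#' @export
print.steady_state_set <- function(x, ...) {
  cat(sprintf("Steady states at alpha = %g (%d fixed point%s)\n", x$alpha,
              length(x$states), if (length(x$states) == 1) "" else "s"))
  print(as.data.frame(x), digits = 6)
  invisible(x)
}

#' @export
as.data.frame.steady_state_set <- function(x, ...) {
  rows <- lapply(x$states, function(s) {
    data.frame(alpha = x$alpha, phi_star = s$phi_star, mu_star = s$mu_star,
               re_eig1 = Re(s$eigenvalues[1]), im_eig1 = Im(s$eigenvalues[1]),
               re_eig2 = Re(s$eigenvalues[2]), im_eig2 = Im(s$eigenvalues[2]),
               stability = s$stability, branch = s$branch,
               marginal = s$marginal, fold_degenerate = s$fold_degenerate)
  })
  do.call(rbind, rows)
}

# number of stable fixed points in a set
n_stable <- function(ss_set) {
  sum(vapply(ss_set$states,
             function(s) startsWith(s$stability, "stable"), TRUE))
}

#' Write a steady-state table to CSV
#'
#' One row per fixed point: a hash of the parameter set, the stimulus value,
#' both state coordinates, the real and imaginary parts of the two
#' eigenvalues, the stability label and the branch label.
#'
#' @param x a \code{"steady_state_set"} or a list of them.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_steady_states_csv <- function(x, path) {
  sets <- if (inherits(x, "steady_state_set")) list(x) else x
  tab <- do.call(rbind, lapply(sets, function(s) {
    df <- as.data.frame(s)
    df$param_hash <- param_hash(s$params)
    df[c("param_hash", setdiff(names(df), "param_hash"))]
  }))
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

param_hash <- function(p) {
  key <- paste(format(c(p$alpha, p$beta, p$kappa, p$gamma, p$epsilon,
                        p$alpha_range), digits = 15), collapse = "|")
  substr(digest_string(key), 1, 12)
}

# md5 of a string via tools::md5sum on a temp file (no extra dependency)
digest_string <- function(s) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(s, f)
  unname(tools::md5sum(f))
}
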