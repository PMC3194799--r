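#' @export
plot.trajectory <- function(x, which = c("time", "phase"), ...) {
  which <- match.arg(which)
  if (which == "time") {
    graphics::plot(x$t, x$phi, type = "l", xlab = "time (dimensionless)",
                   ylab = expression(phi), ...)
    graphics::lines(x$t, x$alpha, lty = 2, col = "red")
  } else {
    graphics::plot(x$phi, x$mu, type = "l", xlab = expression(phi),
                   ylab = expression(mu), ...)
  }
  invisible(x)
}

#' @export
plot.branch_diagram <- function(x, ...) {
  tab <- x$table
  stable <- startsWith(tab$stability, "stable")
  graphics::plot(tab$alpha, tab$phi_star, type = "n",
                 xlab = expression(alpha), ylab = expression(phi^"*"), ...)
  graphics::points(tab$alpha[stable], tab$phi_star[stable], pch = 16,
                   cex = 0.3)
  graphics::points(tab$alpha[!stable], tab$phi_star[!stable], pch = 1,
                   cex = 0.3, col = "grey50")
  for (b in x$saddle_nodes)
    graphics::points(b$alpha_at, b$phi_at, pch = 17, col = "red")
  for (b in x$hopf_points)
    graphics::points(b$alpha_at, b$phi_at, pch = 15, col = "blue")
  invisible(x)
}

#' @export
plot.ensemble_result <- function(x, ...) {
  graphics::plot(x$t, x$F, type = "s", ylim = c(0, 1),
                 xlab = "time (dimensionless)",
                 ylab = "fraction of transition F(t)", ...)
  graphics::abline(h = x$F_s, lty = 3)
  invisible(x)
}
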