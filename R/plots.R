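# Diagnostic figures: fitted response curves with delta-method confidence
# bands, and the proportion-ingested type diagnostic.

# Pointwise 95% delta-method band for an nls fit on a new density grid.
delta_band <- function(fit, grid_df, level = 0.95) {
  est <- stats::coef(fit)
  pred <- function(theta) {
    e <- c(as.list(grid_df), as.list(theta))
    eval(stats::formula(fit)[[3L]], envir = e)
  }
  f0 <- pred(est)
  eps <- pmax(abs(est), 1e-8) * 1e-6
  J <- vapply(seq_along(est), function(j) {
    th <- est
    th[j] <- th[j] + eps[j]
    (pred(th) - f0) / eps[j]
  }, numeric(length(f0)))
  V <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  if (is.null(V)) return(data.frame(fit = f0, lwr = NA, upr = NA))
  se <- sqrt(pmax(rowSums((J %*% V) * J), 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(fit = f0, lwr = f0 - z * se, upr = f0 + z * se)
}

#' Plot a fitted numerical or functional response
#'
#' Draws the per-well rates, the fitted curve and its pointwise 95%
#' delta-method confidence band over a dense density grid.
#'
#' @param object An `nr_fit` or `fr_fit`.
#' @param n_grid Number of grid points for the curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.response_fit <- function(object, n_grid = 200, ...) {
  d <- object$data$d
  obs <- data.frame(d = d, y = object$response)
  grid <- data.frame(d = seq(min(d), max(d), length.out = n_grid))
  if (".theta" %in% names(object$data)) {
    grid$.theta <- object$data$.theta[1L]
  }
  band <- delta_band(object$fit, grid)
  grid <- cbind(grid, band)

  y_lab <- if (inherits(object, "nr_fit")) {
    expression(r ~ (d^-1))
  } else if (object$transform == "log") {
    expression(ln ~ I)
  } else {
    expression(I ~ (prey ~ predator^-1 ~ d^-1))
  }

  ggplot2::ggplot(obs, ggplot2::aes(x = .data$d, y = .data$y)) +
    ggplot2::geom_ribbon(
      data = grid,
      ggplot2::aes(x = .data$d, ymin = .data$lwr, ymax = .data$upr),
      inherit.aes = FALSE, alpha = 0.2
    ) +
    ggplot2::geom_line(
      data = grid, ggplot2::aes(x = .data$d, y = .data$fit),
      inherit.aes = FALSE
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = expression(Prey ~ density ~ (cells ~ mL^-1)),
      y = y_lab,
      title = sprintf("%s (AICc = %.1f)", object$model_id, object$aicc),
      subtitle = sprintf("transform=%s, correction=%s, axis=%s",
                         object$transform, object$correction,
                         object$density_axis)
    ) +
    ggplot2::theme_minimal()
}

#' Proportion-of-prey-ingested diagnostic plot
#'
#' The clearance curve read as a proportion, with the fitted quadratic that
#' backs the FR-type verdict: unimodal (rising then falling) for type III,
#' monotone decreasing for type II.
#'
#' @param rates A [well_rates()] table (needs `density` and
#'   `proportion_ingested`).
#' @param verdict Optional [discriminate_fr_type()] result to annotate.
#' @return A ggplot object.
#' @export
plot_proportion_ingested <- function(rates, verdict = NULL) {
  p <- ggplot2::ggplot(
    rates, ggplot2::aes(x = .data$density, y = .data$proportion_ingested)
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x + I(x^2), se = TRUE,
                         linewidth = 0.6) +
    ggplot2::labs(
      x = expression(Prey ~ density ~ (cells ~ mL^-1)),
      y = expression(Proportion ~ ingested ~ (d^-1)),
      title = "Proportion of prey ingested (clearance) vs prey density"
    ) +
    ggplot2::theme_minimal()
  if (inherits(verdict, "fr_type_verdict")) {
    p <- p + ggplot2::labs(subtitle = sprintf("verdict: %s", verdict$verdict))
  }
  p
}
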