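# Nonlinear least-squares fitting, AICc model selection, FR-type
# discrimination and covariate diagnostics.

#' Small-sample corrected Akaike information criterion
#'
#' For a least-squares fit with Gaussian errors,
#' \eqn{AICc = n \ln(RSS/n) + 2k + 2k(k+1)/(n-k-1)}, where
#' `k = n_params + 1` counts the fitted model parameters plus the residual
#' variance. This is the convention of the standard AICc tooling, so scores
#' are comparable with values produced by those packages.
#'
#' @param rss Residual sum of squares (> 0).
#' @param n Number of observations.
#' @param n_params Number of fitted model parameters (excluding the error
#'   variance, which is added internally).
#' @return The AICc score (more negative = better).
#' @examples
#' aicc(1, 20, 2) # k = 3 including the variance: -52.41
#' @export
aicc <- function(rss, n, n_params) {
  if (rss <= 0) stop("`rss` must be positive", call. = FALSE)
  k <- n_params + 1
  if (n - k - 1 <= 0) {
    stop(sprintf("AICc undefined: need n > n_params + 2 (n = %d, k = %d)",
                 n, k), call. = FALSE)
  }
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# Pick the prey-density axis out of a rates table.
pick_axis <- function(data, density_axis) {
  col <- switch(density_axis, mean = "p_mean", initial = "p_initial")
  if (col %in% names(data)) data[[col]]
  else if ("density" %in% names(data)) data$density
  else stop(sprintf("need a `%s` or `density` column", col), call. = FALSE)
}

# Multi-start wrapper around minpack.lm::nlsLM. `starts` is a list of named
# start lists; returns the converged fit with the lowest RSS or NULL.
nls_multistart <- function(formula, data, starts, lower = NULL) {
  best <- NULL
  best_rss <- Inf
  for (st in starts) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        formula, data = data, start = st, lower = lower,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.finite(rss) && rss < best_rss) {
        best <- fit
        best_rss <- rss
      }
    }
  }
  best
}

# Common constructor for fitted NR/FR objects.
new_response_fit <- function(subclass, model_id, fit, data, response,
                             transform, correction, density_axis, n_params,
                             derived = NULL, n_starts = NA_integer_) {
  co <- summary(fit)$coefficients
  params <- tibble::tibble(
    term = rownames(co),
    estimate = unname(co[, "Estimate"]),
    std.error = unname(co[, "Std. Error"]),
    statistic = unname(co[, "t value"]),
    p.value = unname(co[, "Pr(>|t|)"])
  )
  rss <- sum(stats::resid(fit)^2)
  n <- length(response)
  structure(list(
    model_id = model_id,
    params = params,
    derived = derived,
    rss = rss,
    n = n,
    n_params = n_params,
    # a numerically perfect fit has -Inf AICc (it wins every comparison)
    aicc = if (rss > 0) aicc(rss, n, n_params) else -Inf,
    transform = transform,
    correction = correction,
    density_axis = density_axis,
    data = data,
    response = response,
    fitted = stats::fitted(fit),
    fit = fit,
    converged = fit$convInfo$isConv %||% TRUE,
    n_starts = n_starts
  ), class = c(subclass, "response_fit"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.response_fit <- function(x, ...) {
  cat(sprintf("<%s fit> n = %d, RSS = %.4g, AICc = %.2f\n",
              x$model_id, x$n, x$rss, x$aicc))
  cat(sprintf("  variant: transform=%s, correction=%s, axis=%s\n",
              x$transform, x$correction, x$density_axis))
  print(as.data.frame(x$params), digits = 4, row.names = FALSE)
  if (!is.null(x$derived) && nrow(x$derived)) {
    cat("derived:\n")
    print(as.data.frame(x$derived), digits = 4, row.names = FALSE)
  }
  invisible(x)
}

#' Fit the threshold numerical response
#'
#' Estimates \eqn{(r_{max}, P', k_2)} of
#' \eqn{r = r_{max}(P - P')/(k_2 + (P - P'))} by nonlinear least squares with
#' multi-start initialization (starts span the observed density range;
#' Levenberg–Marquardt steps with box constraints keep all three parameters
#' in their valid domain).
#'
#' @param rates A data frame with a predator growth-rate column `r` and a
#'   prey-density axis (`p_mean`/`p_initial` from [well_rates()], or a
#'   plain `density` column).
#' @param density_axis `"mean"` (log-mean prey over the incubation) or
#'   `"initial"`.
#' @return An object of class `nr_fit` (see [tidy.response_fit()],
#'   [glance.response_fit()], [autoplot.response_fit()]).
#' @export
fit_nr <- function(rates, density_axis = c("mean", "initial")) {
  density_axis <- match.arg(density_axis)
  d <- pick_axis(rates, density_axis)
  r <- rates$r
  ok <- is.finite(d) & is.finite(r) & d > 0
  d <- d[ok]; r <- r[ok]
  if (length(r) < 5L) {
    stop("need at least 5 wells with finite growth rates", call. = FALSE)
  }
  df <- data.frame(d = d, r = r)

  rmax0 <- max(r)
  if (rmax0 <= 0) rmax0 <- 0.1
  pp_grid <- unique(pmax(0, c(0, min(d) * c(0.25, 0.5, 1))))
  k2_grid <- exp(seq(log(max(min(d), 1)), log(max(d)), length.out = 4))
  starts <- list()
  for (pp in pp_grid) for (k2 in k2_grid) {
    starts[[length(starts) + 1L]] <- list(rmax = rmax0, pp = pp, k2 = k2)
  }

  fit <- nls_multistart(
    r ~ rmax * (d - pp) / (k2 + (d - pp)), df, starts,
    lower = c(rmax = 1e-8, pp = 0, k2 = 1e-8)
  )
  if (is.null(fit)) {
    stop(sprintf("NR fit failed to converge from %d starts (n = %d wells)",
                 length(starts), nrow(df)), call. = FALSE)
  }
  new_response_fit("nr_fit", "NR", fit, df, r,
                   transform = "none", correction = "none",
                   density_axis = density_axis, n_params = 3L,
                   n_starts = length(starts))
}

#' Fit a functional-response model
#'
#' Estimates the generalized disk equation
#' \eqn{I = a P^\theta / (1 + a h P^\theta)} by nonlinear least squares with
#' multi-start initialization over log-spaced `(a, h)` (and `theta` when
#' free). The maximum ingestion rate \eqn{I_{max} = 1/h} is reported with a
#' delta-method standard error.
#'
#' Negative ingestion rates (possible in the control-corrected dataset at
#' low prey density) are retained in the untransformed objective — they carry
#' information about the low-density regime. The log-transformed objective
#' (least squares on \eqn{\ln I}, the usual remedy for the variance of
#' ingestion rates growing with prey density) requires strictly positive
#' rates and refuses anything else.
#'
#' @param rates A data frame with an ingestion-rate column `i_cells` and a
#'   prey-density axis (as in [fit_nr()]).
#' @param theta Hill exponent: a fixed number (1 = type II, 2 = classical
#'   type III, any value >= 1) or `"free"` to estimate it.
#' @param transform `"none"` or `"log"`.
#' @param correction Provenance label recorded in the result: `"controls"`
#'   if the ingestion rates were control-corrected, `"none"` otherwise.
#'   (The correction itself happens in [well_rates()].)
#' @param density_axis `"initial"` or `"mean"`.
#' @return An object of class `fr_fit`.
#' @export
fit_fr <- function(rates, theta = 1,
                   transform = c("none", "log"),
                   correction = c("controls", "none"),
                   density_axis = c("initial", "mean")) {
  transform <- match.arg(transform)
  correction <- match.arg(correction)
  density_axis <- match.arg(density_axis)
  free_theta <- identical(theta, "free")
  if (!free_theta && (!is.numeric(theta) || theta < 1)) {
    stop("`theta` must be a number >= 1 or \"free\"", call. = FALSE)
  }

  d <- pick_axis(rates, density_axis)
  i <- rates$i_cells
  ok <- is.finite(d) & is.finite(i) & d > 0
  d <- d[ok]; i <- i[ok]
  if (length(i) < 6L) {
    stop("need at least 6 wells with finite ingestion rates", call. = FALSE)
  }
  if (transform == "log" && any(i <= 0)) {
    stop(paste0(
      "log transform requires strictly positive ingestion rates; ",
      sum(i <= 0), " well(s) have I <= 0. Use transform = \"none\" ",
      "(which retains them) or the uncorrected dataset."
    ), call. = FALSE)
  }
  df <- data.frame(d = d, i = i)

  ipos <- i[i > 0]
  imax0 <- max(ipos)
  h_grid <- c(0.3, 1, 3) / imax0
  theta_grid <- if (free_theta) c(1, 2, 3) else theta
  starts <- list()
  for (th in theta_grid) {
    a0 <- stats::median(ipos / (d[i > 0]^th))
    for (h0 in h_grid) for (fa in c(0.1, 1, 10)) {
      st <- list(a = a0 * fa, h = h0)
      if (free_theta) st$theta <- th
      starts[[length(starts) + 1L]] <- st
    }
  }

  if (!free_theta) df$.theta <- theta  # fixed exponent rides along as data
  if (transform == "log") {
    form <- if (free_theta) {
      log(i) ~ log(a * d^theta / (1 + a * h * d^theta))
    } else {
      log(i) ~ log(a * d^.theta / (1 + a * h * d^.theta))
    }
    response <- log(i)
  } else {
    form <- if (free_theta) {
      i ~ a * d^theta / (1 + a * h * d^theta)
    } else {
      i ~ a * d^.theta / (1 + a * h * d^.theta)
    }
    response <- i
  }

  lower <- if (free_theta) c(a = 1e-300, h = 0, theta = 1) else c(a = 1e-300, h = 0)
  fit <- nls_multistart(form, df, starts, lower = lower)
  if (is.null(fit)) {
    stop(sprintf("FR fit (%s) failed to converge from %d starts",
                 fr_model_id(theta), length(starts)), call. = FALSE)
  }

  co <- summary(fit)$coefficients
  h_hat <- co["h", "Estimate"]
  h_se <- co["h", "Std. Error"]
  derived <- if (h_hat > 0) {
    tibble::tibble(term = "imax", estimate = 1 / h_hat,
                   std.error = h_se / h_hat^2)  # delta method
  } else {
    tibble::tibble(term = "imax", estimate = Inf, std.error = NA_real_)
  }

  new_response_fit("fr_fit", fr_model_id(if (free_theta) "free" else theta),
                   fit, df, response,
                   transform = transform, correction = correction,
                   density_axis = density_axis,
                   n_params = if (free_theta) 3L else 2L,
                   derived = derived, n_starts = length(starts))
}

#' Fit the Michaelis–Menten parameterization of the type II response
#'
#' Same curve family as [fit_fr()] with `theta = 1`, but estimated directly
#' in terms of \eqn{(I_{max}, k)}. Because the two parameterizations describe
#' identical curves, the fitted predictions and the AICc agree with the disk
#' form to numerical tolerance.
#'
#' @inheritParams fit_fr
#' @return An object of class `fr_fit` with `model_id = "FRmm"`.
#' @export
fit_fr_mm <- function(rates,
                      transform = c("none", "log"),
                      correction = c("controls", "none"),
                      density_axis = c("initial", "mean")) {
  transform <- match.arg(transform)
  correction <- match.arg(correction)
  density_axis <- match.arg(density_axis)
  d <- pick_axis(rates, density_axis)
  i <- rates$i_cells
  ok <- is.finite(d) & is.finite(i) & d > 0
  d <- d[ok]; i <- i[ok]
  if (length(i) < 6L) {
    stop("need at least 6 wells with finite ingestion rates", call. = FALSE)
  }
  if (transform == "log" && any(i <= 0)) {
    stop("log transform requires strictly positive ingestion rates",
         call. = FALSE)
  }
  df <- data.frame(d = d, i = i)
  imax0 <- max(i[i > 0])
  # half-saturation starts must also cover curves still near-linear over the
  # observed range (k far above max(d))
  k_grid <- c(unname(stats::quantile(d, c(0.25, 0.5, 0.75))),
              2 * max(d), 20 * max(d))
  starts <- list()
  for (fi in c(1, 2, 4)) for (k0 in k_grid) {
    starts[[length(starts) + 1L]] <- list(imax = imax0 * fi, k = k0)
  }
  form <- if (transform == "log") log(i) ~ log(imax * d / (k + d)) else
    i ~ imax * d / (k + d)
  response <- if (transform == "log") log(i) else i
  fit <- nls_multistart(form, df, starts, lower = c(imax = 1e-12, k = 1e-12))
  if (is.null(fit)) stop("FRmm fit failed to converge", call. = FALSE)
  new_response_fit("fr_fit", "FRmm", fit, df, response,
                   transform = transform, correction = correction,
                   density_axis = density_axis, n_params = 2L,
                   n_starts = length(starts))
}

#' Rank fitted models by AICc
#'
#' Sorts fits by AICc and labels every model within ΔAICc < 2 of the best as
#' having "substantial" support (the conventional threshold below which two
#' models cannot be told apart). Fits are only comparable when they model the
#' identical response vector — same transform, correction, density axis and
#' data — and mixing variants is refused.
#'
#' @param fits A list of `response_fit` objects (or several passed via
#'   `...`).
#' @param ... Additional fits.
#' @return A tibble sorted by AICc with `model_id`, `aicc`, `delta_aicc`,
#'   `support`, `rss`, `n_params`, `n`.
#' @export
rank_models <- function(fits, ...) {
  if (inherits(fits, "response_fit")) fits <- list(fits)
  fits <- c(fits, list(...))
  stopifnot(length(fits) >= 1L,
            all(vapply(fits, inherits, logical(1), "response_fit")))
  if (length(fits) > 1L) {
    ref <- fits[[1L]]
    for (f in fits[-1L]) {
      same_meta <- identical(f$transform, ref$transform) &&
        identical(f$correction, ref$correction) &&
        identical(f$density_axis, ref$density_axis) &&
        f$n == ref$n
      same_resp <- same_meta && isTRUE(all.equal(sort(f$response),
                                                 sort(ref$response)))
      if (!same_resp) {
        stop(paste0(
          "fits are not comparable: AICc ranking requires the identical ",
          "response vector (same transform/correction/axis and data)"
        ), call. = FALSE)
      }
    }
  }
  tab <- tibble::tibble(
    model_id = vapply(fits, `[[`, character(1), "model_id"),
    aicc = vapply(fits, `[[`, numeric(1), "aicc"),
    rss = vapply(fits, `[[`, numeric(1), "rss"),
    n_params = vapply(fits, `[[`, integer(1), "n_params"),
    n = vapply(fits, `[[`, numeric(1), "n")
  )
  tab <- tab[order(tab$aicc, tab$model_id), ]
  tab$delta_aicc <- tab$aicc - tab$aicc[1L]
  tab$support <- ifelse(tab$delta_aicc < 2, "substantial", "weak")
  tab[, c("model_id", "aicc", "delta_aicc", "support", "rss", "n_params", "n")]
}

#' Discriminate FR type from the proportion of prey ingested
#'
#' Fits an ordinary least-squares quadratic,
#' `proportion ~ density + density^2`, to the proportion-of-prey-ingested
#' (clearance) curve. A significantly positive linear term together with a
#' significantly negative quadratic term is the signature of the unimodal
#' clearance curve of a type III response; a significantly negative linear
#' term with a non-negative quadratic is the monotone decline of type II.
#' Anything else is inconclusive. This diagnostic is the decisive tie-break
#' when AICc cannot separate a type II from a weakly sigmoidal type III fit.
#'
#' @param data A data frame with columns `density` and
#'   `proportion_ingested` (at least 8 rows spanning >= one order of
#'   magnitude in density).
#' @param alpha Significance level for both terms (default 0.05).
#' @param weights Optional OLS weights (default unweighted).
#' @return An object of class `fr_type_verdict`: a list with `verdict`
#'   (`"typeIII"`, `"typeII"` or `"inconclusive"`), `coefficients` (tibble)
#'   and `alpha`.
#' @export
discriminate_fr_type <- function(data, alpha = 0.05, weights = NULL) {
  stopifnot(is.data.frame(data),
            all(c("density", "proportion_ingested") %in% names(data)))
  d <- data$density
  y <- data$proportion_ingested
  ok <- is.finite(d) & is.finite(y) & d > 0
  d <- d[ok]; y <- y[ok]
  if (length(d) < 8L) stop("need at least 8 (density, proportion) pairs",
                           call. = FALSE)
  if (max(d) / min(d) < 10) {
    stop("densities must span at least one order of magnitude", call. = FALSE)
  }
  df <- data.frame(d = d, y = y)
  fit <- if (is.null(weights)) {
    stats::lm(y ~ d + I(d^2), data = df)
  } else {
    stats::lm(y ~ d + I(d^2), data = df, weights = weights[ok])
  }
  co <- summary(fit)$coefficients
  lin <- co["d", ]
  quad <- co["I(d^2)", ]
  lin_pos <- lin["Estimate"] > 0 && lin["Pr(>|t|)"] < alpha
  lin_neg <- lin["Estimate"] < 0 && lin["Pr(>|t|)"] < alpha
  quad_neg <- quad["Estimate"] < 0 && quad["Pr(>|t|)"] < alpha
  verdict <- if (lin_pos && quad_neg) "typeIII"
  else if (lin_neg && !quad_neg) "typeII"
  else "inconclusive"
  structure(list(
    verdict = verdict,
    coefficients = tibble::tibble(
      term = rownames(co),
      estimate = co[, "Estimate"],
      std.error = co[, "Std. Error"],
      p.value = co[, "Pr(>|t|)"]
    ),
    alpha = alpha,
    n = length(d),
    fit = fit
  ), class = "fr_type_verdict")
}

#' @export
print.fr_type_verdict <- function(x, ...) {
  cat(sprintf("<FR type verdict> %s (alpha = %g, n = %d)\n",
              x$verdict, x$alpha, x$n))
  print(as.data.frame(x$coefficients), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Covariate bias screens: diluent fraction and predator density
#'
#' Two linear-model diagnostics for systematic bias. First, prey growth
#' rates are regressed on the fraction of diluent (filtered lake water, FLW)
#' added to each container, separately for controls and experimental wells —
#' a significant negative slope indicates that dilution itself depressed
#' prey growth, which breaks the assumption that prey behave identically
#' with and without predators. Second, per-capita ingestion is regressed on
#' diluent fraction and mean predator density; a negative predator
#' coefficient indicates predator interference.
#'
#' @param wells A wells table (both roles).
#' @param rates Optional precomputed [well_rates()] output; derived with
#'   defaults when missing.
#' @return A tibble with `screen`, `term`, `estimate`, `std.error`,
#'   `p.value`, `n`; screens whose covariate does not vary are reported with
#'   `NA` estimates and noted via a message.
#' @export
covariate_effects <- function(wells, rates = NULL) {
  if (is.null(rates)) rates <- well_rates(wells)

  screens <- list()
  add <- function(screen, fit_df, formula) {
    if (is.null(fit_df)) return()
    fit <- stats::lm(formula, data = fit_df)
    co <- summary(fit)$coefficients
    keep <- rownames(co) != "(Intercept)"
    screens[[length(screens) + 1L]] <<- tibble::tibble(
      screen = screen,
      term = rownames(co)[keep],
      estimate = unname(co[keep, "Estimate"]),
      std.error = unname(co[keep, "Std. Error"]),
      p.value = unname(co[keep, "Pr(>|t|)"]),
      n = nrow(fit_df)
    )
  }
  skip <- function(screen, why) {
    message(sprintf("covariate screen `%s` skipped: %s", screen, why))
    screens[[length(screens) + 1L]] <<- tibble::tibble(
      screen = screen, term = NA_character_, estimate = NA_real_,
      std.error = NA_real_, p.value = NA_real_, n = NA_integer_
    )
  }

  ctl <- dplyr::filter(wells, .data$role == "control")
  if (nrow(ctl) >= 3L && stats::sd(ctl$flw_fraction) > 0) {
    add("mu_controls~flw",
        data.frame(mu = specific_growth_rate(ctl$P0, ctl$Pt, ctl$t_days),
                   flw = ctl$flw_fraction),
        mu ~ flw)
  } else {
    skip("mu_controls~flw", "fewer than 3 controls or constant FLW fraction")
  }

  if (nrow(rates) >= 3L && stats::sd(rates$flw_fraction) > 0) {
    add("mu_experimental~flw",
        data.frame(mu = rates$mu_net, flw = rates$flw_fraction),
        mu ~ flw)
  } else {
    skip("mu_experimental~flw", "constant FLW fraction")
  }

  if (nrow(rates) >= 4L && stats::sd(rates$flw_fraction) > 0 &&
      stats::sd(rates$rm) > 0) {
    add("ingestion~flw+rm",
        data.frame(i = rates$i_cells, flw = rates$flw_fraction,
                   rm = rates$rm),
        i ~ flw + rm)
  } else {
    skip("ingestion~flw+rm", "constant covariate")
  }

  dplyr::bind_rows(screens)
}
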