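# Per-well rate arithmetic: growth, grazing, ingestion, clearance, GGE.

#' Specific (exponential) growth rate
#'
#' \eqn{r = \ln(N_t / N_0) / t}, the per-capita rate assuming exponential
#' change over the incubation.
#'
#' @param n0,nt Initial and final cell densities (same units); both must be
#'   strictly positive — a zero count leaves the rate undefined, which is a
#'   different situation from a negative rate (valid).
#' @param t Incubation duration in days.
#'
#' @return Growth rate in d⁻¹. Vectorised.
#'
#' @examples
#' specific_growth_rate(100, 200, 1) # ln 2
#' specific_growth_rate(100, 50, 2)  # negative: population declined
#' @export
specific_growth_rate <- function(n0, nt, t) {
  if (any(!is.finite(n0)) || any(!is.finite(nt)) || any(n0 <= 0) || any(nt <= 0)) {
    stop("densities must be positive: a zero count gives an undefined rate",
         call. = FALSE)
  }
  if (any(t <= 0)) stop("`t` must be positive", call. = FALSE)
  log(nt / n0) / t
}

#' Logarithmic-mean density
#'
#' The time-averaged density of a population changing exponentially between
#' `x0` and `xt`: \eqn{(x_t - x_0) / \ln(x_t / x_0)}, with the continuous
#' limit `x0` when the two values are equal. Used as the "geometric mean"
#' prey (or predator) level of an incubation.
#'
#' @param x0,xt Initial and final densities; strictly positive. Vectorised.
#'
#' @return The logarithmic mean, always between `min(x0, xt)` and
#'   `max(x0, xt)`.
#'
#' @examples
#' log_mean_density(100, 200)      # 100 / ln 2 = 144.27
#' log_mean_density(50000, 10000)  # 40000 / ln 5
#' @export
log_mean_density <- function(x0, xt) {
  if (any(!is.finite(x0)) || any(!is.finite(xt)) || any(x0 <= 0) || any(xt <= 0)) {
    stop("densities must be positive", call. = FALSE)
  }
  out <- (xt - x0) / (log(xt) - log(x0))
  # continuous limit: relative difference below sqrt(eps) -> arithmetic mean
  same <- abs(xt - x0) < sqrt(.Machine$double.eps) * pmax(x0, xt)
  out[same] <- ((x0 + xt) / 2)[same]
  out
}

#' Grazing coefficient against predator-free controls
#'
#' Exponential loss rate of prey attributable to predation,
#' \eqn{g = \mu_{ctrl} - \ln(P_t / P_0)/t}. When `mu_control` is the growth
#' rate of a single control computed from its own counts this is identical to
#' the classical control-vs-experimental difference
#' \eqn{(\ln(C_t/C_0) - \ln(P_t/P_0))/t}. Setting `mu_control = 0` yields the
#' uncorrected variant that ignores prey dynamics in the controls.
#'
#' Negative grazing rates — controls declining faster than experimental
#' wells — are biologically meaningless but diagnostically important, so they
#' are returned as-is; [well_rates()] flags them.
#'
#' @param mu_control Prey growth rate in the (matched) controls, d⁻¹.
#' @param p0,pt Initial and final prey densities in the experimental well.
#' @param t Incubation duration, days.
#'
#' @return Grazing coefficient g in d⁻¹ (may be negative).
#'
#' @examples
#' grazing_rate(log(2), 1000, 1000, 1) # controls doubled, prey held level
#' @export
grazing_rate <- function(mu_control, p0, pt, t) {
  if (any(!is.finite(p0)) || any(!is.finite(pt)) || any(p0 <= 0) || any(pt <= 0)) {
    stop("prey densities must be positive", call. = FALSE)
  }
  if (any(t <= 0)) stop("`t` must be positive", call. = FALSE)
  mu_control - log(pt / p0) / t
}

#' Assign control prey growth rates to experimental wells
#'
#' Controls are run at only a subset of prey levels, so the prey growth rate
#' \eqn{\mu} measured without predators must be extrapolated to every
#' experimental well. Four strategies are provided:
#'
#' * `"density_bins"` (default): control log-densities are cut into `bins`
#'   equal-width intervals; each experimental well receives the mean μ of the
#'   controls in the nearest bin. This mirrors the common practice of
#'   averaging controls over groups of neighbouring prey levels.
#' * `"global_mean"`: every well receives the mean μ over all controls.
#' * `"nearest_control"`: μ of the control closest in log density.
#' * `"interpolate"`: linear interpolation of μ in log density (constant
#'   extrapolation beyond the control range).
#'
#' @param controls Data frame of controls with columns `density`
#'   (cells mL⁻¹) and `mu` (d⁻¹).
#' @param wells Data frame of experimental wells with columns `well_id` and
#'   `density`.
#' @param strategy One of `"density_bins"`, `"global_mean"`,
#'   `"nearest_control"`, `"interpolate"`.
#' @param bins Number of density bins for `"density_bins"`.
#'
#' @return A tibble with `well_id`, `mu_control` and a `mu_source` provenance
#'   string naming the strategy and contributing controls.
#'
#' @examples
#' ctrl <- data.frame(density = c(1e3, 2e3, 2e4, 4e4),
#'                    mu = c(0.1, 0.1, 0.3, 0.3))
#' wells <- data.frame(well_id = c("a", "b"), density = c(1.5e3, 3e4))
#' assign_control_mu(ctrl, wells, "density_bins", bins = 2)
#' @export
assign_control_mu <- function(controls, wells,
                              strategy = c("density_bins", "global_mean",
                                           "nearest_control", "interpolate"),
                              bins = 2) {
  strategy <- match.arg(strategy)
  stopifnot(is.data.frame(controls), is.data.frame(wells))
  if (nrow(controls) == 0L) {
    stop("no controls: only the uncorrected variant (mu_control = 0) is possible",
         call. = FALSE)
  }
  if (any(controls$density <= 0) || any(wells$density <= 0)) {
    stop("densities must be positive", call. = FALSE)
  }
  lcd <- log(controls$density)
  lwd <- log(wells$density)

  if (strategy == "global_mean") {
    mu <- rep(mean(controls$mu), nrow(wells))
    src <- sprintf("global_mean(n=%d)", nrow(controls))
  } else if (strategy == "nearest_control") {
    idx <- vapply(lwd, function(x) which.min(abs(lcd - x)), integer(1))
    mu <- controls$mu[idx]
    src <- sprintf("nearest_control(#%d)", idx)
  } else if (strategy == "interpolate") {
    if (nrow(controls) < 2L) {
      mu <- rep(controls$mu, nrow(wells))
      src <- "interpolate(single control)"
    } else {
      ord <- order(lcd)
      mu <- stats::approx(lcd[ord], controls$mu[ord], xout = lwd, rule = 2,
                          ties = mean)$y
      src <- "interpolate(log-density)"
    }
  } else { # density_bins
    k <- max(1L, min(as.integer(bins), nrow(controls)))
    if (diff(range(lcd)) == 0 || k == 1L) {
      grp <- rep(1L, length(lcd))
      centers <- mean(lcd)
    } else {
      brk <- seq(min(lcd), max(lcd), length.out = k + 1L)
      grp <- findInterval(lcd, brk, rightmost.closed = TRUE, all.inside = TRUE)
      centers <- tapply(lcd, grp, mean)
    }
    mu_by_grp <- tapply(controls$mu, grp, mean)
    pick <- vapply(lwd, function(x) {
      names(centers)[which.min(abs(centers - x))]
    }, character(1))
    mu <- as.numeric(mu_by_grp[pick])
    src <- sprintf("density_bins(k=%d, bin=%s)", k, pick)
  }
  tibble::tibble(well_id = wells$well_id, mu_control = mu, mu_source = src)
}

#' Per-capita ingestion rate
#'
#' \eqn{I = P \, g / R_m}: prey cells removed per predator per day, computed
#' from the (log-mean or initial) prey density `p`, the grazing coefficient
#' `g` and the mean predator density `rm`. When a per-cell prey carbon
#' content `m` (pg C) is supplied, the carbon-specific rate
#' \eqn{I_C = I \cdot m / 1000} (ng C predator⁻¹ d⁻¹) is also returned.
#'
#' @param p Prey density used as the FR x-axis (cells mL⁻¹), positive.
#' @param g Grazing coefficient, d⁻¹ (sign is preserved).
#' @param rm Mean predator density (cells mL⁻¹), positive.
#' @param m Optional per-cell prey carbon, pg C.
#'
#' @return A tibble with `i_cells` (prey predator⁻¹ d⁻¹) and `i_carbon`
#'   (ng C predator⁻¹ d⁻¹, `NA` when `m` is missing).
#'
#' @examples
#' ingestion_rate(10000, 0.1, 25)          # 40 cells / predator / day
#' ingestion_rate(10000, 0.1, 25, m = 27.1)
#' @export
ingestion_rate <- function(p, g, rm, m = NULL) {
  if (any(p <= 0)) stop("`p` must be positive", call. = FALSE)
  if (any(rm <= 0)) stop("`rm` (mean predator density) must be positive",
                         call. = FALSE)
  i_cells <- p * g / rm
  i_carbon <- if (is.null(m)) rep(NA_real_, length(i_cells)) else i_cells * m / 1000
  tibble::tibble(i_cells = i_cells, i_carbon = i_carbon)
}

#' Clearance rate and proportion of prey ingested
#'
#' \eqn{C = I / P}, the volume of medium a predator clears of prey per day
#' (mL predator⁻¹ d⁻¹). Numerically, C is identical to the proportion of the
#' prey population in 1 mL that is ingested per day, which is why the
#' clearance curve doubles as the proportion-ingested diagnostic used for
#' FR-type discrimination.
#'
#' @param i_cells Ingestion rate, prey predator⁻¹ d⁻¹.
#' @param p Prey density, cells mL⁻¹, positive.
#'
#' @return A tibble with `clearance_ml` (mL predator⁻¹ d⁻¹) and
#'   `proportion_ingested` (d⁻¹; same number, read as a fraction of the
#'   1-mL reference volume).
#'
#' @examples
#' clearance_and_proportion(40, 10000) # 0.004 mL = 4.0 uL; 0.4% ingested
#' @export
clearance_and_proportion <- function(i_cells, p) {
  if (any(p <= 0)) stop("`p` must be positive", call. = FALSE)
  cl <- i_cells / p
  tibble::tibble(clearance_ml = cl, proportion_ingested = cl)
}

#' Gross growth efficiency
#'
#' The fraction of ingested prey biomass converted into predator biomass,
#' \eqn{GGE = r M / I_C} on a carbon basis (with `M` the predator's cell
#' carbon in ng C and `I_C` the ingestion in ng C predator⁻¹ d⁻¹), or
#' \eqn{GGE = r V_{pred} / (I \, V_{prey})} on a cell-volume basis. GGE can
#' only lie in (0, 1); values outside that range indicate inconsistent NR/FR
#' estimates and are the core cross-check between the two experiment types.
#'
#' @param r Predator specific growth rate, d⁻¹.
#' @param intake Ingestion rate: ng C predator⁻¹ d⁻¹ (`basis = "carbon"`) or
#'   prey cells predator⁻¹ d⁻¹ (`basis = "volume"`). Must be positive.
#' @param predator_biomass Predator cell carbon (ng C) or cell volume (µm³),
#'   matching `basis`.
#' @param prey_volume Prey cell volume (µm³); only used for
#'   `basis = "volume"`.
#' @param basis `"carbon"` or `"volume"`.
#'
#' @return GGE (dimensionless).
#'
#' @examples
#' # volume basis: r = 0.32/d, ciliate 63650 um^3 eating 667 cells of 221 um^3
#' gross_growth_efficiency(0.32, 667, 63650, prey_volume = 221,
#'                         basis = "volume")
#' @export
gross_growth_efficiency <- function(r, intake, predator_biomass,
                                    prey_volume = NULL,
                                    basis = c("carbon", "volume")) {
  basis <- match.arg(basis)
  if (any(intake <= 0)) {
    stop("`intake` must be positive: GGE is undefined for non-positive ingestion",
         call. = FALSE)
  }
  if (basis == "carbon") {
    r * predator_biomass / intake
  } else {
    if (is.null(prey_volume)) {
      stop("`prey_volume` is required for the volume basis", call. = FALSE)
    }
    r * predator_biomass / (intake * prey_volume)
  }
}

#' Generation time
#'
#' Doubling time of an exponentially growing population,
#' \eqn{G = \ln 2 / r_{max}} (days). Used when judging whether an
#' acclimatization period was long enough (at least one generation per
#' stepwise change of conditions is the usual rule of thumb).
#'
#' @param rmax Maximum specific growth rate, d⁻¹, positive.
#' @return Generation time in days.
#' @examples
#' generation_time(0.32) # 2.17 d
#' @export
generation_time <- function(rmax) {
  if (any(rmax <= 0)) stop("`rmax` must be positive", call. = FALSE)
  log(2) / rmax
}

#' Derive per-well rates from a wells table
#'
#' The central bookkeeping step: takes a validated wells table (see
#' [read_wells()] for the schema, or [simulate_experiment()] which emits it)
#' and returns one row of derived rates per experimental well, with control
#' prey growth rates assigned by [assign_control_mu()].
#'
#' @param wells A wells data frame (experimental + control rows).
#' @param mu_strategy Strategy for [assign_control_mu()]; use
#'   `"uncorrected"` to set `mu_control = 0` everywhere (the variant that
#'   ignores prey dynamics in the controls).
#' @param bins Bins for the `"density_bins"` strategy.
#' @param density_axis Prey density attached to each rate for downstream FR
#'   fitting: `"mean"` (log-mean over the incubation, default) or
#'   `"initial"`.
#' @param rm_method Mean predator density: `"log_mean"` (default) or
#'   `"geometric"` (\eqn{\sqrt{R_0 R_t}}); the two differ by <1% at typical
#'   growth rates.
#' @param prey_carbon Optional per-cell prey carbon (pg C) to populate
#'   carbon-specific ingestion.
#' @param min_count Counted-cell threshold below which a `low_count` flag is
#'   raised (default 50).
#'
#' @return A tibble with one row per experimental well: `well_id`, `r`
#'   (predator growth), `mu_control`, `mu_net` (prey net rate in the well),
#'   `g`, `p_mean`, `p_initial`, `density` (the chosen axis), `rm`,
#'   `i_cells`, `i_carbon`, `clearance_ml`, `proportion_ingested`,
#'   `flw_fraction`, `flags` (semicolon-separated tokens, `""` if clean).
#'
#' @export
well_rates <- function(wells,
                       mu_strategy = c("density_bins", "global_mean",
                                       "nearest_control", "interpolate",
                                       "uncorrected"),
                       bins = 2,
                       density_axis = c("mean", "initial"),
                       rm_method = c("log_mean", "geometric"),
                       prey_carbon = NULL,
                       min_count = 50) {
  mu_strategy <- match.arg(mu_strategy)
  density_axis <- match.arg(density_axis)
  rm_method <- match.arg(rm_method)

  exp_w <- dplyr::filter(wells, .data$role == "experimental")
  ctl_w <- dplyr::filter(wells, .data$role == "control")
  if (nrow(exp_w) == 0L) stop("no experimental wells", call. = FALSE)

  if (mu_strategy == "uncorrected") {
    mu_tab <- tibble::tibble(well_id = exp_w$well_id, mu_control = 0,
                             mu_source = "uncorrected(mu=0)")
  } else {
    if (nrow(ctl_w) == 0L) {
      stop("no control wells; use mu_strategy = \"uncorrected\"", call. = FALSE)
    }
    ctl <- tibble::tibble(
      density = log_mean_density(ctl_w$P0, ctl_w$Pt),
      mu = specific_growth_rate(ctl_w$P0, ctl_w$Pt, ctl_w$t_days)
    )
    mu_tab <- assign_control_mu(
      ctl,
      tibble::tibble(well_id = exp_w$well_id,
                     density = log_mean_density(exp_w$P0, exp_w$Pt)),
      strategy = mu_strategy, bins = bins
    )
  }

  out <- exp_w |>
    dplyr::left_join(mu_tab, by = "well_id") |>
    dplyr::mutate(
      r = specific_growth_rate(.data$R0, .data$Rt, .data$t_days),
      mu_net = specific_growth_rate(.data$P0, .data$Pt, .data$t_days),
      g = grazing_rate(.data$mu_control, .data$P0, .data$Pt, .data$t_days),
      p_mean = log_mean_density(.data$P0, .data$Pt),
      p_initial = .data$P0,
      density = if (density_axis == "mean") .data$p_mean else .data$p_initial,
      rm = if (rm_method == "log_mean") {
        log_mean_density(.data$R0, .data$Rt)
      } else {
        sqrt(.data$R0 * .data$Rt)
      }
    )

  ing <- ingestion_rate(out$density, out$g, out$rm, m = prey_carbon)
  clr <- clearance_and_proportion(ing$i_cells, out$density)

  counts <- c("counted_prey_0", "counted_prey_t", "counted_pred_0",
              "counted_pred_t")
  have_counts <- all(counts %in% names(out))
  flags <- purrr::pmap_chr(
    list(g = out$g,
         low = if (have_counts) {
           purrr::pmap_lgl(out[counts], function(...) {
             any(stats::na.omit(c(...)) < min_count)
           })
         } else rep(FALSE, nrow(out))),
    function(g, low) {
      f <- character(0)
      if (g < 0) f <- c(f, "negative_grazing")
      if (low) f <- c(f, "low_count")
      paste(f, collapse = ";")
    }
  )

  tibble::tibble(
    well_id = out$well_id,
    r = out$r,
    mu_control = out$mu_control,
    mu_source = out$mu_source,
    mu_net = out$mu_net,
    g = out$g,
    p_mean = out$p_mean,
    p_initial = out$p_initial,
    density = out$density,
    rm = out$rm,
    i_cells = ing$i_cells,
    i_carbon = ing$i_carbon,
    clearance_ml = clr$clearance_ml,
    proportion_ingested = clr$proportion_ingested,
    flw_fraction = out$flw_fraction,
    flags = flags
  )
}
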