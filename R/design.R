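# Experiment-design calculator: geometric target-density series and per-
# container volume allocation under three dilution modes.

#' Geometric series of target prey densities
#'
#' Prey levels for a response experiment are spaced geometrically,
#' \eqn{P_k = P_{min} \cdot f^k}, which gives even coverage on the log axis
#' from near-zero to satiating food. Factors between 1.1 and 1.5 are the
#' usual guideline; values outside that band are allowed with a warning.
#'
#' @param p_min,p_max Lowest and highest target densities (cells mL⁻¹).
#' @param factor Multiplicative step between neighbouring levels, in (1, 2].
#' @return A numeric vector of target densities, all <= `p_max`.
#' @examples
#' target_density_series(1000, 8000, 2)    # 1000 2000 4000 8000
#' length(target_density_series(1000, 1e5, 1.3)) # 18 levels
#' @export
target_density_series <- function(p_min, p_max, factor) {
  if (!(p_min > 0 && p_min < p_max)) {
    stop("need 0 < p_min < p_max", call. = FALSE)
  }
  if (!(factor > 1 && factor <= 2)) {
    stop("`factor` must be in (1, 2]", call. = FALSE)
  }
  if (factor < 1.1 || factor > 1.5) {
    warning(sprintf(
      "factor %g is outside the usual 1.1-1.5 guideline", factor
    ), call. = FALSE)
  }
  n <- floor(log(p_max / p_min) / log(factor) + 1e-9)
  p_min * factor^(0:n)
}

#' Allocate inoculation volumes for every container
#'
#' Converts target prey/predator densities into per-container pipetting
#' volumes. Each experimental container receives prey culture
#' \eqn{D_{y2} = V P_{ini} / P_{stock}}, predator culture
#' \eqn{D_x = V R_{ini} / R_{stock}}, and the remainder as diluent. Controls
#' are generated at every `controls_every`-th prey level and receive a
#' filtered predator-culture volume equal to `Dx` instead of live predators,
#' so the dissolved background matches.
#'
#' Dilution modes name the diluent: `"FLW"` filtered lake (or sea) water,
#' `"FPC"` filtered prey culture (which pins `Dy2 + FPC` to a constant
#' across containers, since `Dx` is constant), or `"predator_filtrate"` for
#' species sensitive to dilution. The arithmetic is identical; the label
#' feeds the FLW-fraction covariate and the culture-volume budget.
#'
#' @param targets Target prey densities (cells mL⁻¹), e.g. from
#'   [target_density_series()].
#' @param prey_stock,predator_stock Stock culture densities (cells mL⁻¹);
#'   must exceed the highest corresponding target.
#' @param container_volume Working volume per container, mL.
#' @param target_predator Target predator density (cells mL⁻¹), identical
#'   across containers to avoid predator interference.
#' @param mode Diluent: `"FLW"`, `"FPC"` or `"predator_filtrate"`.
#' @param controls_every Place a predator-free control at every n-th prey
#'   level (default 2).
#' @param control_diluent What replaces the predator inoculum in controls:
#'   `"Dx_filt"` (an equal volume of filtered predator culture, so the
#'   dissolved background matches — the ideal) or `"diluent"` (plain
#'   diluent, the pragmatic choice when the prey cannot be filtered out of
#'   the predator culture; controls then receive systematically more
#'   diluent than experimental containers).
#' @param rounding Pipettable rounding increment in mL (default 0.01;
#'   applied to reported volumes, with the diluent absorbing the residual so
#'   containers still close exactly).
#' @return A `design_plan` tibble: `level`, `role`, `Pini`, `Rini`, `V`,
#'   `Dy2`, `Dx`, `Dx_filt`, `diluent_type`, `diluent_mL`, `flw_fraction`, plus
#'   attributes `prey_culture_mL` and `predator_culture_mL` (total demand).
#' @export
allocate_volumes <- function(targets, prey_stock, predator_stock,
                             container_volume, target_predator,
                             mode = c("FLW", "FPC", "predator_filtrate"),
                             controls_every = 2,
                             control_diluent = c("Dx_filt", "diluent"),
                             rounding = 0.01) {
  mode <- match.arg(mode)
  control_diluent <- match.arg(control_diluent)
  stopifnot(container_volume > 0, target_predator >= 0,
            prey_stock > 0, predator_stock > 0)
  if (max(targets) > prey_stock) {
    stop(sprintf(
      "infeasible design: target %g cells/mL exceeds the prey stock (%g)",
      max(targets), prey_stock
    ), call. = FALSE)
  }
  if (target_predator > predator_stock) {
    stop("infeasible design: predator target exceeds the predator stock",
         call. = FALSE)
  }
  V <- container_volume
  dx <- V * target_predator / predator_stock

  rows <- list()
  for (k in seq_along(targets)) {
    dy2 <- V * targets[k] / prey_stock
    dil <- V - dy2 - dx
    if (dil < -1e-9) {
      stop(sprintf(
        "infeasible design at level %d (Pini = %g): inocula exceed the %g mL container",
        k, targets[k], V
      ), call. = FALSE)
    }
    dil <- max(dil, 0)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      level = k, role = "experimental", Pini = targets[k],
      Rini = target_predator, V = V, Dy2 = dy2, Dx = dx, Dx_filt = 0,
      diluent_type = mode, diluent_mL = dil
    )
    if (controls_every > 0 && (k - 1L) %% controls_every == 0L) {
      # control: same prey level, predator inoculum replaced by filtered
      # predator culture or by plain diluent
      filt <- if (control_diluent == "Dx_filt") dx else 0
      rows[[length(rows) + 1L]] <- tibble::tibble(
        level = k, role = "control", Pini = targets[k], Rini = 0,
        V = V, Dy2 = dy2, Dx = 0, Dx_filt = filt,
        diluent_type = mode, diluent_mL = dil + (dx - filt)
      )
    }
  }
  plan <- dplyr::bind_rows(rows)

  if (rounding > 0) {
    plan$Dy2 <- round(plan$Dy2 / rounding) * rounding
    plan$Dx <- round(plan$Dx / rounding) * rounding
    plan$Dx_filt <- round(plan$Dx_filt / rounding) * rounding
    # closure absorbs the rounding residual into the diluent
    plan$diluent_mL <- plan$V - plan$Dy2 - plan$Dx - plan$Dx_filt
  }
  plan$flw_fraction <- if (mode == "FLW") plan$diluent_mL / plan$V else
    rep(0, nrow(plan))

  # culture-volume budget: live inocula plus any filtered culture demand
  prey_demand <- sum(plan$Dy2) +
    if (mode == "FPC") sum(plan$diluent_mL) else 0
  pred_demand <- sum(plan$Dx) + sum(plan$Dx_filt) +
    if (mode == "predator_filtrate") sum(plan$diluent_mL) else 0

  structure(
    plan,
    prey_culture_mL = prey_demand,
    predator_culture_mL = pred_demand,
    class = c("design_plan", class(plan))
  )
}

#' Advisory checks on a design plan
#'
#' Pure warnings, no errors: flags predator targets spreading more than
#' ±20% across containers (interference risk), expected counted cells below
#' 50 in the counting subsample (imprecise rates), geometric factors
#' outside the 1.1–1.5 guideline, and missing controls.
#'
#' @param plan A [allocate_volumes()] plan (or any data frame with `role`,
#'   `Pini`, `Rini` columns).
#' @param subsample_mL Volume counted per subsample, mL (prey and predator;
#'   a named vector `c(prey = , predator = )` may be given).
#' @return A character vector of warnings (length 0 when the plan is clean).
#' @export
design_checks <- function(plan, subsample_mL = c(prey = 1, predator = 3)) {
  if (length(subsample_mL) == 1L) {
    subsample_mL <- c(prey = unname(subsample_mL),
                      predator = unname(subsample_mL))
  }
  warnings <- character(0)
  expw <- plan[plan$role == "experimental", ]

  rini <- expw$Rini[expw$Rini > 0]
  if (length(rini) > 1L && max(rini) / min(rini) > 1.2) {
    warnings <- c(warnings, sprintf(
      "predator abundance spreads more than 20%% across containers (%.3g-%.3g per mL)",
      min(rini), max(rini)
    ))
  }

  exp_pred_count <- expw$Rini * subsample_mL[["predator"]]
  if (any(exp_pred_count < 50)) {
    warnings <- c(warnings, sprintf(
      "expected predator counts below 50 cells in %d container(s) (minimum %.1f)",
      sum(exp_pred_count < 50), min(exp_pred_count)
    ))
  }
  exp_prey_count <- expw$Pini * subsample_mL[["prey"]]
  if (any(exp_prey_count < 50)) {
    warnings <- c(warnings, sprintf(
      "expected prey counts below 50 cells in %d container(s) (minimum %.1f)",
      sum(exp_prey_count < 50), min(exp_prey_count)
    ))
  }

  p <- sort(unique(expw$Pini))
  if (length(p) > 1L) {
    f <- p[-1] / p[-length(p)]
    if (any(f < 1.1 - 1e-9 | f > 1.5 + 1e-9)) {
      warnings <- c(warnings,
                    "prey-level factors fall outside the 1.1-1.5 guideline")
    }
  }

  if (!any(plan$role == "control")) {
    warnings <- c(warnings, "plan contains no predator-free controls")
  }
  warnings
}
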