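# End-to-end analysis: rates for every dataset variant, model fits with
# AICc ranking, FR-type verdict, GGE consistency and covariate screens.

#' Run the full NR/FR analysis pipeline
#'
#' Derives per-well rates and fits the requested model catalogue for every
#' dataset variant — control-corrected vs uncorrected grazing × initial vs
#' log-mean prey axis × untransformed vs log-transformed ingestion — then
#' ranks models within each variant by AICc, issues the
#' proportion-of-prey-ingested type verdict, checks gross growth efficiency
#' for the (0, 1) consistency range, and screens for diluent and
#' predator-density bias. Variants that are statistically inadmissible
#' (log transform over non-positive ingestion rates) are recorded as
#' refusals and the remaining variants still run. Every fitted estimate
#' carries its variant provenance; it is never reported bare.
#'
#' @param wells A validated wells table ([read_wells()] /
#'   [simulate_experiment()]).
#' @param candidates Named list of FR `theta` specifications (numbers or
#'   `"free"`), as in [fit_fr()].
#' @param corrections,axes,transforms Character vectors selecting which
#'   dataset variants to run.
#' @param mu_strategy,bins Control-assignment settings for [well_rates()]
#'   in the corrected variants.
#' @param prey_volume,predator_volume Cell volumes (µm³) for the GGE block.
#' @param prey_model,predator_model [carbon_model()]s for the GGE block.
#' @param alpha Significance level for the type verdict.
#' @return A `grazefit_report` list: `rates` (per-variant rate tables),
#'   `nr_fits`, `fr_fits`, `rankings`, `refusals`, `type_verdict`, `gge`
#'   (tibble with `gge_outside_range` flags), `covariates`, `flags`.
#' @export
run_pipeline <- function(wells,
                         candidates = list(FR2 = 1, FR3 = 2,
                                           `FR3-theta=3` = 3),
                         corrections = c("controls", "none"),
                         axes = c("initial", "mean"),
                         transforms = c("none", "log"),
                         mu_strategy = "density_bins", bins = 2,
                         prey_volume = 221, predator_volume = 63650,
                         prey_model = carbon_model(0.261, 0.860, "prey"),
                         predator_model = carbon_model(0.216, 0.939,
                                                       "predator"),
                         alpha = 0.05) {
  wells <- validate_wells(wells)
  prey_pg <- carbon_from_volume(prey_volume, prey_model)
  pred_ng <- carbon_from_volume(predator_volume, predator_model) / 1000

  rates_tabs <- list()
  nr_fits <- list()
  fr_fits <- list()
  rankings <- list()
  refusals <- tibble::tibble(variant = character(0), reason = character(0))
  gge_rows <- list()

  has_controls <- any(wells$role == "control")

  for (corr in corrections) {
    strat <- if (corr == "controls") mu_strategy else "uncorrected"
    if (corr == "controls" && !has_controls) {
      refusals <- dplyr::bind_rows(refusals, tibble::tibble(
        variant = "correction=controls",
        reason = "no control wells present; only the uncorrected variant ran"
      ))
      next
    }
    for (axis in axes) {
      rates <- well_rates(wells, mu_strategy = strat, bins = bins,
                          density_axis = axis, prey_carbon = prey_pg)
      key <- sprintf("correction=%s|axis=%s", corr, axis)
      rates_tabs[[key]] <- rates

      nr_key <- sprintf("NR|axis=%s", axis)
      if (is.null(nr_fits[[nr_key]])) {
        nr_fits[[nr_key]] <- tryCatch(fit_nr(rates, density_axis = axis),
                                      error = function(e) e$message)
      }

      for (tr in transforms) {
        vkey <- sprintf("%s|transform=%s", key, tr)
        if (tr == "log" && any(rates$i_cells <= 0)) {
          refusals <- dplyr::bind_rows(refusals, tibble::tibble(
            variant = vkey,
            reason = sprintf(
              "log transform refused: %d well(s) with non-positive ingestion",
              sum(rates$i_cells <= 0)
            )
          ))
          next
        }
        fits <- list()
        for (nm in names(candidates)) {
          f <- tryCatch(
            fit_fr(rates, theta = candidates[[nm]], transform = tr,
                   correction = corr, density_axis = axis),
            error = function(e) NULL
          )
          if (!is.null(f)) fits[[f$model_id]] <- f
        }
        if (length(fits) == 0L) {
          refusals <- dplyr::bind_rows(refusals, tibble::tibble(
            variant = vkey, reason = "no FR candidate converged"
          ))
          next
        }
        fr_fits[[vkey]] <- fits
        rankings[[vkey]] <- rank_models(fits)

        # GGE consistency: best model of the variant with the NR rmax
        nr_fit <- nr_fits[[nr_key]]
        if (inherits(nr_fit, "nr_fit")) {
          rmax <- nr_fit$params$estimate[nr_fit$params$term == "rmax"]
          best <- fits[[rankings[[vkey]]$model_id[1L]]]
          imax <- best$derived$estimate[best$derived$term == "imax"]
          if (length(imax) == 1L && is.finite(imax) && imax > 0) {
            gge_c <- gross_growth_efficiency(
              rmax, imax * prey_pg / 1000, pred_ng, basis = "carbon")
            gge_v <- gross_growth_efficiency(
              rmax, imax, predator_volume, prey_volume, basis = "volume")
            gge_rows[[vkey]] <- tibble::tibble(
              variant = vkey, model_id = best$model_id,
              rmax = rmax, imax = imax,
              gge_carbon = gge_c, gge_volume = gge_v,
              gge_outside_range = gge_c <= 0 | gge_c >= 1 |
                gge_v <= 0 | gge_v >= 1
            )
          }
        }
      }
    }
  }

  # Type verdict on the all-positive dataset the diagnostic was designed
  # for: uncorrected grazing, initial prey axis.
  verdict_rates <- rates_tabs[["correction=none|axis=initial"]]
  if (is.null(verdict_rates)) verdict_rates <- rates_tabs[[1L]]
  type_verdict <- tryCatch(
    discriminate_fr_type(verdict_rates, alpha = alpha),
    error = function(e) e$message
  )

  covariates <- tryCatch(
    suppressMessages(covariate_effects(wells, rates_tabs[[1L]])),
    error = function(e) e$message
  )

  all_flags <- unique(unlist(strsplit(
    unlist(lapply(rates_tabs, `[[`, "flags")), ";", fixed = TRUE
  )))
  all_flags <- all_flags[nzchar(all_flags)]

  structure(list(
    rates = rates_tabs,
    nr_fits = nr_fits,
    fr_fits = fr_fits,
    rankings = rankings,
    refusals = refusals,
    type_verdict = type_verdict,
    gge = dplyr::bind_rows(gge_rows),
    covariates = covariates,
    flags = all_flags,
    prey_carbon_pg = prey_pg,
    predator_carbon_ng = pred_ng
  ), class = "grazefit_report")
}

#' @export
print.grazefit_report <- function(x, ...) {
  cat("== grazefit pipeline report ==\n")
  cat(sprintf("variants analysed: %d; refusals: %d\n",
              length(x$rankings), nrow(x$refusals)))
  for (v in names(x$rankings)) {
    cat("\n--", v, "--\n")
    print(as.data.frame(x$rankings[[v]]), digits = 4, row.names = FALSE)
  }
  if (nrow(x$refusals)) {
    cat("\nrefusals:\n")
    print(as.data.frame(x$refusals), row.names = FALSE)
  }
  if (inherits(x$type_verdict, "fr_type_verdict")) {
    cat("\n")
    print(x$type_verdict)
  }
  if (!is.null(x$gge) && nrow(x$gge)) {
    cat("\nGGE consistency (must lie in (0, 1)):\n")
    print(as.data.frame(x$gge), digits = 3, row.names = FALSE)
  }
  if (length(x$flags)) {
    cat("\nquality flags raised:", paste(x$flags, collapse = ", "), "\n")
  }
  invisible(x)
}
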