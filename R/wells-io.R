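# Wells-table serialization and validation.

wells_schema <- c("well_id", "role", "target_prey", "P0", "Pt", "R0", "Rt",
                  "counted_prey_0", "counted_prey_t", "counted_pred_0",
                  "counted_pred_t", "subsample_mL", "t_days", "flw_fraction")

#' Read and validate a wells table
#'
#' Reads the per-well CSV interchange format (one row per incubation
#' container) and validates it: the header must contain the full schema,
#' roles must be `experimental` or `control`, densities must be
#' non-negative, durations positive, and control rows must leave the
#' predator columns empty (an empty cell is missing data; `0` would be a
#' measured zero, which is invalid for a rate and equally rejected in
#' predator columns of controls). Malformed rows are reported with their
#' row numbers.
#'
#' @param path Path to a CSV file with columns `well_id, role, target_prey,
#'   P0, Pt, R0, Rt, counted_prey_0, counted_prey_t, counted_pred_0,
#'   counted_pred_t, subsample_mL, t_days, flw_fraction`.
#' @return A validated tibble of well observations.
#' @export
read_wells <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  wells <- readr::read_csv(path, col_types = readr::cols(
    well_id = readr::col_character(),
    role = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  validate_wells(wells)
}

#' Validate a wells table already in memory
#'
#' @param wells A data frame in the [read_wells()] schema.
#' @return The validated tibble (invisibly unchanged).
#' @export
validate_wells <- function(wells) {
  missing_cols <- setdiff(wells_schema, names(wells))
  if (length(missing_cols)) {
    stop(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  bad_role <- which(!wells$role %in% c("experimental", "control"))
  if (length(bad_role)) {
    stop(sprintf("row %s: role must be 'experimental' or 'control'",
                 paste(bad_role, collapse = ", ")), call. = FALSE)
  }
  for (col in c("target_prey", "P0", "Pt", "R0", "Rt")) {
    bad <- which(!is.na(wells[[col]]) & wells[[col]] < 0)
    if (length(bad)) {
      stop(sprintf("row %s: negative density in column %s",
                   paste(bad, collapse = ", "), col), call. = FALSE)
    }
  }
  bad_t <- which(!is.na(wells$t_days) & wells$t_days <= 0)
  if (length(bad_t)) {
    stop(sprintf("row %s: t_days must be positive",
                 paste(bad_t, collapse = ", ")), call. = FALSE)
  }
  is_ctl <- wells$role == "control"
  pred_cols <- c("R0", "Rt", "counted_pred_0", "counted_pred_t")
  filled <- Reduce(`|`, lapply(pred_cols, function(cl) !is.na(wells[[cl]])))
  bad_ctl <- which(is_ctl & filled)
  if (length(bad_ctl)) {
    stop(sprintf(
      "row %s: control rows must leave predator columns (R0, Rt, counts) empty",
      paste(bad_ctl, collapse = ", ")
    ), call. = FALSE)
  }
  bad_flw <- which(!is.na(wells$flw_fraction) &
                     (wells$flw_fraction < 0 | wells$flw_fraction > 1))
  if (length(bad_flw)) {
    stop(sprintf("row %s: flw_fraction must lie in [0, 1]",
                 paste(bad_flw, collapse = ", ")), call. = FALSE)
  }
  tibble::as_tibble(wells)
}

#' Write a wells table
#'
#' Writes the CSV in the exact [read_wells()] schema; a write–read round
#' trip is the identity (simulation attributes such as the hidden truth are
#' not serialized).
#'
#' @param wells A wells tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wells <- function(wells, path) {
  readr::write_csv(wells[, wells_schema], path, progress = FALSE)
  invisible(path)
}
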