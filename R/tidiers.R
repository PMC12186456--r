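# broom-style accessors for fitted response objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted response model
#'
#' One row per estimated parameter (plus derived quantities such as
#' \eqn{I_{max} = 1/h} when present), in the usual `term` / `estimate` /
#' `std.error` / `statistic` / `p.value` layout.
#'
#' @param x An `nr_fit` or `fr_fit` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.response_fit <- function(x, ...) {
  out <- x$params
  if (!is.null(x$derived) && nrow(x$derived)) {
    out <- dplyr::bind_rows(
      out,
      dplyr::mutate(x$derived, statistic = NA_real_, p.value = NA_real_)
    )
  }
  dplyr::mutate(out, model_id = x$model_id, .before = 1L)
}

#' One-row summary of a fitted response model
#'
#' @param x An `nr_fit` or `fr_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with the model identity, fit statistics and the
#'   full dataset-variant provenance (transform, correction, density axis).
#' @export
glance.response_fit <- function(x, ...) {
  tibble::tibble(
    model_id = x$model_id,
    rss = x$rss,
    n = x$n,
    n_params = x$n_params,
    aicc = x$aicc,
    transform = x$transform,
    correction = x$correction,
    density_axis = x$density_axis,
    converged = x$converged
  )
}

#' @export
tidy.fr_type_verdict <- function(x, ...) {
  dplyr::mutate(x$coefficients, verdict = x$verdict, .before = 1L)
}
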