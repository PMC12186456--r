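# Cell sizing and volume-to-carbon conversion shared by all downstream stages.

#' Cell volume of a prolate spheroid
#'
#' Computes cell volume from length and width assuming the cell is a prolate
#' spheroid rotated about its long axis, the standard convention for sizing
#' ciliates and flagellates from microscope measurements:
#' \eqn{V = (\pi/6) \, L \, W^2}.
#'
#' @param length Cell length in µm (the long axis). Vectorised.
#' @param width Cell width in µm; must satisfy `width <= length`.
#'
#' @return Cell volume in µm³.
#'
#' @examples
#' spheroid_volume(10, 10) # sphere of diameter 10: pi * 10^3 / 6
#' spheroid_volume(20, 10)
#' @export
spheroid_volume <- function(length, width) {
  if (any(!is.finite(length)) || any(!is.finite(width))) {
    stop("`length` and `width` must be finite numbers", call. = FALSE)
  }
  if (any(width <= 0)) {
    stop("cell dimensions must be positive", call. = FALSE)
  }
  if (any(length < width)) {
    stop("`length` must be >= `width` (prolate spheroid about the long axis)",
         call. = FALSE)
  }
  (pi / 6) * length * width^2
}

#' Allometric volume-to-carbon model
#'
#' A power-law model \eqn{C = s \cdot V^{e}} converting cell volume (µm³) to
#' cell carbon (pg C). Coefficients are organism-specific; protist plankton
#' conventionally use different coefficients for small flagellates and for
#' ciliates, so models are stored per organism rather than globally.
#'
#' @param scale Multiplier `s` in pg C µm^(-3e); must be positive.
#' @param exponent Allometric exponent `e`, in (0, 1.2].
#' @param organism Optional label carried through reports.
#'
#' @return An object of class `carbon_model`.
#'
#' @examples
#' # coefficients used for a cryptophyte prey and a ciliate predator
#' carbon_model(0.261, 0.860, "prey")
#' carbon_model(0.216, 0.939, "predator")
#' @export
carbon_model <- function(scale, exponent, organism = "") {
  stopifnot(is.numeric(scale), length(scale) == 1L,
            is.numeric(exponent), length(exponent) == 1L)
  if (scale <= 0) stop("`scale` must be positive", call. = FALSE)
  if (exponent <= 0 || exponent > 1.2) {
    stop("`exponent` must lie in (0, 1.2]", call. = FALSE)
  }
  structure(
    list(scale = scale, exponent = exponent, organism = as.character(organism)),
    class = "carbon_model"
  )
}

#' @export
print.carbon_model <- function(x, ...) {
  lab <- if (nzchar(x$organism)) paste0(" [", x$organism, "]") else ""
  cat(sprintf("<carbon_model%s> C = %g * V^%g  (pg C, V in um^3)\n",
              lab, x$scale, x$exponent))
  invisible(x)
}

#' Per-cell carbon from cell volume
#'
#' Applies an allometric [carbon_model()] to one or more cell volumes.
#'
#' @param volume Cell volume(s) in µm³; must be positive.
#' @param model A [carbon_model()].
#'
#' @return Cell carbon in pg C (divide by 1000 for ng C).
#'
#' @examples
#' carbon_from_volume(221, carbon_model(0.261, 0.860))    # ~27 pg C
#' carbon_from_volume(63650, carbon_model(0.216, 0.939))  # ~7000 pg = 7.00 ng C
#' @export
carbon_from_volume <- function(volume, model) {
  stopifnot(inherits(model, "carbon_model"))
  if (any(!is.finite(volume)) || any(volume <= 0)) {
    stop("`volume` must be positive and finite", call. = FALSE)
  }
  model$scale * volume^model$exponent
}

#' Biomass concentration from cell density
#'
#' Converts a cell density and a per-cell carbon content to a biomass
#' concentration: density (cells mL⁻¹) × carbon (pg C cell⁻¹) × 10⁻⁶
#' gives mg C L⁻¹.
#'
#' @param density Cell density in cells mL⁻¹; non-negative. Vectorised.
#' @param carbon_per_cell Per-cell carbon in pg C.
#'
#' @return Biomass concentration in mg C L⁻¹.
#'
#' @examples
#' biomass_concentration(40000, 27.1) # ~1.08 mg C / L
#' @export
biomass_concentration <- function(density, carbon_per_cell) {
  if (any(!is.finite(density)) || any(density < 0)) {
    stop("`density` must be non-negative and finite", call. = FALSE)
  }
  if (any(carbon_per_cell <= 0)) {
    stop("`carbon_per_cell` must be positive", call. = FALSE)
  }
  density * carbon_per_cell * 1e-6
}
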