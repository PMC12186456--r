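# Closed-form numerical- and functional-response families.

#' Parameters of the threshold numerical response
#'
#' The saturating consumer growth model with an x-intercept:
#' \eqn{r(P) = r_{max} (P - P') / (k_2 + (P - P'))}. `p_prime` is the
#' threshold prey density at which growth is zero; `k2` is a
#' half-saturation-like constant on the same axis as `P` (cells mL⁻¹ or
#' mg C L⁻¹, whichever the data use).
#'
#' @param rmax Maximum growth rate, d⁻¹ (> 0).
#' @param p_prime Threshold prey density (>= 0).
#' @param k2 Saturation constant (> 0).
#' @return An object of class `nr_params`.
#' @examples
#' nr_params(0.32, 1349, 5000)
#' @export
nr_params <- function(rmax, p_prime, k2) {
  stopifnot(length(rmax) == 1L, length(p_prime) == 1L, length(k2) == 1L)
  if (rmax <= 0) stop("`rmax` must be positive", call. = FALSE)
  if (p_prime < 0) stop("`p_prime` must be non-negative", call. = FALSE)
  if (k2 <= 0) stop("`k2` must be positive", call. = FALSE)
  structure(list(rmax = rmax, p_prime = p_prime, k2 = k2),
            class = "nr_params")
}

#' Parameters of the generalized Holling disk equation
#'
#' \eqn{I(P) = a P^\theta / (1 + a h P^\theta)}. `a` is the space clearance
#' rate (volume searched per predator per day; the initial slope when
#' θ = 1), `h` the handling time (days per prey item, so
#' \eqn{I_{max} = 1/h}), and `theta` the Hill exponent: θ = 1 gives the
#' type II hyperbola, θ > 1 sigmoidal type III curves (θ = 2 being the
#' classical type III), and h = 0 with θ = 1 the linear type I regime.
#'
#' @param a Space clearance rate (> 0). Units are mL^θ predator⁻¹ d⁻¹.
#' @param h Handling time in days per prey (>= 0; 0 means type I, unbounded
#'   ingestion).
#' @param theta Hill exponent (>= 1).
#' @return An object of class `fr_params` with derived `imax` (`Inf` when
#'   `h = 0`) and half-saturation `k = (1/(a h))^{1/\theta}`.
#' @examples
#' fr_params(a = 0.01, h = 0.001)            # type II
#' fr_params(a = 8.3e-11, h = 1/667, theta = 3) # strongly sigmoidal type III
#' @export
fr_params <- function(a, h, theta = 1) {
  stopifnot(length(a) == 1L, length(h) == 1L, length(theta) == 1L)
  if (a <= 0) stop("`a` must be positive", call. = FALSE)
  if (h < 0) stop("`h` must be non-negative", call. = FALSE)
  if (theta < 1) stop("`theta` must be >= 1", call. = FALSE)
  structure(list(
    a = a, h = h, theta = theta,
    imax = if (h > 0) 1 / h else Inf,
    k = if (h > 0) (1 / (a * h))^(1 / theta) else NA_real_
  ), class = "fr_params")
}

#' Predict consumer growth rate from the threshold numerical response
#'
#' Evaluates \eqn{r = r_{max}(P - P')/(k_2 + (P - P'))}. Below the threshold
#' the same expression is returned (negative growth), which is the model's
#' own continuation; it diverges where the denominator crosses zero, which is
#' rejected.
#'
#' @param p Prey density (>= 0). Vectorised.
#' @param params An [nr_params()] object.
#' @return Growth rate, d⁻¹.
#' @examples
#' pars <- nr_params(0.4, 1000, 5000)
#' nr_predict(1000, pars) # 0 at the threshold
#' nr_predict(6000, pars) # 0.2
#' @export
nr_predict <- function(p, params) {
  stopifnot(inherits(params, "nr_params"))
  if (any(p < 0)) stop("`p` must be non-negative", call. = FALSE)
  denom <- params$k2 + (p - params$p_prime)
  if (any(denom <= 0)) {
    stop("singular model: k2 + (P - P') must stay positive over the data",
         call. = FALSE)
  }
  params$rmax * (p - params$p_prime) / denom
}

#' Predict ingestion rate from the generalized disk equation
#'
#' @param p Prey density (>= 0). Vectorised.
#' @param params An [fr_params()] object.
#' @return Ingestion rate, prey predator⁻¹ d⁻¹.
#' @examples
#' fr_predict(1000, fr_params(0.004, 0, 1))       # type I: a * P = 4
#' fr_predict(1000, fr_params(0.01, 0.001, 1))    # 9.90
#' @export
fr_predict <- function(p, params) {
  stopifnot(inherits(params, "fr_params"))
  if (any(p < 0)) stop("`p` must be non-negative", call. = FALSE)
  pp <- p^params$theta
  params$a * pp / (1 + params$a * params$h * pp)
}

#' Michaelis–Menten form of the type II functional response
#'
#' \eqn{I = I_{max} P / (k + P)}, algebraically identical to the θ = 1 disk
#' equation with \eqn{I_{max} = 1/h} and \eqn{k = 1/(a h)} (multiply
#' numerator and denominator of the disk form by \eqn{1/(ah)}).
#'
#' @param p Prey density (>= 0). Vectorised.
#' @param imax Maximum ingestion rate (> 0).
#' @param k Half-saturation prey density (> 0).
#' @return Ingestion rate, prey predator⁻¹ d⁻¹.
#' @examples
#' fr_predict_mm(20000, imax = 667, k = 20000) # imax / 2 at P = k
#' @export
fr_predict_mm <- function(p, imax, k) {
  if (imax <= 0) stop("`imax` must be positive", call. = FALSE)
  if (k <= 0) stop("`k` must be positive", call. = FALSE)
  if (any(p < 0)) stop("`p` must be non-negative", call. = FALSE)
  imax * p / (k + p)
}

#' Clearance-rate curve of a functional response
#'
#' \eqn{C(P) = I(P)/P = a P^{\theta-1} / (1 + a h P^\theta)}. The shape of
#' this curve is the classical FR-type diagnostic: for θ = 1 it declines
#' monotonically from its maximum `a` at P → 0; for θ > 1 it rises to an
#' interior maximum (at the inflection point of the sigmoid ingestion curve)
#' and then declines.
#'
#' @param p Prey density (> 0). Vectorised.
#' @param params An [fr_params()] object.
#' @return Clearance rate, mL predator⁻¹ d⁻¹.
#' @export
clearance_curve <- function(p, params) {
  stopifnot(inherits(params, "fr_params"))
  if (any(p <= 0)) stop("`p` must be positive", call. = FALSE)
  fr_predict(p, params) / p
}

#' Maximum ingestion rate from handling time
#'
#' \eqn{I_{max} = 1/h}. Two fits sharing the same handling time necessarily
#' share the same maximum ingestion rate, whatever their other parameters.
#'
#' @param h Handling time, days per prey; must be positive — `h = 0` is the
#'   type I regime where ingestion is unbounded.
#' @return Maximum ingestion rate, prey predator⁻¹ d⁻¹.
#' @examples
#' imax_from_handling(0.0015) # ~667
#' @export
imax_from_handling <- function(h) {
  if (any(h == 0)) {
    stop("h = 0 is the type I regime: maximum ingestion is unbounded",
         call. = FALSE)
  }
  if (any(h < 0)) stop("`h` must be non-negative", call. = FALSE)
  1 / h
}

# Canonical model-identifier strings used in all fit reports.
# "FR2" = disk with theta = 1; "FR3" = theta = 2; "FR3-theta=x" = fixed
# theta x; "FR-free-theta" = theta estimated; "FRmm" = Michaelis-Menten
# parameterization; "NR" = threshold numerical response.
fr_model_id <- function(theta) {
  if (identical(theta, "free")) return("FR-free-theta")
  stopifnot(is.numeric(theta), length(theta) == 1L)
  if (theta == 1) "FR2"
  else if (theta == 2) "FR3"
  else sprintf("FR3-theta=%g", theta)
}
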