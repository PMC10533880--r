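#' Parameters of the tumor-diameter survival curve
#'
#' The relationship between tumor diameter at diagnosis (TD, in mm) and
#' 15-year tumor-related survival is described by a three-parameter Gompertz
#' curve,
#' \deqn{S_{15}(TD) = 100 - a \exp\{-b \exp(-c \cdot TD)\}}
#' with survival in percent. The default coefficients were fitted to
#' cancer-registry survival observed in 5-mm tumor-diameter increments:
#' `amplitude` (a) is the maximal survival deficit in percent, `shape` (b)
#' is unitless, and `decay` (c) is per mm.
#'
#' @param amplitude Maximal long-run survival deficit, percent. Must be in
#'   (0, 100].
#' @param shape Unitless Gompertz shape parameter, strictly positive.
#' @param decay Exponential decay rate per mm of tumor diameter, strictly
#'   positive.
#' @return An object of class `gompertz_params`.
#' @examples
#' p <- gompertz_params()
#' fifteen_year_survival(16, p) # 86.0
#' @export
gompertz_params <- function(amplitude = 58.4, shape = 4.46, decay = 0.071) {
  if (!is.numeric(amplitude) || length(amplitude) != 1L || !is.finite(amplitude) ||
      amplitude <= 0 || amplitude > 100) {
    stop("`amplitude` must be a single number in (0, 100]", call. = FALSE)
  }
  if (!is.numeric(shape) || length(shape) != 1L || !is.finite(shape) || shape <= 0) {
    stop("`shape` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(decay) || length(decay) != 1L || !is.finite(decay) || decay <= 0) {
    stop("`decay` must be a single positive number", call. = FALSE)
  }
  structure(list(amplitude = amplitude, shape = shape, decay = decay),
            class = "gompertz_params")
}

#' 15-year tumor-related survival for a given tumor diameter
#'
#' Evaluates the Gompertz tumor-diameter survival curve. Survival is strictly
#' decreasing in diameter and bounded below by `100 - amplitude` percent
#' (the asymptote for arbitrarily large tumors).
#'
#' @param td Tumor diameter at diagnosis in mm; non-negative, vectorized.
#' @param params A [gompertz_params()] object.
#' @return 15-year tumor-related survival in percent, same length as `td`.
#' @export
fifteen_year_survival <- function(td, params = gompertz_params()) {
  stopifnot(inherits(params, "gompertz_params"))
  if (!is.numeric(td) || any(!is.finite(td))) {
    stop("`td` must be finite numeric", call. = FALSE)
  }
  if (any(td < 0)) {
    stop("`td` must be non-negative (tumor diameter in mm)", call. = FALSE)
  }
  100 - params$amplitude * exp(-params$shape * exp(-params$decay * td))
}

#' Tumor diameter implied by a 15-year survival level
#'
#' Closed-form inverse of [fifteen_year_survival()]. Only survival levels
#' attainable for a non-negative diameter are accepted, i.e. values in
#' `(100 - amplitude, fifteen_year_survival(0)]`.
#'
#' @param s15 15-year tumor-related survival in percent.
#' @param params A [gompertz_params()] object.
#' @return Tumor diameter in mm.
#' @examples
#' td_for_survival(76) # 22.7
#' @export
td_for_survival <- function(s15, params = gompertz_params()) {
  stopifnot(inherits(params, "gompertz_params"))
  if (!is.numeric(s15) || any(!is.finite(s15))) {
    stop("`s15` must be finite numeric", call. = FALSE)
  }
  lo <- 100 - params$amplitude
  hi <- fifteen_year_survival(0, params)
  if (any(s15 <= lo) || any(s15 > hi)) {
    stop(sprintf(
      "`s15` must lie in (%.6g, %.6g] percent to correspond to a tumor diameter >= 0",
      lo, hi), call. = FALSE)
  }
  # s = 100 - a*exp(-b*exp(-c*td))  =>  td = -log(-log((100 - s)/a)/b)/c
  -log(-log((100 - s15) / params$amplitude) / params$shape) / params$decay
}

#' Tumor size-class mixture of screen-detected breast cancer
#'
#' Size distribution of invasive breast cancers detected within an organized
#' screening program, as three diameter classes with representative mean
#' diameters. Shares are renormalized to sum to one before use, so mixtures
#' reported to limited precision (e.g. 33.8/46.0/18.7 percent, summing to
#' 98.5) are handled consistently.
#'
#' @param shares Positive class shares (fractions or percentages; only the
#'   relative sizes matter).
#' @param mean_td Mean tumor diameter per class, mm.
#' @param labels Class labels.
#' @return An object of class `size_class_mix`.
#' @export
size_class_mix <- function(shares = c(0.338, 0.460, 0.187),
                           mean_td = c(7, 15, 28),
                           labels = c("<=10 mm", ">10-20 mm", ">20 mm")) {
  if (length(shares) != length(mean_td) || length(shares) != length(labels)) {
    stop("`shares`, `mean_td` and `labels` must have equal length", call. = FALSE)
  }
  if (!is.numeric(shares) || any(!is.finite(shares)) || any(shares < 0)) {
    stop("`shares` must be finite and non-negative", call. = FALSE)
  }
  if (sum(shares) <= 0) {
    stop("at least one class share must be positive", call. = FALSE)
  }
  if (!is.numeric(mean_td) || any(!is.finite(mean_td)) || any(mean_td <= 0)) {
    stop("`mean_td` must be positive diameters in mm", call. = FALSE)
  }
  structure(list(labels = labels, shares = shares, mean_td = mean_td),
            class = "size_class_mix")
}

#' Weighted mean tumor diameter of a size-class mixture
#'
#' @param mix A [size_class_mix()] object.
#' @return Weighted mean diameter in mm, with shares renormalized to sum to 1.
#' @examples
#' weighted_mean_td(size_class_mix()) # 14.7 mm
#' @export
weighted_mean_td <- function(mix = size_class_mix()) {
  stopifnot(inherits(mix, "size_class_mix"))
  sum(mix$shares / sum(mix$shares) * mix$mean_td)
}
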