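#' GM-content estimate with provenance
#'
#' Lightweight container for a whole-field %GM estimate, recording the
#' method used (`single_ring`, `two_part` or `standard_grid`) and the inputs
#' it was computed from, so that downstream reports can show how a number
#' was obtained.
#'
#' @param value estimate in percent (>= 0).
#' @param method character method tag.
#' @param inputs named list echoing the inputs used.
#' @return object of class `gm_estimate`.
#' @export
gm_estimate <- function(value, method, inputs = list()) {
  stopifnot(is.numeric(value), length(value) == 1, value >= 0)
  structure(list(value = value, method = method, inputs = inputs),
            class = "gm_estimate")
}

#' @export
print.gm_estimate <- function(x, ...) {
  cat(sprintf("<gm_estimate> %%GM = %.4g (method: %s)\n", x$value, x$method))
  invisible(x)
}

#' @export
as.double.gm_estimate <- function(x, ...) x$value

#' Whole-field %GM from a single pooled ring sample
#'
#' Estimates the overall GM content of a field from one measured quantity:
#' the mean cross-pollination `K_d` along the contour at sampling depth `d`
#' (typically the pooled 8-sample mean at d = 3 m).  The field is mapped to
#' its equivalent square `a = 4 I`, the flow model is calibrated so its
#' depth-`d` contour mean equals `K_d`, and the model's whole-field mean is
#' returned.  Any sampling depth with `d <= 2 I` is supported (surveys at
#' d = 6 or 8 m use the same formula with their own depth).
#'
#' This estimator only sees pollen that entered through the border: GM
#' present for internal reasons (seed admixture, volunteers) raises `K_d` by
#' a constant and is *halved* on extrapolation to the field mean.  Use
#' [estimate_two_part()] with a centre sample when internal origin cannot be
#' excluded.
#'
#' @param K_d measured contour mean in percent (>= 0).
#' @param d sampling depth in metres (default 3).
#' @param I Self-Protection Index of the field in metres.
#' @return a [gm_estimate()] with method `"single_ring"`.
#' @examples
#' estimate_single_ring(K_d = 0.3, d = 3, I = 30)$value   # 0.15
#' @export
estimate_single_ring <- function(K_d, d = 3, I) {
  if (!is.finite(I) || I <= 0) stop("I must be > 0")
  if (!is.finite(d) || d < 0) stop("d must be >= 0")
  if (d > 2 * I) stop("sampling depth d exceeds half the equivalent square side (d > 2I)")
  if (!is.finite(K_d) || K_d < 0) stop("K_d must be >= 0")
  m <- calibrate_flow_model(equivalent_square_side(I), d, K_d)
  gm_estimate(field_mean(m), "single_ring", list(K_d = K_d, d = d, I = I))
}

#' Predicted cross-pollination at the field centre
#'
#' Evaluates the calibrated flow model at the centre of the equivalent
#' square (`d = a/2`), where the density is `4K/(2I + 1)`.  Comparing this
#' prediction with a measured centre sample `K_c` reveals GM of internal
#' origin: external pollen flow alone cannot raise the centre much above
#' the prediction.
#'
#' @inheritParams estimate_single_ring
#' @return predicted centre cross-pollination in percent.
#' @examples
#' predict_center(K_d = 0.3, d = 3, I = 30)   # 0.06
#' @export
predict_center <- function(K_d, d = 3, I) {
  if (!is.finite(I) || I <= 0) stop("I must be > 0")
  if (!is.finite(d) || d < 0 || d > 2 * I) stop("sampling depth d outside [0, 2I]")
  if (!is.finite(K_d) || K_d < 0) stop("K_d must be >= 0")
  m <- calibrate_flow_model(equivalent_square_side(I), d, K_d)
  m$K * 4 / (2 * I + 1)
}

#' Two-part %GM estimate from a ring sample and a centre sample
#'
#' Splits the field into the 10 m peripheral ring and the central portion
#' (see [ring_partition()]) and estimates the overall %GM as the
#' area-weighted average
#' \deqn{%GM = (K_3 A_R + K_c A_C) / A_T,}
#' using the measured 3 m contour mean `K_3` for the ring (the model shows
#' the mean at depth 3 m closely matches the 0--10 m ring mean) and the
#' measured centre sample `K_c` for the central portion.  Because `K_c` is
#' measured, not extrapolated, this estimator picks up GM of internal origin
#' (seed admixture, volunteers) at full weight.
#'
#' For very large fields (I > 67 m) the centre sample overstates the central
#' portion slightly (about `0.0002 * I` percent); a warning reports the
#' size of the effect but no correction is applied, since cross-pollination
#' in the centre of such fields is in practice negligible.
#'
#' @param K_3 measured ring contour mean in percent (>= 0).
#' @param K_c measured centre value in percent (>= 0).
#' @param geom a [field_geometry()].
#' @param ring_w ring width in metres (default 10).
#' @param mode partition mode passed to [ring_partition()].
#' @return a [gm_estimate()] with method `"two_part"`.
#' @examples
#' g <- field_geometry(15000, 500)
#' estimate_two_part(1.30, 1.06, g)$value   # 1.13
#' @export
estimate_two_part <- function(K_3, K_c, geom, ring_w = 10,
                              mode = c("auto", "approx", "exact")) {
  stopifnot(inherits(geom, "field_geometry"))
  if (!is.finite(K_3) || K_3 < 0) stop("K_3 must be >= 0")
  if (!is.finite(K_c) || K_c < 0) stop("K_c must be >= 0")
  rp <- ring_partition(geom, ring_w, match.arg(mode))
  I <- self_protection_index(geom)
  if (I > 67) {
    warning(sprintf(
      "central portion of large fields (I = %.3g m > 67 m) tends to be overestimated by about %.3g%%",
      I, 2e-4 * I))
  }
  value <- (K_3 * rp$ring_area_m2 + K_c * rp$central_area_m2) / geom$area_m2
  gm_estimate(value, "two_part",
              list(K_3 = K_3, K_c = K_c, ring = rp, I = I,
                   area_m2 = geom$area_m2, perimeter_m = geom$perimeter_m))
}

#' GM contribution of internal origin
#'
#' The single-ring estimate reflects only pollen flow from outside; the
#' two-part estimate also includes GM produced inside the field (seed
#' admixture, volunteer plants), because it uses the measured centre value.
#' Their difference therefore estimates the internal contribution to the
#' overall %GM.  The difference is floored at 0 (a negative value has no
#' physical meaning and arises only from measurement noise or field-shape
#' deviations from the model).
#'
#' @inheritParams estimate_two_part
#' @param d depth of the ring measurement in metres (default 3).
#' @return internal %GM contribution in percent (>= 0).
#' @examples
#' g <- field_geometry(15000, 500)
#' internal_contribution(1.30, 1.06, g)   # about 0.48
#' @export
internal_contribution <- function(K_3, K_c, geom, d = 3, ring_w = 10) {
  stopifnot(inherits(geom, "field_geometry"))
  I <- self_protection_index(geom)
  two <- estimate_two_part(K_3, K_c, geom, ring_w)$value
  one <- estimate_single_ring(K_3, d, I)$value
  max(0, two - one)
}

#' Sample size needed to quantify a GM proportion
#'
#' Binomial sample size for estimating a kernel-level GM proportion `p_gm`
#' (percent) with half-width `E` (percent points) at the confidence implied
#' by the `z` statistic: `kernels = z^2 p (100 - p) / E^2`, converted to
#' cobs with `kernels_per_cob` kernels each.  With the defaults
#' (0.9% at z = 1.95, E = 0.1, 189 kernels per cob) about 180 cobs are
#' required, which motivates pooled 20-cob samples in the simplified survey
#' (8 x 20 = 160 cobs in the mixed periphery sample).
#'
#' @param p_gm GM proportion to quantify, percent in (0, 100).
#' @param z standard-normal quantile (default 1.95, ~95% confidence).
#' @param E confidence half-width in percent points (default 0.1).
#' @param kernels_per_cob kernels per cob (default 189).
#' @return list with `kernels` (rounded up) and `cobs` (rounded up).
#' @examples
#' sample_size(0.9)   # about 33,915 kernels, 180 cobs
#' @export
sample_size <- function(p_gm, z = 1.95, E = 0.1, kernels_per_cob = 189) {
  if (!is.finite(p_gm) || p_gm <= 0 || p_gm >= 100) stop("p_gm must be in (0, 100) percent")
  if (z <= 0 || E <= 0 || kernels_per_cob <= 0) stop("z, E and kernels_per_cob must be > 0")
  kernels <- z^2 * p_gm * (100 - p_gm) / E^2
  list(kernels = ceiling(kernels), cobs = ceiling(kernels / kernels_per_cob))
}
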