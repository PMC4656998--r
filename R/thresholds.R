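#' Maximum possible %GM of a field given its Self-Protection Index
#'
#' Under the worst realistic border pressure -- a field completely
#' surrounded by flowering-synchronised GM donors, for which the maximum
#' border mean is `K0_max` (10.625% for MON810, half of the 21.3%
#' cross-fertilization measured at d = 0 because the event is homozygous) --
#' the whole-field %GM of a field with index I is obtained by calibrating
#' the flow model at the border (d = 0) and taking its field mean.  This is
#' an upper bound for any real donor configuration.
#'
#' @param I Self-Protection Index in metres (> 0, vectorised).
#' @param K0_max maximum border mean in percent (default 10.625).
#' @return maximum %GM in percent.
#' @examples
#' max_gm(62.2)   # about 0.9
#' @export
max_gm <- function(I, K0_max = 10.625) {
  if (any(!is.finite(I) | I <= 0)) stop("I must be > 0")
  if (!is.finite(K0_max) || K0_max < 0) stop("K0_max must be >= 0")
  vapply(I, function(ii) {
    a <- equivalent_square_side(ii)
    field_mean(calibrate_flow_model(a, 0, K0_max))
  }, numeric(1))
}

#' Critical Self-Protection Index for a labeling threshold
#'
#' Solves `max_gm(I, K0_max) = gm_threshold` for I.  Fields with a larger
#' index can never exceed the threshold through cross-pollination alone
#' (internal origin excluded), whatever their neighbourhood, so no
#' coexistence measure is needed for them.  With the defaults
#' (K0_max = 10.625%, threshold 0.9%) the critical index is 62.2 m,
#' roughly a 6.25 ha square field.  `max_gm` is strictly decreasing in I,
#' so the root is unique; it is found by bracketed root solving on
#' [1e-3, 1e4] m.
#'
#' @param K0_max maximum border mean in percent (default 10.625).
#' @param gm_threshold labeling threshold in percent (default 0.9,
#'   the EU value); must be below `K0_max`.
#' @return critical index I in metres.
#' @examples
#' round(protective_index(), 1)   # 62.2
#' @export
protective_index <- function(K0_max = 10.625, gm_threshold = 0.9) {
  if (!is.finite(gm_threshold) || gm_threshold <= 0) stop("gm_threshold must be > 0")
  if (gm_threshold >= K0_max) {
    stop("no root: gm_threshold must be below K0_max (max_gm tends to K0_max as I -> 0)")
  }
  stats::uniroot(function(I) max_gm(I, K0_max) - gm_threshold,
                 interval = c(1e-3, 1e4), tol = 1e-6)$root
}

#' Mean %GM of the interior after stripping a peripheral ring
#'
#' Maize harvesting usually starts with the field periphery.  If the yield
#' of a `strip_w`-wide border ring is collected and commercialised
#' separately (labelled as GM), the remaining interior has mean GM content
#' `region_mean(strip_w, a/2)` of the flow model calibrated from an
#' observed border mean `K_0` or a contour mean `K_d` at depth `d`.
#'
#' @param I Self-Protection Index in metres, or a [field_geometry()].
#' @param strip_w width of the stripped ring in metres (0 < strip_w < 2I).
#' @param K_0 observed border mean in percent (d = 0 calibration), or
#' @param K_d,d observed contour mean and its depth (exactly one of `K_0`
#'   and `K_d` must be given).
#' @return interior mean %GM in percent.
#' @examples
#' interior_after_strip(43, 3, K_0 = 10.625)   # about 0.9
#' @export
interior_after_strip <- function(I, strip_w = 3, K_0 = NULL, K_d = NULL, d = NULL) {
  if (inherits(I, "field_geometry")) I <- self_protection_index(I)
  if (!is.finite(I) || I <= 0) stop("I must be > 0")
  a <- equivalent_square_side(I)
  if (!is.finite(strip_w) || strip_w <= 0 || strip_w >= a / 2) {
    stop("strip too wide: need 0 < strip_w < a/2 = 2I")
  }
  if (is.null(K_0) == is.null(K_d)) stop("give exactly one of K_0 or (K_d, d)")
  m <- if (!is.null(K_0)) {
    calibrate_flow_model(a, 0, K_0)
  } else {
    if (is.null(d)) stop("d is required with K_d")
    calibrate_flow_model(a, d, K_d)
  }
  region_mean(m, strip_w, a / 2)
}

#' Periphery-stripping heuristic rule
#'
#' Quick screen for whether a field will fall below the 0.9% threshold
#' after separate commercialisation of a 3 m peripheral ring: the rule
#' fires when `I > 43` or `K_3 < (1 + I)/22`.  This is a published
#' heuristic; the exact model counterpart is [interior_after_strip()], and
#' the `K_3` clause is stricter (more conservative) than the exact bound.
#' The return value carries attribute `rule = "heuristic"` to flag this.
#'
#' @param I Self-Protection Index in metres (> 0).
#' @param K_3 measured 3 m contour mean in percent (> 0... >= 0 accepted).
#' @return `TRUE` if the interior is predicted below 0.9% after stripping.
#' @examples
#' strip_rule(50, 5)    # TRUE (I clause)
#' strip_rule(20, 0.5)  # TRUE (K_3 clause)
#' @export
strip_rule <- function(I, K_3) {
  if (!is.finite(I) || I <= 0) stop("I must be > 0")
  if (!is.finite(K_3) || K_3 < 0) stop("K_3 must be >= 0")
  structure(I > 43 || K_3 < (1 + I) / 22, rule = "heuristic")
}
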