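#' Decision-support report for a surveyed field
#'
#' Runs the recommended decision flow on the measurements of a simplified
#' survey: estimate the overall %GM from the pooled periphery analysis
#' (single-ring estimator); when the centre analysis is available, also
#' compute the two-part estimate and let it govern the decision (it is the
#' one that detects GM of internal origin, which the single-ring estimator
#' halves); compare the governing estimate with the labeling threshold; and,
#' when possible, attribute the content to external pollen flow versus
#' internal origin.  Every rule fired is appended to a human-readable audit
#' trail.
#'
#' @param geom a [field_geometry()].
#' @param k3 pooled periphery contour mean in percent (required).
#' @param d sampling depth of the periphery samples in metres (default 3).
#' @param k_c centre analysis in percent, or `NULL` if not taken.
#' @param threshold labeling threshold in percent (default 0.9, EU).
#' @param ring_w ring width for the two-part estimator (default 10).
#' @return object of class `decision_report`: list with `estimates`
#'   (named list of [gm_estimate()]), `governing`, `threshold_pct`,
#'   `label_required`, `internal_pct` (`NA` without a centre sample),
#'   `internal_suspected`, `audit` (character vector).
#' @examples
#' g <- field_geometry(15000, 500)
#' decide(g, k3 = 1.30, k_c = 1.06)
#' @export
decide <- function(geom, k3, d = 3, k_c = NULL, threshold = 0.9, ring_w = 10) {
  stopifnot(inherits(geom, "field_geometry"))
  if (is.null(k3) || !is.finite(k3)) stop("incomplete data: the pooled periphery value k3 is required")
  I <- self_protection_index(geom)
  audit <- sprintf("I = A/p = %.6g/%.6g = %.4g m (equivalent square side %.4g m)",
                   geom$area_m2, geom$perimeter_m, I, 4 * I)
  single <- estimate_single_ring(k3, d, I)
  audit <- c(audit, sprintf(
    "single-ring estimate from pooled K_%g = %.4g%%: %%GM = %.4g%%",
    d, k3, single$value))
  estimates <- list(single_ring = single)
  internal <- NA_real_
  internal_suspected <- FALSE
  if (!is.null(k_c)) {
    two <- estimate_two_part(k3, k_c, geom, ring_w)
    estimates$two_part <- two
    audit <- c(audit, sprintf(
      "two-part estimate from K_%g = %.4g%% and K_c = %.4g%%: %%GM = %.4g%% (governs: it reflects internal origin)",
      d, k3, k_c, two$value))
    att <- attribute_origin(k3, k_c, geom, d = d, ring_w = ring_w)
    internal <- att$internal_pct
    internal_suspected <- att$internal_suspected
    audit <- c(audit, sprintf(
      "internal-origin contribution %.4g%%%s", internal,
      if (internal_suspected) " -- internal origin suspected" else ""))
    governing <- "two_part"
  } else {
    audit <- c(audit,
               "no centre analysis: single-ring governs (internal origin cannot be assessed)")
    governing <- "single_ring"
  }
  gv <- estimates[[governing]]$value
  label_required <- gv >= threshold
  audit <- c(audit, sprintf("governing %%GM = %.4g%% %s threshold %.4g%% -> %s",
                            gv, if (label_required) ">=" else "<", threshold,
                            if (label_required) "GM labeling required"
                            else "no GM labeling required"))
  structure(list(estimates = estimates, governing = governing,
                 threshold_pct = threshold, label_required = label_required,
                 internal_pct = internal,
                 internal_suspected = internal_suspected, audit = audit),
            class = "decision_report")
}

#' @export
print.decision_report <- function(x, ...) {
  cat("<decision_report>\n")
  for (line in x$audit) cat(" -", line, "\n")
  invisible(x)
}

#' Identify the donor direction from individual periphery analyses
#'
#' Samples taken close to a GM donor field show clearly higher values than
#' the rest of the periphery.  This flags the periphery sectors whose value
#' exceeds both an absolute floor (the detection limit) and `alpha` times
#' the median of the 8 values, and ranks them.  The alpha-times-median rule
#' is a pragmatic screen -- published workflows identify the direction by
#' inspection -- so both knobs are explicit arguments.
#'
#' @param values the 8 individual periphery %GM analyses, in perimeter
#'   order.
#' @param alpha multiple of the median above which a sector is flagged
#'   (default 2).
#' @param lod absolute floor in percent (default 0.01).
#' @param sides optional side labels (e.g. from [measure_simplified()]).
#' @return data frame ranked by decreasing value: `sector`, `side`,
#'   `value_pct`, `flagged`.
#' @examples
#' identify_donor_sides(c(2.1, 1.8, 0.1, 0.1, 0.05, 0.1, 0.1, 0.2))
#' @export
identify_donor_sides <- function(values, alpha = 2, lod = 0.01, sides = NULL) {
  if (length(values) != 8) stop("8 periphery values are required")
  if (anyNA(values)) stop("missing periphery values")
  cutoff <- max(lod, alpha * stats::median(values))
  out <- data.frame(sector = seq_len(8),
                    side = if (is.null(sides)) NA_integer_ else sides,
                    value_pct = values,
                    flagged = values > cutoff)
  out[order(-out$value_pct), ]
}

#' Attribute adventitious GM to internal versus external origin
#'
#' Computes the internal-origin contribution ([internal_contribution()],
#' the excess of the two-part estimate over the purely flow-based
#' single-ring estimate) and classifies the field as "internal origin
#' suspected" when that contribution exceeds a configurable fraction of
#' the total estimate.
#'
#' @inheritParams internal_contribution
#' @param frac fraction of the two-part estimate above which internal
#'   origin is flagged (default 0.25).
#' @return list with `internal_pct`, `total_pct` (two-part estimate),
#'   `internal_suspected`.
#' @export
attribute_origin <- function(K_3, K_c, geom, d = 3, ring_w = 10, frac = 0.25) {
  if (is.null(K_c)) stop("attribution unavailable: a centre analysis is required")
  total <- estimate_two_part(K_3, K_c, geom, ring_w)$value
  internal <- internal_contribution(K_3, K_c, geom, d, ring_w)
  list(internal_pct = internal, total_pct = total,
       internal_suspected = total > 0 && internal > frac * total)
}
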