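#' Survey sample sets
#'
#' A sample set is a data frame of sample points (one row each) with the
#' layout metadata needed to aggregate measurements: `id`, `role`
#' (`"perimeter"`, `"transect"` or `"center"`), `arm` (position of the
#' transect arm around the perimeter, 1-8, `NA` for centre points),
#' `transect` (1-4), `side` (edge of the layout rectangle the point belongs
#' to, 1 = south, 2 = east, 3 = north, 4 = west), planar coordinates `x`,
#' `y` in metres, sampling depth `depth_d`, `n_cobs`, and the measured
#' `value_pct` (`NA` until measured).  The design name and the field
#' geometry travel as attributes `design` and `geom`.
#'
#' Layout coordinates use the field's boundary polygon when it is a
#' rectangle, and otherwise the equivalent rectangle with the same area and
#' perimeter (falling back to the equal-area square when no rectangle has
#' both).
#'
#' @name sample_set
NULL

new_sample_set <- function(df, design, geom) {
  df$id <- seq_len(nrow(df))
  df <- df[, c("id", "role", "arm", "transect", "side", "x", "y",
               "depth_d", "n_cobs", "value_pct")]
  structure(df, design = design, geom = geom,
            class = c("sample_set", "data.frame"))
}

layout_rectangle <- function(geom) {
  if (!is.null(geom$polygon) && nrow(geom$polygon) == 4) {
    xr <- range(geom$polygon[, 1]); yr <- range(geom$polygon[, 2])
    L <- diff(xr); W <- diff(yr)
    # only trust an axis-aligned rectangle; otherwise use the equivalent one
    if (abs(2 * (L + W) - geom$perimeter_m) < 1e-6 * geom$perimeter_m &&
        abs(L * W - geom$area_m2) < 1e-6 * geom$area_m2) {
      return(c(L = max(L, W), W = min(L, W)))
    }
  }
  equivalent_rectangle(geom)
}

# map arc length s (from (0,0), counter-clockwise) on the L x W rectangle
# boundary to the boundary point, the side index and the inward unit normal
rect_boundary_point <- function(s, L, W) {
  p <- 2 * (L + W)
  s <- s %% p
  if (s < L)             list(pt = c(s, 0),              side = 1L, nrm = c(0, 1))
  else if (s < L + W)    list(pt = c(L, s - L),          side = 2L, nrm = c(-1, 0))
  else if (s < 2 * L + W) list(pt = c(L - (s - L - W), W), side = 3L, nrm = c(0, -1))
  else                   list(pt = c(0, W - (s - 2 * L - W)), side = 4L, nrm = c(1, 0))
}

#' Standard 28-sample survey design
#'
#' The standard survey crosses the field with 4 transects.  Their 8
#' intersections with the boundary (the transect arms) are equidistant
#' along the perimeter (arc gaps p/8, offset p/16 from the first corner,
#' about 50-60 m apart in typical fields); arms at antipodal arc positions
#' are joined, so every transect passes through the field centre and at
#' least two pairs run in perpendicular directions.  Each arm carries a
#' 3-cob sample at depths 0, 3 and 10 m inside the border (24 depth
#' samples, 8 per depth), and each transect carries one crossing sample
#' where the transects meet -- the field centre, at depth equal to half
#' the narrow side: 28 points in total.
#'
#' @param geom a [field_geometry()].
#' @return a [sample_set] of 28 rows with `design = "standard"`.
#' @examples
#' ss <- design_standard(field_geometry(15000, 500))
#' table(ss$depth_d)
#' @export
design_standard <- function(geom) {
  stopifnot(inherits(geom, "field_geometry"))
  dims <- layout_rectangle(geom)
  L <- dims[["L"]]; W <- dims[["W"]]
  if (W / 2 < 10) {
    warning("degenerate design: field narrower than 20 m, the 10 m depth reaches past the centre line")
  }
  p <- 2 * (L + W)
  depths <- c(0, 3, 10)
  rows <- list()
  for (k in 1:8) {
    b <- rect_boundary_point(p / 16 + (k - 1) * p / 8, L, W)
    for (d in depths) {
      pt <- b$pt + min(d, W / 2) * b$nrm
      rows[[length(rows) + 1]] <- data.frame(
        role = if (d == 0) "perimeter" else "transect",
        arm = k, transect = (k - 1L) %% 4L + 1L, side = b$side,
        x = pt[1], y = pt[2], depth_d = d, n_cobs = 3L, value_pct = NA_real_)
    }
  }
  for (tr in 1:4) {
    rows[[length(rows) + 1]] <- data.frame(
      role = "center", arm = NA_integer_, transect = tr, side = NA_integer_,
      x = L / 2, y = W / 2, depth_d = W / 2, n_cobs = 3L, value_pct = NA_real_)
  }
  new_sample_set(do.call(rbind, rows), "standard", geom)
}

#' Simplified 9-sample survey design
#'
#' Eight 20-cob samples taken equidistantly around the field perimeter
#' (arc-length gaps p/8, offset by p/16 so points sit away from corners) at
#' depth `d` inside the border, plus one 20-cob sample at the field centre.
#' The 8 periphery samples are ground separately; an equal aliquot of each
#' forms a single mixed sample (160 cobs), so quantification needs only two
#' qPCR analyses (pooled periphery + centre), while the 8 individual
#' samples remain available to locate the donor direction.
#'
#' @param geom a [field_geometry()].
#' @param d sampling depth in metres (default 3; use 6 or 8 to match
#'   surveys at those depths).
#' @param n_cobs cobs per sample (default 20).
#' @return a [sample_set] of 9 rows with `design = "simplified"`.
#' @export
design_simplified <- function(geom, d = 3, n_cobs = 20L) {
  stopifnot(inherits(geom, "field_geometry"))
  dims <- layout_rectangle(geom)
  L <- dims[["L"]]; W <- dims[["W"]]
  if (!is.finite(d) || d <= 0) stop("d must be > 0")
  if (d >= W / 2) stop("sampling depth d reaches past the field centre line")
  p <- 2 * (L + W)
  rows <- list()
  for (k in 0:7) {
    b <- rect_boundary_point(p / 16 + k * p / 8, L, W)
    pt <- b$pt + d * b$nrm
    rows[[length(rows) + 1]] <- data.frame(
      role = "perimeter", arm = k + 1L, transect = NA_integer_, side = b$side,
      x = pt[1], y = pt[2], depth_d = d, n_cobs = as.integer(n_cobs),
      value_pct = NA_real_)
  }
  rows[[length(rows) + 1]] <- data.frame(
    role = "center", arm = NA_integer_, transect = NA_integer_,
    side = NA_integer_, x = L / 2, y = W / 2, depth_d = W / 2,
    n_cobs = as.integer(n_cobs), value_pct = NA_real_)
  new_sample_set(do.call(rbind, rows), "simplified", geom)
}

#' Aggregate standard-survey measurements into a whole-field estimate
#'
#' Reproduces the area-weighted grid aggregation of the standard survey:
#' the field is partitioned into sub-areas bounded by adjacent transect
#' arms (8 sectors) and adjacent depth contours (rings 0-3, 3-10 and
#' 10-centre).  Each sub-area takes the mean of the 4 samples at its
#' vertices (the two bounding arms at the two bounding depths; for the
#' innermost ring, the two arms at 10 m and the crossing samples of their
#' transects).  The field %GM is the area-weighted mean over all
#' sub-areas, with ring areas from [ring_partition()] split equally among
#' the 8 sectors.
#'
#' @param ss a measured standard [sample_set].
#' @param geom a [field_geometry()]; defaults to the geometry stored in
#'   `ss`.
#' @return a [gm_estimate()] with method `"standard_grid"`.
#' @export
aggregate_standard <- function(ss, geom = attr(ss, "geom")) {
  stopifnot(inherits(ss, "sample_set"))
  if (!identical(attr(ss, "design"), "standard")) stop("ss is not a standard design")
  if (anyNA(ss$value_pct)) stop("incomplete data: all 28 samples must be measured")
  A_T <- geom$area_m2
  a3 <- ring_partition(geom, 3, "approx")$ring_area_m2
  a10 <- ring_partition(geom, 10, "approx")$ring_area_m2
  ring_area <- c(a3, a10 - a3, A_T - a10)
  depths <- c(0, 3, 10)
  val <- function(arm, d) ss$value_pct[!is.na(ss$arm) & ss$arm == arm & ss$depth_d == d]
  arm_tr <- vapply(1:8, function(k) unique(ss$transect[!is.na(ss$arm) & ss$arm == k]), integer(1))
  cross_val <- function(tr) ss$value_pct[ss$role == "center" & ss$transect == tr]
  total <- 0
  for (sct in 1:8) {
    a1 <- sct; a2 <- sct %% 8 + 1
    for (r in 1:3) {
      v <- if (r < 3) {
        mean(c(val(a1, depths[r]), val(a1, depths[r + 1]),
               val(a2, depths[r]), val(a2, depths[r + 1])))
      } else {
        mean(c(val(a1, 10), val(a2, 10),
               cross_val(arm_tr[a1]), cross_val(arm_tr[a2])))
      }
      total <- total + v * ring_area[r] / 8
    }
  }
  gm_estimate(total / A_T, "standard_grid",
              list(ring_area_m2 = ring_area, area_m2 = A_T))
}

#' Pooled periphery mean of a simplified survey
#'
#' The physical pooling of equal aliquots of the 8 ground periphery samples
#' realises their arithmetic mean; this function computes that mean from
#' the individual values (used when the 8 samples were measured
#' individually, or to model the pooled sample).
#'
#' @param ss a simplified [sample_set] with all 8 periphery values present.
#' @return pooled contour mean `K_d` in percent.
#' @export
pool_periphery <- function(ss) {
  stopifnot(inherits(ss, "sample_set"))
  v <- ss$value_pct[ss$role == "perimeter"]
  if (length(v) != 8) stop("expected 8 periphery samples")
  if (anyNA(v)) stop("missing periphery measurements")
  mean(v)
}

#' Normalize transect profiles and compare with the model curve
#'
#' Validation helper for depth-decay data: given per-transect %GM values
#' at the design depths, transects that are zero at every depth are
#' discarded (they carry no pattern information), every value is divided by
#' its transect mean so each transect has the same weight, and per-depth
#' means and standard errors are returned.  The `profile` column rescales
#' the normalized means so the first depth equals 1, matching the
#' theoretical decay curve `perimeter_mean(d)/perimeter_mean(0)` reported
#' in the `theory` column when an index `I` is supplied.
#'
#' @param values matrix or data frame, one row per transect, one column per
#'   depth.
#' @param depths numeric vector of depths (metres), one per column.
#' @param I optional Self-Protection Index for the theoretical curve.
#' @return data frame with columns `depth_d`, `mean_norm`, `se_norm`,
#'   `profile`, `se_profile`, `n` and (if `I` given) `theory`; attribute
#'   `n_dropped` counts discarded all-zero transects.  When every transect
#'   is all-zero an empty data frame is returned with `n_dropped` set.
#' @export
normalize_transects <- function(values, depths, I = NULL) {
  m <- as.matrix(values)
  if (ncol(m) != length(depths)) stop("one depth per column is required")
  keep <- rowSums(m != 0) > 0
  n_dropped <- sum(!keep)
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0) {
    out <- data.frame(depth_d = numeric(0), mean_norm = numeric(0),
                      se_norm = numeric(0), profile = numeric(0),
                      se_profile = numeric(0), n = integer(0))
    attr(out, "n_dropped") <- n_dropped
    return(out)
  }
  norm <- m / rowMeans(m)
  mu <- colMeans(norm)
  se <- apply(norm, 2, stats::sd) / sqrt(nrow(norm))
  out <- data.frame(depth_d = depths, mean_norm = mu, se_norm = se,
                    profile = mu / mu[1], se_profile = se / mu[1],
                    n = nrow(norm), row.names = NULL)
  if (!is.null(I)) {
    a <- equivalent_square_side(I)
    out$theory <- unit_perimeter_mean(a, depths) / unit_perimeter_mean(a, 0)
  }
  attr(out, "n_dropped") <- n_dropped
  out
}
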