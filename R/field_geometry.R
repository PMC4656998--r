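#' Field geometry: area, perimeter and optional boundary polygon
#'
#' Builds the geometric description of a maize field used throughout the
#' package.  A field can be given either as summary numbers (area in m\eqn{^2}
#' and perimeter in m, the only two quantities the estimators need) or as a
#' planar boundary polygon in metre coordinates, from which area and
#' perimeter are computed by the shoelace formula and summed edge lengths.
#'
#' If both the summaries and a polygon are supplied they must agree within
#' 0.1%.  The isoperimetric inequality (area \eqn{\le p^2/(4\pi)}) is
#' enforced: no planar field can violate it, so a violation indicates a unit
#' or transcription error.
#'
#' @param area_m2 field area in square metres.
#' @param perimeter_m field perimeter in metres.
#' @param polygon optional simple closed ring: a two-column matrix (or
#'   data.frame) of x, y metre coordinates.  Orientation is irrelevant; a
#'   repeated closing vertex is accepted and dropped.
#' @return An object of class `field_geometry`: a list with elements
#'   `area_m2`, `perimeter_m` and `polygon` (a matrix or `NULL`).
#' @examples
#' field_geometry(15000, 500)                       # 100 m x 150 m rectangle
#' field_geometry(polygon = cbind(c(0, 100, 100, 0), c(0, 0, 150, 150)))
#' @export
field_geometry <- function(area_m2 = NULL, perimeter_m = NULL, polygon = NULL) {
  if (is.null(polygon) && (is.null(area_m2) || is.null(perimeter_m))) {
    stop("supply either both area_m2 and perimeter_m, or a polygon")
  }
  if (!is.null(polygon)) {
    polygon <- as_ring(polygon)
    A <- shoelace_area(polygon)
    P <- ring_length(polygon)
    if (!is.null(area_m2) && abs(A - area_m2) > 1e-3 * area_m2) {
      stop(sprintf("polygon area %.6g disagrees with stored area_m2 %.6g by more than 0.1%%",
                   A, area_m2))
    }
    if (!is.null(perimeter_m) && abs(P - perimeter_m) > 1e-3 * perimeter_m) {
      stop(sprintf("polygon perimeter %.6g disagrees with stored perimeter_m %.6g by more than 0.1%%",
                   P, perimeter_m))
    }
    area_m2 <- A
    perimeter_m <- P
  }
  if (!is.finite(area_m2) || area_m2 <= 0) stop("invalid geometry: area_m2 must be > 0")
  if (!is.finite(perimeter_m) || perimeter_m <= 0) stop("invalid geometry: perimeter_m must be > 0")
  if (area_m2 > perimeter_m^2 / (4 * pi) * (1 + 1e-9)) {
    stop("invalid geometry: area exceeds the isoperimetric bound p^2/(4*pi)")
  }
  structure(list(area_m2 = area_m2, perimeter_m = perimeter_m, polygon = polygon),
            class = "field_geometry")
}

#' @export
print.field_geometry <- function(x, ...) {
  cat(sprintf("<field_geometry> area %.6g m^2, perimeter %.6g m, I = %.4g m%s\n",
              x$area_m2, x$perimeter_m, self_protection_index(x),
              if (is.null(x$polygon)) "" else sprintf(" (%d-vertex polygon)", nrow(x$polygon))))
  invisible(x)
}

# normalise polygon input: numeric matrix, open ring (no repeated last vertex)
as_ring <- function(polygon) {
  m <- as.matrix(polygon)
  if (ncol(m) != 2 || nrow(m) < 3) stop("polygon must have >= 3 vertices with x, y columns")
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("polygon contains missing coordinates")
  n <- nrow(m)
  if (all(m[1, ] == m[n, ])) m <- m[-n, , drop = FALSE]
  if (nrow(m) < 3) stop("polygon must have >= 3 distinct vertices")
  dimnames(m) <- list(NULL, c("x", "y"))
  m
}

signed_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

shoelace_area <- function(ring) abs(signed_area(ring))

ring_length <- function(ring) {
  d <- rbind(ring[-1, , drop = FALSE], ring[1, , drop = FALSE]) - ring
  sum(sqrt(rowSums(d^2)))
}

#' Self-Protection Index of a field
#'
#' The Self-Protection Index I is the field area divided by its perimeter
#' (metres).  It expresses how much self pollen a field produces relative to
#' the border through which foreign pollen can enter: large compact fields
#' (large I) dilute external cross-pollination, narrow or small fields
#' (small I) are exposed.  For a square of side a, I = a/4.
#'
#' @param geom a [field_geometry()] object.
#' @return I in metres.
#' @examples
#' self_protection_index(field_geometry(15000, 500))   # 30
#' @export
self_protection_index <- function(geom) {
  stopifnot(inherits(geom, "field_geometry"))
  geom$area_m2 / geom$perimeter_m
}

#' Side of the equivalent square
#'
#' The model maps any field with Self-Protection Index I onto a square field
#' with the same index; since a square of side a has I = a/4, the equivalent
#' square side is a = 4I.
#'
#' @param I Self-Protection Index in metres (> 0).
#' @return side length a in metres.
#' @examples
#' equivalent_square_side(30)   # 120
#' @export
equivalent_square_side <- function(I) {
  if (any(!is.finite(I) | I <= 0)) stop("I must be a positive length in metres")
  4 * I
}

#' Partition a field into a peripheral ring and a central portion
#'
#' Splits the field area into the ring of width `w` along the boundary
#' (default 10 m, the ring used by the two-part estimator) and the remaining
#' central portion.  Two modes are available:
#'
#' * `"approx"`: the square-field formula \eqn{A_R = w p - 4 w^2}, exact for
#'   a perfect square and a good approximation for compact shapes.  The
#'   result is clamped to `[0, area]`: in small fields the formula can
#'   exceed the total area, in which case the whole field is ring
#'   (`central_area_m2 = 0`).
#' * `"exact"`: requires a polygon; the central portion is the inward offset
#'   of the boundary by `w`, computed by clipping the polygon with the
#'   inward half-plane of every edge (exact for convex fields).
#'
#' `"auto"` uses `"exact"` when a polygon is stored, `"approx"` otherwise.
#'
#' @param geom a [field_geometry()] object.
#' @param w ring width in metres (> 0, and `w <= p/4` so the approximation
#'   stays non-negative).
#' @param mode `"auto"`, `"approx"` or `"exact"`.
#' @return A list of class `ring_partition` with `ring_width_m`,
#'   `ring_area_m2`, `central_area_m2`, `mode`.
#' @examples
#' ring_partition(field_geometry(15000, 500), 10)   # A_R = 4600, A_C = 10400
#' @export
ring_partition <- function(geom, w = 10, mode = c("auto", "approx", "exact")) {
  stopifnot(inherits(geom, "field_geometry"))
  mode <- match.arg(mode)
  if (!is.finite(w) || w <= 0) stop("invalid ring width: w must be > 0")
  if (mode == "auto") mode <- if (is.null(geom$polygon)) "approx" else "exact"
  A_T <- geom$area_m2
  if (mode == "approx") {
    raw <- w * geom$perimeter_m - 4 * w^2
    if (raw < 0) {
      stop(sprintf("invalid ring width: w*p - 4*w^2 = %.4g < 0 (w exceeds p/4)", raw))
    }
    A_R <- min(max(raw, 0), A_T)
  } else {
    if (is.null(geom$polygon)) stop("exact mode requires a polygon")
    inner <- polygon_inner_offset(geom$polygon, w)
    A_inner <- if (is.null(inner) || nrow(inner) < 3) 0 else shoelace_area(inner)
    A_R <- min(max(A_T - A_inner, 0), A_T)
  }
  structure(list(ring_width_m = w, ring_area_m2 = A_R,
                 central_area_m2 = A_T - A_R, mode = mode),
            class = "ring_partition")
}

# Inward offset of a simple ring by w: clip by the inward half-plane of each
# edge (Sutherland-Hodgman).  Exact for convex rings; for non-convex rings it
# can keep slivers near reflex vertices, which is acceptable for the mildly
# irregular shapes of agricultural fields.
polygon_inner_offset <- function(ring, w) {
  orient <- sign(signed_area(ring))
  n <- nrow(ring)
  poly <- ring
  for (i in seq_len(n)) {
    p1 <- ring[i, ]
    p2 <- ring[i %% n + 1, ]
    e <- p2 - p1
    len <- sqrt(sum(e^2))
    if (len == 0) next
    nrm <- c(-e[2], e[1]) / len * orient   # inward unit normal for CCW rings
    poly <- clip_halfplane(poly, p1 + w * nrm, nrm)
    if (is.null(poly) || nrow(poly) < 3) return(NULL)
  }
  poly
}

# keep the part of poly with dot(x - p0, nrm) >= 0
clip_halfplane <- function(poly, p0, nrm) {
  n <- nrow(poly)
  s <- (poly[, 1] - p0[1]) * nrm[1] + (poly[, 2] - p0[2]) * nrm[2]
  out_x <- numeric(0); out_y <- numeric(0)
  for (i in seq_len(n)) {
    j <- i %% n + 1
    if (s[i] >= 0) {
      out_x <- c(out_x, poly[i, 1]); out_y <- c(out_y, poly[i, 2])
    }
    if ((s[i] >= 0) != (s[j] >= 0)) {
      t <- s[i] / (s[i] - s[j])
      out_x <- c(out_x, poly[i, 1] + t * (poly[j, 1] - poly[i, 1]))
      out_y <- c(out_y, poly[i, 2] + t * (poly[j, 2] - poly[i, 2]))
    }
  }
  if (length(out_x) < 3) return(NULL)
  cbind(x = out_x, y = out_y)
}

# Rectangle with the same area and perimeter when they are compatible
# (p^2/16 >= A); otherwise fall back to the square with the same area.  Used
# to lay out sampling designs when only the summaries are known.
equivalent_rectangle <- function(geom) {
  A <- geom$area_m2; p <- geom$perimeter_m
  half <- p / 2
  disc <- half^2 / 4 - A
  if (disc >= 0) {
    s1 <- half / 2 + sqrt(disc)
    s2 <- half - s1
    c(L = max(s1, s2), W = min(s1, s2))
  } else {
    s <- sqrt(A)
    c(L = s, W = s)
  }
}
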