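#' Cross-pollination flow model on the equivalent square
#'
#' The model describes adventitious cross-pollination inside a square field
#' of side `a` as the superposition of four border kernels, one per side,
#' each decaying with the distance to that side as 1/(distance + 1):
#' \deqn{\rho(x, y) = K \left[\frac{1}{x+1} + \frac{1}{y+1} +
#'   \frac{1}{a-x+1} + \frac{1}{a-y+1}\right]}
#' with `K` a proportionality constant in percent units.  `K` is *not* the
#' border mean: the mean cross-pollination along any depth contour is
#' obtained by integrating the density around the contour
#' (see [perimeter_mean()]).
#'
#' @param K proportionality constant (percent units, >= 0).
#' @param a square side in metres (> 0).
#' @return An object of class `square_flow_model`.
#' @examples
#' m <- square_flow_model(K = 0.94384, a = 120)
#' field_mean(m)
#' @export
square_flow_model <- function(K, a) {
  if (!is.finite(K) || K < 0) stop("K must be >= 0")
  if (!is.finite(a) || a <= 0) stop("a must be > 0")
  structure(list(K = K, a = a), class = "square_flow_model")
}

#' @export
print.square_flow_model <- function(x, ...) {
  cat(sprintf("<square_flow_model> K = %.6g %%, a = %.6g m (I = %.6g m), field mean %.4g %%\n",
              x$K, x$a, x$a / 4, field_mean(x)))
  invisible(x)
}

#' Cross-pollination density at a point of the equivalent square
#'
#' @param model a [square_flow_model()].
#' @param x,y coordinates in metres, `0 <= x, y <= a` (vectorised,
#'   recycled together).
#' @return density in percent; symmetric under `x <-> a - x`,
#'   `y <-> a - y` and `x <-> y`.
#' @export
flow_density <- function(model, x, y) {
  stopifnot(inherits(model, "square_flow_model"))
  a <- model$a
  if (any(x < 0 | x > a | y < 0 | y > a)) {
    stop("point outside the square: need 0 <= x, y <= a")
  }
  model$K * (1 / (x + 1) + 1 / (y + 1) + 1 / (a - x + 1) + 1 / (a - y + 1))
}

# mean of the K = 1 density around the depth-d contour (square of side a-2d)
unit_perimeter_mean <- function(a, d) {
  s <- a - 2 * d
  centre <- 4 / (a / 2 + 1)
  ifelse(s < 1e-7 * (a + 1),
         centre,
         (2 * log((a - d + 1) / (d + 1)) + s * (1 / (d + 1) + 1 / (a - d + 1))) / s)
}

#' Mean cross-pollination along the contour at depth d
#'
#' All points at distance `d` from the border of the square lie on a
#' concentric square of side `a - 2d`.  Integrating the density around that
#' contour and dividing by its perimeter gives the closed form
#' \deqn{\bar K(d) = K\,\frac{2 \ln\frac{a-d+1}{d+1} +
#'   (a-2d)\left(\frac{1}{d+1} + \frac{1}{a-d+1}\right)}{a-2d}.}
#' At `d = a/2` the contour degenerates to the centre point and the centre
#' density `4K/(a/2+1)` is returned (the expression is continuous there).
#'
#' @param model a [square_flow_model()].
#' @param d depth from the border in metres, `0 <= d <= a/2` (vectorised).
#' @return mean cross-pollination in percent.
#' @examples
#' m <- square_flow_model(1, 120)
#' perimeter_mean(m, 3)
#' @export
perimeter_mean <- function(model, d) {
  stopifnot(inherits(model, "square_flow_model"))
  a <- model$a
  if (any(d < 0 | d > a / 2)) stop("depth d outside [0, a/2]")
  model$K * unit_perimeter_mean(a, d)
}

#' Mean cross-pollination over a concentric square region
#'
#' Average density over the frame between depths `d1` and `d2`
#' (`0 <= d1 < d2 <= a/2`), i.e. the region between the concentric squares
#' of sides `a - 2 d1` and `a - 2 d2`:
#' \deqn{\frac{4K(a-2d_1)\ln\frac{a-d_1+1}{d_1+1} -
#'       4K(a-2d_2)\ln\frac{a-d_2+1}{d_2+1}}{(a-2d_1)^2 - (a-2d_2)^2}.}
#' With `d2 = a/2` the inner square vanishes and the region is the whole
#' central portion beyond depth `d1`.
#'
#' @param model a [square_flow_model()].
#' @param d1,d2 depths in metres with `0 <= d1 < d2 <= a/2`.
#' @return mean cross-pollination in percent.
#' @export
region_mean <- function(model, d1, d2) {
  stopifnot(inherits(model, "square_flow_model"))
  a <- model$a
  if (any(d1 < 0) || any(d2 > a / 2) || any(d1 >= d2)) {
    stop("need 0 <= d1 < d2 <= a/2")
  }
  s1 <- a - 2 * d1
  s2 <- a - 2 * d2
  num <- 4 * model$K * (s1 * log((a - d1 + 1) / (d1 + 1)) -
                          s2 * log((a - d2 + 1) / (d2 + 1)))
  num / (s1^2 - s2^2)
}

#' Whole-field mean cross-pollination
#'
#' The average of the density over the whole square,
#' \eqn{%GM = 4 K \ln(a+1) / a}: the overall GM content of the field under
#' the model.
#'
#' @param model a [square_flow_model()].
#' @return overall %GM in percent.
#' @examples
#' field_mean(square_flow_model(0.94384, 120))   # about 0.15
#' @export
field_mean <- function(model) {
  stopifnot(inherits(model, "square_flow_model"))
  4 * model$K * log(model$a + 1) / model$a
}

#' Calibrate the flow model from an observed contour mean
#'
#' Given the measured mean cross-pollination `K_d_observed` along the
#' contour at depth `d` of a field with equivalent square side `a`, returns
#' the model whose [perimeter_mean()] at `d` equals the observation.  Since
#' every model quantity is proportional to `K`, calibration is a single
#' division.
#'
#' @param a equivalent square side in metres.
#' @param d sampling depth in metres, `0 <= d <= a/2`.
#' @param K_d_observed observed contour mean in percent (>= 0).
#' @return a [square_flow_model()].
#' @examples
#' calibrate_flow_model(120, 3, 0.3)   # K = 0.94384
#' @export
calibrate_flow_model <- function(a, d, K_d_observed) {
  if (!is.finite(a) || a <= 0) stop("a must be > 0")
  if (!is.finite(d) || d < 0 || d > a / 2) stop("depth d outside [0, a/2]")
  if (!is.finite(K_d_observed) || K_d_observed < 0) stop("K_d_observed must be >= 0")
  square_flow_model(K_d_observed / unit_perimeter_mean(a, d), a)
}
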