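# Independent numerical oracles: brute-force quadrature of the border-kernel
# density, written without reference to the package's closed forms.

oracle_density <- function(K, a, x, y) {
  K * (1 / (x + 1) + 1 / (y + 1) + 1 / (a - x + 1) + 1 / (a - y + 1))
}

# line integral of the density around the depth-d contour / contour length
oracle_perimeter_mean <- function(K, a, d) {
  side <- function(f) stats::integrate(f, d, a - d, rel.tol = 1e-12)$value
  tot <- side(function(x) oracle_density(K, a, x, d)) +
    side(function(x) oracle_density(K, a, x, a - d)) +
    side(function(y) oracle_density(K, a, d, y)) +
    side(function(y) oracle_density(K, a, a - d, y))
  tot / (4 * (a - 2 * d))
}

# 2-D integral of the density over the concentric square [d, a-d]^2
oracle_square_integral <- function(K, a, d) {
  inner <- Vectorize(function(y) {
    stats::integrate(function(x) oracle_density(K, a, x, y),
                     d, a - d, rel.tol = 1e-12)$value
  })
  stats::integrate(inner, d, a - d, rel.tol = 1e-12)$value
}

oracle_field_mean <- function(K, a) oracle_square_integral(K, a, 0) / a^2

oracle_region_mean <- function(K, a, d1, d2) {
  num <- oracle_square_integral(K, a, d1) -
    if (d2 < a / 2) oracle_square_integral(K, a, d2) else 0
  num / ((a - 2 * d1)^2 - (a - 2 * d2)^2)
}

# geometry helpers used across tests
square_geom <- function(a) field_geometry(a^2, 4 * a)

rect_geom <- function(L, W) field_geometry(L * W, 2 * (L + W))

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
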