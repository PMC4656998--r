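test_that("single-ring estimator reproduces the printed worked example", {
  expect_equal(round(estimate_single_ring(0.3, 3, 30)$value, 2), 0.15)
  expect_equal(round(estimate_single_ring(1.30, 3, 30)$value, 2), 0.65)
  expect_equal(round(estimate_single_ring(0.04, 3, 22.57)$value, 2), 0.02)
  expect_equal(estimate_single_ring(0, 3, 30)$value, 0)
  expect_error(estimate_single_ring(0.3, 70, 30), "sampling depth")
})

test_that("single-ring estimator is homogeneous of degree 1 in K_d", {
  base <- estimate_single_ring(0.2, 3, 25)$value
  for (s in c(0.5, 2, 10)) {
    expect_equal(estimate_single_ring(0.2 * s, 3, 25)$value, base * s,
                 tolerance = 1e-12)
  }
  # and supports other sampling depths (d = 6, 8 surveys)
  for (d in c(6, 8)) {
    est <- estimate_single_ring(0.24, d, 26.12)$value
    expect_gt(est, 0)
    m <- calibrate_flow_model(4 * 26.12, d, 0.24)
    expect_equal(est, field_mean(m), tolerance = 1e-12)
  }
})

test_that("centre prediction follows the calibrated density at d = a/2", {
  expect_equal(round(predict_center(0.3, 3, 30), 2), 0.06)
  expect_equal(predict_center(0, 3, 30), 0)
  # oracle: calibrate numerically and evaluate the density at the centre
  K <- 0.3 / oracle_perimeter_mean(1, 700, 3)
  expect_equal(predict_center(0.3, 3, 175), oracle_density(K, 700, 350, 350),
               tolerance = 1e-8)
})

test_that("two-part estimator is the area-weighted ring/centre average", {
  g <- field_geometry(15000, 500)
  expect_equal(estimate_two_part(1.30, 1.06, g)$value,
               (1.30 * 4600 + 1.06 * 10400) / 15000)
  expect_equal(round(estimate_two_part(1.30, 1.06, g)$value, 2), 1.13)
  # survey field 147: perimeter from A and I
  g147 <- field_geometry(4772, 4772 / 14.46)
  expect_equal(round(estimate_two_part(0.35, 0.20, g147)$value, 2), 0.29)
  # weighted average of equal values is that value
  expect_equal(estimate_two_part(0.7, 0.7, g)$value, 0.7)
  # clamped geometry (all ring) degenerates to K_3
  g_small <- field_geometry(2134, 335)
  expect_equal(estimate_two_part(0.42, 0.05, g_small)$value, 0.42)
  # warning for very large fields where the centre portion is overestimated
  expect_warning(estimate_two_part(0.1, 0.01, square_geom(4 * 80)), "overestimated")
})

test_that("estimators are monotone in each measured input", {
  g <- field_geometry(15000, 500)
  k <- seq(0, 2, by = 0.25)
  sr <- vapply(k, function(v) estimate_single_ring(v, 3, 30)$value, numeric(1))
  tp_k3 <- vapply(k, function(v) estimate_two_part(v, 0.5, g)$value, numeric(1))
  tp_kc <- vapply(k, function(v) estimate_two_part(0.5, v, g)$value, numeric(1))
  expect_true(all(diff(sr) > 0))
  expect_true(all(diff(tp_k3) > 0))
  expect_true(all(diff(tp_kc) > 0))
})

test_that("on exact model inputs the single-ring estimate is exact and the two-part close", {
  # two-part closeness is asserted over the field sizes the surveys cover
  # (I about 6-40 m); for much larger fields the centre point increasingly
  # understates the central-region mean and the deviation grows
  for (I in c(10, 20, 40)) {
    a <- 4 * I
    m <- square_flow_model(1.3, a)
    truth <- field_mean(m)
    est <- estimate_single_ring(perimeter_mean(m, 3), 3, I)$value
    expect_rel(est, truth, 1e-10)
    two <- estimate_two_part(perimeter_mean(m, 3), flow_density(m, a / 2, a / 2),
                             square_geom(a))$value
    expect_rel(two, truth, 0.15)
  }
})

test_that("internal contribution is the floored two-part excess", {
  g <- field_geometry(15000, 500)
  expect_equal(round(internal_contribution(1.30, 1.06, g), 2), 0.48)
  # pure-model field: no internal admixture to detect
  m <- calibrate_flow_model(120, 3, 0.3)
  expect_lt(internal_contribution(perimeter_mean(m, 3),
                                  flow_density(m, 60, 60), g), 0.02)
  # centre below the model prediction floors at 0
  expect_equal(internal_contribution(0.3, 0, g), 0)
})

test_that("internal contribution grows with seeded admixture", {
  g <- square_geom(120)
  m <- square_flow_model(0.94384, 120)
  s <- c(0, 0.3, 0.6, 1.0)
  internal <- vapply(s, function(ad) {
    internal_contribution(perimeter_mean(m, 3) + ad,
                          flow_density(m, 60, 60) + ad, g)
  }, numeric(1))
  expect_true(all(diff(internal) > 0))
  expect_equal(internal[1], 0)
})

test_that("binomial sample size reproduces the 180-cob requirement", {
  ss <- sample_size(0.9, z = 1.95, E = 0.1, kernels_per_cob = 189)
  expect_equal(ss$kernels, ceiling(1.95^2 * 0.9 * 99.1 / 0.01))
  expect_equal(ss$cobs, 180)
  expect_equal(sample_size(0.9, E = 50)$cobs, 1)
  expect_error(sample_size(0), "percent")
  expect_error(sample_size(100), "percent")
})
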