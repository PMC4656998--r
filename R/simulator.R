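#' Configuration of a synthetic cross-pollination field
#'
#' Collects everything needed to generate a synthetic field with the
#' statistical structure observed in coexistence studies:
#'
#' * side-specific border pressure: the expected cob-level cross-pollination
#'   at a point is `admixture_pct + sum_i side_V0[i] / (d_i + 1)` with `d_i`
#'   the distance to side `i` of the layout rectangle (1 = south, 2 = east,
#'   3 = north, 4 = west).  Equal coefficients on a square reproduce the
#'   [square_flow_model()] density with `K = side_V0`.
#' * cob-level biological dispersion: adjacent cobs under the same pollen
#'   pressure vary widely; draws use a gamma family with a constant
#'   coefficient of variation anchored so that the SD is
#'   `cob_noise_sd_at_0p9` (default 0.6) at a mean of 0.9%.
#' * qPCR measurement error: multiplicative lognormal noise with relative
#'   SD `qpcr_rsd` (default 0.20), censored below the limit of detection
#'   `lod_pct` (default 0.01) and flagged approximate below the limit of
#'   quantification `loq_pct` (default 0.3).
#' * optional GM of internal origin (`admixture_pct`, e.g. accidental
#'   sowing of GM seed), added uniformly over the field.
#'
#' The distribution families (gamma for cobs, lognormal for qPCR) are
#' modelling choices: the data behind the defaults report only dispersion
#' levels, not shapes.
#'
#' @param geometry a [field_geometry()].
#' @param side_V0 length-4 vector of per-side kernel coefficients in
#'   percent (a single value is recycled).
#' @param admixture_pct internal-origin GM added everywhere (default 0).
#' @param cob_noise_sd_at_0p9 cob SD at a 0.9% mean (default 0.6; 0
#'   disables biological noise).
#' @param qpcr_rsd relative SD of the qPCR measurement (default 0.20; 0
#'   disables measurement noise).
#' @param lod_pct,loq_pct detection and quantification limits in percent.
#' @param cobs_per_point cobs per field sample (default 20).
#' @param row_spacing_m,plant_spacing_m planting lattice spacing (defaults
#'   0.75 m between rows, 0.15 m within rows).
#' @param seed optional integer seed recorded in the config and applied by
#'   the stochastic operations.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(geometry, side_V0 = c(0, 0, 0, 0),
                              admixture_pct = 0,
                              cob_noise_sd_at_0p9 = 0.6,
                              qpcr_rsd = 0.20,
                              lod_pct = 0.01, loq_pct = 0.3,
                              cobs_per_point = 20L,
                              row_spacing_m = 0.75, plant_spacing_m = 0.15,
                              seed = NULL) {
  stopifnot(inherits(geometry, "field_geometry"))
  if (length(side_V0) == 1) side_V0 <- rep(side_V0, 4)
  if (length(side_V0) != 4 || any(!is.finite(side_V0) | side_V0 < 0)) {
    stop("side_V0 must be 4 non-negative percentages")
  }
  stopifnot(admixture_pct >= 0, cob_noise_sd_at_0p9 >= 0, qpcr_rsd >= 0,
            lod_pct >= 0, loq_pct >= lod_pct,
            cobs_per_point >= 1, row_spacing_m > 0, plant_spacing_m > 0)
  structure(list(geometry = geometry, side_V0 = side_V0,
                 admixture_pct = admixture_pct,
                 cob_noise_sd_at_0p9 = cob_noise_sd_at_0p9,
                 qpcr_rsd = qpcr_rsd, lod_pct = lod_pct, loq_pct = loq_pct,
                 cobs_per_point = as.integer(cobs_per_point),
                 row_spacing_m = row_spacing_m,
                 plant_spacing_m = plant_spacing_m,
                 dims = layout_rectangle(geometry), seed = seed),
            class = "simulation_config")
}

#' Expected cob-level cross-pollination at field coordinates
#'
#' @param cfg a [simulation_config()].
#' @param x,y metre coordinates in the layout rectangle (vectorised).
#' @return expected %GM of a cob grown at (x, y).
#' @export
cob_mean_at <- function(cfg, x, y) {
  stopifnot(inherits(cfg, "simulation_config"))
  L <- cfg$dims[["L"]]; W <- cfg$dims[["W"]]
  v <- cfg$side_V0
  cfg$admixture_pct +
    v[1] / (y + 1) + v[2] / (L - x + 1) + v[3] / (W - y + 1) + v[4] / (x + 1)
}

# analytic mean of the kernel field over the layout rectangle
true_field_mean <- function(cfg) {
  L <- cfg$dims[["L"]]; W <- cfg$dims[["W"]]
  v <- cfg$side_V0
  cfg$admixture_pct +
    (v[1] + v[3]) * log(W + 1) / W + (v[2] + v[4]) * log(L + 1) / L
}

#' Generate the true (noise-free) per-cob field
#'
#' Evaluates the expected cob-level cross-pollination on the planting
#' lattice of the layout rectangle.  The measurement layer
#' ([draw_cob_values()], [measure_qpcr()]) is applied separately, so this
#' grid is the simulation ground truth.
#'
#' @param cfg a [simulation_config()].
#' @return object of class `simulated_field`: list with the lattice
#'   coordinate vectors `x`, `y`, the matrix `mu` of expected cob %GM
#'   (rows follow `x`), the analytic `true_mean`, and the `config`.
#' @export
simulate_true_field <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  L <- cfg$dims[["L"]]; W <- cfg$dims[["W"]]
  x <- seq(cfg$row_spacing_m / 2, L, by = cfg$row_spacing_m)
  y <- seq(cfg$plant_spacing_m / 2, W, by = cfg$plant_spacing_m)
  mu <- outer(x, y, function(xx, yy) cob_mean_at(cfg, xx, yy))
  structure(list(x = x, y = y, mu = mu,
                 lattice_mean = mean(mu), true_mean = true_field_mean(cfg),
                 config = cfg),
            class = "simulated_field")
}

#' @export
print.simulated_field <- function(x, ...) {
  cat(sprintf("<simulated_field> %d x %d cob lattice, true mean %.4g %%\n",
              length(x$x), length(x$y), x$true_mean))
  invisible(x)
}

#' Draw individual cob values around a local mean
#'
#' Gamma draws with mean `mu` and constant coefficient of variation
#' `sd_at_0p9 / 0.9` (so the SD equals `sd_at_0p9` when `mu = 0.9`),
#' reproducing the strong between-cob dispersion seen under identical
#' pollen pressure.  `mu = 0` (or zero noise) returns the mean exactly.
#'
#' @param mu local expected cob %GM (scalar).
#' @param n_cobs number of draws.
#' @param sd_at_0p9 SD at a 0.9% mean (default 0.6).
#' @return vector of `n_cobs` non-negative cob %GM values.
#' @export
draw_cob_values <- function(mu, n_cobs, sd_at_0p9 = 0.6) {
  stopifnot(length(mu) == 1, mu >= 0, n_cobs >= 1)
  if (mu == 0 || sd_at_0p9 == 0) return(rep(mu, n_cobs))
  shape <- (0.9 / sd_at_0p9)^2
  stats::rgamma(n_cobs, shape = shape, rate = shape / mu)
}

#' Apply qPCR measurement error, LOD censoring and LOQ flagging
#'
#' Multiplicative lognormal error with relative SD `rsd` (mean preserved),
#' then censoring: results below the limit of detection are reported as 0
#' (flag `"censored"`); results between LOD and LOQ are returned but
#' flagged `"approximate"`; the rest are `"quantified"`.  Flags are
#' attached as attribute `flag`.
#'
#' @param true_pct true sample %GM (vectorised).
#' @param rsd relative SD of the assay (default 0.20; 0 disables noise).
#' @param lod,loq detection/quantification limits in percent.
#' @return measured %GM vector with attribute `flag`.
#' @export
measure_qpcr <- function(true_pct, rsd = 0.20, lod = 0.01, loq = 0.3) {
  stopifnot(all(true_pct >= 0), rsd >= 0)
  out <- true_pct
  pos <- true_pct > 0
  if (rsd > 0 && any(pos)) {
    sdlog <- sqrt(log(1 + rsd^2))
    out[pos] <- true_pct[pos] *
      stats::rlnorm(sum(pos), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  flag <- ifelse(out < lod, "censored",
                 ifelse(out < loq, "approximate", "quantified"))
  out[out < lod] <- 0
  attr(out, "flag") <- flag
  out
}

#' Draw the biological content of every sample of a design
#'
#' For each point of a [sample_set], draws `n_cobs` cob values around the
#' local expected mean and stores their average (the ground, well-mixed
#' sample content, before any measurement) in `value_pct`.
#'
#' @param cfg a [simulation_config()].
#' @param ss a [sample_set] laid out on the same geometry.
#' @return `ss` with `value_pct` filled.
#' @export
sample_biological <- function(cfg, ss) {
  stopifnot(inherits(cfg, "simulation_config"), inherits(ss, "sample_set"))
  ss$value_pct <- vapply(seq_len(nrow(ss)), function(i) {
    mu <- cob_mean_at(cfg, ss$x[i], ss$y[i])
    mean(draw_cob_values(mu, ss$n_cobs[i], cfg$cob_noise_sd_at_0p9))
  }, numeric(1))
  ss
}

#' Measure a simplified survey: pooled periphery + centre qPCR
#'
#' Models the laboratory protocol of the simplified design: equal aliquots
#' of the 8 ground periphery samples are mixed and the pool is measured
#' once by qPCR; the centre sample is measured separately; optionally the
#' 8 individual periphery samples are also measured (for donor-direction
#' identification).  Measurement error applies once per analysis.
#'
#' @param cfg a [simulation_config()].
#' @param ss a simplified [sample_set] with biological `value_pct` filled
#'   (see [sample_biological()]).
#' @param individual also run the 8 individual periphery analyses?
#' @return list with `pooled_k3`, `k_c`, `individual` (vector of 8 or
#'   `NULL`), `sides` (side index of each periphery sample) and `d`.
#' @export
measure_simplified <- function(cfg, ss, individual = FALSE) {
  stopifnot(identical(attr(ss, "design"), "simplified"))
  if (anyNA(ss$value_pct)) stop("biological sample values missing")
  peri <- ss[ss$role == "perimeter", ]
  pooled <- as.numeric(measure_qpcr(mean(peri$value_pct), cfg$qpcr_rsd,
                                    cfg$lod_pct, cfg$loq_pct))
  kc <- as.numeric(measure_qpcr(ss$value_pct[ss$role == "center"],
                                cfg$qpcr_rsd, cfg$lod_pct, cfg$loq_pct))
  ind <- if (individual) {
    as.numeric(measure_qpcr(peri$value_pct, cfg$qpcr_rsd,
                            cfg$lod_pct, cfg$loq_pct))
  }
  list(pooled_k3 = pooled, k_c = kc, individual = ind,
       sides = peri$side, d = peri$depth_d[1])
}

#' Measure every sample of a standard survey by qPCR
#'
#' @param cfg a [simulation_config()].
#' @param ss a standard [sample_set] with biological `value_pct` filled.
#' @return `ss` with `value_pct` replaced by the 28 qPCR readings.
#' @export
measure_standard <- function(cfg, ss) {
  stopifnot(identical(attr(ss, "design"), "standard"))
  if (anyNA(ss$value_pct)) stop("biological sample values missing")
  ss$value_pct <- as.numeric(measure_qpcr(ss$value_pct, cfg$qpcr_rsd,
                                          cfg$lod_pct, cfg$loq_pct))
  ss
}

#' Paired standard-vs-simplified experiment over simulated fields
#'
#' For each configuration, simulates the field, runs both surveys
#' (standard grid aggregation; simplified single-ring and two-part
#' estimates from the pooled periphery and centre analyses) and tabulates
#' them against the analytic truth.  A least-squares regression of the
#' simplified single-ring estimate on the standard estimate summarises the
#' agreement (slope and R^2), mirroring how paired field campaigns are
#' reported.
#'
#' @param cfgs list of [simulation_config()] objects (>= 2).
#' @param d sampling depth of the simplified survey (default 3).
#' @param seed optional integer seed for reproducibility.
#' @return list with `table` (data frame: `field`, `I`, `truth`,
#'   `standard`, `simplified_k3`, `simplified_two_part`), `slope`,
#'   `r_squared`.  With a degenerate batch (no variation in the standard
#'   estimates) the regression is undefined: slope and R^2 are `NA` and a
#'   warning is issued.
#' @export
run_paired_experiment <- function(cfgs, d = 3, seed = NULL) {
  if (length(cfgs) < 2) stop("need at least 2 fields")
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_along(cfgs), function(i) {
    cfg <- cfgs[[i]]
    geom <- cfg$geometry
    I <- self_protection_index(geom)
    std <- measure_standard(cfg, sample_biological(cfg, design_standard(geom)))
    std_est <- aggregate_standard(std, geom)$value
    simp <- sample_biological(cfg, design_simplified(geom, d = d))
    meas <- measure_simplified(cfg, simp)
    data.frame(field = i, I = I, truth = true_field_mean(cfg),
               standard = std_est,
               simplified_k3 = estimate_single_ring(meas$pooled_k3, d, I)$value,
               simplified_two_part = estimate_two_part(meas$pooled_k3,
                                                       meas$k_c, geom)$value)
  })
  tab <- do.call(rbind, rows)
  if (stats::var(tab$standard) < 1e-30 || stats::var(tab$simplified_k3) < 1e-30) {
    warning("regression undefined: no variation across fields")
    return(list(table = tab, slope = NA_real_, r_squared = NA_real_))
  }
  fit <- stats::lm(simplified_k3 ~ standard, data = tab)
  list(table = tab, slope = unname(stats::coef(fit)[2]),
       r_squared = summary(fit)$r.squared)
}
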