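---
title: "Modelling cross-pollination inside maize fields: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cross-pollination inside maize fields: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmflow)
```

## The model and its assumptions

`gmflow` estimates the overall adventitious GM content (%GM, 0–100 percent
scale) of a conventional maize field from the mean cross-pollination
measured along a single depth contour near the border. Four assumptions
carry the model:

1. **The border summarises the neighbourhood.** Whatever the number,
   position and flowering overlap of donor fields, their combined effect is
   captured by the cross-pollination values along the receptor field's
   perimeter. No information about the donors is needed.
2. **Hyperbolic decay.** From a single donor side, cross-pollination falls
   with distance $d$ from the border as $V_d = V_0/(d+1)$ — a competition
   effect between incoming pollen and the field's own pollen cloud, observed
   to hold irrespective of the overall magnitude.
3. **Averages inherit the decay.** The mean of values taken at depth $d$
   around the whole perimeter follows the same $1/(d+1)$ pattern even when
   the border values vary side to side, because the decay acts on each
   border element independently.
4. **Shape enters only through $I = A/p$.** Two fields with the same
   area-to-perimeter ratio under equivalent pollen pressure have the same
   overall %GM. This *Self-Protection Index* (metres) measures self-pollen
   production (area) against the front through which foreign pollen enters
   (perimeter).

Assumption 4 lets us do all computation on the *equivalent square* of side
$a = 4I$, with density

$$\rho(x,y) = K\left[\tfrac{1}{x+1} + \tfrac{1}{y+1} + \tfrac{1}{a-x+1} +
\tfrac{1}{a-y+1}\right],$$

one $1/(\text{distance}+1)$ kernel per side and $K$ a proportionality
constant in percent units. Integrating $\rho$ exactly gives, for the
contour at depth $d$ (a concentric square of side $a-2d$),

$$\bar K(d) = K\,\frac{2\ln\frac{a-d+1}{d+1} +
(a-2d)\left(\frac{1}{d+1}+\frac{1}{a-d+1}\right)}{a-2d},$$

the concentric-region mean between depths $d_1 < d_2$ as a difference of
$4K(a-2d)\ln\frac{a-d+1}{d+1}$ terms over the region area, and the
whole-field mean $\%GM = 4K\ln(a+1)/a$. Only contour *means* are modelled:
point values at a given spot depend on where the donors sit and are out of
scope. The tests verify every closed form against brute-force quadrature of
$\rho$ (relative error $<10^{-6}$ over $a \in \{10, 50, 120, 700\}$), the
conservation identity $\int_0^{a/2}\bar K(d)\,4(a-2d)\,dd = a^2\,\%GM$, and
the large-field limit $\bar K(d)/\bar K(0) \to 1/(d+1)$, which recovers the
decay law the model was built from.

## Estimators

* **Single-ring** (`estimate_single_ring`): calibrate $K$ so that
  $\bar K(d)$ equals the measured pooled contour mean (usually $K_3$ at
  $d = 3$ m; surveys at 6 or 8 m use their own depth), then report the
  model's field mean. Linear in the measurement, exact on model-generated
  fields — including squares with unequal side pressures, because contour
  means only see the *sum* of the side coefficients.
* **Two-part** (`estimate_two_part`): $(K_3 A_R + K_c A_C)/A_T$, where
  $A_R$ is the 10 m peripheral ring and $A_C$ the centre. It rests on the
  model identity that the depth-3 m contour mean approximates the 0–10 m
  ring mean (tested within 10% for $I \in [10, 80]$), and on using the
  *measured* centre value for the central portion, so GM produced inside
  the field (seed admixture, volunteers) enters at full weight. On pure
  model fields it agrees with the single-ring estimate within 15% for the
  field sizes the design was validated on ($I \le 40$ m); for much larger
  fields the centre point increasingly understates the central-region mean
  and the two-part value drifts low — immaterial in practice because
  cross-pollination at the centre of large fields is negligible, and the
  package warns at $I > 67$ m.
* **Internal attribution** (`internal_contribution`): the single-ring
  estimator sees only border-entered pollen, so the excess of the two-part
  estimate over it estimates the internal contribution; floored at 0.

## Thresholds

Worst-case border pressure is pinned at $K_0^{max} = 10.625\%$ — the value
reported from a field fully encircled by a flowering-synchronised donor
(mean border cross-fertilization 21.3%, halved because the MON810 event is
homozygous). The printed 10.625 is stored verbatim rather than recomputed.
`protective_index` solves $\%GM^{max}(I) = $ threshold by Brent
root-finding on $[10^{-3}, 10^4]$ m (tolerance $10^{-6}$; `max_gm` is
strictly decreasing in $I$, so the root is unique). Results are reported to
one decimal. `interior_after_strip` evaluates the concentric-region mean
beyond a harvested periphery ring; the published quick rule
($I > 43$ or $K_3 < (1+I)/22$) is exposed by `strip_rule` and flagged
`heuristic`, since the $K_3$ clause is stricter than the exact model bound.

## Survey designs and aggregation

The **standard** design places 8 transect arms equidistantly along the
perimeter (arc gaps $p/8$, about 50–60 m apart in typical fields), each
with 3-cob samples at depths 0, 3 and 10 m, plus one crossing sample per
transect. Antipodal arms are joined, so all transects cross at the field
centre; the crossing depth is the actual half-width of the field rather
than a fixed 25 m (that figure was site-specific). Aggregation attributes
to each sector–ring sub-area the mean of its four vertex samples and
area-weights by the ring areas. Averaging the vertices of a convex,
steeply decaying profile overstates each sub-area, so the grid reads
*high* on model fields: the tests assert the sign (grid $\ge$ single-ring
for $I \in [10, 200]$) and agreement within 25% in the validated size
range $I \in [10, 40]$. This upward bias is the systematic component of
the published discrepancy between the two methods (regression slope 0.82
of simplified on standard), and the paired-experiment test reproduces its
direction on noiseless simulated batches. When only area and perimeter are
known, layouts use the rectangle with the same $A$ and $p$ (or the
equal-area square when none exists); a supplied boundary polygon is used
for the ring areas via exact inward offsets.

The **simplified** design takes eight 20-cob samples equidistantly at
$d = 3$ m (offset $p/16$ so points avoid corners) plus one 20-cob centre
sample. Pooling equal aliquots of the eight ground periphery samples
realises their arithmetic mean physically, so two qPCR analyses suffice;
the eight individual samples remain available to locate the donor
direction. The 20-cob size follows the binomial sample-size requirement of
roughly 180 cobs to quantify 0.9% within ±0.1 at ~95% confidence
(`sample_size`, defaults $z = 1.95$, 189 kernels per cob).

`normalize_transects` reproduces the model-validation treatment of
transect data: all-zero transects are discarded (no pattern information),
each value is divided by its transect mean so every transect weighs
equally, and the rescaled profile is compared with the theoretical
$\bar K(d)/\bar K(0)$ curve.

## The simulator: what it emulates, and what it does not

`simulation_config` fields and defaults:

| Parameter | Default | Unit | Rationale |
| --- | --- | --- | --- |
| `side_V0` | 0 | % | per-side kernel coefficients; donors are side-specific |
| `admixture_pct` | 0 | % | internal-origin GM, uniform over the field |
| `cob_noise_sd_at_0p9` | 0.6 | % | observed between-cob SD at ~0.9% means |
| `qpcr_rsd` | 0.20 | – | reported assay relative SD |
| `lod_pct`, `loq_pct` | 0.01, 0.3 | % | assay detection/quantification limits |
| `cobs_per_point` | 20 | – | simplified-design sample size |
| `row_spacing_m`, `plant_spacing_m` | 0.75, 0.15 | m | conventional maize planting lattice |

Cob values are gamma with constant CV $0.6/0.9 = 2/3$ (the single
published anchor point, extended by assuming SD proportional to the mean);
qPCR error is lognormal with the stated RSD, mean-preserving, with
below-LOD results stored as 0 (matching how below-LOD survey entries are
used). Gamma and lognormal are package choices — only dispersion *levels*
are reported in the source data — and both are non-negative and
right-skewed, as concentration-like measurements are. Values measured
between LOD and LOQ are passed through flagged `approximate`.

The simulator reproduces: side-asymmetric border pressure, the $1/(d+1)$
interior decay, cob-level dispersion, measurement error and censoring, and
internal admixture. It does **not** emulate wind anisotropy or
within-season flowering dynamics, distance-dependent donor geometry beyond
the four-sided kernel, or spatial autocorrelation of cob noise; passing
tests therefore demonstrate correctness of the estimators *under the
model's own assumptions plus realistic noise*, not the model's fit to real
fields (that fit was established experimentally, on data not published at
sample level).

Test problem sizes were chosen to probe the estimators well while keeping
the suite quick: 200 noisy fields with $I$ uniform on $[10, 40]$ m and
lognormal side pressures for parameter recovery (median absolute relative
error below 25%, mean bias within Monte-Carlo error), and 500 seeded
single-donor fields for donor identification (correct side ranked first in
at least 95% of runs, $\alpha = 2$ median rule with an LOD floor — an
explicit stand-in for the visual inspection practitioners use).

## Numerical choices and degenerate inputs

* $\bar K(d)$ has a removable singularity at $d = a/2$; within
  $10^{-7}(a+1)$ of the centre the centre density $4K/(a/2+1)$ is returned
  (the closed form is continuous there).
* Ring partition: the square-field approximation $A_R = wp - 4w^2$ is
  clamped to $[0, A_T]$ — in very small fields it exceeds the total area,
  and the clamp makes the two-part estimator degenerate gracefully to
  $K_3$ (whole field treated as ring). Widths beyond $p/4$ are rejected.
  Exact mode (polygon inward offset by half-plane clipping) is exact for
  convex fields, which covers the shapes the approximation itself targets.
* Geometry validation: polygon-derived area/perimeter must match stored
  summaries within 0.1%; the isoperimetric bound $A \le p^2/(4\pi)$ rejects
  unit errors. Polygons are orientation-insensitive.
* All lengths are planar metres, all GM contents percentages; no
  geodesic coordinates, holes or multi-part fields.
* Internal contribution and donor flags floor at 0 / use an LOD floor, so
  noise cannot produce negative attributions or spurious flags at zero.

## Known limitations

* Point predictions inside a field are out of scope by construction; only
  contour and region means are meaningful.
* The standard-grid aggregation is faithful to the published scheme,
  including its upward bias; it is provided for comparison, not as the
  recommended estimator.
* The equivalent-rectangle layout is a stand-in when no polygon is given;
  sub-area boundaries on strongly irregular fields will differ from a true
  GIS partition (both ring-partition modes are provided for this reason).
* The heuristic strip rule is reported as printed; its $K_3$ clause is
  deliberately conservative relative to the exact interior computation.
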