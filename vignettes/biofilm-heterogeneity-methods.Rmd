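---
title: "Methods: quantifying spatial heterogeneity in hose biofilms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying spatial heterogeneity in hose biofilms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biofilmscale)
```

`biofilmscale` analyses spatial heterogeneity of a tubing biofilm sampled at
high resolution: a 120 cm hose cut into 20 × 6 cm pieces, bisected into top
and bottom halves, imaged by optical coherence tomography (OCT, 30 B-scans
of 2 × 1 mm per piece and half), and sectioned into 1.2 cm units — 200
sections and 1200 images per hose. This vignette documents the models, the
parameters that matter, the numerical choices, and what the synthetic data
generator does and does not emulate.

## The synthetic hose model

The generator is the package's ground truth: every downstream stage is
validated by recovering what the generator put in. It is organised around
one master seed from which independent RNG streams are split for the
thickness field, the TCC values, the community table, the missing-section
mask, and the images, so regenerating one artifact never shifts another.

### Thickness field

Per hose half, thickness along the hose is

\[ T(x) = b + s\,x + \varepsilon(x), \qquad \varepsilon(x) =
c \cdot \bar{T} \cdot Z(x), \]

where \(b\) is the baseline (µm), \(s\) the longitudinal slope (µm/cm),
and \(Z\) a stationary Gaussian process built by moving-average smoothing
of white noise to the topography correlation length (`topo_wavelength`,
default 6 mm — the "hills and dunes" scale), standardized, and scaled by
the small-scale coefficient of variation `smallscale_cv` times the mean
trend level. The field is clipped at zero; configurations that would clip
more than half the hose are rejected as nonsensical. The default grid step
is 1 mm.

Defaults emulate a biofilm grown for a year under controlled twice-daily
warm-water flushing: slopes 0.83 (top) and 2.13 (bottom) µm/cm with
baselines chosen so the half means are 252 and 386 µm, and `smallscale_cv`
of 0.12/0.24. Because adjacent 1.2 cm section means are autocorrelated at
the topography wavelength, the realized adjacent-section variation sits
somewhat below the field-level CV target:

```{r adjacent-variation}
sim <- simulate_hose(sim_config(seed = 1))
top <- sim$sections[sim$sections$half == "top", ]
bottom <- sim$sections[sim$sections$half == "bottom", ]
c(top = adjacent_variation(top$true_thickness_um)$mean,
  bottom = adjacent_variation(bottom$true_thickness_um)$mean)
#>       top    bottom
#>  7.828562 17.236791
```

`smallscale_cv` deliberately keeps its simple contracted meaning
(detrended field CV) rather than being re-parameterized in terms of the
derived pair statistic.

Section means of the field are defined as the integral average of the
piecewise-linear field over the section (trapezoidal weights). This is
exactly what the imaging path estimates when it averages dense per-column
thickness, so the two routes are comparable at sub-pixel accuracy.

### Total cell concentrations

TCC couples to thickness through standardized section thickness
\(z^{th}_i\):

\[ \mathrm{TCC}_i = \mu \left( 1 + c_v \left( \rho\, z^{th}_i +
\sqrt{1-\rho^2}\, z_i \right) \right), \]

clipped at zero, with defaults \(\mu = 2.4\times 10^7\) cells/cm²,
\(c_v = 0.2\), and \(\rho = 0.4\) (a deliberately weak coupling: cell
counts are far less variable than structure). In this symmetric form the
sample Pearson correlation approaches \(\rho\) and the realized CV
approaches \(c_v\), which is what the recovery tests assert.

### Community table

Expected per-section proportions start from a dominant profile (defaults:
three taxa at 24.7%, 23.4% and 9.6% — about 58% of reads) over a
geometric-decay background tail of rank ratio 0.9 across the remaining
taxa (384 total). Three structures are layered on top:

- a smooth per-taxon lognormal fluctuation along the hose
  (`composition_noise`, log-sd 0.45, correlation length ~5 sections). This
  is what gives adjacent sections a realistic Bray-Curtis dissimilarity;
  pure multinomial resampling at 50 000 reads would produce BC ≈ 0.01,
  far below what real section pairs show:

  ```{r adjacent-bc}
  adjacent_dissimilarity(sim$community)
  #> Adjacent-section Bray-Curtis: 0.11 +/- 0.04 (range 0.05-0.32, n = 187)
  ```

- a shared smooth fluctuation applied as a multiplicative tilt
  \(e^{\pm s g(x)}\) to an anticorrelated dominant pair. The tilt keeps
  expected proportions strictly positive for any strength, which an
  additive shift cannot guarantee;
- localized additive step changes in relative abundance (default: +0.081
  for the third dominant on top-half sections 81–91), with the
  non-stepped taxa rescaled so columns still sum to one; a step that would
  drive a proportion negative is rejected.

Counts are then drawn multinomially per section; sections go missing
(columns of `NA`, never imputed) with probability 0.025, emulating failed
DNA amplification.

The tail ratio 0.9 was chosen by closed-form calculation: at 50 000 reads
it yields ~70 detected taxa per section (realistic for this system) and a
pooled Pielou evenness near 0.4–0.5. A flatter tail that made all 384 taxa
detectable in the pooled table would push evenness to ~0.55; with a
3-dominant community those two emulation targets cannot be met
simultaneously, and per-section realism was preferred.

### B-scan rendering

Images are 8-bit grayscale, row 1 nearest the probe, with water ≈ 30,
biofilm ≈ 120, substratum ≈ 220 and additive Gaussian noise (default sd 8)
— arbitrary but fixed levels so tests are stable. The substratum interface
sits at a fixed depth leaving ~100 µm of visible substratum; the surface
row follows the true thickness at each lateral position (2/4 µm axial/
lateral pixels by default). Floating detached-biofilm artifacts (elliptical
blobs at biofilm intensity, Poisson-many per image) can be placed in the
water; their bounding boxes are recorded as ground truth so masking can be
tested as a round trip.

## Interface detection

Detection follows per-column gray-scale gradient analysis: smooth the
axial intensity profile with a 5-pixel moving average, take a centred
finite difference, and locate interfaces as suprathreshold gradient runs.

Numerical choices that matter:

- **Threshold.** `threshold_k` (default 4) times a robust per-column noise
  scale — the MAD of the smoothed gradient over the whole column — with an
  absolute floor (`min_gradient = 2`) so noise-free images don't collapse
  to a zero threshold. A short background window proved too noisy an
  estimator: underestimating the sd by chance triggers false surface
  crossings in the water.
- **Runs, not single crossings.** A detection requires at least two
  consecutive suprathreshold rows; isolated noise spikes in ~400 water
  rows would otherwise fire regularly.
- **Which run.** The substratum is the *deepest* suprathreshold run (the
  deepest transition in a column is substratum by construction, below the
  surface and any floating artifacts); the surface is the *first* run from
  the probe side, above the substratum neighbourhood. Choosing the global
  gradient maximum for the substratum is not robust: the two interface
  steps have similar magnitude and noise can swap them.
- **Tie-break.** Within a run the reported row is
  `ceiling((first + last)/2)`. For an ideal step edge the smoothed
  gradient plateaus symmetrically around the half-pixel boundary, and this
  tie-break returns exactly the first row of the new layer — which is why
  noise-free detection is exact to the row.
- **Degenerate columns.** A column whose region above the substratum run
  is at water level reports coinciding interfaces (zero thickness); a
  column with no suprathreshold run at all is *undetected* — a value, not
  an error. Thickness below ~3 axial pixels biases upward by up to 2
  pixels because the two interface runs merge; that regime lies at or
  below the 4.4 µm detection limit and is flagged censored.

Per-column thickness is `(substratum − surface) × axial_pixel`. Censored
columns contribute `detection_limit / 2` to the image mean by default (the
averaging of sub-limit regions is not standardized; exclusion is available
via `censor_policy = "exclude"`). Undetected columns never contribute, and
an image with more than half its columns undetected is flagged and dropped
from its section mean — the programmatic counterpart of sending an image
to manual repair. Manual repair itself is explicit: mask boxes reset
pixels to water level, and override files assign interface rows per column
range.

## Heterogeneity statistics

Adjacent-section variation uses the symmetric pair denominator
`|x_{i+1}-x_i| / ((x_i+x_{i+1})/2) × 100`; the asymmetric
first-of-pair denominator is exposed as an option but direction
independence is the better default for a flow-oriented series. Missing
sections break adjacency everywhere — no pair, no Bray-Curtis record, and
no representativeness window ever spans a gap.

µm-scale variation within a section is the relative range
`(max − min)/max` of the per-column profile; fold range is `max/min` of a
positive series; longitudinal trends are ordinary least squares with
percent increase evaluated between the fitted endpoints; half-versus-half
comparisons use Welch's t-test (zero-variance equal-mean groups return
p = 1 by convention).

The representativeness curve averages windows of `k` adjacent sections and
reports the mean absolute relative deviation of window means from the
global mean — the expected error of sampling a `1.2 k` cm patch instead
of the whole system. Sliding windows are the default (maximal use of 200
sections); disjoint windows are available where strict independence
between simulated samples matters. The curve is exactly zero at the full
gap-free series length.

## Community metrics

Shannon diversity uses the natural log, so Pielou evenness is
`J' = H'/ln S` (with `J' = 0` by convention for a single-taxon section);
the log base is exposed. Bray-Curtis between adjacent sections is computed
on proportions by default, so unequal read depths do not register as
compositional change; raw counts are an option. Dominance (taxa holding at
least 1% of reads) is assessed on the table pooled across sections — not
per section — with lexicographic tie-breaks for determinism. No
rarefaction or depth normalization beyond proportions is applied; counts
are used as delivered. Taxon-covariate correlations are plain Pearson on
relative abundances.

## Volume reconstruction

All volume operations are exact arithmetic: `V_biofilm = T × 10⁸` µm³/cm²,
`V_cells = TCC × v̄` with `v̄ = 0.3 µm³` per cell by default (an
SEM-derived constant, configurable), and the fraction
`V_cells/V_biofilm × 100`. Hose totals default to the *unit* area model
(1 cm² per section), which is how published hose totals are computed
(average concentration × section count); the *geometric* half-shell model
(`section_length × π d/2` ≈ 1.51 cm² per section at d = 0.8 cm) is
implemented for users who want physical areas. The two models differ by a
constant factor and the volume fraction is invariant to a common area
rescaling.

## What the generator does not emulate

Synthetic hoses capture trend, autocorrelated topography, weak
TCC-thickness coupling, dominance structure, spatially smooth
compositional drift, localized steps, and missing sections. They do not
emulate read-level sequencing error, chimeras, PCR or primer bias,
flow-cytometer gating, detector-specific OCT speckle statistics, refraction
at the water-biofilm interface, or non-stationary topography (e.g.
localized sloughing scars). Passing the recovery suite therefore
demonstrates that the *estimators* are correct and unbiased under a
realistic stochastic model — not that any particular real hose satisfies
that model.

## Problem sizes and determinism

The test suite validates the full-scale configuration (200 sections, 1200
images at 2 µm axial resolution) in the noise-free imaging round trip, and
uses 10–100 seed replicates for Monte-Carlo recovery checks and 1000
random instances for metric-versus-oracle comparisons; a 12 cm hose with
coarser imaging pixels serves for the fast unit tests. The full-scale
round trip streams one image at a time (`measure_hose_thickness()`), so
memory stays in the tens of MB. All randomness flows from explicit seeds;
identical configuration plus seed reproduces every table, image, and
report byte for byte.
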