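---
title: "Semi-quantitative scintigraphy scoring: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-quantitative scintigraphy scoring: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srsquant)
```

## The measurement problem

Somatostatin receptors are over-expressed by activated lymphocytes, so a
radiolabelled somatostatin analogue imaged with a planar gamma camera marks
immune-mediated inflammation: joints in rheumatoid arthritis, salivary glands
in secondary Sjögren's syndrome.  The raw data are grids of detected counts.
Because injected dose, uptake time and camera sensitivity vary between scans,
absolute counts are not comparable; every quantity in this package is
therefore a *target-to-background* (T/B) ratio — mean counts per pixel in a
target region over mean counts per pixel in a reference region (calf muscle
for joints, temporal region for salivary imaging).  T/B is dimensionless and
invariant under any global rescaling of the image, which the test suite
checks explicitly.

Two instruments are built on that ratio:

1. **Static receptor imaging.**  Each joint or gland region is assigned an
   ordinal score 0–5 from its T/B (see below), readers are averaged, and a
   patient is summarised by the number of positive regions `n`, the *global
   score* (sum of positive regions' scores) and the *severity index*
   (global score / n).
2. **Dynamic salivary imaging (sialoscintigraphy).**  A 32-minute dynamic
   acquisition with a secretory stimulus (lemon juice) at minute 16.  The
   *uptake score* of a time window is the T/B of activity summed over the
   window (both parotid glands pooled, temporal background); the *functional
   score* is the pre-stimulus uptake score (minutes 12–16) divided by the
   post-stimulus one (minutes 28–32).  A gland that secretes on stimulation
   loses activity, so stronger secretion gives a larger functional score.

## The 0–5 scale and its boundary convention

`score_from_tb()` bins T/B as: 0 below 0.8; 1 on [0.8, 1.0]; 2 on
(1.0, 1.2]; 3 on (1.2, 1.4]; 4 on (1.4, 1.6]; 5 above 1.6.  The clinical
definition fixes the outer bins with strict inequalities (`< 0.8`, `> 1.6`)
but describes interior bins only as "between"; one convention has to be
chosen, and we fix *upper-inclusive* interior boundaries (1.2 scores 2), with
0.8 and 1.6 belonging to scores 1 and 4 so that the strict outer inequalities
hold verbatim.  The convention is unit-tested against a brute-force lookup on
a 0.01-step grid so it cannot drift silently.

Two positivity readings also coexist in clinical usage: "score greater
than 1" and "score from 1 to 5".  The stricter `> 1` rule is the one attached
to the formula for `n`, so it is the default
(`positivity_threshold = 1`); the alternative is available by setting the
threshold just below 1.  With two readers this matters: an average of
(1, 1) is not positive, (1, 2) → 1.5 is.

Reader averaging keeps half-integers at full precision; rounding to one
decimal happens only at presentation (table writers), never inside
aggregation, so printed tables can be reproduced without compounding
rounding error.

## Phantom model

Clinical images cannot ship with a package, so every downstream stage is
validated against synthetic phantoms with analytic ground truth.

**Static phantom** (`phantom_spec()`, `simulate_static()`): a spatially
uniform background of `background_rate` expected counts per pixel, circular
hotspots where the expected value is `background_rate × true_tb`, an
isotropic Gaussian point-spread function (PSF), and independent Poisson
counts per pixel.  The order is physical: blur the rate map first (the PSF is
a property of the collimator/detector), then Poisson-sample (shot noise is
detection noise).  The blur operator is column-normalised, i.e. each source
pixel redistributes its expected counts with weights renormalised where the
kernel is cut off by the detector edge, so the expected total count is
conserved *exactly*; the conservation test would catch any regression here.

The Poisson error budget is what makes parameter recovery testable: with a
radius-10 hotspot on a 10⁴ counts/pixel background, the relative standard
error of the measured T/B is `sqrt(1/N_t + 1/N_b)` ≈ 7 × 10⁻⁴, far below
both the 1 % recovery tolerance and the 0.05 distance-to-boundary used in
the recovery checks.  Recovery runs use `psf_sigma_px = 0` so the check
isolates counting noise; the default elsewhere is 1 px, a realistic
low-energy-high-resolution collimator blur at ~4 mm pixels.

**Dynamic phantom** (`gland_kinetics()`, `simulate_dynamic()`): gland pixels
carry an *additive* excess over the constant background rate,

* before the stimulus: `g(t) = plateau × (1 − exp(−k_u t))`,
* after the stimulus at `t_s`: exponential decay from `g(t_s)` toward
  `residual_fraction × plateau` with constant `k_w`.

The additive form is forced by the limiting cases: complete instantaneous
washout must drive the gland's T/B to exactly 1 (gland tissue still sits on
background activity), and the functional score then equals the pre-stimulus
uptake score.  Both limits are asserted in the tests using the closed-form
window integrals (`analytic_sgs_scores()`), which are themselves checked
against numerical quadrature.  Expected per-frame counts use the exact time
integral of the rate over each frame, not a midpoint approximation.  Static
`true_tb` values on gland hotspots are ignored in dynamic mode; the kinetics
define the signal.  No radioactive-decay correction is applied within the
32-minute window (the drift is ≲ 6 % and standard practice leaves it
uncorrected); a correction could be added upstream of the series if wanted.

**Default kinetic parameters** (counts/px/s): plateau excess 2 over
background 0.5, uptake constant 1/240 s⁻¹ (≈ 4-min rise time), washout
constant 1/120 s⁻¹, residual fraction 0.3.  These give functional scores in
the 2–3 range at the default windows; clinical functional scores in the
packaged cohort run ≈ 4.4–7.6, i.e. the phantom is deliberately placed where
the pre/post windows are both well inside the modelled rise and decay so the
analytic comparison is most sensitive.

## Cohort generator

`simulate_cohort()` emulates a paired pre/post-therapy cohort at the level
the clinical tables report.  Per joint, a latent T/B is drawn from
N(1.05, 0.25) truncated at 0; the post-therapy value adds a treatment effect
N(−0.25, 0.10); each of two readers scores a reader-perturbed T/B
(N(0, 0.05)) through `score_from_tb()`; aggregation then uses exactly the
production code path.  Defaults: 11 patients (the paired clinical subset
size) with 16 scored joints each.  These values were fixed once, from the
clinical score ranges (pre-therapy global scores of order 10–25, roughly
half of joints positive) and from a design simulation of the null generator
showing paired-t rejection near 5 %; they are not tuned per test.

What the generator does *not* emulate: inter-joint correlation within a
patient, reader bias (only symmetric noise), anatomy (no atlas — circular
hotspots, uniform background), scatter, attenuation, dead time, motion.
Passing tests therefore demonstrate that the *measurement and aggregation
chain* is correct and calibrated under the stated noise model — not that the
clinical images themselves would reproduce.

## Statistics

Pre/post inference uses the classical paired Student's t on differences with
two-sided p-values (sidedness is unstated in clinical reports of this kind;
two-sided is the conservative reading).  Group comparisons default to the
pooled-variance unpaired t with Welch as an option; regression is ordinary
least squares.  All three are checked against direct formula evaluation
(normal equations for OLS) to 1e-10, and the paired t additionally against
a 1000-replicate null simulation (Kolmogorov–Smirnov uniformity of p-values,
and the type-I error band 3.3–7.0 % at α = 0.05).

Patients with no positive joint have an undefined severity index.  They are
excluded *pairwise* from the severity comparison — only the metric with the
undefined value loses the pair, and the dropped count is reported — rather
than listwise; the choice is explicit because clinical practice is silent.
Degenerate inputs are flagged rather than guessed at: zero variance of
paired differences yields a flagged result with no p-value (except the
all-equal case, which is exactly t = 0, p = 1), and a zero background mean
is an error because T/B is undefined.

## Numerical and interface conventions

* Pixels: 0-based `(row, col)`, centers at integer coordinates; a pixel
  belongs to a polygon mask when its *center* is inside or on the boundary.
  Masks are invariant under vertex-order reversal.
* Time: seconds from injection; SGS windows are half-open `[start, end)` and
  must be tiled exactly by frame edges — no fractional-frame interpolation.
  Phantoms are generated to comply, and a non-tiling window is an error.
* Background pooling: multiple background regions of one role pool as total
  counts over total pixels (variance-minimising and deterministic).
* "Summed activity in both parotids": counts are summed across gland masks
  before normalisation; the background is normalised per pixel and scaled by
  the gland pixel count, keeping the score dimensionless.  Summing versus
  averaging frames changes nothing when frames tile the window evenly.
* Anterior/posterior views are treated independently; no geometric-mean
  combination is attempted (acquisition practice is unstated, and combining
  views is a lossy choice better made by the caller).
* Each simulation object carries one integer seed and all its randomness
  flows from it; equal spec, equal bytes.
* The fixture image dialect is a single JSON document per object (metadata
  plus integer count grids), chosen over a binary container so fixtures are
  diffable, generable in code and bit-exact for counts.  DICOM support is
  read-only and limited to uncompressed little-endian planar
  nuclear-medicine objects — enough to ingest clinical statics and dynamics,
  nothing more.

## Problem sizes used by the checks

The shipped tests and the acceptance script run: 48×48 phantoms at 10⁴
counts/pixel (600 replicates for bin recovery), 24×24 dynamic phantoms with
32 one-minute frames (30 replicates for the kinetics comparison), and 1000
null-cohort replicates for t-test calibration.  These sizes put Monte-Carlo
error well below every tolerance while keeping a full run in the order of a
minute on one core; they are choices of the package, documented here so they
can be scaled up by anyone wanting tighter Monte-Carlo intervals.

## Known limitations

* No tomographic reconstruction, attenuation or scatter modelling; the
  phantom is a planar counting model only.
* Readers are modelled as independent noisy scoring passes over measured
  T/B; real visual scoring has structured, correlated disagreement.
* The severity index is undefined at n = 0 and the paired severity
  comparison silently shrinks accordingly (with a reported count); small
  cohorts can lose power there.
* DICOM ingestion does not interpret energy windows, detector heads or
  whole-body sweep geometry.
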