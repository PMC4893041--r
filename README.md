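# srsquant

Semi-quantitative analysis of planar somatostatin-receptor scintigraphy
(SRS) and salivary-gland scintigraphy (SGS) for inflammation imaging.

Activated lymphocytes over-express somatostatin receptors, so a
radiolabelled somatostatin analogue imaged with a planar gamma camera marks
immune-mediated inflammation — joints in rheumatoid arthritis, salivary
glands in secondary Sjögren's syndrome.  This package is for nuclear-medicine
and rheumatology researchers who need the full quantification chain from
count images to cohort statistics, reproducibly and with synthetic ground
truth to validate every step.

## What it computes

**Target-to-background ratio.**  For a target region T and background region
B (calf muscle for joints, temporal region for SGS),

    T/B = mean counts per pixel in T / mean counts per pixel in B.

**Ordinal 0–5 uptake score** per region from T/B: 0 (< 0.8), 1 ([0.8, 1.0]),
2 ((1.0, 1.2]), 3 ((1.2, 1.4]), 4 ((1.4, 1.6]), 5 (> 1.6).  Two readers are
averaged; per patient,

    n              = number of positive regions (average score > 1)
    global score   = sum of positive regions' scores
    severity index = global score / n        (undefined when n = 0)

**SGS uptake and functional scores.**  With a secretory stimulus at minute
16 of a 32-minute dynamic acquisition,

    uptake score     = T/B of activity summed over a window
                       (pre: 12–16 min; post: 28–32 min; both parotids pooled)
    functional score = uptake score (pre) / uptake score (post)

**Cohort statistics.**  Mean ± SD table builders, paired and unpaired
Student's t, OLS regression, and a report reconstructing the standard
pre/post-therapy tables.

**Synthetic ground truth.**  Poisson phantoms (uniform background, circular
hotspots with known T/B, Gaussian PSF applied before Poisson sampling),
analytic salivary kinetics (exponential uptake to a plateau, stimulated
exponential washout, closed-form window scores), and a paired-cohort score
simulator — all seeded and reproducible.

## Worked example

Simulate a three-joint phantom with known T/B {1.5, 1.1, 0.5}, quantify it,
and score the patient with two readers:

```r
library(srsquant)

spec <- phantom_spec(
  matrix_size = c(64, 64), background_rate = 1e4, psf_sigma_px = 0, seed = 41L,
  hotspots = list(hotspot(c(10, 12), 5, 1.5, "wrist-left"),
                  hotspot(c(10, 34), 5, 1.1, "wrist-right"),
                  hotspot(c(26, 12), 5, 0.5, "knee-left")))
sim <- simulate_static(spec)
res <- score_pipeline(sim$frame, phantom_roiset(spec), n_readers = 2)
res$stages$uptake[, c("region_id", "n_pixels", "tb_ratio")]
#>     region_id n_pixels  tb_ratio
#> 1  wrist-left       72 1.4999019
#> 2 wrist-right       73 1.0993002
#> 3   knee-left       72 0.5008371
res
#> <patient_scorecard> patient NA, phase NA
#>   joints: n = 2, global score = 6.0, severity index = 3.0
```

The measured ratios sit within Poisson error of the truth (10⁴ counts/pixel
puts the relative standard error near 0.07 %), the three regions score
{4, 2, 0}, and only the two scores above 1 count as positive: n = 2, global
score 6, severity index 3.0.

The packaged 18-patient clinical cohort (`srs_cohort()`) reproduces its
published summary statistics:

```r
rep <- build_report(srs_cohort())
rep$comparisons$joints_global
#> <paired_comparison> joints_global: n = 11, mean 12.64 -> 5.18, t(10) = 4.617, p = 0.000955
```

Joint uptake falls sharply after anti-TNF-α therapy (global score 12.6 →
5.2, p ≈ 0.001 two-sided, paired t on the 11 treated patients), while
salivary-gland metrics do not change significantly — the clinical picture the
cohort is known for.

An end-to-end reproducible run (phantom cohort → quantify → score → report,
with a manifest of seeds and checksums):

```r
run_pipeline(system.file("extdata", "demo_run.yaml", package = "srsquant"),
             out_dir = "runs/demo")
```

or from a shell via the thin CLI:

```sh
Rscript inst/cli/srsquant.R run --config inst/extdata/demo_run.yaml --out runs/demo
```

## Package layout

- `R/` — imaging IO (fixture JSON dialect + read-only planar DICOM), ROI
  polygons and rasterization, phantom and cohort simulators, T/B and SGS
  quantification, 0–5 scoring and aggregation, cohort statistics and report
  builders, pipeline orchestration.
- `inst/extdata/` — packaged per-patient clinical score tables (CSV) and the
  demo pipeline configuration.
- `vignettes/scintigraphy-quantification.Rmd` — models, assumptions,
  parameter defaults, numerical conventions and design decisions.
- `tests/testthat/` — unit, property and end-to-end acceptance tests.
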