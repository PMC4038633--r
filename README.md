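# collafluor

Objective, non-invasive monitoring of collagen during wound healing from two
complementary optical readouts:

1. **Laser-induced autofluorescence spectra** of skin/granulation tissue
   (325 nm excitation). The emission shows a collagen peak near **405 nm**
   and the dominant NADH peak near **455 nm**. After preprocessing, the
   normalized intensity at 405 nm and the band area over **350–405 nm** track
   collagen deposition over the healing time course.
2. **Picro-Sirius red histology under polarized light**, where thick type I
   collagen fibers appear red/yellow birefringent and thin type III fibers
   green. Pixels are scored in HSI color space by closeness to reference
   colors; total collagen is the summed percentage score of the red, yellow
   and green classes.

The package is aimed at researchers analysing wound-healing time courses
(e.g. low-level laser therapy studies with un-wounded, un-illuminated and
laser-treated arms observed on days 0, 5, 10, 30, 45 and 60 post-wounding),
and at anyone who needs a tested reference implementation of the
spectral-preprocessing and color-scoring conventions involved.

## The method in brief

For each spectrum *I(λ)* the preprocessing chain is, in fixed order:

- **Fourier smoothing** — FFT, low-pass filter, inverse FFT. A smoothing
  fraction *p* (default 0.80) zeroes the highest-frequency *p* fraction of
  bins (DC always kept) with a raised-cosine taper over the outermost 10% of
  the retained band;
- **two-point baseline correction** — subtract the straight line through the
  start and end points of the spectrum;
- **normalization** — divide by the global maximum, which is the NADH peak
  (verified, not assumed: a flag is raised if the maximum leaves the
  440–470 nm window).

Per spectrum, the collagen metrics are the normalized intensity at the grid
point nearest 405 nm and the trapezoidal integral over 350–405 nm. Replicate
spectra (4 per site, 4 sites per animal) are averaged in two stages so the
animal is the statistical unit. Groups are compared per day with
repeated-measures ANOVA (group between, day within) plus Bonferroni-adjusted
per-day Student's t contrasts, and reported as mean ± SEM and fold changes.

For each histology image, RGB is converted to HSI; a pixel's score against a
reference color is `max(0, 1 − d/hue_tol)` in circular hue distance `d`,
gated to zero at low saturation, out-of-range intensity or missing chroma.
Each pixel is assigned to the best-scoring class (priority red > yellow >
green on ties) and class percentage scores use the total pixel count as
denominator.

A seeded synthetic-data module simulates two-Gaussian spectra (collagen
405/σ18, NADH 455/σ28, linear baseline, optional hemoglobin dip at 420 nm,
additive noise) with group/day collagen trajectories, plus fiber images with
exactly known red/yellow/green pixel fractions, so the full pipeline is
testable without any external data.

## Worked example

```r
library(collafluor)

# simulate the default monitoring design: 3 groups x 15 animals x 6 days
# x 4 sites x 4 replicates = 4320 spectra
study <- simulate_study(seed = 1)
length(study$spectra)
#> [1] 4320

report <- run_spectral_pipeline(study)
subset(report$summary, metric == "collagen_intensity" & day == 10)
#> # A tibble: 3 × 6
#>   group                   day     n metric              mean     sem
#>   <chr>                 <int> <int> <chr>              <dbl>   <dbl>
#> 1 laser_treated            10    15 collagen_intensity 0.568 0.00723
#> 2 unilluminated_control    10    15 collagen_intensity 0.483 0.0181
#> 3 unwounded_control        10    15 collagen_intensity 0.564 0.00390

report$stats$collagen_intensity$contrasts[3, c("day", "p_adj", "label")]
#> # A tibble: 1 × 3
#>     day   p_adj label
#>   <int>   <dbl> <chr>
#> 1    10 0.00102 P<0.01
```

On day 10 the simulated laser-treated arm shows a higher mean collagen
intensity (0.568 ± 0.007) than the un-illuminated control (0.483 ± 0.018), a
fold change of 1.175, and the Bonferroni-adjusted contrast is significant
(P<0.01) — the behaviour the trajectory preset encodes.

Histology images are scored the same way:

```r
sim <- simulate_histology(histology_params(width = 512, height = 512,
                                           class_fractions = c(red = 0.30)))
quantify_collagen(sim$image)
#> <collagen_scores> 262144 pixels, total collagen 30.00%
```

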