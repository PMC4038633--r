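---
title: "Methods: collagen monitoring from autofluorescence and Picro-Sirius red histology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: collagen monitoring from autofluorescence and Picro-Sirius red histology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(collafluor)
```

## The measurement problem

During dermal wound healing, collagen is deposited progressively in the
granulation tissue. Two optical readouts can track this without repeated
biopsy:

- **Tissue autofluorescence.** Under 325 nm excitation, skin emits with two
  main features: a collagen peak near 405 nm and the dominant NADH peak near
  455 nm. Because absolute intensities depend on probe geometry and optical
  coupling, the collagen signal is expressed relative to the NADH maximum.
- **Collagen birefringence.** Picro-Sirius red stained sections viewed
  between crossed polarizers show thick type I fibers as red/yellow and thin
  type III fibers as weakly green birefringent; color-resolved pixel scoring
  quantifies each class.

`collafluor` implements both quantification chains plus the group statistics
that connect them, and ships simulators that generate data with exactly the
statistical structure the analysis assumes, so every stage is testable end
to end with no external data.

## Spectral model and preprocessing

A spectrum is a strictly increasing wavelength grid (nm) with intensities in
arbitrary units. The analysis needs coverage of 350–460 nm (collagen band
plus NADH window); narrower spectra are flagged by `validate_spectrum()`.

Preprocessing applies three stages in a fixed order (`preprocess()`):

1. **Fourier smoothing** (`fourier_smooth()`). The intensities are Fourier
   transformed, a filter is applied, and the result inverse transformed.
   Commercial spectroscopy packages describe such filters by a single
   "smoothing percentage" without a published definition, so the convention
   here is explicit and reproducible: a smoothing fraction $p$ zeroes the
   highest-frequency $p$ fraction of FFT bins (the lowest $1-p$ retained,
   symmetric, DC always kept), with a raised-cosine taper over the outermost
   10% of the retained band to suppress ringing. $p = 0$ is the identity,
   and the DC bin is never touched, so the spectral mean is preserved to
   machine precision. The default $p = 0.80$ matches the smoothing level
   applied throughout the study. Whether the original "80%" referred to bins
   removed, bins kept, or a kernel width cannot be determined from the
   description; the choice here is a documented package convention. The
   filter requires a uniform grid; `resample_spectrum()` exists for
   irregular input but is never applied silently, because interpolation can
   bias peak metrics.
2. **Two-point baseline correction** (`baseline_correct()`). The straight
   line through the intensities at the first and last samples (or two
   user-chosen anchor wavelengths) is subtracted. Anchor intensities are
   read at the single nearest grid point, without local averaging. The
   output is exactly zero at the anchors, and the operation is a projection
   (idempotent). Negative residuals are retained — clipping would bias the
   band integral.
3. **Normalization** (`normalize_max()`). Intensities are divided by the
   global maximum, asserted by the spectroscopy to be the NADH peak. The
   package verifies rather than assumes this: the wavelength of the maximum
   is recorded and flagged when it leaves the NADH window (default
   440–470 nm), since early-wound spectra can behave differently. The raw
   maximum is used, not a fitted peak height. Normalization is idempotent
   and scale-invariant.

## Collagen metrics

- `collagen_intensity()` reads the normalized intensity at the grid point
  nearest 405 nm (ties toward the lower wavelength). The wavelength is
  fixed; a local-maximum search would change the statistic.
- `collagen_auc()` integrates the normalized intensity over 350–405 nm with
  the composite trapezoid rule, interpolating linearly at band edges that
  fall between grid points. On the package's 1 nm synthetic grid the
  trapezoid error against the closed-form Gaussian integral is about
  0.001%.

Sixteen spectra are recorded per animal per day (4 replicates at each of 4
sites). Averaging is two-staged (`average_study()`): replicates to site
means, then site means to one spectrum per animal per day, with equal
weights. This makes the animal the statistical unit, consistent with group
sizes counted in animals. Grids must match exactly for averaging; no silent
resampling.

`summarize_by_group()` reports mean ± SEM per (group, day) with
$\mathrm{SEM} = s/\sqrt{n}$, $n$ = number of animals. A single-animal cell
gets `sem = NA` rather than a misleading 0. `fold_change()` reports
test/control mean ratios rounded to 3 decimals for spectral metrics and 2
decimals for histology percentage scores, mirroring the reporting precision
of each family.

## Histology scoring in HSI space

`rgb_to_hsi()` uses the classical arccos formulation
($I=(R+G+B)/3$, $S = 1 - \min/I$, hue from the arccos expression with the
$B>G$ reflection). Achromatic pixels get hue 0, saturation 0 and a false
`chromatic` flag. No color calibration or white balance is attempted.

A reference color (`reference_color()`) is a hue target with tolerance plus
hard gates: per-pixel score $\max(0, 1 - d/\mathrm{tol})$ in circular hue
distance $d$, forced to 0 below `sat_min`, outside `int_range`, or without
chroma. This realizes "closer shades score high, distant shades low,
other colors zero" with the fewest parameters; the original software's score
scale is not published, so the scale here is defined on $[0,1]$ with linear
falloff. Defaults (red 0°/20°, yellow 50°/20°, green 120°/30°,
`sat_min` 0.2, intensity 0.05–0.95) are engineering choices, overridable in
the run configuration.

`quantify_collagen()` assigns each pixel exclusively to its best-scoring
class (ties: red > yellow > green) to prevent double counting when
references overlap, then reports per class the score sum, positive-score
area in pixels, and the percentage score with the **total pixel count** as
denominator — so an image entirely at a reference color scores 100%, and
un-wounded skin sections land in the ~15% range typical of this
normalization. Whether the original scores were per-image normalized or
absolute sums is unknown; the per-image normalization adopted here is what
makes percentage scores comparable across images. Total collagen is the sum
of the three class percentages (type I = red + yellow, type III = green).

Qualitative pathologist records (fiber color, thick/thin, dermal layer,
orientation, presence/absence) are read and validated by
`read_qualitative_scores()` for joint reporting only; no computation is done
on them.

## Group statistics

- `students_t_unpaired()`: pooled-variance Student's t, two-tailed (the
  named test; not Welch). Zero pooled variance is handled by convention:
  equal means give $t=0, p=1$; unequal means give the $p=0$ limit with a
  warning.
- `rm_anova_bonferroni()`: mixed two-factor ANOVA with group as the
  between-subjects factor and day as the repeated within-subjects factor
  (animal as error stratum), fitted with `stats::aov`. No sphericity
  correction is applied, since none is named in the procedure being
  reproduced. Per-day laser-vs-control contrasts use Student's t with a
  Bonferroni multiplier equal to the number of days tested — this matches
  per-day significance letters on time-course figures. Animals missing any
  day are dropped with a warning. The layout (day rather than site as the
  repeated factor) is the natural reading of per-day significance marks,
  adopted without certainty.
- `significance_label()`: strict-inequality bins at 0.05/0.01/0.001.

Under a seeded null simulation matching the study design the per-day
adjusted false-positive rate stays below 0.05, and the unadjusted t-test
type-I error at $\alpha = 0.05$ sits in $[0.04, 0.06]$ at 2000 replicates —
both checked in the test suite.

## What the simulators emulate — and what they do not

`simulate_spectrum()` builds baseline + collagen Gaussian + NADH Gaussian,
optionally multiplied by a hemoglobin dip at 420 nm, plus additive Gaussian
noise. Gaussian peak shapes and the widths (collagen σ = 18 nm, NADH σ =
28 nm) are fixture conveniences chosen so that the noiseless normalized
405 nm intensity lands near 0.56 under the un-wounded preset; true emission
lineshapes and overlaps in tissue are not published, so recovery tests
validate **self-consistency of the pipeline**, not absolute spectroscopy.
The hemoglobin dip defaults to off for in vivo presets (it is prominent
mainly ex vivo) and no reabsorption correction is attempted, matching the
procedure being reproduced.

`fig4_trajectory()` encodes the reported group/day mean ± SEM values of the
monitoring experiment as simulation targets (un-wounded flat ≈ 0.56;
controls rising from ≈ 0.32 at day 0; laser rising faster and plateauing by
day 30), with between-animal sd = SEM·√15. Two of the printed day-0 SEMs
(0.299 and 0.1204) are an order of magnitude above every other SEM in the
series and are treated as typographical for 0.0299 and 0.01204. This preset
is an emulation of summary statistics, not data.

`simulate_study()` draws one target intensity per animal × day (clamped to
the invertible range of the amplitude calibration, which matters only in
the far tails of the day-0 wounded cells), converts it to a collagen
amplitude by inverting the noiseless pipeline response with a monotone
spline (81 nodes; inversion error below 1e-8), and adds independent
per-replicate spectral noise (default sd 0.01 of the NADH amplitude).
Site-level effects beyond replicate noise are not modeled, so the two-stage
and flat averages coincide up to noise — real probe-repositioning
variability would add a site stratum the simulator does not emulate.

`simulate_histology()` paints random line-segment fibers class by class
until the target pixel count is reached exactly (the last fiber is trimmed
at random), applies optional per-pixel hue jitter, and quantizes to 8 bits
so the in-memory image is byte-identical to its PNG round trip. Because
foreground pixels sit exactly at the class colors when jitter is 0, the
scorer must reproduce the painted fraction exactly — a counting oracle used
throughout the tests. Real birefringence photographs differ in every
optical respect (texture, partial volume, illumination gradients);
passing these tests shows the scorer's arithmetic is right, not that the
default tolerances are optimal for any particular microscope.

## Numerical and design choices

- Stage order smooth → baseline → normalize is fixed, following the stated
  processing order.
- 405 nm readout uses nearest-grid-point with lower-wavelength tie-break.
- Trapezoid integration; synthetic grid spacing fixed at 1 nm.
- Normalization failure (non-positive maximum, e.g. a purely linear
  spectrum after baseline removal) is an error, not a silent zero.
- The amplitude calibration inverts the *full* pipeline rather than a
  closed-form two-Gaussian ratio, so smoothing and baseline effects are
  included in the ground truth attached to simulated spectra.
- Problem sizes in the test suite: the full 4320-spectrum design is
  simulated once for design counts and 100 times for the ordering-recovery
  check; noise-recovery uses 100–200 replicate spectra; the null t-test
  uses 2000 replicates and the null RM-ANOVA contrast check 300. These
  sizes give Monte-Carlo error comfortably below the asserted margins.

## Known limitations

- NADH levels themselves vary during healing, so normalizing to the NADH
  maximum entangles the collagen readout with metabolic state; the package
  reproduces this convention rather than correcting it.
- Hemoglobin reabsorption near 420 nm can distort the collagen hump in
  vivo; no correction is implemented (deliberately out of scope).
- Spectral discrimination of collagen types I vs III is not possible from
  the two-peak model; histology carries that information.
- The HSI scorer does not segment fibers or estimate orientation; it is a
  per-pixel color measure only.
- Fold changes are ratios of rounded reported means where used as worked
  examples; one published day-45 value (1.43) differs in the last digit
  from the ratio of the printed means (1.44), evidently computed from
  unrounded means.
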