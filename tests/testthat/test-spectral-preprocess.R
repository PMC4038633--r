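grid231 <- seq(320, 550, 1)

test_that("fourier_smooth passes low frequencies and kills high ones", {
  n <- length(grid231)
  # constant signal: only the DC bin, unchanged at any fraction
  flat <- spectrum(grid231, rep(2.5, n))
  for (p in c(0.2, 0.8, 1)) {
    expect_equal(fourier_smooth(flat, p)$intensities, rep(2.5, n),
                 tolerance = 1e-12)
  }
  # fraction 0 is the identity
  noisy <- noisy_spectrum(seed = 21, noise_sd = 0.05)
  expect_identical(fourier_smooth(noisy, 0)$intensities, noisy$intensities)

  # integer-cycle sinusoids: below the retained band -> preserved;
  # above -> attenuated by >= 90%
  cutoff <- 0.2 * floor(n / 2)            # fraction 0.8 keeps f <= 23
  mk <- function(cycles) spectrum(grid231, 5 + sin(2 * pi * cycles * (seq_len(n) - 1) / n))
  low <- mk(10)                            # inside the untapered band
  out_low <- fourier_smooth(low, 0.8)
  expect_lt(max(abs(out_low$intensities - low$intensities)) /
              diff(range(low$intensities)), 1e-6)
  high <- mk(60)                           # far above the cutoff
  out_high <- fourier_smooth(high, 0.8)
  amp_in <- diff(range(high$intensities)) / 2
  amp_out <- diff(range(out_high$intensities)) / 2
  expect_lt(amp_out / amp_in, 0.10)

  # the DC mean is always preserved
  expect_equal(mean(fourier_smooth(noisy, 0.8)$intensities),
               mean(noisy$intensities), tolerance = 1e-9)

  # non-uniform grids are refused
  bumpy <- spectrum(c(grid231[1:100], grid231[101:n] + 0.3), rep(1, n))
  expect_error(fourier_smooth(bumpy, 0.5), "uniform")
})

test_that("two-point baseline correction is exact and a projection", {
  lin <- spectrum(grid231, 3 + 0.01 * grid231)
  out <- baseline_correct(lin)
  expect_equal(out$intensities, rep(0, length(grid231)), tolerance = 1e-12)

  # already baseline-free signal with zero endpoints is unchanged
  bump <- spectrum(grid231, sin(pi * (grid231 - 320) / 230)^2)
  expect_equal(baseline_correct(bump)$intensities, bump$intensities,
               tolerance = 1e-12)

  # additive trend: the bump is recovered exactly
  trend <- 1.5 - 0.002 * (grid231 - 320)
  mix <- spectrum(grid231, bump$intensities + trend)
  rec <- baseline_correct(mix)
  expect_equal(rec$intensities, bump$intensities, tolerance = 1e-9)

  # projection: applying twice equals applying once
  sp <- noisy_spectrum(seed = 4)
  once <- baseline_correct(sp)
  twice <- baseline_correct(once)
  expect_equal(twice$intensities, once$intensities, tolerance = 1e-12)

  # output is exactly zero at interior anchors too
  anch <- baseline_correct(sp, 350, 500)
  expect_equal(anch$intensities[match(c(350, 500), grid231)], c(0, 0))
  expect_error(baseline_correct(sp, 300, 500), "coverage")
})

test_that("normalize_max scales to unit maximum and flags odd peaks", {
  sp <- simulate_spectrum(template_params(nadh_amp = 2), truth = FALSE)
  n <- normalize_max(sp)
  expect_equal(max(n$intensities), 1, tolerance = 1e-12)
  expect_equal(n$normalization_factor, max(sp$intensities))
  expect_true(n$nadh_in_window)

  # idempotence and scale invariance
  n2 <- normalize_max(n)
  expect_equal(n2$intensities, n$intensities, tolerance = 1e-12)
  expect_equal(n2$normalization_factor, 1, tolerance = 1e-12)
  scaled <- spectrum(sp$wavelengths, 7.3 * sp$intensities)
  expect_equal(normalize_max(scaled)$intensities, n$intensities,
               tolerance = 1e-12)

  # two-Gaussian spectrum with amplitudes 0.8 / 1.6: the collagen peak of
  # the normalized spectrum matches the densely evaluated model
  p <- template_params(collagen_amp = 0.8, nadh_amp = 1.6)
  dense_w <- seq(320, 550, 0.01)
  model <- 0.8 * exp(-(dense_w - 405)^2 / (2 * 18^2)) +
    1.6 * exp(-(dense_w - 455)^2 / (2 * 28^2))
  expected <- model[dense_w == 405] / max(model)
  got <- collagen_intensity(normalize_max(simulate_spectrum(p, truth = FALSE)))
  expect_equal(got, expected, tolerance = 1e-4)

  # degenerate inputs
  expect_error(normalize_max(spectrum(grid231, rep(0, length(grid231)))),
               "not positive")
  odd <- spectrum(grid231, exp(-(grid231 - 380)^2 / 200))
  expect_warning(nw <- normalize_max(odd), "outside the NADH window")
  expect_false(nw$nadh_in_window)
})

test_that("the full preprocess chain composes the stages in order", {
  # a purely linear spectrum is annihilated by the baseline stage (smoothing
  # disabled: a non-periodic ramp is not a fixed point of the FFT filter)
  lin <- spectrum(grid231, 1 + 0.004 * grid231)
  expect_error(preprocess(lin, preprocess_config(smoothing_fraction = 0)),
               "not positive")

  sp <- simulate_spectrum(spectrum_params(noise_sd = 0.01), seed = 3,
                          truth = FALSE)
  n <- preprocess(sp)
  expect_equal(max(n$intensities), 1, tolerance = 1e-12)
  prov <- attr(n, "provenance")
  expect_identical(prov$stages,
                   c("fourier_smooth", "baseline_correct", "normalize_max"))
  expect_equal(prov$smoothing_fraction, 0.8)

  # noisy replicates of one template: mean recovered collagen intensity
  # within +/- 0.02 of the noiseless truth
  p <- spectrum_params(noise_sd = 0.01)
  truth <- attr(simulate_spectrum(p), "truth")$collagen_intensity
  vals <- vapply(1:100, function(k) {
    collagen_intensity(preprocess(simulate_spectrum(p, seed = 7000 + k,
                                                    truth = FALSE),
                                  warn = FALSE))
  }, numeric(1))
  expect_lt(abs(mean(vals) - truth), 0.02)
})

test_that("preprocessing preserves collagen/NADH rank order across amplitudes", {
  amps <- seq(0.05, 0.7, length.out = 10)
  ratios <- vapply(amps, function(a) {
    sp <- simulate_spectrum(spectrum_params(collagen_amp = a), truth = FALSE)
    collagen_intensity(preprocess(sp, warn = FALSE))
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})
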