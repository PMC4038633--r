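# Shared fixtures, all generated in code.

# A small but complete study design for fast pipeline tests.
small_design <- function() {
  study_design(animals_per_group = 4L, days = c(0L, 5L, 10L),
               sites = 2L, replicates = 2L)
}

# Noiseless two-peak template used across preprocessing/metric tests.
template_params <- function(...) {
  spectrum_params(baseline_offset = 0, baseline_slope = 0, ...)
}

# Write a spectrum file with explicit lines (for parser edge cases).
write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

# Deterministic uniform-grid spectrum with seeded noise.
noisy_spectrum <- function(seed, noise_sd = 0.01, ...) {
  simulate_spectrum(template_params(noise_sd = noise_sd, ...), seed = seed,
                    truth = FALSE)
}

expect_spectrum_equal <- function(a, b, tol = 1e-9) {
  expect_equal(a$wavelengths, b$wavelengths, tolerance = tol)
  expect_equal(a$intensities, b$intensities, tolerance = tol)
}
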