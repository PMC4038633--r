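test_that("read_spectrum parses delimited files and rejects bad rows", {
  f <- write_lines_tmp(c("350,0.1", "351,0.2", "352,0.3"))
  sp <- suppressWarnings(read_spectrum(f))
  expect_s3_class(sp, "spectrum")
  expect_length(sp$wavelengths, 3L)
  expect_equal(sp$intensities, c(0.1, 0.2, 0.3))

  # decreasing wavelengths are rejected, not sorted
  f2 <- write_lines_tmp(c("352,0.1", "351,0.2"))
  expect_error(suppressWarnings(read_spectrum(f2)), "strictly increasing")

  # malformed numeric rows name the offending line
  f3 <- write_lines_tmp(c("wavelength_nm,intensity_au", "350,0.1",
                          "351,oops", "352,0.3"))
  expect_error(suppressWarnings(read_spectrum(f3)), "line 3")

  # header row and tab dialect
  f4 <- write_lines_tmp(c("wl\tint", "350\t1", "351\t2"))
  sp4 <- suppressWarnings(read_spectrum(f4, dialect = "tsv"))
  expect_equal(sp4$intensities, c(1, 2))
})

test_that("write/read round trip preserves values and metadata", {
  meta <- spectrum_meta(animal_id = "lt03", group = "laser_treated",
                        day = 10L, site = 2L, replicate = 4L, sex = "male",
                        age_weeks = 8L)
  sp <- simulate_spectrum(template_params(noise_sd = 0.02), seed = 11,
                          meta = meta, truth = FALSE)
  f <- tempfile(fileext = ".csv")
  write_spectrum(sp, f)
  expect_true(any(grepl("# sex: male", readLines(f))))
  back <- read_spectrum(f)
  # 8 significant digits written; agreement well beyond 6
  expect_equal(back$intensities, sp$intensities, tolerance = 1e-6)
  expect_equal(back$wavelengths, sp$wavelengths, tolerance = 1e-6)
  for (fld in c("animal_id", "group", "day", "site", "replicate", "sex",
                "age_weeks")) {
    expect_identical(back$meta[[fld]], sp$meta[[fld]])
  }
})

test_that("spectrum validation flags short grids and narrow coverage", {
  sp <- spectrum(c(350, 351, 352), c(1, 2, 3))
  flags <- suppressWarnings(validate_spectrum(sp, warn = FALSE))
  expect_setequal(flags, c("short_grid", "incomplete_coverage"))
  ok <- spectrum(seq(320, 550, 1), rep(1, 231))
  expect_length(validate_spectrum(ok, warn = FALSE), 0L)
})

test_that("averaging is exact, permutation-invariant and grid-strict", {
  grid <- seq(320, 550, 1)
  s0 <- spectrum(grid, rep(0, length(grid)))
  s2 <- spectrum(grid, rep(2, length(grid)))
  avg <- average_replicates(list(s0, s2))
  expect_equal(avg$intensities, rep(1, length(grid)))

  # identity on a single spectrum
  one <- average_replicates(list(s2))
  expect_equal(one$intensities, s2$intensities)

  # permutation invariance and idempotence on identical inputs
  reps <- lapply(1:4, function(k) noisy_spectrum(seed = k))
  a <- average_replicates(reps)
  b <- average_replicates(rev(reps))
  expect_spectrum_equal(a, b)
  same <- average_replicates(list(reps[[1]], reps[[1]], reps[[1]]))
  expect_spectrum_equal(same, reps[[1]])

  # mismatched grids error rather than resample
  shifted <- spectrum(grid + 0.5, rep(1, length(grid)))
  expect_error(average_replicates(list(s2, shifted)), "grids differ")

  # the mean of 4 seeded noisy copies tracks the template
  sd_noise <- 0.01
  template <- simulate_spectrum(template_params(), truth = FALSE)
  dev <- a$intensities - template$intensities
  expect_lt(max(abs(dev)), 4 * sd_noise / sqrt(4))
  expect_lt(abs(mean(dev)), 2 * sd_noise / sqrt(4 * length(grid)) * 4)
})

test_that("load_study round-trips a simulated study and validates keys", {
  dir <- file.path(tempdir(), "study_io")
  unlink(dir, recursive = TRUE)
  st <- simulate_study(design = small_design(), seed = 5, out_dir = dir)
  loaded <- load_study(file.path(dir, "manifest.csv"))
  expect_equal(length(loaded$spectra), design_size(small_design()))
  comp <- study_completeness(loaded)
  expect_true(all(comp$complete))
  expect_equal(sum(comp$n_observed), length(loaded$spectra))

  # spectra intensities survive the file round trip
  expect_equal(loaded$spectra[[1]]$intensities, st$spectra[[1]]$intensities,
               tolerance = 1e-6)

  # duplicated replicate row -> duplicate-key error
  man <- readr::read_csv(file.path(dir, "manifest.csv"),
                         show_col_types = FALSE)
  dup <- rbind(man, man[1, ])
  fdup <- file.path(dir, "manifest_dup.csv")
  readr::write_csv(dup, fdup)
  expect_error(load_study(fdup), "duplicate")

  # unknown group label -> error
  bad <- man
  bad$group[1] <- "mystery_group"
  fbad <- file.path(dir, "manifest_bad.csv")
  readr::write_csv(bad, fbad)
  expect_error(load_study(fbad), "unknown group")

  # empty manifest -> empty dataset with a warning
  fempty <- file.path(dir, "manifest_empty.csv")
  readr::write_csv(man[0, ], fempty)
  expect_warning(empty <- load_study(fempty), "empty manifest")
  expect_length(empty$spectra, 0L)
})

test_that("two-stage averaging reduces a study to one spectrum per animal-day", {
  st <- simulate_study(design = small_design(), seed = 9)
  site_level <- average_study(st, "site")
  d <- small_design()
  expect_length(site_level$spectra,
                length(d$groups) * d$animals_per_group * length(d$days) * d$sites)
  animal_level <- average_study(st, "animal")
  expect_length(animal_level$spectra,
                length(d$groups) * d$animals_per_group * length(d$days))
  expect_identical(animal_level$spectra[[1]]$meta$aggregated, "animal")
  # equal replicate counts: two-stage average equals the flat mean
  key <- paste(st$manifest$animal_id, st$manifest$day)
  first <- which(key == key[1])
  flat <- average_replicates(st$spectra[first], aggregated = "animal")
  meta1 <- vapply(animal_level$spectra, function(s)
    paste(s$meta$animal_id, s$meta$day), character(1))
  expect_spectrum_equal(animal_level$spectra[[which(meta1 == key[1])]], flat)
})
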