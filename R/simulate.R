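#' Parameters of the two-peak synthetic autofluorescence spectrum
#'
#' A synthetic tissue spectrum is built as
#' `baseline + (collagen Gaussian + NADH Gaussian) * (1 - hemoglobin dip) +
#' noise` on a 1 nm grid. The collagen emission is centered at 405 nm and
#' the NADH emission at 455 nm; the NADH amplitude must exceed the collagen
#' amplitude so the global maximum is the NADH peak, matching in vivo
#' spectra. The hemoglobin reabsorption dip near 420 nm is modeled
#' multiplicatively and is off by default (it is prominent mainly ex vivo).
#'
#' @param grid Wavelength grid in nm (default 320-550 nm, 1 nm step).
#' @param collagen_center,collagen_sigma Collagen Gaussian center/width (nm).
#' @param nadh_center,nadh_sigma NADH Gaussian center/width (nm).
#' @param collagen_amp,nadh_amp Peak amplitudes (a.u.);
#'   `nadh_amp > collagen_amp` required.
#' @param baseline_offset,baseline_slope Linear baseline
#'   `offset + slope * (lambda - min(grid))`.
#' @param noise_sd Additive Gaussian noise s.d. (a.u.).
#' @param hb_dip_depth Fractional depth in \[0, 1\] of the hemoglobin dip at
#'   `hb_dip_center`; 0 disables it.
#' @param hb_dip_center,hb_dip_sigma Dip center/width (nm).
#'
#' @return An object of class `spectrum_params`.
#' @export
spectrum_params <- function(grid = seq(320, 550, by = 1),
                            collagen_center = 405, collagen_sigma = 18,
                            nadh_center = 455, nadh_sigma = 28,
                            collagen_amp = 0.36, nadh_amp = 1,
                            baseline_offset = 0.08, baseline_slope = -2e-4,
                            noise_sd = 0, hb_dip_depth = 0,
                            hb_dip_center = 420, hb_dip_sigma = 10) {
  stopifnot(all(diff(grid) > 0), min(grid) <= 350, max(grid) >= 460,
            collagen_sigma > 0, nadh_sigma > 0,
            collagen_amp > 0, nadh_amp > 0, noise_sd >= 0,
            hb_dip_depth >= 0, hb_dip_depth <= 1, hb_dip_sigma > 0)
  if (nadh_amp <= collagen_amp) {
    stop("nadh_amp must exceed collagen_amp (the NADH peak is the global ",
         "maximum in these spectra)", call. = FALSE)
  }
  structure(as.list(environment()), class = "spectrum_params")
}

gauss <- function(x, center, sigma) exp(-(x - center)^2 / (2 * sigma^2))

# Deterministic (noiseless) spectrum from params; noise added separately.
build_spectrum_intensities <- function(p) {
  w <- p$grid
  sig <- p$collagen_amp * gauss(w, p$collagen_center, p$collagen_sigma) +
    p$nadh_amp * gauss(w, p$nadh_center, p$nadh_sigma)
  sig <- sig * (1 - p$hb_dip_depth * gauss(w, p$hb_dip_center, p$hb_dip_sigma))
  base <- p$baseline_offset + p$baseline_slope * (w - w[1])
  base + sig
}

#' Simulate a single autofluorescence spectrum
#'
#' Deterministic for a fixed seed. The returned spectrum carries a `truth`
#' attribute: the collagen intensity and AUC the noiseless spectrum yields
#' after the full default preprocessing chain (ground truth for recovery
#' tests).
#'
#' @param params A [spectrum_params()].
#' @param seed Integer seed (`NULL` uses the current RNG state).
#' @param meta A [spectrum_meta()] attached to the result.
#' @param truth Attach the noiseless post-pipeline ground truth
#'   (default `TRUE`).
#' @param config [preprocess_config()] used to compute the ground truth.
#'
#' @return A `spectrum`.
#' @export
simulate_spectrum <- function(params = spectrum_params(), seed = NULL,
                              meta = spectrum_meta(), truth = TRUE,
                              config = preprocess_config()) {
  stopifnot(inherits(params, "spectrum_params"))
  clean <- build_spectrum_intensities(params)
  noise <- if (params$noise_sd > 0) {
    draw <- function() rnorm(length(clean), 0, params$noise_sd)
    if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  } else 0
  sp <- spectrum(params$grid, clean + noise, meta)
  if (truth) {
    nclean <- preprocess(spectrum(params$grid, clean), config, warn = FALSE)
    attr(sp, "truth") <- list(
      collagen_intensity = collagen_intensity(nclean),
      collagen_auc = collagen_auc(nclean)
    )
  }
  sp
}

# Monotone map between collagen amplitude and the noiseless post-pipeline
# normalized collagen intensity, inverted with a monotone (Hyman) spline.
make_amp_calibration <- function(params = spectrum_params(),
                                 config = preprocess_config(),
                                 amp_range = c(0.02, 0.80), n = 81) {
  amps <- seq(amp_range[1], amp_range[2], length.out = n)
  ints <- vapply(amps, function(a) {
    p <- params; p$collagen_amp <- a; p$noise_sd <- 0
    nsp <- preprocess(spectrum(p$grid, build_spectrum_intensities(p)),
                      config, warn = FALSE)
    collagen_intensity(nsp)
  }, numeric(1))
  if (any(diff(ints) <= 0)) {
    stop("amplitude-to-intensity map is not monotone over ",
         "the requested range", call. = FALSE)
  }
  list(to_amp = stats::splinefun(ints, amps, method = "hyman"),
       intensity_range = range(ints), amp_range = amp_range)
}

#' Default group/day collagen-intensity trajectory preset
#'
#' Target normalized collagen intensity (mean, between-animal sd) per group
#' and day for the simulator. The shape emulates the wound-healing time
#' course: un-wounded skin flat near 0.56; wounded groups starting near
#' 0.31-0.32 on day 0 and rising, with the laser-treated group rising faster
#' and plateauing by day 30. Between-animal sd = SEM * sqrt(15) for the
#' 15-animal groups. This is an emulation of the study's reported summary
#' values, not measured data.
#'
#' @return A tibble `group, day, mean, sem, sd`.
#' @export
fig4_trajectory <- function() {
  tr <- dplyr::bind_rows(
    tibble::tibble(group = "unwounded_control", day = study_days(),
                   mean = c(0.5600, 0.5614, 0.5614, 0.5514, 0.5589, 0.5580),
                   sem = c(0.0058, 0.0026, 0.0050, 0.0070, 0.0040, 0.0061)),
    tibble::tibble(group = "unilluminated_control", day = study_days(),
                   mean = c(0.3200, 0.4615, 0.4890, 0.5042, 0.5496, 0.54909),
                   sem = c(0.0299, 0.0241, 0.0148, 0.0081, 0.0097, 0.0066)),
    tibble::tibble(group = "laser_treated", day = study_days(),
                   mean = c(0.30919, 0.5404, 0.5698, 0.5675, 0.5596, 0.5562),
                   sem = c(0.01204, 0.0120, 0.0103, 0.0123, 0.0124, 0.0096))
  )
  tr$sd <- tr$sem * sqrt(15)
  tr
}

#' Simulate a complete autofluorescence study
#'
#' Draws one target collagen intensity per animal x day from the trajectory
#' (normal with the between-animal sd, clamped to the feasible range of the
#' amplitude calibration), maps it to a collagen amplitude via the noiseless
#' pipeline calibration, and emits `sites x replicates` noisy copies of each
#' animal-day spectrum. Deterministic for a fixed seed. With the default
#' design this produces 3 x 15 x 6 x 4 x 4 = 4320 spectra, 16 per animal per
#' day.
#'
#' @param design A [study_design()].
#' @param trajectory A trajectory tibble (`group, day, mean, sd`), default
#'   [fig4_trajectory()].
#' @param base_params [spectrum_params()] template (collagen amplitude is
#'   overridden per animal-day).
#' @param noise_sd Additive spectral noise s.d. per replicate (a.u., on the
#'   scale of the unit NADH amplitude).
#' @param seed Integer seed.
#' @param out_dir If non-`NULL`, write each spectrum as a native text file
#'   plus a `manifest.csv` there.
#' @param config [preprocess_config()] used for the amplitude calibration.
#'
#' @return A `study_dataset`; its manifest carries a `truth_intensity`
#'   column with each animal-day's target intensity.
#' @export
simulate_study <- function(design = study_design(),
                           trajectory = fig4_trajectory(),
                           base_params = spectrum_params(),
                           noise_sd = 0.01, seed = 1, out_dir = NULL,
                           config = preprocess_config()) {
  stopifnot(inherits(design, "study_design"), is.data.frame(trajectory),
            all(c("group", "day", "mean", "sd") %in% names(trajectory)))
  cells <- tidyr::expand_grid(
    group = design$groups,
    animal = seq_len(design$animals_per_group),
    day = design$days
  )
  cells <- dplyr::left_join(cells, trajectory[, c("group", "day", "mean", "sd")],
                            by = c("group", "day"))
  if (anyNA(cells$mean)) {
    stop("trajectory does not cover every (group, day) cell of the design",
         call. = FALSE)
  }
  grp_tag <- c(unwounded_control = "uw", unilluminated_control = "uc",
               laser_treated = "lt")
  cells$animal_id <- sprintf("%s%02d", grp_tag[cells$group], cells$animal)

  cal <- make_amp_calibration(base_params, config)
  lo <- cal$intensity_range[1] + 0.01
  hi <- cal$intensity_range[2] - 0.01
  n_rep <- design$sites * design$replicates
  w <- base_params$grid

  sim <- function() {
    target <- pmin(pmax(rnorm(nrow(cells), cells$mean, cells$sd), lo), hi)
    amps <- cal$to_amp(target)
    # noiseless animal-day spectra: baseline + NADH part + amp * collagen part
    collagen_part <- gauss(w, base_params$collagen_center,
                           base_params$collagen_sigma)
    dip <- 1 - base_params$hb_dip_depth *
      gauss(w, base_params$hb_dip_center, base_params$hb_dip_sigma)
    fixed <- base_params$baseline_offset +
      base_params$baseline_slope * (w - w[1]) +
      base_params$nadh_amp *
        gauss(w, base_params$nadh_center, base_params$nadh_sigma) * dip
    m <- outer(collagen_part * dip, amps) + fixed
    idx <- rep(seq_len(nrow(cells)), each = n_rep)
    e <- m[, idx] + matrix(rnorm(length(w) * length(idx), 0, noise_sd),
                           nrow = length(w))
    list(target = target, e = e, idx = idx)
  }
  r <- withr::with_seed(seed, sim())

  site_rep <- tidyr::expand_grid(site = seq_len(design$sites),
                                 replicate = seq_len(design$replicates))
  man <- cells[r$idx, c("animal_id", "group", "day")]
  man$site <- rep(site_rep$site, times = nrow(cells))
  man$replicate <- rep(site_rep$replicate, times = nrow(cells))
  man$truth_intensity <- r$target[r$idx]
  man <- tibble::as_tibble(man)

  spectra <- lapply(seq_len(nrow(man)), function(j) {
    spectrum(w, r$e[, j],
             spectrum_meta(animal_id = man$animal_id[j], group = man$group[j],
                           day = man$day[j], site = man$site[j],
                           replicate = man$replicate[j]))
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- sprintf("%s_day%02d_s%d_r%d.csv", man$animal_id, man$day,
                     man$site, man$replicate)
    for (j in seq_along(spectra)) {
      write_spectrum(spectra[[j]], file.path(out_dir, files[j]))
    }
    man_out <- dplyr::bind_cols(tibble::tibble(file = files), man)
    readr::write_csv(man_out, file.path(out_dir, "manifest.csv"))
    man <- man_out
  }
  study_dataset(spectra, design = design, manifest = man)
}

#' Parameters of the synthetic fiber-image generator
#'
#' @param width,height Image size in pixels.
#' @param class_fractions Named numeric (subset of `red`, `yellow`,
#'   `green`): target fraction of all pixels painted with each fiber class.
#'   The sum must leave room for background (<= 0.9).
#' @param hue_jitter_sd Per-pixel hue jitter s.d. in degrees around the
#'   class hue (0 = exact class colors).
#' @param fiber_thickness Range (px) of fiber stroke thickness.
#' @param fiber_length Range of fiber length as a fraction of the smaller
#'   image dimension.
#' @param saturation,intensity HSI saturation/intensity of fiber colors.
#' @param background Background RGB triple in \[0, 1\] (default black, as
#'   between crossed polarizers).
#'
#' @return An object of class `histology_params`.
#' @export
histology_params <- function(width = 256L, height = 256L,
                             class_fractions = c(red = 0.10, yellow = 0.05,
                                                 green = 0.05),
                             hue_jitter_sd = 0,
                             fiber_thickness = c(2, 6),
                             fiber_length = c(0.2, 0.8),
                             saturation = 1, intensity = 0.3,
                             background = c(0, 0, 0)) {
  stopifnot(width >= 8L, height >= 8L, hue_jitter_sd >= 0,
            length(background) == 3L, all(background >= 0 & background <= 1),
            saturation > 0, saturation <= 1, intensity > 0, intensity < 1)
  if (is.null(names(class_fractions)) ||
      !all(names(class_fractions) %in% c("red", "yellow", "green"))) {
    stop("class_fractions must be named with red/yellow/green", call. = FALSE)
  }
  if (any(class_fractions < 0) || sum(class_fractions) > 0.9) {
    stop("infeasible class fractions (must be >= 0 and sum to <= 0.9)",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "histology_params")
}

class_hues <- c(red = 0, yellow = 50, green = 120)

#' Simulate a Picro-Sirius-like fiber image with known class fractions
#'
#' Paints randomly placed line-segment fibers of each class (red, yellow,
#' green; hue-jittered if requested) on the background until the target
#' pixel fraction is hit exactly (the last fiber is trimmed at random), so
#' the achieved fraction equals `round(fraction * n_pixels) / n_pixels`.
#' Pixels are quantized to 8 bits, so the in-memory image equals its
#' PNG round trip. Deterministic for a fixed seed.
#'
#' @param params A [histology_params()].
#' @param seed Integer seed.
#'
#' @return A list: `image` (RGB array), `truth` (tibble `class, n_px,
#'   fraction` of exactly achieved fractions), `n_pixels`.
#' @export
simulate_histology <- function(params = histology_params(), seed = 1) {
  stopifnot(inherits(params, "histology_params"))
  h <- params$height; w <- params$width; n_px <- h * w
  run <- function() {
    rch <- matrix(params$background[1], h, w)
    gch <- matrix(params$background[2], h, w)
    bch <- matrix(params$background[3], h, w)
    taken <- matrix(FALSE, h, w)
    counts <- setNames(integer(length(params$class_fractions)),
                       names(params$class_fractions))
    col_idx <- matrix(rep(seq_len(w), each = h), h, w)
    row_idx <- matrix(rep(seq_len(h), times = w), h, w)
    min_dim <- min(h, w)
    for (cls in names(params$class_fractions)) {
      target <- round(params$class_fractions[[cls]] * n_px)
      got <- 0L
      guard <- 0L
      px_all <- integer(0)
      while (got < target) {
        guard <- guard + 1L
        if (guard > 20000L) stop("fiber painting did not converge",
                                 call. = FALSE)
        len <- runif(1, params$fiber_length[1], params$fiber_length[2]) * min_dim
        th <- runif(1, params$fiber_thickness[1], params$fiber_thickness[2])
        ax <- runif(1, 1, w); ay <- runif(1, 1, h)
        ang <- runif(1, 0, 2 * pi)
        bx <- ax + len * cos(ang); by <- ay + len * sin(ang)
        x0 <- max(1, floor(min(ax, bx) - th)); x1 <- min(w, ceiling(max(ax, bx) + th))
        y0 <- max(1, floor(min(ay, by) - th)); y1 <- min(h, ceiling(max(ay, by) + th))
        if (x0 > x1 || y0 > y1) next
        sel <- row_idx >= y0 & row_idx <= y1 & col_idx >= x0 & col_idx <= x1
        px <- which(sel & !taken)
        if (!length(px)) next
        pxx <- col_idx[px]; pyy <- row_idx[px]
        vx <- bx - ax; vy <- by - ay
        tproj <- pmin(pmax(((pxx - ax) * vx + (pyy - ay) * vy) /
                             (vx^2 + vy^2), 0), 1)
        dx <- pxx - (ax + tproj * vx); dy <- pyy - (ay + tproj * vy)
        px <- px[dx^2 + dy^2 <= (th / 2)^2]
        if (!length(px)) next
        need <- target - got
        if (length(px) > need) px <- sample(px, need)
        taken[px] <- TRUE
        px_all <- c(px_all, px)
        got <- got + length(px)
      }
      if (length(px_all)) {
        hues <- class_hues[[cls]] +
          if (params$hue_jitter_sd > 0) rnorm(length(px_all), 0, params$hue_jitter_sd) else 0
        rgb <- hsi_to_rgb(hues, params$saturation, params$intensity)
        rch[px_all] <- rgb[, "r"]; gch[px_all] <- rgb[, "g"]; bch[px_all] <- rgb[, "b"]
      }
      counts[cls] <- got
    }
    img <- array(c(rch, gch, bch), dim = c(h, w, 3))
    img <- round(img * 255) / 255   # 8-bit quantization, PNG-stable
    list(img = img, counts = counts)
  }
  r <- withr::with_seed(seed, run())
  total_px <- n_px
  list(image = r$img,
       truth = tibble::tibble(class = names(r$counts), n_px = unname(r$counts),
                              fraction = unname(r$counts) / total_px),
       n_pixels = total_px)
}

#' Simulate a histology image set for a study arm comparison
#'
#' Generates one image per animal per (group, day) with a class-fraction
#' trajectory: total painted fraction follows `totals`, split across
#' classes by `mix`. Writes PNGs plus a manifest when `out_dir` is given.
#'
#' @param groups Group labels to simulate.
#' @param days Days to simulate.
#' @param animals_per_group Images (animals) per group per day.
#' @param totals A data frame `group, day, total_fraction` of target painted
#'   fractions.
#' @param animal_sd Between-animal s.d. of the painted total fraction
#'   (draws are truncated at 0 and 0.85).
#' @param mix Named fractions (summing to 1) splitting the total across
#'   red/yellow/green.
#' @param params Base [histology_params()] (class fractions overridden).
#' @param seed Integer seed.
#' @param out_dir If non-`NULL`, write PNGs and `image_manifest.csv` there.
#'
#' @return A tibble manifest with columns `animal_id, group, day, file`
#'   (file paths when written, else an `image` list-column) and the per-image
#'   truth fractions.
#' @export
simulate_histology_study <- function(groups = c("unilluminated_control",
                                                "laser_treated"),
                                     days = c(10L, 30L),
                                     animals_per_group = 3L,
                                     totals, animal_sd = 0,
                                     mix = c(red = 0.5, yellow = 0.3,
                                             green = 0.2),
                                     params = histology_params(),
                                     seed = 1, out_dir = NULL) {
  stopifnot(is.data.frame(totals),
            all(c("group", "day", "total_fraction") %in% names(totals)),
            abs(sum(mix) - 1) < 1e-9)
  cells <- tidyr::expand_grid(group = groups, day = days,
                              animal = seq_len(animals_per_group))
  cells <- dplyr::left_join(cells, totals, by = c("group", "day"))
  if (anyNA(cells$total_fraction)) {
    stop("totals does not cover every (group, day)", call. = FALSE)
  }
  grp_tag <- c(unwounded_control = "uw", unilluminated_control = "uc",
               laser_treated = "lt")
  cells$animal_id <- sprintf("%s%02d", grp_tag[cells$group], cells$animal)
  if (animal_sd > 0) {
    cells$total_fraction <- withr::with_seed(seed,
      pmin(pmax(rnorm(nrow(cells), cells$total_fraction, animal_sd), 0), 0.85))
  }
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  rows <- lapply(seq_len(nrow(cells)), function(j) {
    p <- params
    p$class_fractions <- mix * cells$total_fraction[j]
    sim <- simulate_histology(p, seed = seed + j)
    row <- tibble::tibble(animal_id = cells$animal_id[j],
                          group = cells$group[j], day = cells$day[j],
                          truth_total_fraction = sum(sim$truth$fraction))
    if (!is.null(out_dir)) {
      f <- sprintf("%s_day%02d.png", cells$animal_id[j], cells$day[j])
      write_image(sim$image, file.path(out_dir, f))
      row$file <- f
    } else {
      row$image <- list(sim$image)
    }
    row
  })
  man <- dplyr::bind_rows(rows)
  if (!is.null(out_dir)) {
    readr::write_csv(man, file.path(out_dir, "image_manifest.csv"))
  }
  man
}
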