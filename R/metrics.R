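#' Collagen peak intensity at a fixed wavelength
#'
#' Reads the normalized intensity at the grid point nearest the target
#' wavelength (ties resolved toward the lower wavelength). The collagen
#' emission sits near 405 nm, so the statistic is the fixed-wavelength
#' intensity, not a local-maximum search — searching would change the
#' statistic.
#'
#' @param nspec A `normalized_spectrum` (or any `spectrum`).
#' @param target_nm Target wavelength, default 405 nm.
#'
#' @return The intensity at the nearest grid point (in \[0, 1\] for a
#'   normalized non-negative spectrum).
#' @export
collagen_intensity <- function(nspec, target_nm = 405) {
  stopifnot(inherits(nspec, "spectrum"))
  w <- nspec$wavelengths
  if (target_nm < w[1] || target_nm > w[length(w)]) {
    stop("target wavelength ", target_nm, " nm is outside the spectrum's ",
         "coverage [", w[1], ", ", w[length(w)], "] nm", call. = FALSE)
  }
  nspec$intensities[nearest_index(w, target_nm)]
}

#' Area under the collagen band
#'
#' Composite trapezoidal integral of the (normalized) intensity over
#' \[`lo`, `hi`\] nm, with linear interpolation at the two band edges when
#' they fall between grid points. The default band 350-405 nm covers the
#' collagen emission up to its peak.
#'
#' @param nspec A `normalized_spectrum` (or any `spectrum`).
#' @param lo,hi Band edges in nm, `lo < hi`, inside the coverage.
#'
#' @return The band area (dimensionless x nm); at most `hi - lo` for
#'   intensities <= 1.
#' @export
collagen_auc <- function(nspec, lo = 350, hi = 405) {
  stopifnot(inherits(nspec, "spectrum"), lo < hi)
  w <- nspec$wavelengths
  if (lo < w[1] || hi > w[length(w)]) {
    stop("integration band [", lo, ", ", hi, "] nm is outside the ",
         "spectrum's coverage [", w[1], ", ", w[length(w)], "] nm",
         call. = FALSE)
  }
  inner <- w > lo & w < hi
  xs <- c(lo, w[inner], hi)
  ys <- c(approx(w, nspec$intensities, xout = lo)$y,
          nspec$intensities[inner],
          approx(w, nspec$intensities, xout = hi)$y)
  pracma::trapz(xs, ys)
}

#' Per-spectrum collagen metrics for a set of preprocessed spectra
#'
#' @param nspecs A list of `normalized_spectrum` objects (e.g. one per
#'   animal per day after [average_study()] and [preprocess()]).
#' @param target_nm Wavelength for [collagen_intensity()].
#' @param band Length-2 band for [collagen_auc()].
#'
#' @return A tibble with the metadata columns and `collagen_intensity`,
#'   `collagen_auc`, `nadh_in_window`.
#' @export
collagen_metrics <- function(nspecs, target_nm = 405, band = c(350, 405)) {
  if (inherits(nspecs, "spectrum")) nspecs <- list(nspecs)
  rows <- lapply(nspecs, function(s) {
    m <- s$meta
    tibble::tibble(
      animal_id = m$animal_id, group = m$group, day = m$day,
      site = m$site, replicate = m$replicate,
      collagen_intensity = collagen_intensity(s, target_nm),
      collagen_auc = collagen_auc(s, band[1], band[2]),
      nadh_in_window = isTRUE(s$nadh_in_window)
    )
  })
  dplyr::bind_rows(rows)
}

#' Group/day mean and SEM of a collagen metric
#'
#' Summarizes per-animal metric values (one value per animal per day — the
#' animal is the statistical unit) into mean and standard error of the mean
#' per (group, day). Empty cells are simply absent; a warning lists any
#' (group, day) cell with a single animal (SEM 0 by convention there would
#' be misleading, so SEM is `NA`).
#'
#' @param metrics A tibble with columns `group, day, animal_id` and the
#'   metric column.
#' @param metric Name of the metric column (e.g. `"collagen_intensity"`).
#'
#' @return A tibble `group, day, n, metric, mean, sem` with `n` = number of
#'   distinct animals.
#' @export
summarize_by_group <- function(metrics, metric = "collagen_intensity") {
  stopifnot(is.data.frame(metrics), metric %in% names(metrics),
            all(c("group", "day", "animal_id") %in% names(metrics)))
  per_animal <- dplyr::summarise(
    dplyr::group_by(metrics, .data$group, .data$day, .data$animal_id),
    value = mean(.data[[metric]]), .groups = "drop"
  )
  out <- dplyr::summarise(
    dplyr::group_by(per_animal, .data$group, .data$day),
    n = dplyr::n_distinct(.data$animal_id),
    mean = mean(.data$value),
    sem = if (dplyr::n() > 1L) sd(.data$value) / sqrt(dplyr::n()) else NA_real_,
    .groups = "drop"
  )
  if (any(out$n == 1L)) {
    warning("cells with a single animal have sem = NA", call. = FALSE)
  }
  tibble::tibble(group = out$group, day = out$day, n = out$n,
                 metric = metric, mean = out$mean, sem = out$sem)
}

#' Fold change of a treated mean over a control mean
#'
#' Ratio `test_mean / control_mean`, rounded to the reporting precision used
#' for each measurement family: 3 decimals for spectral intensity/AUC, 2
#' decimals for histology percentage scores.
#'
#' @param test_mean Treated-group mean (e.g. laser group).
#' @param control_mean Control-group mean; must be positive.
#' @param digits Rounding digits (3 for spectral metrics, 2 for image
#'   scores).
#'
#' @return The rounded fold change.
#' @export
fold_change <- function(test_mean, control_mean, digits = 3) {
  if (!is.numeric(control_mean) || any(control_mean <= 0)) {
    stop("fold change undefined: control mean must be positive", call. = FALSE)
  }
  round(test_mean / control_mean, digits)
}
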