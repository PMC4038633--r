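#' Spectral preprocessing configuration
#'
#' Parameters for the three-stage preprocessing chain applied to every
#' spectrum: Fourier low-pass smoothing, two-point baseline correction and
#' normalization to the NADH (global-maximum) peak.
#'
#' @param smoothing_fraction Fraction in \[0, 1\] of the highest-frequency
#'   FFT bins removed by the smoother (default 0.80, the smoothing level
#'   applied to all spectra in the study).
#' @param baseline_anchors Either `"endpoints"` (default: first and last
#'   wavelength samples) or a numeric length-2 vector of anchor wavelengths
#'   in nm, `lo < hi`.
#' @param nadh_window Wavelength interval (nm) in which the global maximum
#'   (the NADH peak, nominally ~455 nm) is expected; default `c(440, 470)`.
#'
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(smoothing_fraction = 0.80,
                              baseline_anchors = "endpoints",
                              nadh_window = c(440, 470)) {
  stopifnot(is.numeric(smoothing_fraction), length(smoothing_fraction) == 1L,
            smoothing_fraction >= 0, smoothing_fraction <= 1)
  if (!identical(baseline_anchors, "endpoints")) {
    stopifnot(is.numeric(baseline_anchors), length(baseline_anchors) == 2L,
              baseline_anchors[1] < baseline_anchors[2])
  }
  stopifnot(is.numeric(nadh_window), length(nadh_window) == 2L,
            nadh_window[1] < nadh_window[2])
  structure(list(smoothing_fraction = smoothing_fraction,
                 baseline_anchors = baseline_anchors,
                 nadh_window = as.numeric(nadh_window)),
            class = "preprocess_config")
}

is_uniform_grid <- function(w, rel_tol = 1e-6) {
  d <- diff(w)
  max(abs(d - mean(d))) <= rel_tol * mean(d)
}

#' Fourier low-pass smoothing of a spectrum
#'
#' Fourier-transforms the intensities, applies a low-pass filter and
#' inverse-transforms. A `smoothing_fraction` of p zeroes the highest-
#' frequency p fraction of FFT bins (the lowest 1-p fraction is retained,
#' symmetrically, with the DC bin always kept) and applies a raised-cosine
#' taper over the outermost 10% of the retained band to suppress ringing.
#' `smoothing_fraction = 0` returns the input unchanged. The grid must be
#' uniform (FFT assumption).
#'
#' @param x A `spectrum` on a uniformly spaced grid.
#' @param smoothing_fraction Fraction in \[0, 1\] of bins removed.
#'
#' @return A smoothed `spectrum` on the same grid.
#' @export
fourier_smooth <- function(x, smoothing_fraction = 0.80) {
  stopifnot(inherits(x, "spectrum"),
            smoothing_fraction >= 0, smoothing_fraction <= 1)
  if (!is_uniform_grid(x$wavelengths)) {
    stop("fourier_smooth requires a uniformly spaced wavelength grid; ",
         "use resample_spectrum() first", call. = FALSE)
  }
  if (smoothing_fraction == 0) return(x)

  y <- x$intensities
  n <- length(y)
  k <- seq_len(n) - 1L
  f <- pmin(k, n - k)                     # symmetric frequency index
  fmax <- floor(n / 2)
  cutoff <- (1 - smoothing_fraction) * fmax
  taper_lo <- 0.9 * cutoff
  taper_width <- max(cutoff - taper_lo, .Machine$double.eps)
  wgt <- ifelse(f <= taper_lo, 1,
         ifelse(f <= cutoff,
                0.5 * (1 + cos(pi * pmin((f - taper_lo) / taper_width, 1))),
                0))
  wgt[f == 0] <- 1                        # DC always retained
  ys <- Re(fft(fft(y) * wgt, inverse = TRUE)) / n
  spectrum(x$wavelengths, ys, x$meta)
}

nearest_index <- function(w, target) {
  # ties broken toward the lower wavelength (which.min takes the first)
  which.min(abs(w - target))
}

#' Two-point baseline correction
#'
#' Subtracts the straight line through the intensities at two anchor
#' wavelengths (by default the start and end points of the spectrum).
#' Anchor intensities are taken at the single nearest grid point. The output
#' is exactly zero at both anchors; negative residuals are retained, not
#' clipped (clipping would bias band areas).
#'
#' @param x A `spectrum`.
#' @param anchor_lo,anchor_hi Anchor wavelengths in nm, or `NULL` for the
#'   first/last sample.
#'
#' @return A baseline-corrected `spectrum`.
#' @export
baseline_correct <- function(x, anchor_lo = NULL, anchor_hi = NULL) {
  stopifnot(inherits(x, "spectrum"))
  w <- x$wavelengths
  if (is.null(anchor_lo)) anchor_lo <- w[1]
  if (is.null(anchor_hi)) anchor_hi <- w[length(w)]
  if (anchor_lo < w[1] || anchor_hi > w[length(w)] || anchor_lo >= anchor_hi) {
    stop("baseline anchors must lie inside the spectrum's coverage with ",
         "anchor_lo < anchor_hi", call. = FALSE)
  }
  i_lo <- nearest_index(w, anchor_lo)
  i_hi <- nearest_index(w, anchor_hi)
  if (i_lo == i_hi) stop("baseline anchors resolve to the same grid point",
                         call. = FALSE)
  slope <- (x$intensities[i_hi] - x$intensities[i_lo]) / (w[i_hi] - w[i_lo])
  line <- x$intensities[i_lo] + slope * (w - w[i_lo])
  spectrum(w, x$intensities - line, x$meta)
}

#' Normalize a spectrum to its global maximum (NADH peak)
#'
#' Divides the intensities by the global maximum, so the spectrum's maximum
#' is exactly 1. The NADH emission (~455 nm) is the highest peak in these
#' tissue spectra; rather than assuming this, the wavelength of the maximum
#' is recorded and a flag is raised if it falls outside `nadh_window`.
#'
#' @param x A `spectrum` with positive maximum intensity.
#' @param nadh_window Interval (nm) in which the maximum is expected.
#' @param warn Emit a warning when the maximum falls outside the window.
#'
#' @return An object of class `normalized_spectrum` (a `spectrum` with
#'   fields `normalization_factor`, `nadh_peak_wavelength`,
#'   `nadh_in_window`).
#' @export
normalize_max <- function(x, nadh_window = c(440, 470), warn = TRUE) {
  stopifnot(inherits(x, "spectrum"))
  imax <- which.max(x$intensities)
  peak <- x$intensities[imax]
  if (peak <= 0) {
    stop("normalization undefined: spectrum maximum is not positive",
         call. = FALSE)
  }
  peak_w <- x$wavelengths[imax]
  in_window <- peak_w >= nadh_window[1] && peak_w <= nadh_window[2]
  if (warn && !in_window) {
    warning(sprintf("global maximum at %.1f nm lies outside the NADH window [%g, %g] nm",
                    peak_w, nadh_window[1], nadh_window[2]), call. = FALSE)
  }
  out <- spectrum(x$wavelengths, x$intensities / peak, x$meta)
  out$normalization_factor <- peak
  out$nadh_peak_wavelength <- peak_w
  out$nadh_in_window <- in_window
  class(out) <- c("normalized_spectrum", "spectrum")
  out
}

#' Full spectral preprocessing chain
#'
#' Applies, in this fixed order: [fourier_smooth()], [baseline_correct()],
#' [normalize_max()]. Stage parameters are recorded in the result's
#' `provenance` attribute.
#'
#' @param x A `spectrum`.
#' @param config A [preprocess_config()].
#' @param warn Passed to [normalize_max()].
#'
#' @return A `normalized_spectrum` with maximum intensity exactly 1.
#' @export
preprocess <- function(x, config = preprocess_config(), warn = TRUE) {
  stopifnot(inherits(x, "spectrum"), inherits(config, "preprocess_config"))
  s <- fourier_smooth(x, config$smoothing_fraction)
  if (identical(config$baseline_anchors, "endpoints")) {
    s <- baseline_correct(s)
    anchors <- range(x$wavelengths)
  } else {
    s <- baseline_correct(s, config$baseline_anchors[1], config$baseline_anchors[2])
    anchors <- config$baseline_anchors
  }
  n <- normalize_max(s, config$nadh_window, warn = warn)
  attr(n, "provenance") <- list(
    stages = c("fourier_smooth", "baseline_correct", "normalize_max"),
    smoothing_fraction = config$smoothing_fraction,
    baseline_anchors = anchors,
    nadh_window = config$nadh_window
  )
  n
}
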