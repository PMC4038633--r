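#' Acquisition metadata for a single spectrum
#'
#' Identifies where a spectrum sits in the study hierarchy:
#' group -> animal -> day -> site -> replicate. Four tissue sites are probed
#' per animal and four spectra recorded per site.
#'
#' @param animal_id Opaque animal label.
#' @param group One of [study_groups()], or `NA`.
#' @param day Day post-wounding, one of [study_days()], or `NA`.
#' @param site Probing site on the wound/skin, integer 1-4, or `NA`.
#' @param replicate Replicate spectrum within a site, integer 1-4, or `NA`.
#' @param sex Optional, `"male"` or `"female"`.
#' @param age_weeks Optional positive integer age in weeks.
#' @param aggregated `NA` for a raw spectrum, or `"site"`/`"animal"` for an
#'   averaged spectrum (the replicate/site slots are then `NA`).
#'
#' @return An object of class `spectrum_meta`.
#' @export
spectrum_meta <- function(animal_id = NA_character_, group = NA_character_,
                          day = NA_integer_, site = NA_integer_,
                          replicate = NA_integer_, sex = NA_character_,
                          age_weeks = NA_integer_, aggregated = NA_character_) {
  group <- as.character(group)
  if (!is.na(group) && !group %in% study_group_levels) {
    stop("unknown group label: '", group, "' (expected one of ",
         paste(study_group_levels, collapse = ", "), ")", call. = FALSE)
  }
  day <- as.integer(day)
  if (!is.na(day) && !day %in% study_day_levels) {
    stop("day must be one of ", paste(study_day_levels, collapse = ", "),
         ", got ", day, call. = FALSE)
  }
  site <- as.integer(site)
  if (!is.na(site) && (site < 1L || site > 4L)) {
    stop("site must be an integer in 1..4", call. = FALSE)
  }
  replicate <- as.integer(replicate)
  if (!is.na(replicate) && (replicate < 1L || replicate > 4L)) {
    stop("replicate must be an integer in 1..4", call. = FALSE)
  }
  sex <- as.character(sex)
  if (!is.na(sex) && !sex %in% c("male", "female")) {
    stop("sex must be 'male' or 'female'", call. = FALSE)
  }
  age_weeks <- as.integer(age_weeks)
  if (!is.na(age_weeks) && age_weeks <= 0L) {
    stop("age_weeks must be positive", call. = FALSE)
  }
  structure(
    list(animal_id = as.character(animal_id), group = group, day = day,
         site = site, replicate = replicate, sex = sex,
         age_weeks = age_weeks, aggregated = as.character(aggregated)),
    class = "spectrum_meta"
  )
}

#' Construct a spectrum
#'
#' A wavelength grid (nm, strictly increasing) with intensities in arbitrary
#' units plus acquisition metadata. Intensities may be negative after
#' baseline correction; raw instrument spectra are non-negative.
#'
#' @param wavelengths Numeric, strictly increasing, in nm.
#' @param intensities Numeric, same length as `wavelengths`.
#' @param meta A [spectrum_meta()] object.
#'
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(wavelengths, intensities, meta = spectrum_meta()) {
  wavelengths <- as.numeric(wavelengths)
  intensities <- as.numeric(intensities)
  if (length(wavelengths) != length(intensities)) {
    stop("wavelengths and intensities must have the same length", call. = FALSE)
  }
  if (length(wavelengths) < 2L) {
    stop("a spectrum needs at least 2 samples", call. = FALSE)
  }
  if (anyNA(wavelengths) || anyNA(intensities) ||
      any(!is.finite(wavelengths)) || any(!is.finite(intensities))) {
    stop("wavelengths and intensities must be finite", call. = FALSE)
  }
  if (any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing (input is not sorted; ",
         "refusing to sort silently)", call. = FALSE)
  }
  if (!inherits(meta, "spectrum_meta")) {
    stop("meta must be a spectrum_meta object", call. = FALSE)
  }
  structure(list(wavelengths = wavelengths, intensities = intensities,
                 meta = meta),
            class = "spectrum")
}

#' Validate a spectrum for downstream collagen metrics
#'
#' Checks the soft invariants that the collagen pipeline relies on: at least
#' 16 grid points and wavelength coverage of the 350-460 nm window (collagen
#' band plus NADH peak). Violations are flagged, not fatal, because short or
#' narrow spectra are still legal objects.
#'
#' @param x A `spectrum`.
#' @param warn Emit a warning when flags are raised.
#'
#' @return Invisibly, a character vector of flags (possibly empty); one or
#'   both of `"short_grid"` and `"incomplete_coverage"`.
#' @export
validate_spectrum <- function(x, warn = TRUE) {
  stopifnot(inherits(x, "spectrum"))
  flags <- character(0)
  if (length(x$wavelengths) < 16L) flags <- c(flags, "short_grid")
  if (min(x$wavelengths) > 350 || max(x$wavelengths) < 460) {
    flags <- c(flags, "incomplete_coverage")
  }
  if (warn && length(flags)) {
    warning("spectrum validation flags: ", paste(flags, collapse = ", "),
            call. = FALSE)
  }
  invisible(flags)
}

#' @export
print.spectrum <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<spectrum> %d points, %.1f-%.1f nm\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths)))
  if (!is.na(m$animal_id) || !is.na(m$group)) {
    cat(sprintf("  animal=%s group=%s day=%s site=%s replicate=%s\n",
                m$animal_id, m$group, m$day, m$site, m$replicate))
  }
  invisible(x)
}

# Fields serialized in the '#'-prefixed header of native spectrum files.
meta_fields <- c("animal_id", "group", "day", "site", "replicate",
                 "sex", "age_weeks", "aggregated")

#' Read a spectrum from a delimited text file
#'
#' The native dialect is two numeric columns (wavelength_nm, intensity_au),
#' comma/tab/whitespace separated, with optional `#`-prefixed
#' `key: value` metadata lines and an optional column-name header row.
#' Rows with non-monotone wavelengths are rejected, never silently sorted.
#'
#' @param path File to read.
#' @param dialect One of `"auto"` (default, sniffed from the first data
#'   line), `"csv"`, `"tsv"`, `"two_column_text"` (whitespace).
#'
#' @return A validated [spectrum()].
#' @export
read_spectrum <- function(path,
                          dialect = c("auto", "csv", "tsv", "two_column_text")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  is_comment <- grepl("^\\s*#", lines)
  is_blank <- grepl("^\\s*$", lines)

  meta_args <- list()
  for (ln in lines[is_comment]) {
    m <- regmatches(ln, regexec("^\\s*#\\s*([A-Za-z_]+)\\s*:\\s*(.*?)\\s*$", ln))[[1]]
    if (length(m) == 3L && m[2] %in% meta_fields) meta_args[[m[2]]] <- m[3]
  }
  meta <- do.call(spectrum_meta, meta_args)

  data_idx <- which(!is_comment & !is_blank)
  if (!length(data_idx)) stop("no data rows in ", path, call. = FALSE)

  sep <- switch(dialect,
    csv = ",", tsv = "\t", two_column_text = "\\s+",
    auto = {
      first <- lines[data_idx[1]]
      if (grepl(",", first)) "," else if (grepl("\t", first)) "\t" else "\\s+"
    }
  )

  w <- numeric(0); i <- numeric(0)
  for (k in seq_along(data_idx)) {
    lineno <- data_idx[k]
    fields <- strsplit(trimws(lines[lineno]), sep)[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 2L) {
      stop("line ", lineno, " of ", path, ": expected at least 2 columns",
           call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(fields[1:2]))
    if (anyNA(vals)) {
      if (k == 1L) next  # header row with column names
      stop("malformed numeric row at line ", lineno, " of ", path,
           call. = FALSE)
    }
    w <- c(w, vals[1]); i <- c(i, vals[2])
  }
  if (length(w) < 2L) stop("fewer than 2 numeric rows in ", path, call. = FALSE)
  sp <- spectrum(w, i, meta)
  validate_spectrum(sp, warn = TRUE)
  sp
}

#' Write a spectrum to the native two-column text format
#'
#' Writes `#`-prefixed `key: value` metadata lines, a column-name header and
#' CSV data rows at 8 significant digits (round-trips to well beyond 6
#' significant digits).
#'
#' @param x A `spectrum`.
#' @param path Output file.
#'
#' @return Invisibly, `path`.
#' @export
write_spectrum <- function(x, path) {
  stopifnot(inherits(x, "spectrum"))
  m <- x$meta
  hdr <- character(0)
  for (f in meta_fields) {
    if (!is.na(m[[f]])) hdr <- c(hdr, sprintf("# %s: %s", f, m[[f]]))
  }
  out <- c(hdr, "wavelength_nm,intensity_au",
           sprintf("%.8g,%.8g", x$wavelengths, x$intensities))
  tryCatch(writeLines(out, path),
           error = function(e) stop("cannot write spectrum to ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Linearly resample a spectrum onto a new wavelength grid
#'
#' Provided as an explicit utility: averaging and smoothing require exactly
#' matching/uniform grids and never resample silently, because interpolation
#' can bias peak metrics.
#'
#' @param x A `spectrum`.
#' @param new_wavelengths Strictly increasing grid inside the coverage of `x`.
#'
#' @return A resampled `spectrum` with the same metadata.
#' @export
resample_spectrum <- function(x, new_wavelengths) {
  stopifnot(inherits(x, "spectrum"))
  new_wavelengths <- as.numeric(new_wavelengths)
  if (min(new_wavelengths) < min(x$wavelengths) ||
      max(new_wavelengths) > max(x$wavelengths)) {
    stop("new grid extends beyond the spectrum's coverage; ",
         "extrapolation is not supported", call. = FALSE)
  }
  yi <- approx(x$wavelengths, x$intensities, xout = new_wavelengths)$y
  spectrum(new_wavelengths, yi, x$meta)
}

# Shared metadata of a set of spectra: fields equal across all inputs are
# kept, differing fields become NA.
combine_meta <- function(metas, aggregated) {
  args <- list()
  for (f in meta_fields) {
    vals <- unique(vapply(metas, function(m) as.character(m[[f]]), character(1)))
    args[[f]] <- if (length(vals) == 1L) vals else NA_character_
  }
  args$aggregated <- aggregated
  if (aggregated == "site") args$replicate <- NA_character_
  if (aggregated == "animal") { args$replicate <- NA_character_; args$site <- NA_character_ }
  do.call(spectrum_meta, args)
}

#' Average replicate spectra on a shared wavelength grid
#'
#' Pointwise arithmetic mean of the intensities. All inputs must share an
#' exactly identical wavelength grid (use [resample_spectrum()] first if
#' not). Metadata fields shared by all inputs are kept; differing fields
#' become `NA`; the result is marked as aggregated.
#'
#' @param spectra A list of `spectrum` objects (length >= 1).
#' @param aggregated Label recorded in the result's metadata
#'   (`"site"` or `"animal"`).
#'
#' @return A single averaged `spectrum`.
#' @export
average_replicates <- function(spectra, aggregated = "site") {
  if (inherits(spectra, "spectrum")) spectra <- list(spectra)
  stopifnot(length(spectra) >= 1L,
            all(vapply(spectra, inherits, logical(1), "spectrum")))
  w0 <- spectra[[1]]$wavelengths
  for (s in spectra) {
    if (length(s$wavelengths) != length(w0) || any(s$wavelengths != w0)) {
      stop("wavelength grids differ; averaging requires exactly matching ",
           "grids (see resample_spectrum())", call. = FALSE)
    }
  }
  m <- vapply(spectra, function(s) s$intensities, numeric(length(w0)))
  avg <- if (is.matrix(m)) rowMeans(m) else m
  spectrum(w0, avg, combine_meta(lapply(spectra, `[[`, "meta"), aggregated))
}
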