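#' Describe a study design
#'
#' The monitoring experiment used 3 groups of 15 animals, observed on 6 days
#' post-wounding, with 4 probing sites per animal and 4 replicate spectra
#' per site (4320 spectra in total).
#'
#' @param groups Character vector of group labels.
#' @param animals_per_group Number of animals in each group.
#' @param days Integer vector of observation days.
#' @param sites Sites probed per animal per day.
#' @param replicates Replicate spectra recorded per site.
#'
#' @return An object of class `study_design`.
#' @export
study_design <- function(groups = study_groups(), animals_per_group = 15L,
                         days = study_days(), sites = 4L, replicates = 4L) {
  stopifnot(length(groups) >= 1L, all(groups %in% study_group_levels),
            animals_per_group >= 1L, length(days) >= 1L,
            all(days %in% study_day_levels), sites >= 1L, sites <= 4L,
            replicates >= 1L, replicates <= 4L)
  structure(list(groups = groups,
                 animals_per_group = as.integer(animals_per_group),
                 days = sort(as.integer(days)), sites = as.integer(sites),
                 replicates = as.integer(replicates)),
            class = "study_design")
}

#' Total number of spectra a complete design implies
#' @param design A [study_design()].
#' @return Integer count groups x animals x days x sites x replicates.
#' @export
design_size <- function(design) {
  stopifnot(inherits(design, "study_design"))
  length(design$groups) * design$animals_per_group * length(design$days) *
    design$sites * design$replicates
}

manifest_from_spectra <- function(spectra) {
  tibble::tibble(
    animal_id = vapply(spectra, function(s) s$meta$animal_id, character(1)),
    group = vapply(spectra, function(s) s$meta$group, character(1)),
    day = vapply(spectra, function(s) s$meta$day, integer(1)),
    site = vapply(spectra, function(s) s$meta$site, integer(1)),
    replicate = vapply(spectra, function(s) s$meta$replicate, integer(1))
  )
}

#' Bundle spectra and a design into a study dataset
#'
#' @param spectra List of [spectrum()] objects.
#' @param design A [study_design()] (or `NULL` to infer nothing).
#' @param manifest Optional tibble of per-spectrum metadata; rebuilt from the
#'   spectra when omitted.
#'
#' @return An object of class `study_dataset`.
#' @export
study_dataset <- function(spectra, design = NULL, manifest = NULL) {
  stopifnot(is.list(spectra),
            all(vapply(spectra, inherits, logical(1), "spectrum")))
  if (is.null(manifest)) manifest <- manifest_from_spectra(spectra)
  structure(list(spectra = spectra, design = design, manifest = manifest),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("<study_dataset> %d spectra", length(x$spectra)))
  if (!is.null(x$design)) {
    cat(sprintf(" (design: %d groups x %d animals x %d days x %d sites x %d replicates = %d)",
                length(x$design$groups), x$design$animals_per_group,
                length(x$design$days), x$design$sites, x$design$replicates,
                design_size(x$design)))
  }
  cat("\n")
  invisible(x)
}

#' Load a study from a manifest file
#'
#' The manifest is a CSV with columns `file, animal_id, group, day, site,
#' replicate` (optionally `sex, age_weeks`); `file` paths are resolved
#' relative to the manifest's directory. Duplicate
#' (animal, day, site, replicate) keys and unknown group labels are errors.
#'
#' @param manifest Path to the manifest CSV.
#' @param base_dir Directory against which `file` entries are resolved.
#'
#' @return A `study_dataset` with an inferred [study_design()].
#' @export
load_study <- function(manifest, base_dir = dirname(manifest)) {
  man <- readr::read_csv(manifest, show_col_types = FALSE,
                         progress = FALSE)
  if (nrow(man) == 0L) {
    warning("empty manifest: ", manifest, call. = FALSE)
    return(study_dataset(list(), design = NULL, manifest = man))
  }
  required <- c("file", "animal_id", "group", "day", "site", "replicate")
  missing_cols <- setdiff(required, names(man))
  if (length(missing_cols)) {
    stop("manifest is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad_groups <- setdiff(unique(man$group), study_group_levels)
  if (length(bad_groups)) {
    stop("unknown group label(s) in manifest: ",
         paste(bad_groups, collapse = ", "), call. = FALSE)
  }
  key <- paste(man$animal_id, man$day, man$site, man$replicate, sep = "|")
  if (anyDuplicated(key)) {
    stop("duplicate (animal_id, day, site, replicate) in manifest: ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  spectra <- lapply(seq_len(nrow(man)), function(r) {
    row <- man[r, ]
    sp <- read_spectrum(file.path(base_dir, row$file))
    sp$meta <- spectrum_meta(
      animal_id = row$animal_id, group = row$group, day = row$day,
      site = row$site, replicate = row$replicate,
      sex = if ("sex" %in% names(man)) row$sex else NA_character_,
      age_weeks = if ("age_weeks" %in% names(man)) row$age_weeks else NA_integer_
    )
    sp
  })
  design <- study_design(
    groups = intersect(study_group_levels, unique(man$group)),
    animals_per_group = max(table(unique(man[, c("animal_id", "group")])$group)),
    days = sort(unique(man$day)),
    sites = max(man$site), replicates = max(man$replicate)
  )
  study_dataset(spectra, design = design, manifest = man)
}

#' Per-(group, day) completeness report
#'
#' Compares observed spectrum counts against the counts a complete design
#' implies and lists incomplete cells.
#'
#' @param study A `study_dataset` with a design.
#'
#' @return A tibble with columns `group, day, n_observed, n_expected,
#'   complete`; the reported total (`sum(n_observed)`) equals the number of
#'   spectra.
#' @export
study_completeness <- function(study) {
  stopifnot(inherits(study, "study_dataset"), !is.null(study$design))
  d <- study$design
  expected <- d$animals_per_group * d$sites * d$replicates
  grid <- tidyr::expand_grid(group = d$groups, day = d$days)
  obs <- dplyr::count(study$manifest, .data$group, .data$day,
                      name = "n_observed")
  out <- dplyr::left_join(grid, obs, by = c("group", "day"))
  out$n_observed[is.na(out$n_observed)] <- 0L
  out$n_expected <- expected
  out$complete <- out$n_observed == out$n_expected
  tibble::as_tibble(out)
}

# Group-average columns of an intensity matrix by a key; returns averaged
# matrix plus one representative index per key (for metadata).
average_columns <- function(m, key) {
  idx <- split(seq_along(key), key)
  avg <- vapply(idx, function(j) rowMeans(m[, j, drop = FALSE]),
                numeric(nrow(m)))
  list(m = avg, rep_index = vapply(idx, `[`, integer(1), 1L))
}

#' Average a study's spectra to site or animal level
#'
#' Implements the two-stage averaging scheme: the 4 replicate spectra of a
#' site are averaged first; site averages are then averaged per animal per
#' day (equal weights), making the animal the statistical unit. `level =
#' "animal"` performs both stages.
#'
#' @param study A `study_dataset` whose spectra share one wavelength grid.
#' @param level `"site"` or `"animal"`.
#'
#' @return A new `study_dataset` of averaged spectra.
#' @export
average_study <- function(study, level = c("site", "animal")) {
  level <- match.arg(level)
  stopifnot(inherits(study, "study_dataset"), length(study$spectra) >= 1L)
  w0 <- study$spectra[[1]]$wavelengths
  for (s in study$spectra) {
    if (length(s$wavelengths) != length(w0) || any(s$wavelengths != w0)) {
      stop("averaging requires one shared wavelength grid across the study",
           call. = FALSE)
    }
  }
  m <- vapply(study$spectra, function(s) s$intensities, numeric(length(w0)))
  metas <- lapply(study$spectra, `[[`, "meta")
  keyify <- function(fields) {
    vapply(metas, function(mm) paste(unlist(mm[fields]), collapse = "|"),
           character(1))
  }

  # stage 1: replicate -> site
  s1 <- average_columns(m, keyify(c("animal_id", "day", "site")))
  metas1 <- lapply(seq_along(s1$rep_index), function(j) {
    mm <- metas[[s1$rep_index[j]]]
    mm$replicate <- NA_integer_; mm$aggregated <- "site"; mm
  })
  if (level == "site") {
    spectra <- lapply(seq_len(ncol(s1$m)), function(j)
      spectrum(w0, s1$m[, j], metas1[[j]]))
    return(study_dataset(spectra, design = study$design))
  }

  # stage 2: site -> animal
  key2 <- vapply(metas1, function(mm)
    paste(mm$animal_id, mm$day, sep = "|"), character(1))
  s2 <- average_columns(s1$m, key2)
  spectra <- lapply(seq_len(ncol(s2$m)), function(j) {
    mm <- metas1[[s2$rep_index[j]]]
    mm$site <- NA_integer_; mm$aggregated <- "animal"
    spectrum(w0, s2$m[, j], mm)
  })
  study_dataset(spectra, design = study$design)
}
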