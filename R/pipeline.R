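#' Full-run configuration
#'
#' Bundles every tunable of the analysis: preprocessing parameters, metric
#' band settings, histology reference colors, the statistical contrast and
#' the seed. Round-trips through YAML unchanged via [write_run_config()] /
#' [read_run_config()].
#'
#' @param preprocess A [preprocess_config()].
#' @param target_nm Wavelength of the collagen intensity readout (nm).
#' @param auc_band Length-2 integration band (nm).
#' @param references Named list of [reference_color()] objects.
#' @param contrast Length-2 (test, control) group labels for per-day
#'   contrasts and fold changes.
#' @param seed Integer seed recorded with the run.
#'
#' @return An object of class `run_config`.
#' @export
run_config <- function(preprocess = preprocess_config(),
                       target_nm = 405, auc_band = c(350, 405),
                       references = default_reference_colors(),
                       contrast = c("laser_treated", "unilluminated_control"),
                       seed = 1L) {
  stopifnot(inherits(preprocess, "preprocess_config"),
            length(auc_band) == 2L, auc_band[1] < auc_band[2],
            length(contrast) == 2L)
  structure(list(preprocess = preprocess, target_nm = target_nm,
                 auc_band = as.numeric(auc_band), references = references,
                 contrast = contrast, seed = as.integer(seed)),
            class = "run_config")
}

#' Write a run configuration to YAML
#' @param config A [run_config()].
#' @param path Output YAML file.
#' @return Invisibly, `path`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  plain <- list(
    preprocess = unclass(config$preprocess),
    metrics = list(target_nm = config$target_nm, auc_band = config$auc_band),
    histoquant = lapply(config$references, unclass),
    stats = list(contrast = config$contrast),
    seed = config$seed
  )
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' Read a run configuration from YAML
#' @param path YAML file written by [write_run_config()] (missing keys fall
#'   back to defaults).
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  pp <- y$preprocess %||% list()
  anchors <- pp$baseline_anchors %||% "endpoints"
  if (is.list(anchors)) anchors <- unlist(anchors)
  refs <- if (!is.null(y$histoquant)) {
    lapply(y$histoquant, function(r) {
      reference_color(r$name, r$hue_center, r$hue_tol, r$sat_min,
                      unlist(r$int_range), r$falloff %||% "linear")
    })
  } else default_reference_colors()
  run_config(
    preprocess = preprocess_config(
      smoothing_fraction = pp$smoothing_fraction %||% 0.80,
      baseline_anchors = anchors,
      nadh_window = unlist(pp$nadh_window %||% c(440, 470))
    ),
    target_nm = y$metrics$target_nm %||% 405,
    auc_band = unlist(y$metrics$auc_band %||% c(350, 405)),
    references = refs,
    contrast = unlist(y$stats$contrast %||%
                        c("laser_treated", "unilluminated_control")),
    seed = y$seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Per-animal-per-day metrics table for a study: two-stage averaging,
# preprocessing, then collagen metrics.
spectral_metrics_table <- function(study, config = run_config()) {
  animal_avg <- average_study(study, "animal")
  nspecs <- lapply(animal_avg$spectra, preprocess, config = config$preprocess,
                   warn = FALSE)
  collagen_metrics(nspecs, target_nm = config$target_nm,
                   band = config$auc_band)
}

fold_change_table <- function(summary_tbl, contrast, digits) {
  wide <- tidyr::pivot_wider(summary_tbl[, c("group", "day", "metric", "mean")],
                             names_from = "group", values_from = "mean")
  if (!all(contrast %in% names(wide))) return(tibble::tibble())
  ok <- !is.na(wide[[contrast[1]]]) & !is.na(wide[[contrast[2]]])
  wide <- wide[ok, ]
  tibble::tibble(day = wide$day, metric = wide$metric,
                 fold_change = fold_change(wide[[contrast[1]]],
                                           wide[[contrast[2]]], digits))
}

#' Run the spectral analysis pipeline
#'
#' Two-stage replicate averaging (replicates -> site -> animal), spectral
#' preprocessing, collagen intensity and AUC per animal per day, group/day
#' mean +/- SEM, repeated-measures ANOVA with Bonferroni-adjusted per-day
#' contrasts, and laser-vs-control fold changes. Deterministic given the
#' data and configuration.
#'
#' @param study A `study_dataset`, or a path to a manifest CSV
#'   (see [load_study()]).
#' @param config A [run_config()].
#' @param out_dir If non-`NULL`, write `metrics.csv`, `summary.csv`,
#'   `stats.csv`, `fold_changes.csv` and `run.log` there.
#'
#' @return A list of class `spectral_report`: `metrics`, `summary`,
#'   `stats` (per metric), `fold_changes`, `nadh_flags`, `config`.
#' @export
run_spectral_pipeline <- function(study, config = run_config(),
                                  out_dir = NULL) {
  if (is.character(study)) study <- load_study(study)
  stopifnot(inherits(study, "study_dataset"), inherits(config, "run_config"))
  metrics <- spectral_metrics_table(study, config)
  nadh_flags <- metrics[!metrics$nadh_in_window,
                        c("animal_id", "group", "day")]

  summaries <- dplyr::bind_rows(
    summarize_by_group(metrics, "collagen_intensity"),
    summarize_by_group(metrics, "collagen_auc")
  )
  run_stats <- function(metric) {
    tbl <- metrics[, c("animal_id", "group", "day")]
    tbl$value <- metrics[[metric]]
    tryCatch(rm_anova_bonferroni(tbl, contrast = config$contrast),
             error = function(e) {
               warning("statistics skipped for ", metric, ": ",
                       conditionMessage(e), call. = FALSE)
               NULL
             })
  }
  stats_list <- list(collagen_intensity = run_stats("collagen_intensity"),
                     collagen_auc = run_stats("collagen_auc"))
  folds <- fold_change_table(summaries, config$contrast, digits = 3)

  report <- structure(
    list(metrics = metrics, summary = summaries, stats = stats_list,
         fold_changes = folds, nadh_flags = nadh_flags, config = config),
    class = "spectral_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(metrics, file.path(out_dir, "metrics.csv"))
    readr::write_csv(summaries, file.path(out_dir, "summary.csv"))
    stats_tbl <- dplyr::bind_rows(lapply(names(stats_list), function(mn) {
      if (is.null(stats_list[[mn]])) return(tibble::tibble())
      dplyr::mutate(stats_list[[mn]]$contrasts, metric = mn, .before = 1)
    }))
    readr::write_csv(stats_tbl, file.path(out_dir, "stats.csv"))
    readr::write_csv(folds, file.path(out_dir, "fold_changes.csv"))
    writeLines(c(
      sprintf("collafluor %s", as.character(utils::packageVersion("collafluor"))),
      sprintf("run date (UTC): %s", format(Sys.time(), tz = "UTC")),
      sprintf("spectra: %d; animals x days after averaging: %d",
              length(study$spectra), nrow(metrics)),
      sprintf("smoothing_fraction: %g", config$preprocess$smoothing_fraction),
      sprintf("target_nm: %g; auc_band: [%g, %g]", config$target_nm,
              config$auc_band[1], config$auc_band[2]),
      sprintf("seed: %d", config$seed),
      sprintf("NADH-window warnings: %d", nrow(nadh_flags)),
      if (nrow(nadh_flags)) paste("  flagged:",
        paste(sprintf("%s/day%d", nadh_flags$animal_id, nadh_flags$day),
              collapse = ", ")) else "  flagged: none"
    ), file.path(out_dir, "run.log"))
  }
  report
}

#' Run the histology image analysis pipeline
#'
#' Scores every image with [quantify_collagen()], aggregates the total
#' collagen percentage per animal, summarizes per (group, day) as mean +/-
#' SEM, compares the contrast groups per day with Student's unpaired t-test
#' and reports fold changes (2 decimals). Unreadable images are skipped with
#' a warning.
#'
#' @param images One of: a manifest tibble with columns `animal_id, group,
#'   day` and either `file` (paths) or `image` (list of RGB arrays); a path
#'   to such a manifest CSV (files resolved relative to it); or a directory
#'   of PNG/TIFF images (scores only, no group statistics).
#' @param config A [run_config()].
#' @param out_dir If non-`NULL`, write `histo_scores.csv`,
#'   `histo_summary.csv`, `histo_stats.csv`, `histo_fold_changes.csv`.
#'
#' @return A list of class `histology_report`: `scores` (per image, per
#'   class), `summary`, `stats`, `fold_changes`, `skipped`, `config`.
#' @export
run_histology_pipeline <- function(images, config = run_config(),
                                   out_dir = NULL) {
  base_dir <- "."
  if (is.character(images) && length(images) == 1L) {
    if (dir.exists(images)) {
      files <- list.files(images, pattern = "\\.(png|tif|tiff)$",
                          ignore.case = TRUE)
      if (!length(files)) {
        stop("no PNG/TIFF images found in directory: ", images, call. = FALSE)
      }
      base_dir <- images
      images <- tibble::tibble(animal_id = NA_character_,
                               group = NA_character_, day = NA_integer_,
                               file = files)
    } else {
      base_dir <- dirname(images)
      images <- readr::read_csv(images, show_col_types = FALSE,
                                progress = FALSE)
    }
  }
  stopifnot(is.data.frame(images), nrow(images) >= 1L)
  has_meta <- all(c("animal_id", "group", "day") %in% names(images)) &&
    !all(is.na(images$group))

  skipped <- character(0)
  rows <- lapply(seq_len(nrow(images)), function(j) {
    img <- tryCatch({
      if ("image" %in% names(images)) images$image[[j]]
      else read_image(file.path(base_dir, images$file[j]))
    }, error = function(e) e)
    id <- if ("file" %in% names(images)) images$file[j] else sprintf("image_%03d", j)
    if (inherits(img, "error")) {
      warning("skipping unreadable image ", id, ": ",
              conditionMessage(img), call. = FALSE)
      skipped <<- c(skipped, id)
      return(NULL)
    }
    q <- quantify_collagen(img, config$references)
    out <- q$scores
    out$image <- id
    out$total_collagen_pct <- q$total_collagen_pct
    if (has_meta) {
      out$animal_id <- images$animal_id[j]
      out$group <- images$group[j]
      out$day <- images$day[j]
    }
    out
  })
  scores <- dplyr::bind_rows(rows)
  if (!nrow(scores)) stop("no readable images", call. = FALSE)

  summary_tbl <- stats_res <- folds <- NULL
  if (has_meta) {
    totals <- dplyr::distinct(scores, .data$image, .data$animal_id,
                              .data$group, .data$day, .data$total_collagen_pct)
    tot_metric <- tibble::tibble(animal_id = totals$animal_id,
                                 group = totals$group, day = totals$day,
                                 total_collagen_pct = totals$total_collagen_pct)
    summary_tbl <- summarize_by_group(tot_metric, "total_collagen_pct")
    per_animal <- dplyr::summarise(
      dplyr::group_by(tot_metric, .data$group, .data$day, .data$animal_id),
      value = mean(.data$total_collagen_pct), .groups = "drop")
    stats_res <- dplyr::bind_rows(lapply(sort(unique(per_animal$day)), function(d) {
      a <- per_animal$value[per_animal$group == config$contrast[1] &
                              per_animal$day == d]
      b <- per_animal$value[per_animal$group == config$contrast[2] &
                              per_animal$day == d]
      if (length(a) < 2L || length(b) < 2L) return(tibble::tibble())
      tt <- students_t_unpaired(a, b)
      tibble::tibble(day = d,
                     contrast = paste(config$contrast, collapse = " vs "),
                     statistic = tt$statistic, df = tt$df, p = tt$p_value,
                     label = tt$label)
    }))
    folds <- fold_change_table(summary_tbl, config$contrast, digits = 2)
  }

  report <- structure(
    list(scores = scores, summary = summary_tbl, stats = stats_res,
         fold_changes = folds, skipped = skipped, config = config),
    class = "histology_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(scores, file.path(out_dir, "histo_scores.csv"))
    if (!is.null(summary_tbl)) {
      readr::write_csv(summary_tbl, file.path(out_dir, "histo_summary.csv"))
      readr::write_csv(stats_res, file.path(out_dir, "histo_stats.csv"))
      readr::write_csv(folds, file.path(out_dir, "histo_fold_changes.csv"))
    }
  }
  report
}

#' Joint spectral/histology report
#'
#' Full-joins the two summary tables by (group, day); a cell present in
#' either input stream is never dropped.
#'
#' @param spectral A `spectral_report` (or its `summary` tibble).
#' @param histology A `histology_report` (or its `summary` tibble).
#'
#' @return A tibble with one row per (group, day, metric).
#' @export
joint_report <- function(spectral, histology) {
  s <- if (inherits(spectral, "spectral_report")) spectral$summary else spectral
  h <- if (inherits(histology, "histology_report")) histology$summary else histology
  dplyr::arrange(dplyr::bind_rows(s, h), .data$metric, .data$group, .data$day)
}

#' Time-course plot of a summarized collagen metric
#'
#' Bars with SEM whiskers per group and day, mirroring the conventional
#' presentation of wound-healing collagen time courses.
#'
#' @param summary_tbl A summary tibble (`group, day, n, metric, mean, sem`).
#' @param metric Which metric to plot.
#'
#' @return A ggplot object.
#' @export
plot_collagen_timecourse <- function(summary_tbl,
                                     metric = "collagen_intensity") {
  d <- summary_tbl[summary_tbl$metric == metric, ]
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$day), y = .data$mean,
                                  fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      position = ggplot2::position_dodge(0.8), width = 0.25) +
    ggplot2::labs(x = "day post-wounding", y = metric, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Ordering-recovery evaluation of the simulator + pipeline
#'
#' Repeatedly simulates the default study and checks, per run, whether the
#' recovered group/day mean collagen intensity preserves the preset
#' ordering: laser-treated above un-illuminated control at the specified
#' days.
#'
#' @param n_runs Number of seeded simulation runs.
#' @param seed Base seed; run r uses `seed * 1000 + r`.
#' @param days Days at which the ordering is required.
#' @param design,trajectory,config Passed to [simulate_study()] /
#'   [spectral_metrics_table()].
#'
#' @return A list: `n_runs`, `n_recovered`, logical vector `recovered`.
#' @export
evaluate_ordering_recovery <- function(n_runs = 100, seed = 1,
                                       days = c(5, 10, 30),
                                       design = study_design(),
                                       trajectory = fig4_trajectory(),
                                       config = run_config()) {
  recovered <- vapply(seq_len(n_runs), function(r) {
    st <- simulate_study(design = design, trajectory = trajectory,
                         seed = seed * 1000 + r, config = config$preprocess)
    metrics <- spectral_metrics_table(st, config)
    sm <- summarize_by_group(metrics, "collagen_intensity")
    wide <- tidyr::pivot_wider(sm[sm$day %in% days, c("group", "day", "mean")],
                               names_from = "group", values_from = "mean")
    all(wide$laser_treated > wide$unilluminated_control)
  }, logical(1))
  list(n_runs = n_runs, n_recovered = sum(recovered), recovered = recovered)
}
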