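#' Significance label for a p-value
#'
#' Maps p-values onto the conventional reporting bins with thresholds 0.05,
#' 0.01 and 0.001 (strict `<`, so e.g. p = 0.009 is labelled `P<0.01` and
#' p = 0.01 falls in the `P<0.05` bin).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#'
#' @return Character vector with values `"ns"`, `"P<0.05"`, `"P<0.01"`,
#'   `"P<0.001"`.
#' @export
significance_label <- function(p) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1, na.rm = TRUE))
  out <- rep("ns", length(p))
  out[p < 0.05] <- "P<0.05"
  out[p < 0.01] <- "P<0.01"
  out[p < 0.001] <- "P<0.001"
  out[is.na(p)] <- NA_character_
  out
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)`; never below the raw p-value.
#'
#' @param p Numeric vector of raw p-values.
#' @param m Number of comparisons (here, the number of days tested).
#'
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p, m) {
  stopifnot(m >= 1)
  pmin(1, m * p)
}

#' Student's unpaired two-tailed t-test (pooled variance)
#'
#' Wraps `stats::t.test(var.equal = TRUE)`. Degenerate samples with zero
#' pooled variance are handled by convention: equal means give `t = 0,
#' p = 1`; unequal means give the `p = 0` limit with a warning.
#'
#' @param a,b Numeric samples, each of length >= 2.
#'
#' @return A one-row tibble `statistic, df, p_value, adjusted_p, label`
#'   (`adjusted_p` is `NA` here; filled in by multiplicity procedures).
#' @export
students_t_unpaired <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) >= 2L, length(b) >= 2L)
  n1 <- length(a); n2 <- length(b)
  pooled_var <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  df <- n1 + n2 - 2
  if (pooled_var < .Machine$double.eps) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      stat <- 0; p <- 1
    } else {
      warning("zero pooled variance with unequal means; p = 0 limit",
              call. = FALSE)
      stat <- sign(mean(a) - mean(b)) * Inf; p <- 0
    }
  } else {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    stat <- unname(tt$statistic); p <- tt$p.value
  }
  tibble::tibble(statistic = stat, df = df, p_value = p,
                 adjusted_p = NA_real_, label = significance_label(p))
}

#' Repeated-measures ANOVA with Bonferroni-adjusted per-day contrasts
#'
#' Mixed two-factor ANOVA on per-animal metric values: group is the
#' between-subjects factor, day the repeated within-subjects factor
#' (animal as error stratum, no sphericity correction). Per-day contrasts
#' between two named groups use Student's pooled t-test with a Bonferroni
#' multiplier equal to the number of days tested. Animals not measured at
#' every day are dropped with a warning (complete cases only).
#'
#' @param tbl A data frame with columns `animal_id, group, day, value`
#'   (one value per animal per day).
#' @param contrast Length-2 character vector naming the (test, control)
#'   groups compared at each day.
#'
#' @return A list of class `rm_anova` with elements `anova` (tibble:
#'   effect, df, df_resid, statistic, p) and `contrasts` (tibble: day,
#'   contrast, statistic, df, p, p_adj, label).
#' @export
rm_anova_bonferroni <- function(tbl,
                                contrast = c("laser_treated",
                                             "unilluminated_control")) {
  stopifnot(is.data.frame(tbl),
            all(c("animal_id", "group", "day", "value") %in% names(tbl)),
            length(contrast) == 2L)
  tbl <- tibble::as_tibble(tbl)
  days <- sort(unique(tbl$day))
  groups <- unique(tbl$group)
  if (length(groups) < 2L || length(days) < 2L) {
    stop("rm_anova_bonferroni needs >= 2 groups and >= 2 days", call. = FALSE)
  }
  # complete cases: every animal observed at every day
  counts <- dplyr::count(tbl, .data$animal_id)
  incomplete <- counts$animal_id[counts$n < length(days)]
  if (length(incomplete)) {
    warning("dropping ", length(incomplete),
            " animal(s) not measured at every day: ",
            paste(incomplete, collapse = ", "), call. = FALSE)
    tbl <- tbl[!tbl$animal_id %in% incomplete, ]
  }
  n_per_group <- dplyr::summarise(
    dplyr::group_by(tbl, .data$group),
    n = dplyr::n_distinct(.data$animal_id), .groups = "drop")
  if (any(n_per_group$n < 2L)) {
    stop("each group needs at least 2 complete animals", call. = FALSE)
  }

  if (var(tbl$value) < .Machine$double.eps) {
    # degenerate data (no variation at all): F := 0, p := 1 by convention
    anova_tbl <- tibble::tibble(
      effect = c("group", "day", "group:day"),
      df = NA_real_, df_resid = NA_real_, statistic = 0, p = 1)
  } else {
    df <- data.frame(
      value = tbl$value,
      group = factor(tbl$group),
      day = factor(tbl$day),
      animal_id = factor(tbl$animal_id)
    )
    fit <- aov(value ~ group * day + Error(animal_id), data = df)
    sfit <- summary(fit)
    pull_effects <- function(stratum) {
      tab <- sfit[[stratum]][[1]]
      rn <- trimws(rownames(tab))
      keep <- rn != "Residuals"
      resid_df <- tab[rn == "Residuals", "Df"]
      tibble::tibble(effect = rn[keep], df = tab[keep, "Df"],
                     df_resid = resid_df,
                     statistic = tab[keep, "F value"],
                     p = tab[keep, "Pr(>F)"])
    }
    anova_tbl <- dplyr::bind_rows(pull_effects("Error: animal_id"),
                                  pull_effects("Error: Within"))
    # zero residual variance in a stratum -> F := 0, p := 1
    bad <- !is.finite(anova_tbl$statistic)
    anova_tbl$statistic[bad] <- 0
    anova_tbl$p[bad] <- 1
  }

  m <- length(days)
  contrasts <- dplyr::bind_rows(lapply(days, function(d) {
    a <- tbl$value[tbl$group == contrast[1] & tbl$day == d]
    b <- tbl$value[tbl$group == contrast[2] & tbl$day == d]
    tt <- students_t_unpaired(a, b)
    tibble::tibble(day = d,
                   contrast = paste(contrast[1], "vs", contrast[2]),
                   statistic = tt$statistic, df = tt$df, p = tt$p_value,
                   p_adj = bonferroni_adjust(tt$p_value, m),
                   label = significance_label(bonferroni_adjust(tt$p_value, m)))
  }))
  structure(list(anova = anova_tbl, contrasts = contrasts,
                 n_days = m, contrast = contrast),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("<rm_anova> group (between) x day (within), Bonferroni m =",
      x$n_days, "\n")
  print(x$anova)
  cat("per-day contrasts (", paste(x$contrast, collapse = " vs "), "):\n",
      sep = "")
  print(x$contrasts)
  invisible(x)
}
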