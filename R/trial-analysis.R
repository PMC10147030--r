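#' Long-format field-trial dataset
#'
#' Validates a long-format table of plant heights from a completely
#' randomized fertilization trial. Required columns: `species`, `accession`,
#' `treatment` (control / conventional / organic, or any factor with >= 2
#' levels), `replicate` (positive integer within treatment),
#' `months_after_planting` (non-negative, planting at month 0) and
#' `height_cm` (non-negative). Optional logical column `fruiting`.
#'
#' @param records data.frame with the columns above.
#' @return the validated data.frame with class `trial_dataset` prepended.
#' @export
trial_dataset <- function(records) {
  needed <- c("species", "accession", "treatment", "replicate",
              "months_after_planting", "height_cm")
  if (!is.data.frame(records))
    validation_error("records must be a data.frame")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0)
    validation_error(sprintf("trial dataset missing column(s): %s",
                             paste(missing, collapse = ", ")))
  records$species <- trimws(as.character(records$species))
  records$accession <- trimws(as.character(records$accession))
  records$treatment <- as.character(records$treatment)
  if (any(is.na(records$replicate)) || any(records$replicate < 1) ||
      any(records$replicate != floor(records$replicate)))
    validation_error("replicate must be a positive integer")
  records$replicate <- as.integer(records$replicate)
  if (any(is.na(records$months_after_planting)) ||
      any(records$months_after_planting < 0))
    validation_error("months_after_planting must be non-negative")
  if (any(is.na(records$height_cm)) || any(records$height_cm < 0))
    validation_error("height_cm must be non-negative")
  if (!"fruiting" %in% names(records)) {
    records$fruiting <- NA
  }
  records$fruiting <- as.logical(records$fruiting)
  key <- paste(records$accession, records$treatment, records$replicate,
               records$months_after_planting, sep = "\r")
  if (anyDuplicated(key))
    validation_error("duplicate (accession, treatment, replicate, month) records")
  class(records) <- unique(c("trial_dataset", class(records)))
  records
}

#' Growing season of a measurement month
#'
#' Planting happens at month 0 at the start of a growing season; season 1
#' covers months (0, 12], season 2 months (12, 24], and so on. Month 0
#' itself belongs to season 1.
#'
#' @param months_after_planting numeric vector of months.
#' @return integer vector of season indices (>= 1).
#' @export
growing_season <- function(months_after_planting) {
  pmax(1L, as.integer(ceiling(months_after_planting / 12)))
}

#' Juvenile growth rate
#'
#' Percent increase in tree height between the 6- and 18-month measurements:
#' `100 * (height_18m - height_6m) / height_6m`. Negative results (shrinkage)
#' are allowed and keep their sign.
#'
#' @param height_6m height at 6 months after planting (cm), strictly positive.
#' @param height_18m height at 18 months after planting (cm), non-negative.
#' @return growth rate in percent.
#' @export
#' @examples
#' growth_rate(100, 120)  # 20
growth_rate <- function(height_6m, height_18m) {
  if (!is.numeric(height_6m) || !is.numeric(height_18m))
    type_error("heights must be numeric")
  if (any(is.na(height_6m)) || any(height_6m <= 0))
    validation_error("height at 6 months must be strictly positive")
  if (any(is.na(height_18m)) || any(height_18m < 0))
    validation_error("height at 18 months must be non-negative")
  100 * (height_18m - height_6m) / height_6m
}

subset_date <- function(dataset, accession, months_after_planting,
                        tol = 1e-8) {
  stopifnot(inherits(dataset, "trial_dataset"))
  sub <- dataset[dataset$accession == trimws(accession) &
                 abs(dataset$months_after_planting - months_after_planting) < tol, ,
                 drop = FALSE]
  if (nrow(sub) == 0L)
    validation_error(sprintf("no records for accession %s at month %g",
                             accession, months_after_planting))
  n_per <- table(sub$treatment)
  if (length(n_per) < 2L || any(n_per < 2L))
    validation_error(sprintf(
      "accession %s month %g: need >= 2 treatments with >= 2 replicates each",
      accession, months_after_planting))
  sub$treatment <- factor(sub$treatment)
  sub
}

new_anova_result <- function(factor, df_between, df_within, ss_between,
                             ss_within, F, p_value, alpha, degenerate = FALSE) {
  structure(
    list(factor = factor, df_between = as.integer(df_between),
         df_within = as.integer(df_within), ss_between = ss_between,
         ss_within = ss_within, F = F, p_value = p_value, alpha = alpha,
         degenerate = degenerate),
    class = "anova_result"
  )
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> %s: F(%d, %d) = %s, p = %s%s\n",
              x$factor, x$df_between, x$df_within,
              format(x$F, digits = 4), format(x$p_value, digits = 4),
              if (x$degenerate) " [degenerate: zero within-group variance]" else ""))
  invisible(x)
}

# aov-based one-way fit shared by oneway_anova() and tukey_hsd()
fit_oneway <- function(sub) {
  fit <- stats::aov(height_cm ~ treatment, data = sub)
  tab <- summary(fit)[[1]]
  ssb <- tab["treatment", "Sum Sq"]
  ssw <- tab["Residuals", "Sum Sq"]
  sst <- ssb + ssw
  degenerate <- ssw <= 1e-12 * max(sst, 1)
  list(fit = fit, tab = tab, ssb = ssb, ssw = ssw, degenerate = degenerate)
}

#' Per-date one-way ANOVA of height across fertilization treatments
#'
#' Classical completely-randomized one-way decomposition of `height_cm` by
#' `treatment` for one accession at one measurement date, as run discretely
#' per genotype and date in the trial analysis. A date where all within-group
#' variance is zero yields a flagged degenerate result (F and p are `NA`)
#' rather than an error.
#'
#' @param dataset a [trial_dataset()].
#' @param accession accession to analyse.
#' @param months_after_planting measurement date (months after planting).
#' @param alpha significance level carried into the result (default 0.05).
#' @return an `anova_result`.
#' @export
oneway_anova <- function(dataset, accession, months_after_planting,
                         alpha = 0.05) {
  sub <- subset_date(dataset, accession, months_after_planting)
  fo <- fit_oneway(sub)
  dfb <- fo$tab["treatment", "Df"]
  dfw <- fo$tab["Residuals", "Df"]
  if (fo$degenerate)
    return(new_anova_result("treatment", dfb, dfw, fo$ssb, fo$ssw,
                            NA_real_, NA_real_, alpha, degenerate = TRUE))
  new_anova_result("treatment", dfb, dfw, fo$ssb, fo$ssw,
                   fo$tab["treatment", "F value"],
                   fo$tab["treatment", "Pr(>F)"], alpha)
}

#' Tukey HSD pairwise treatment comparison at one date
#'
#' Tukey's honestly-significant-difference test on the one-way fit of
#' [oneway_anova()], using the Tukey-Kramer standard error when replicate
#' counts differ (plant death). Significance of each unordered treatment
#' pair is judged at `alpha` on the studentized-range adjusted p-value.
#'
#' @inheritParams oneway_anova
#' @return object of class `tukey_result`: data.frame `pairs` with columns
#'   `treatment_a`, `treatment_b`, `mean_diff` (mean(a) - mean(b), cm),
#'   `adj_p`, `significant`, plus `alpha` and `degenerate` attributes-like
#'   fields.
#' @export
tukey_hsd <- function(dataset, accession, months_after_planting,
                      alpha = 0.05) {
  sub <- subset_date(dataset, accession, months_after_planting)
  fo <- fit_oneway(sub)
  lev <- levels(sub$treatment)
  k <- length(lev)
  # pair ordering of stats::TukeyHSD: lower triangle, column-major
  ia <- unlist(lapply(seq_len(k - 1), function(j) (j + 1):k))
  ib <- rep(seq_len(k - 1), times = (k - 1):1)
  means <- tapply(sub$height_cm, sub$treatment, mean)
  if (fo$degenerate) {
    pairs <- data.frame(
      treatment_a = lev[ia], treatment_b = lev[ib],
      mean_diff = as.numeric(means[ia] - means[ib]),
      adj_p = NA_real_, significant = NA, stringsAsFactors = FALSE)
  } else {
    th <- stats::TukeyHSD(fo$fit, "treatment", conf.level = 1 - alpha)$treatment
    pairs <- data.frame(
      treatment_a = lev[ia], treatment_b = lev[ib],
      mean_diff = unname(th[, "diff"]),
      adj_p = unname(th[, "p adj"]),
      significant = unname(th[, "p adj"] < alpha),
      stringsAsFactors = FALSE)
  }
  structure(list(pairs = pairs, alpha = alpha, degenerate = fo$degenerate,
                 accession = trimws(accession),
                 months_after_planting = months_after_planting),
            class = "tukey_result")
}

#' @export
print.tukey_result <- function(x, ...) {
  cat(sprintf("<tukey_result> %s at month %g (alpha = %g)%s\n",
              x$accession, x$months_after_planting, x$alpha,
              if (x$degenerate) " [degenerate]" else ""))
  print(x$pairs)
  invisible(x)
}

#' Mixed-design repeated-measures ANOVA for one accession and season
#'
#' Univariate mixed-design decomposition of height over one growing season:
#' between-subjects factor = fertilization treatment, within-subjects factor
#' = measurement time, subject = replicate plant nested in treatment. No
#' sphericity correction is applied. The replicate-by-time grid must be
#' complete; with `incomplete = "exclude"` replicates missing any timepoint
#' are dropped listwise, with the default `"error"` an informative error is
#' raised instead.
#'
#' @param dataset a [trial_dataset()].
#' @param accession accession to analyse.
#' @param season growing season index (see [growing_season()]).
#' @param alpha significance level (default 0.05).
#' @param incomplete `"error"` (default) or `"exclude"`.
#' @return list of class `rm_anova_result` with `anova_result` components
#'   `treatment` (between-subjects), `time` (within-subjects) and
#'   `interaction`.
#' @export
repeated_measures_anova <- function(dataset, accession, season,
                                    alpha = 0.05,
                                    incomplete = c("error", "exclude")) {
  incomplete <- match.arg(incomplete)
  stopifnot(inherits(dataset, "trial_dataset"))
  sub <- dataset[dataset$accession == trimws(accession) &
                 growing_season(dataset$months_after_planting) == season, ,
                 drop = FALSE]
  if (nrow(sub) == 0L)
    validation_error(sprintf("no records for accession %s in season %d",
                             accession, season))
  times <- sort(unique(sub$months_after_planting))
  if (length(times) < 2L)
    validation_error("repeated-measures analysis needs >= 2 timepoints in the season")
  sub$subject <- paste(sub$treatment, sub$replicate, sep = ":")
  counts <- table(sub$subject)
  complete <- names(counts)[counts == length(times)]
  if (length(complete) < length(counts)) {
    bad <- setdiff(names(counts), complete)
    if (incomplete == "error")
      validation_error(sprintf(
        paste("unbalanced replicate-by-time grid for accession %s season %d:",
              "replicate(s) %s lack some timepoints; re-run with",
              'incomplete = "exclude" to drop them listwise'),
        accession, season, paste(bad, collapse = ", ")))
    sub <- sub[sub$subject %in% complete, , drop = FALSE]
  }
  n_per <- table(unique(sub[c("subject", "treatment")])$treatment)
  if (length(n_per) < 2L || any(n_per < 2L))
    validation_error("need >= 2 treatments with >= 2 complete replicates each")

  sub$treatment <- factor(sub$treatment)
  sub$time_f <- factor(sub$months_after_planting)
  sub$subject <- factor(sub$subject)
  fit <- stats::aov(height_cm ~ treatment * time_f + Error(subject / time_f),
                    data = sub)
  sm <- summary(fit)
  between <- sm[["Error: subject"]][[1]]
  within <- sm[["Error: subject:time_f"]][[1]]
  grab <- function(tab, row, label) {
    rn <- trimws(rownames(tab))
    i <- match(row, rn); r <- match("Residuals", rn)
    new_anova_result(label, tab[i, "Df"], tab[r, "Df"],
                     tab[i, "Sum Sq"], tab[r, "Sum Sq"],
                     tab[i, "F value"], tab[i, "Pr(>F)"], alpha)
  }
  structure(
    list(treatment = grab(between, "treatment", "treatment"),
         time = grab(within, "time_f", "time"),
         interaction = grab(within, "treatment:time_f", "treatment:time"),
         accession = trimws(accession), season = season, alpha = alpha,
         n_subjects = sum(n_per), timepoints = times),
    class = "rm_anova_result"
  )
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat(sprintf("<rm_anova_result> %s, season %d (%d subjects, %d timepoints)\n",
              x$accession, x$season, x$n_subjects, length(x$timepoints)))
  print(x$treatment); print(x$time); print(x$interaction)
  invisible(x)
}

match_month <- function(months, target, tol = 1) {
  cand <- months[abs(months - target) <= tol]
  if (length(cand) == 0L) return(NA_real_)
  cand[order(abs(cand - target), cand)][1]
}

#' Growth summaries per accession and treatment
#'
#' For each accession-by-treatment cell: the mean height across replicates
#' at (or nearest within +/- `tolerance_months` of) 6 and 18 months after
#' planting, the juvenile growth rate computed on those treatment-level
#' means, and the first growing season with observed fruiting. The months
#' actually matched are reported (`matched_month_6`, `matched_month_18`);
#' a missing timepoint yields `NA` for that cell. Also returns, per
#' accession, the best treatment by 18-month height (ties broken
#' alphabetically).
#'
#' @param dataset a [trial_dataset()].
#' @param tolerance_months maximal distance for nearest-date matching
#'   (default 1 month).
#' @return list with data.frames `summaries` (one row per accession x
#'   treatment) and `best_treatment` (one row per accession).
#' @export
summarize_trial <- function(dataset, tolerance_months = 1) {
  stopifnot(inherits(dataset, "trial_dataset"))
  cells <- unique(dataset[c("species", "accession", "treatment")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- dataset[dataset$accession == cells$accession[i] &
                    dataset$treatment == cells$treatment[i], , drop = FALSE]
    months <- sort(unique(cell$months_after_planting))
    m6 <- match_month(months, 6, tolerance_months)
    m18 <- match_month(months, 18, tolerance_months)
    mh <- function(m) if (is.na(m)) NA_real_ else
      mean(cell$height_cm[cell$months_after_planting == m])
    h6 <- mh(m6); h18 <- mh(m18)
    gr <- if (!is.na(h6) && h6 > 0 && !is.na(h18)) growth_rate(h6, h18) else NA_real_
    fr <- cell$fruiting %in% TRUE
    onset <- if (any(fr)) min(growing_season(cell$months_after_planting[fr]))
             else NA_integer_
    data.frame(species = cells$species[i], accession = cells$accession[i],
               treatment = cells$treatment[i],
               matched_month_6 = m6, height_6m_cm = h6,
               matched_month_18 = m18, height_18m_cm = h18,
               growth_rate_pct = gr, fruit_onset_season = onset,
               stringsAsFactors = FALSE)
  })
  summaries <- do.call(rbind, rows)
  best <- do.call(rbind, lapply(split(summaries, summaries$accession), function(d) {
    d <- d[order(ifelse(is.na(d$height_18m_cm), Inf, -d$height_18m_cm),
                 d$treatment), , drop = FALSE]
    d[1, , drop = FALSE]
  }))
  rownames(best) <- NULL
  rownames(summaries) <- NULL
  list(summaries = summaries, best_treatment = best)
}

#' Rubric inputs extracted from a trial
#'
#' Reduces growth summaries to the per-genotype quantities the
#' multifaceted rubric consumes: 18-month height (best treatment, converted
#' cm to m), juvenile growth rate (best across treatments), and earliest
#' fruit-onset season across treatments. "Best" reflects the attainable
#' cultivation potential of the genotype under the most favourable tested
#' regime.
#'
#' @param dataset a [trial_dataset()].
#' @param tolerance_months passed to [summarize_trial()].
#' @return data.frame with columns `species`, `accession`, `height_18m_m`,
#'   `growth_rate_pct`, `fruit_onset_season`.
#' @export
rubric_inputs_from_trial <- function(dataset, tolerance_months = 1) {
  s <- summarize_trial(dataset, tolerance_months)$summaries
  max_or_na <- function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  min_or_na <- function(v) if (all(is.na(v))) NA_integer_ else
    as.integer(min(v, na.rm = TRUE))
  out <- do.call(rbind, lapply(split(s, s$accession), function(d) {
    data.frame(species = d$species[1], accession = d$accession[1],
               height_18m_m = max_or_na(d$height_18m_cm) / 100,
               growth_rate_pct = max_or_na(d$growth_rate_pct),
               fruit_onset_season = min_or_na(d$fruit_onset_season),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
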