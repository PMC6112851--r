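## Period grouping, relative changes, learning trajectories, imitation
## scoring and the cohort-level statistics.

PERIOD_LEVELS <- c("pre", "post_1_2", "post_3_4", "post_5_6",
                   "crystallization")

#' Assign experimental periods to feature rows
#'
#' Groups recording days into two-day periods relative to the surgery day:
#' `pre` (the two days before surgery), `post_1_2`, `post_3_4`,
#' `post_5_6` (offsets 1-6 after surgery), and `crystallization` (days
#' 90-91 post hatch). Other days are left unlabeled (`NA`). Birds without
#' pre-period data are flagged in the `flagged_birds` attribute.
#'
#' @param features Feature table with `bird`, `day_dph` columns (e.g. from
#'   [generate_cohort()] or a segment-table import).
#' @param surgery_day Surgery day (dph); either a single value or a named
#'   vector/data frame mapping birds to days. Defaults to a `surgery_dph`
#'   column in `features` if present.
#' @return `features` with a `period` factor column added.
#' @export
assign_periods <- function(features, surgery_day = NULL) {
  abort_if(!all(c("bird", "day_dph") %in% names(features)),
           "`features` needs `bird` and `day_dph` columns")
  if (is.null(surgery_day)) {
    abort_if(!"surgery_dph" %in% names(features),
             "`surgery_day` missing and no `surgery_dph` column present")
    sday <- features$surgery_dph
  } else if (length(surgery_day) == 1L && is.null(names(surgery_day))) {
    sday <- rep(surgery_day, nrow(features))
  } else {
    sday <- unname(surgery_day[as.character(features$bird)])
    abort_if(anyNA(sday), "surgery day unknown for some birds")
  }
  off <- features$day_dph - sday
  period <- rep(NA_character_, nrow(features))
  period[off %in% c(-2L, -1L)] <- "pre"
  period[off %in% 1:2] <- "post_1_2"
  period[off %in% 3:4] <- "post_3_4"
  period[off %in% 5:6] <- "post_5_6"
  period[features$day_dph %in% c(90L, 91L)] <- "crystallization"
  features$period <- factor(period, levels = PERIOD_LEVELS)
  by_bird <- tapply(period == "pre", features$bird,
                    function(z) any(z, na.rm = TRUE))
  flagged <- names(by_bird)[!by_bird]
  if (length(flagged))
    warning("no pre-period data for bird(s): ",
            paste(flagged, collapse = ", "), call. = FALSE)
  attr(features, "flagged_birds") <- flagged
  features
}

#' Per-period feature summaries
#'
#' Mean, SD, coefficient of variation and rendition count of a feature for
#' every bird x syllable x period cell.
#'
#' @param features Output of [assign_periods()].
#' @param value Feature column to summarize (default `"duration_ms"`).
#' @return Data frame `bird`, `group` (if present), `syllable`, `period`,
#'   `mean`, `sd`, `cv`, `n`.
#' @export
period_summary <- function(features, value = "duration_ms") {
  abort_if(!"period" %in% names(features),
           "run assign_periods() first")
  abort_if(!value %in% names(features), "no column `", value, "`")
  keep <- !is.na(features$period) & !is.na(features[[value]])
  f <- features[keep, , drop = FALSE]
  key <- interaction(f$bird, f$syllable, f$period, drop = TRUE)
  v <- f[[value]]
  n <- as.vector(rowsum(rep(1, length(v)), key))
  s1 <- as.vector(rowsum(v, key))
  s2 <- as.vector(rowsum(v^2, key))
  mu <- s1 / n
  va <- pmax((s2 - n * mu^2) / pmax(n - 1, 1), 0)
  sdv <- ifelse(n > 1, sqrt(va), NA_real_)
  parts <- do.call(rbind, strsplit(levels(key), ".", fixed = TRUE))
  out <- data.frame(bird = parts[, 1],
                    syllable = utils::type.convert(parts[, 2],
                                                   as.is = TRUE),
                    period = factor(parts[, 3], levels = PERIOD_LEVELS),
                    mean = mu, sd = sdv, cv = sdv / mu, n = n)
  if ("group" %in% names(f)) {
    grp <- tapply(as.character(f$group), key, `[`, 1L)
    out$group <- unname(grp[levels(key)])
  }
  out[order(out$bird, out$syllable, out$period), , drop = FALSE]
}

#' Relative change of a feature versus the pre period
#'
#' Absolute percent change of the period mean relative to the pre-surgery
#' mean: `100 * |post_mean / pre_mean - 1|`. The signed raw ratio is also
#' returned for audit.
#'
#' @param summary Output of [period_summary()].
#' @return Data frame with one row per bird x syllable x non-pre period:
#'   `bird`, `group` (if present), `syllable`, `period`, `ratio`
#'   (post/pre), `rel_change_pct`.
#' @export
relative_change <- function(summary) {
  pre <- summary[summary$period == "pre", , drop = FALSE]
  abort_if(nrow(pre) == 0L, "no pre-period rows in summary")
  abort_if(any(pre$mean == 0), "pre-period mean of zero")
  key <- function(d) paste(d$bird, d$syllable)
  pre_mean <- setNames(pre$mean, key(pre))
  post <- summary[summary$period != "pre" & !is.na(summary$period), ,
                  drop = FALSE]
  base <- unname(pre_mean[key(post)])
  abort_if(anyNA(base), "missing pre baseline for some bird/syllable")
  post$ratio <- post$mean / base
  post$rel_change_pct <- 100 * abs(post$ratio - 1)
  keep <- c("bird", if ("group" %in% names(post)) "group", "syllable",
            "period", "ratio", "rel_change_pct")
  rownames(post) <- NULL
  post[, keep, drop = FALSE]
}

#' Coefficient of variation
#'
#' Sample SD divided by the mean; scale-invariant rendition-to-rendition
#' variability measure.
#'
#' @param values Numeric vector (`n >= 2`, positive mean).
#' @return CV as a fraction.
#' @export
coefficient_of_variation <- function(values) {
  values <- values[!is.na(values)]
  abort_if(length(values) < 2L, "need at least two values")
  m <- mean(values)
  abort_if(m <= 0, "mean must be positive")
  sd(values) / m
}

#' Learning trajectory of a feature
#'
#' Signed difference, in percent points, between the relative change at
#' crystallization and the relative change at post days 5-6, both taken
#' against the same pre-surgery baseline. Positive values indicate
#' continued learning-related change after the acute post-surgery period.
#'
#' @param rel_changes Output of [relative_change()] containing both the
#'   `post_5_6` and `crystallization` periods.
#' @return Data frame `bird`, `group` (if present), `syllable`,
#'   `trajectory_pct`.
#' @export
learning_trajectory <- function(rel_changes) {
  cr <- rel_changes[rel_changes$period == "crystallization", ,
                    drop = FALSE]
  p56 <- rel_changes[rel_changes$period == "post_5_6", , drop = FALSE]
  abort_if(nrow(cr) == 0L || nrow(p56) == 0L,
           "need both crystallization and post_5_6 relative changes")
  key <- function(d) paste(d$bird, d$syllable)
  p56_val <- setNames(p56$rel_change_pct, key(p56))
  base <- unname(p56_val[key(cr)])
  abort_if(anyNA(base), "post_5_6 missing for some bird/syllable")
  out <- data.frame(bird = cr$bird, syllable = cr$syllable,
                    trajectory_pct = cr$rel_change_pct - base)
  if ("group" %in% names(cr)) out$group <- cr$group
  rownames(out) <- NULL
  out
}

#' Spectrogram cross-correlation similarity score
#'
#' Similarity between each pupil song and a tutor template as the peak,
#' over time lag, of the normalized cross-correlation between their
#' log-magnitude spectrograms (per-frame mean removed, hence invariant to
#' global gain). When more songs are supplied than `n_sample`, a seeded
#' random subset (by default 50-100 clean bouts are scored in practice) is
#' drawn.
#'
#' @param songs A list of [audio_recording()] objects (pupil song bouts).
#' @param template An [audio_recording()] or [motif_template()] of the
#'   tutor motif.
#' @param n_sample Optional number of songs to sample.
#' @param seed Seed for the sampling.
#' @return A list: `scores` (per scored song) and `mean_score`.
#' @export
spectrogram_similarity_score <- function(songs, template, n_sample = NULL,
                                         seed = NULL) {
  if (inherits(songs, "audio_recording")) songs <- list(songs)
  tmpl_audio <- if (inherits(template, "motif_template")) template$audio
    else template
  abort_if(!inherits(tmpl_audio, "audio_recording"),
           "`template` must be an audio_recording or motif_template")
  rates <- vapply(songs, `[[`, numeric(1), "sample_rate")
  abort_if(any(rates != tmpl_audio$sample_rate),
           "songs and template must share a sample rate")
  if (!is.null(n_sample) && length(songs) > n_sample) {
    songs <- with_seed(seed,
                       songs[sample.int(length(songs), n_sample)])
  }
  Tm <- log_spec_matrix(compute_spectrogram(tmpl_audio))
  scores <- vapply(songs, function(s) {
    abort_if(length(s$samples) < length(tmpl_audio$samples) / 2,
             "song much shorter than the template")
    Sm <- log_spec_matrix(compute_spectrogram(s))
    spec_xcorr_peak(Sm, Tm, max_lag = NULL, min_overlap = 0.9)$peak
  }, numeric(1))
  list(scores = scores, mean_score = mean(scores))
}

#' Normalized imitation score
#'
#' Imitation score at crystallization divided by the score before surgery;
#' values above 1 indicate improvement. Any external imitation scorer can
#' supply the two inputs (the package's own
#' [spectrogram_similarity_score()] is one choice).
#'
#' @param score_pre Pre-surgery imitation score (> 0).
#' @param score_cryst Imitation score at crystallization.
#' @return The ratio.
#' @export
normalized_imitation <- function(score_pre, score_cryst) {
  abort_if(any(score_pre <= 0), "`score_pre` must be > 0")
  score_cryst / score_pre
}

#' Lesion size vs imitation improvement correlation
#'
#' Pearson correlation between the proportion of the lateral DCN left
#' intact and the normalized imitation score, with the p-value for the
#' null hypothesis of no correlation.
#'
#' @param records Data frame with `pct_intact` and `normalized_score`
#'   columns (see [generate_cohort()]), at least 3 rows with variance in
#'   both variables.
#' @return A one-row data frame: `test`, `estimate` (r), `statistic`,
#'   `p_value`, `n`.
#' @export
lesion_size_correlation <- function(records) {
  abort_if(!all(c("pct_intact", "normalized_score") %in% names(records)),
           "`records` needs pct_intact and normalized_score columns")
  x <- records$pct_intact
  y <- records$normalized_score
  abort_if(length(x) < 3L, "need at least 3 records")
  abort_if(sd(x) == 0 || sd(y) == 0, "zero variance in inputs")
  ct <- cor.test(x, y, method = "pearson")
  data.frame(test = "pearson_correlation",
             estimate = unname(ct$estimate),
             statistic = unname(ct$statistic),
             p_value = ct$p.value, n = length(x))
}
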