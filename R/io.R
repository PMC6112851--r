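## CSV interchange formats: spike tables, stimulation tables, feature and
## cohort tables. Comma-separated, UTF-8, mandatory header row, times in
## seconds written with full precision.

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  abort_if(length(missing) > 0L,
           what, " is missing column(s): ",
           paste(missing, collapse = ", "))
  invisible(df)
}

check_numeric <- function(df, cols, what) {
  for (cl in cols) {
    abort_if(!is.numeric(df[[cl]]),
             what, " column `", cl, "` must be numeric")
  }
  invisible(df)
}

#' Read a spike-time CSV
#'
#' Expected columns: `unit_id`, `time_s`. Times must be non-negative;
#' unsorted times are sorted with a warning.
#'
#' @param path CSV path.
#' @return A named list of [spike_train()] objects, one per unit.
#' @export
read_spike_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("unit_id", "time_s"), "spike CSV")
  check_numeric(df, "time_s", "spike CSV")
  abort_if(any(df$time_s < 0), "spike CSV contains negative times")
  sp <- split(df$time_s, df$unit_id)
  Map(function(t, id) spike_train(t, unit_id = id), sp, names(sp))
}

#' Write spike trains to CSV
#'
#' @param trains A [spike_train()] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spike_csv <- function(trains, path) {
  if (inherits(trains, "spike_train")) trains <- list(trains)
  df <- do.call(rbind, lapply(trains, function(tr)
    data.frame(unit_id = tr$unit_id, time_s = tr$times_s)))
  write.csv(format(df, digits = 15, scientific = FALSE), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a stimulation-event CSV
#'
#' Expected columns: `onset_s`, `pulse_ms`, `intensity_ma`, `condition`.
#' One protocol per condition label is returned.
#'
#' @param path CSV path.
#' @return A named list of [stim_protocol()] objects, one per condition.
#' @export
read_stim_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("onset_s", "pulse_ms", "intensity_ma", "condition"),
                "stimulation CSV")
  check_numeric(df, c("onset_s", "pulse_ms"), "stimulation CSV")
  abort_if(any(df$onset_s < 0), "stimulation CSV contains negative times")
  lapply(split(df, df$condition), function(g) {
    if (is.unsorted(g$onset_s, strictly = TRUE)) {
      warning("stimulation onsets were unsorted; sorting", call. = FALSE)
      g <- g[order(g$onset_s), , drop = FALSE]
    }
    stim_protocol(g$onset_s, pulse_ms = g$pulse_ms[1L],
                  intensity_ma = g$intensity_ma[1L],
                  condition = g$condition[1L])
  })
}

#' Write stimulation protocols to CSV
#'
#' @param protocols A [stim_protocol()] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stim_csv <- function(protocols, path) {
  if (inherits(protocols, "stim_protocol")) protocols <- list(protocols)
  df <- do.call(rbind, lapply(protocols, function(p)
    data.frame(onset_s = p$onsets_s, pulse_ms = p$pulse_ms,
               intensity_ma = p$intensity_ma, condition = p$condition)))
  write.csv(format(df, digits = 15, scientific = FALSE), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a syllable feature table
#'
#' Expected columns: `bird`, `day_dph`, `rendition`, `syllable`,
#' `duration_ms`, `rel_amplitude`, `f0_hz` (optionally `group`, `kind`).
#'
#' @param path CSV path.
#' @return A validated data frame.
#' @export
read_features_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("bird", "day_dph", "rendition", "syllable",
                      "duration_ms", "rel_amplitude", "f0_hz"),
                "feature CSV")
  check_numeric(df, c("day_dph", "duration_ms"), "feature CSV")
  df
}

#' Write a feature (or any result) table to CSV
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort metadata CSV
#'
#' Expected columns: `bird`, `group`, `surgery_dph`, `pct_intact`.
#'
#' @param path CSV path.
#' @return A validated data frame.
#' @export
read_cohort_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("bird", "group", "surgery_dph", "pct_intact"),
                "cohort CSV")
  check_numeric(df, c("surgery_dph", "pct_intact"), "cohort CSV")
  abort_if(!all(df$group %in% c("lesion", "sham")),
           "cohort CSV `group` must be lesion or sham")
  df
}
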