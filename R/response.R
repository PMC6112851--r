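## Detection, timing, sizing and classification of evoked responses in a
## PSTH, and pharmacology comparisons between conditions.

#' Detect evoked response events in a PSTH
#'
#' A response starts at the first of at least `min_consecutive` consecutive
#' bins whose rate lies strictly above (excitation) or below (inhibition)
#' the baseline mean +/- `k` baseline SD, and ends on the return of two
#' consecutive bins inside that confidence band. A run of
#' `min_consecutive` bins beyond the opposite threshold likewise terminates
#' the current event and opens a new one of the opposite polarity, so that
#' adjacent response phases (e.g. excitation running directly into
#' inhibition) are resolved as separate events; isolated single bins of
#' either polarity never start or split an event. Bins whose start lies
#' within `artifact_blank_ms` after the stimulation onset are excluded
#' from detection (stimulation-artifact blanking).
#'
#' When the baseline SD is zero while spikes are present, the threshold
#' falls back to the Poisson standard error of the baseline rate estimate,
#' `sqrt(mean / (n_trials * bin_s))`, and the result is flagged degenerate.
#'
#' @param psth A [compute_psth()] result.
#' @param k Threshold in baseline SD units (default 2.5).
#' @param min_consecutive Minimum consecutive supra-threshold bins
#'   (default 2).
#' @param artifact_blank_ms Post-onset blanking period, ms (default 2).
#' @param search_window_ms Length-2 post-stimulus search window, ms;
#'   defaults to `c(0, psth$post_ms)` capped at 300 ms.
#' @return A data frame with one row per event: `polarity`, `onset_ms`,
#'   `offset_ms`, `strength_spikes` (signed excess spikes per stimulation),
#'   `peak_hz` (extreme rate in the event window). Attribute `degenerate`
#'   marks the zero-SD fallback.
#' @export
detect_response_events <- function(psth, k = 2.5, min_consecutive = 2L,
                                   artifact_blank_ms = 2,
                                   search_window_ms = NULL) {
  abort_if(!inherits(psth, "psth"), "`psth` must be a psth object")
  sw <- search_window_ms %||% c(0, min(psth$post_ms, 300))
  sd0 <- psth$baseline_sd_hz
  degenerate <- FALSE
  bin_s <- psth$bin_ms / 1000
  if (is.na(sd0) || sd0 == 0) {
    degenerate <- TRUE
    sd0 <- sqrt(psth$baseline_mean_hz / (psth$n_trials * bin_s))
    if (psth$baseline_mean_hz > 0 || any(psth$rate_hz > 0)) {
      warning("baseline SD is zero; using Poisson fallback threshold",
              call. = FALSE)
    }
  }
  hi <- psth$baseline_mean_hz + k * sd0
  lo <- psth$baseline_mean_hz - k * sd0

  starts <- psth$bin_start_ms
  keep <- starts >= max(sw[1], artifact_blank_ms) &
    (starts + psth$bin_ms) <= sw[2]
  idx <- which(keep)
  empty <- data.frame(polarity = character(0), onset_ms = numeric(0),
                      offset_ms = numeric(0), strength_spikes = numeric(0),
                      peak_hz = numeric(0))
  attr(empty, "degenerate") <- degenerate
  if (!length(idx)) return(empty)

  r <- psth$rate_hz[idx]
  t0 <- starts[idx]
  d <- integer(length(r))
  d[r > hi] <- 1L
  d[r < lo] <- -1L

  m <- length(d)
  run_starts <- function(i, p) {
    ## TRUE if a run of >= min_consecutive bins of polarity p starts at i
    j <- i + min_consecutive - 1L
    j <= m && all(d[i:j] == p)
  }
  events <- list()
  i <- 1L
  while (i <= m) {
    if (d[i] != 0L && run_starts(i, d[i])) {
      p <- d[i]
      s <- i
      j <- i + 1L
      e <- i
      repeat {
        if (j > m) break
        if (d[j] == p) { e <- j; j <- j + 1L; next }
        if (d[j] == 0L && (j == m || d[j + 1L] == 0L)) break
        if (d[j] == -p && run_starts(j, -p)) break
        j <- j + 1L
      }
      last_p <- max(which(d[s:e] == p)) + s - 1L
      events[[length(events) + 1L]] <- list(p = p, s = s, e = last_p)
      ## resume after the event body; an opposite run restarts right away
      i <- if (j <= m && d[j] == -p) j else e + 1L
      i <- max(i, last_p + 1L)
    } else {
      i <- i + 1L
    }
  }
  if (!length(events)) return(empty)
  out <- do.call(rbind, lapply(events, function(ev) {
    bins <- ev$s:ev$e
    strength <- sum((r[bins] - psth$baseline_mean_hz) * bin_s)
    peak <- if (ev$p > 0) max(r[bins]) else min(r[bins])
    data.frame(
      polarity = if (ev$p > 0) "excitation" else "inhibition",
      onset_ms = t0[ev$s],
      offset_ms = t0[ev$e] + psth$bin_ms,
      strength_spikes = strength,
      peak_hz = peak
    )
  }))
  rownames(out) <- NULL
  attr(out, "degenerate") <- degenerate
  out
}

#' Latency of the first evoked response
#'
#' Time between the stimulation onset and the beginning of the first
#' excitatory or inhibitory response event.
#'
#' @param events Event table from [detect_response_events()].
#' @return Latency in ms, or `NA_real_` when no event was detected.
#' @export
first_response_latency <- function(events) {
  if (is.null(events) || nrow(events) == 0L) return(NA_real_)
  min(events$onset_ms)
}

#' Evoked response strength
#'
#' Sum over the response bins of the difference between the PSTH rate and
#' the mean baseline rate, times the bin width: the average number of
#' excess spikes induced by a single stimulation. `mode = "first_excitation"`
#' (used for single units in high-rate structures) integrates the first
#' excitatory event only; `mode = "total"` (used for low-rate multiunit
#' recordings with bimodal responses) sums all excitatory events.
#'
#' @param psth A [compute_psth()] result.
#' @param events Event table from [detect_response_events()] on the same
#'   PSTH.
#' @param mode `"first_excitation"` (default) or `"total"`.
#' @return Excess spikes per stimulation; 0 (with a warning) when no
#'   excitatory event is present.
#' @export
response_strength <- function(psth, events,
                              mode = c("first_excitation", "total")) {
  mode <- match.arg(mode)
  abort_if(!inherits(psth, "psth"), "`psth` must be a psth object")
  if (is.null(events) || nrow(events) == 0L) return(0)
  exc <- events[events$polarity == "excitation", , drop = FALSE]
  if (nrow(exc) == 0L) {
    warning("no excitatory event; response strength set to 0",
            call. = FALSE)
    return(0)
  }
  if (mode == "first_excitation") exc <- exc[1L, , drop = FALSE]
  bin_s <- psth$bin_ms / 1000
  total <- 0
  for (i in seq_len(nrow(exc))) {
    bins <- psth$bin_start_ms >= exc$onset_ms[i] &
      psth$bin_start_ms < exc$offset_ms[i]
    total <- total +
      sum((psth$rate_hz[bins] - psth$baseline_mean_hz) * bin_s)
  }
  total
}

#' Peak firing rate in the response period
#'
#' Maximal PSTH value over the bins belonging to excitatory response
#' events.
#'
#' @inheritParams response_strength
#' @return Peak rate in Hz.
#' @export
peak_response_rate <- function(psth, events) {
  abort_if(!inherits(psth, "psth"), "`psth` must be a psth object")
  abort_if(is.null(events) || nrow(events) == 0L,
           "no response events; peak rate undefined")
  exc <- events[events$polarity == "excitation", , drop = FALSE]
  abort_if(nrow(exc) == 0L,
           "no excitatory response event; peak rate undefined")
  peaks <- vapply(seq_len(nrow(exc)), function(i) {
    bins <- psth$bin_start_ms >= exc$onset_ms[i] &
      psth$bin_start_ms < exc$offset_ms[i]
    max(psth$rate_hz[bins])
  }, numeric(1))
  max(peaks)
}

#' Classify a response profile
#'
#' Maps the temporally ordered polarity sequence of detected events onto
#' the response taxonomy observed in pallidal recordings: a single
#' excitation, a biphasic excitation-inhibition response, or a triphasic
#' rapid inhibition / excitation / late inhibition response. Any other
#' sequence (including an isolated inhibition) is labelled `"other"`.
#'
#' @param events Event table from [detect_response_events()].
#' @return One of `"none"`, `"excitation_only"`, `"biphasic"`,
#'   `"triphasic"`, `"other"`.
#' @export
classify_profile <- function(events) {
  pol <- if (is.null(events)) character(0) else events$polarity
  key <- paste(substr(pol, 1, 1), collapse = "")
  if (key == "") return("none")
  switch(key,
         "e" = "excitation_only",
         "ei" = "biphasic",
         "iei" = "triphasic",
         "other")
}

#' Percentage of resting response
#'
#' Response strength under a (drug) condition expressed as a percentage of
#' the resting (baseline) response strength, the measure used to quantify
#' drug dispersion and blockade efficiency.
#'
#' @param strength_condition Response strength under the condition.
#' @param strength_baseline Resting response strength (> 0).
#' @return Percentage (100 = unchanged, 0 = complete blockade).
#' @export
percent_resting_response <- function(strength_condition,
                                     strength_baseline) {
  abort_if(!is_number(strength_baseline) || strength_baseline <= 0,
           "`strength_baseline` must be > 0")
  100 * strength_condition / strength_baseline
}

#' Compare response measures between two conditions
#'
#' Paired Wilcoxon signed-rank (same units recorded under both conditions)
#' or Wilcoxon rank-sum test, applied to response strengths, peak rates or
#' spontaneous rates.
#'
#' @param values_a,values_b Numeric vectors of per-unit measures.
#' @param paired Logical; paired signed-rank when `TRUE` (default).
#' @return A one-row statistics data frame (see [run_test()]).
#' @export
compare_conditions <- function(values_a, values_b, paired = TRUE) {
  run_test(values_a, values_b,
           kind = if (paired) "wilcoxon_paired" else "wilcoxon_ranksum")
}
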