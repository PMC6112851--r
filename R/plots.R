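## Diagnostic plots: PSTH with the baseline confidence band, segmentation
## overlays, latency and duration distributions. Base graphics, best
## effort; plotting never interrupts an analysis.

#' Plot a PSTH with its baseline confidence band
#'
#' Draws the PSTH as a rate histogram with the mean baseline firing rate
#' (dashed black) and the mean +/- `k` SD confidence band (dotted red);
#' detected response events, when supplied, are shaded.
#'
#' @param psth A [compute_psth()] result.
#' @param events Optional event table from [detect_response_events()].
#' @param k Band half-width in baseline SD units (default 2.5).
#' @param ... Passed to [graphics::plot()].
#' @return `psth`, invisibly.
#' @export
plot_psth <- function(psth, events = NULL, k = 2.5, ...) {
  t <- psth$bin_start_ms + psth$bin_ms / 2
  plot(t, psth$rate_hz, type = "s", xlab = "time from stimulation (ms)",
       ylab = "firing rate (Hz)", ...)
  if (!is.null(events) && nrow(events) > 0L) {
    for (i in seq_len(nrow(events))) {
      rect(events$onset_ms[i], 0, events$offset_ms[i],
           max(psth$rate_hz),
           col = if (events$polarity[i] == "excitation")
             grDevices::adjustcolor("orange", 0.2)
           else grDevices::adjustcolor("blue", 0.2),
           border = NA)
    }
  }
  abline(h = psth$baseline_mean_hz, lty = 2)
  abline(h = psth$baseline_mean_hz + c(-k, k) * psth$baseline_sd_hz,
         lty = 3, col = "red")
  abline(v = 0, col = "grey")
  invisible(psth)
}

#' Plot envelope segmentation overlay
#'
#' Shows the amplitude envelope, the segmentation threshold and the
#' detected syllable onsets/offsets (at the threshold crossings).
#'
#' @param envelope An [compute_envelope()] result.
#' @param segments Segment table from [segment_syllables()].
#' @param ... Passed to [graphics::plot()].
#' @return `segments`, invisibly.
#' @export
plot_segmentation <- function(envelope, segments, ...) {
  plot(envelope$times_s, envelope$values, type = "l", xlab = "time (s)",
       ylab = "RMS envelope", ...)
  thr <- attr(segments, "threshold")
  if (!is.null(thr)) abline(h = thr, lty = 3, col = "red")
  if (nrow(segments) > 0L) {
    points(segments$onset_s, rep(thr %||% 0, nrow(segments)), pch = 2,
           col = "darkgreen")
    points(segments$offset_s, rep(thr %||% 0, nrow(segments)), pch = 6,
           col = "darkgreen")
  }
  invisible(segments)
}

#' Histogram of first-response latencies
#'
#' @param latencies_ms Numeric vector of latencies (ms); `NA`s dropped.
#' @param bin_ms Histogram bin width, ms.
#' @param ... Passed to [graphics::hist()].
#' @return The histogram object, invisibly.
#' @export
plot_latency_hist <- function(latencies_ms, bin_ms = 5, ...) {
  x <- latencies_ms[!is.na(latencies_ms)]
  if (!length(x)) {
    warning("no latencies to plot", call. = FALSE)
    return(invisible(NULL))
  }
  breaks <- seq(0, max(x) + bin_ms, by = bin_ms)
  invisible(hist(x, breaks = breaks,
                 xlab = "response latency (ms)", main = "", ...))
}

#' Per-period feature distributions
#'
#' One boxplot per experimental period for a feature column, the standard
#' diagnostic for duration/F0 drift across learning.
#'
#' @param features Output of [assign_periods()].
#' @param value Feature column (default `"duration_ms"`).
#' @param ... Passed to [graphics::boxplot()].
#' @return Invisibly, the boxplot statistics.
#' @export
plot_period_distributions <- function(features, value = "duration_ms",
                                      ...) {
  abort_if(!"period" %in% names(features), "run assign_periods() first")
  keep <- !is.na(features$period)
  invisible(graphics::boxplot(
    features[[value]][keep] ~ droplevels(features$period[keep]),
    xlab = "period", ylab = value, ...))
}
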