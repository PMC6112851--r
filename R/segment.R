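## Envelope-threshold syllable segmentation and relative amplitude.

#' Segment syllables by envelope threshold
#'
#' Within a motif window, the segmentation threshold is derived from the
#' quietest point of the smoothed envelope (the smallest amplitude in the
#' motif, i.e. the deepest inter-syllable gap), inflated by a margin, and
#' floored at a multiple of the background noise level:
#' `threshold = max(min(envelope) * min_margin, background * floor_factor)`.
#' Syllable onsets and offsets are the times at which the envelope crosses
#' this threshold (linearly interpolated between envelope samples).
#' Sub-threshold dips shorter than `min_gap_ms` are closed and
#' supra-threshold runs shorter than `min_dur_ms` are discarded, which
#' suppresses threshold chatter. Intervals are half-open
#' `[onset, offset)`; all times are seconds from the start of the
#' recording.
#'
#' @param envelope An [compute_envelope()] result.
#' @param motif_window Length-2 `(start_s, end_s)` window to segment;
#'   defaults to the whole envelope.
#' @param threshold Absolute threshold override; when `NULL` (default) the
#'   rule above applies.
#' @param min_margin Multiplier on the minimum envelope (default 1.1).
#' @param floor_factor Multiplier on the background level (default 3).
#' @param background Background RMS estimate; defaults to the 5th
#'   percentile of the envelope within the window.
#' @param min_gap_ms Minimum inter-syllable gap, ms (default 5).
#' @param min_dur_ms Minimum syllable duration, ms (default 10).
#' @return A data frame of segments: `onset_s`, `offset_s`, `duration_ms`,
#'   `peak_envelope`. Attribute `threshold` records the value used. A
#'   threshold above the envelope maximum yields zero segments with a
#'   warning.
#' @export
segment_syllables <- function(envelope, motif_window = NULL,
                              threshold = NULL, min_margin = 1.1,
                              floor_factor = 3, background = NULL,
                              min_gap_ms = 5, min_dur_ms = 10) {
  abort_if(!inherits(envelope, "envelope"),
           "`envelope` must be an envelope object")
  t <- envelope$times_s
  w <- motif_window %||% range(t)
  abort_if(w[1] < min(t) - 1e-9 || w[2] > max(t) + 1e-9,
           "`motif_window` lies outside the envelope")
  sel <- which(t >= w[1] & t <= w[2])
  e <- envelope$values[sel]
  ts <- t[sel]
  if (is.null(threshold)) {
    background <- background %||% unname(quantile(e, 0.05))
    threshold <- max(min(e) * min_margin, background * floor_factor)
  }
  empty <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      duration_ms = numeric(0), peak_envelope = numeric(0))
  attr(empty, "threshold") <- threshold
  if (threshold >= max(e)) {
    warning("threshold is at or above the envelope maximum; no segments",
            call. = FALSE)
    return(empty)
  }
  above <- e > threshold
  ## close sub-minimum gaps
  r <- rle(above)
  dt_ms <- 1000 / envelope$rate_hz
  gap_runs <- !r$values & r$lengths * dt_ms < min_gap_ms
  inner <- seq_along(r$values) > 1L & seq_along(r$values) < length(r$values)
  r$values[gap_runs & inner] <- TRUE
  above <- inverse.rle(r)
  ## drop sub-minimum syllables
  r <- rle(above)
  r$values[r$values & r$lengths * dt_ms < min_dur_ms] <- FALSE
  above <- inverse.rle(r)
  r <- rle(above)
  if (!any(r$values)) return(empty)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  cross_time <- function(i_lo, i_hi) {
    ## linear interpolation of the threshold crossing between samples
    if (i_lo < 1L || i_hi > length(e) || i_lo == i_hi)
      return(ts[max(1L, min(i_hi, length(e)))])
    e1 <- e[i_lo]; e2 <- e[i_hi]
    if (e2 == e1) return(ts[i_hi])
    f <- (threshold - e1) / (e2 - e1)
    ts[i_lo] + f * (ts[i_hi] - ts[i_lo])
  }
  out <- do.call(rbind, lapply(runs, function(ri) {
    s <- starts[ri]; en <- ends[ri]
    onset <- cross_time(s - 1L, s)
    offset <- cross_time(en, en + 1L)
    data.frame(onset_s = onset, offset_s = offset,
               duration_ms = (offset - onset) * 1000,
               peak_envelope = max(e[s:en]))
  }))
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  out
}

#' Relative syllable amplitude
#'
#' Peak sound envelope during the syllable divided by the peak sound
#' envelope over the whole motif; the loudest syllable scores 1.
#'
#' @param segments Segment table from [segment_syllables()].
#' @param envelope The motif [compute_envelope()] result.
#' @param motif_window Optional `(start_s, end_s)` window defining the
#'   motif over which the reference peak is taken.
#' @return The segment table with a `rel_amplitude` column in `(0, 1]`.
#' @export
relative_amplitude <- function(segments, envelope, motif_window = NULL) {
  abort_if(!inherits(envelope, "envelope"),
           "`envelope` must be an envelope object")
  t <- envelope$times_s
  w <- motif_window %||% range(t)
  peak_motif <- max(envelope$values[t >= w[1] & t <= w[2]])
  abort_if(peak_motif <= 0, "motif envelope peak is zero")
  segments$rel_amplitude <- pmin(segments$peak_envelope / peak_motif, 1)
  segments
}
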