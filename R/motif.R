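## Template-based motif detection, spectral-similarity sorting and bout
## segmentation.

#' Motif template
#'
#' Bundles a clean, pre-selected motif recording with its envelope and
#' spectrogram for repeated matching against continuous recordings.
#'
#' @param audio An [audio_recording()] holding one clean motif
#'   (0.2 to 2 s).
#' @param smoothing_ms Envelope smoothing window, ms.
#' @return An object of class `motif_template`.
#' @export
motif_template <- function(audio, smoothing_ms = 5) {
  abort_if(!inherits(audio, "audio_recording"),
           "`audio` must be an audio_recording")
  dur <- length(audio$samples) / audio$sample_rate
  abort_if(dur < 0.2 || dur > 2,
           "template motif duration must be between 0.2 and 2 s")
  structure(
    list(audio = audio,
         envelope = compute_envelope(audio, smoothing_ms = smoothing_ms),
         spectrogram = compute_spectrogram(audio),
         duration_s = dur),
    class = "motif_template"
  )
}

## Normalized (Pearson) sliding cross-correlation of template `b` against
## signal `a`; returns one coefficient per start position (length
## n - m + 1). FFT-based via stats::convolve, with running sums for the
## per-window normalization.
norm_xcorr <- function(a, b) {
  m <- length(b); n <- length(a)
  abort_if(m > n, "template is longer than the signal")
  b0 <- b - mean(b)
  sb <- sqrt(sum(b0^2))
  num <- convolve(a, b0, type = "open")[m:n]
  sa <- cumsum(c(0, a)); sa2 <- cumsum(c(0, a^2))
  s1 <- sa[(m + 1):(n + 1)] - sa[1:(n - m + 1)]
  s2 <- sa2[(m + 1):(n + 1)] - sa2[1:(n - m + 1)]
  denom <- sqrt(pmax(s2 - s1^2 / m, 0)) * sb
  r <- ifelse(denom > 1e-12, num / denom, 0)
  pmin(pmax(r, -1), 1)
}

#' Detect putative motifs by envelope cross-correlation
#'
#' Computes the normalized cross-correlation between the sound envelope of
#' the recording and the template envelope, keeps local maxima above
#' `peak_threshold`, and applies non-maximum suppression over one template
#' length so that overlapping candidates yield a single detection.
#'
#' @param audio An [audio_recording()].
#' @param template A [motif_template()].
#' @param peak_threshold Minimum envelope correlation (default 0.6).
#' @return A data frame of candidate occurrences: `start_s`, `end_s`,
#'   `env_corr`.
#' @export
detect_motif_candidates <- function(audio, template, peak_threshold = 0.6) {
  abort_if(!inherits(template, "motif_template"),
           "`template` must be a motif_template")
  env_a <- compute_envelope(audio,
                            smoothing_ms = template$envelope$smoothing_ms)
  tv <- template$envelope$values
  av <- env_a$values
  ## recordings slightly shorter than the template (e.g. a lone, slightly
  ## compressed motif) are padded with the background level so at least
  ## one alignment exists
  if (length(av) < length(tv)) {
    pad <- rep(unname(quantile(av, 0.05)), length(tv) - length(av))
    av <- c(av, pad)
  }
  r <- norm_xcorr(av, tv)
  m <- length(tv)
  ## local maxima above threshold
  cand <- which(r > peak_threshold)
  cand <- cand[r[cand] >= c(r[1], r)[cand] & r[cand] >= c(r, r[length(r)])[cand + 1L]]
  if (!length(cand)) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      env_corr = numeric(0)))
  }
  ## non-maximum suppression over one template length
  keep <- integer(0)
  for (i in cand[order(r[cand], decreasing = TRUE)]) {
    if (!length(keep) || all(abs(keep - i) >= m)) keep <- c(keep, i)
  }
  keep <- sort(keep)
  start_s <- env_a$times_s[keep]
  data.frame(start_s = start_s,
             end_s = start_s + template$duration_s,
             env_corr = r[keep])
}

#' Sort motif candidates by spectral similarity to the template
#'
#' For each candidate window, computes the peak (over time lag) normalized
#' two-dimensional cross-correlation between the candidate and template
#' log-magnitude spectrograms (per-frame mean removed) and accepts the
#' candidate when the similarity reaches `threshold`. The threshold is an
#' experimenter-set configuration value, not a constant of the method.
#'
#' @param audio The [audio_recording()] the candidates came from.
#' @param candidates Data frame from [detect_motif_candidates()].
#' @param template A [motif_template()].
#' @param threshold Acceptance threshold on the similarity (default 0.5).
#' @param max_lag_frames Maximal time shift explored, in spectrogram
#'   frames (default 10).
#' @return The candidate table with columns `similarity` and `accepted`
#'   added; rows are retained for audit, use `accepted` to filter.
#' @export
filter_by_spectral_similarity <- function(audio, candidates, template,
                                          threshold = 0.5,
                                          max_lag_frames = 10L) {
  abort_if(!inherits(template, "motif_template"),
           "`template` must be a motif_template")
  if (nrow(candidates) == 0L) {
    candidates$similarity <- numeric(0)
    candidates$accepted <- logical(0)
    return(candidates)
  }
  Tm <- log_spec_matrix(template$spectrogram)
  sr <- audio$sample_rate
  n <- length(audio$samples)
  sims <- vapply(seq_len(nrow(candidates)), function(i) {
    i1 <- max(1L, as.integer(round(candidates$start_s[i] * sr)) + 1L)
    i2 <- min(n, as.integer(round(candidates$end_s[i] * sr)))
    seg <- audio$samples[i1:i2]
    if (length(seg) < template$spectrogram$n) return(-1)
    Cs <- compute_spectrogram(audio_recording(seg, sr))
    spec_xcorr_peak(log_spec_matrix(Cs), Tm, max_lag = max_lag_frames,
                    min_overlap = 0.8)$peak
  }, numeric(1))
  candidates$similarity <- sims
  candidates$accepted <- sims >= threshold
  candidates
}

#' Group motif occurrences into song bouts
#'
#' Consecutive motifs separated by less than `max_gap_s` (500 ms) of
#' silence belong to the same bout; a gap of `max_gap_s` or more starts a
#' new bout. Every occurrence is assigned to exactly one bout.
#'
#' @param occurrences Data frame with `start_s` and `end_s` columns
#'   (accepted motif occurrences, any order).
#' @return A list with `bouts` (data frame: `bout`, `start_s`, `end_s`,
#'   `n_motifs`) and `occurrences` (the input, time-ordered, with a `bout`
#'   index column).
#' @export
segment_bouts <- function(occurrences, max_gap_s = 0.5) {
  if (nrow(occurrences) == 0L) {
    return(list(bouts = data.frame(bout = integer(0), start_s = numeric(0),
                                   end_s = numeric(0), n_motifs = integer(0)),
                occurrences = cbind(occurrences, bout = integer(0))))
  }
  occ <- occurrences[order(occurrences$start_s), , drop = FALSE]
  gaps <- occ$start_s[-1L] - occ$end_s[-nrow(occ)]
  occ$bout <- cumsum(c(1L, as.integer(gaps >= max_gap_s)))
  bouts <- do.call(rbind, lapply(split(occ, occ$bout), function(g) {
    data.frame(bout = g$bout[1L], start_s = min(g$start_s),
               end_s = max(g$end_s), n_motifs = nrow(g))
  }))
  rownames(bouts) <- NULL
  rownames(occ) <- NULL
  list(bouts = bouts, occurrences = occ)
}
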