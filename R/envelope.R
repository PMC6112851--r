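## Amplitude envelope and spectrogram computation for song audio.

#' Root-mean-square amplitude envelope
#'
#' RMS of the waveform over a sliding window, evaluated on a regular
#' (default 1 kHz) grid. The 5 ms default window resolves inter-syllable
#' gaps down to about 10 ms while rejecting carrier ripple for fundamental
#' frequencies of 400 Hz and above.
#'
#' @param audio An [audio_recording()].
#' @param smoothing_ms RMS window length, ms (> 0).
#' @param rate_hz Envelope sampling rate, Hz (default 1000).
#' @return An object of class `envelope` with fields `values`, `times_s`,
#'   `rate_hz`, `smoothing_ms`.
#' @export
compute_envelope <- function(audio, smoothing_ms = 5, rate_hz = 1000) {
  abort_if(!inherits(audio, "audio_recording"),
           "`audio` must be an audio_recording")
  abort_if(!is_number(smoothing_ms) || smoothing_ms <= 0,
           "`smoothing_ms` must be > 0")
  sr <- audio$sample_rate
  n <- length(audio$samples)
  dur <- n / sr
  abort_if(smoothing_ms / 1000 > dur,
           "smoothing window is longer than the recording")
  cum <- c(0, cumsum(audio$samples^2))
  t <- seq(0, dur, by = 1 / rate_hz)
  hw <- smoothing_ms / 2000
  i1 <- pmax(1L, as.integer(round((t - hw) * sr)) + 1L)
  i2 <- pmin(n, as.integer(round((t + hw) * sr)))
  i2 <- pmax(i2, i1)
  vals <- sqrt((cum[i2 + 1L] - cum[i1]) / (i2 - i1 + 1L))
  structure(list(values = vals, times_s = t, rate_hz = rate_hz,
                 smoothing_ms = smoothing_ms),
            class = "envelope")
}

#' Magnitude spectrogram
#'
#' Short-time Fourier transform magnitude with a 256-point Hanning window
#' moved in 128-point steps (the standard parameters for zebra finch song
#' at 44.1 kHz).
#'
#' @param audio An [audio_recording()].
#' @param n Window length in samples (default 256).
#' @param hop Hop size in samples (default 128).
#' @return An object of class `spectrogram`: `mag` (freq x time magnitude
#'   matrix), `freq_hz`, `time_s`, `n`, `hop`, `sample_rate`.
#' @export
compute_spectrogram <- function(audio, n = 256L, hop = 128L) {
  abort_if(!inherits(audio, "audio_recording"),
           "`audio` must be an audio_recording")
  abort_if(length(audio$samples) < n,
           "audio shorter than one analysis window (", n, " samples)")
  sg <- signal::specgram(audio$samples, n = n, Fs = audio$sample_rate,
                         window = signal::hanning(n), overlap = n - hop)
  structure(list(mag = abs(sg$S), freq_hz = sg$f, time_s = sg$t,
                 n = n, hop = hop, sample_rate = audio$sample_rate),
            class = "spectrogram")
}

## Log-magnitude with per-column (per-frame) mean removal; emphasizes
## spectral shape over loudness and makes similarity gain-invariant.
log_spec_matrix <- function(spec, eps = 1e-10) {
  lm <- log(spec$mag + eps)
  sweep(lm, 2L, colMeans(lm))
}

## Peak over time lag of the normalized 2-D cross-correlation between two
## processed spectrogram matrices (same frequency axis). `max_lag` bounds
## the time shift in frames; NULL slides the shorter matrix over the whole
## longer one. `min_overlap` is the minimal overlap fraction of the
## shorter matrix.
spec_xcorr_peak <- function(A, B, max_lag = NULL, min_overlap = 0.5) {
  abort_if(nrow(A) != nrow(B), "spectrograms have different frequency axes")
  ta <- ncol(A); tb <- ncol(B)
  lags <- -(tb - 1L):(ta - 1L)
  if (!is.null(max_lag)) lags <- lags[abs(lags) <= max_lag]
  min_cols <- max(2L, ceiling(min_overlap * min(ta, tb)))
  best <- -1
  best_lag <- 0L
  for (lag in lags) {
    a1 <- max(1L, 1L + lag); a2 <- min(ta, tb + lag)
    if (a2 - a1 + 1L < min_cols) next
    b1 <- a1 - lag; b2 <- a2 - lag
    va <- as.vector(A[, a1:a2]); vb <- as.vector(B[, b1:b2])
    sda <- sd(va); sdb <- sd(vb)
    if (sda == 0 || sdb == 0) next
    r <- sum((va - mean(va)) * (vb - mean(vb))) /
      ((length(va) - 1L) * sda * sdb)
    if (r > best) { best <- r; best_lag <- lag }
  }
  list(peak = best, lag_frames = best_lag)
}
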