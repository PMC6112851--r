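## Autocorrelation-based fundamental frequency estimation for harmonic
## syllables.

#' Estimate fundamental frequency by autocorrelation
#'
#' Computes the normalized autocorrelation of the waveform over the lag
#' range corresponding to `[f_min, f_max]` in one or more analysis windows
#' and takes the fundamental as the inverse of the lag of the highest
#' peak, refined by parabolic interpolation. To avoid octave errors, when
#' several peaks come within 5\% of the highest one, the shortest such lag
#' (highest frequency) wins. A window whose peak correlation falls below
#' `harmonicity_threshold` (relative to the zero-lag value) is considered
#' non-harmonic and yields `NA`. The estimate is invariant to a polarity
#' flip of the waveform (the autocorrelation is even in the signal sign).
#'
#' Defaults cover the zebra finch harmonic-stack band: `f_min` 300 Hz,
#' `f_max` 1500 Hz, a single 40 ms window centered in the segment, and a
#' harmonicity threshold of 0.5. Syllables with several sub-syllabic
#' elements of distinct fundamental can be measured by passing several
#' window centers.
#'
#' @param audio An [audio_recording()] (typically one syllable), or the
#'   samples of one.
#' @param sample_rate Required when `audio` is a bare numeric vector.
#' @param f_min,f_max Search band, Hz (`f_min < f_max < ` Nyquist / 2).
#' @param harmonicity_threshold Minimum normalized autocorrelation peak
#'   (default 0.5).
#' @param window_ms Analysis window length, ms (default 40).
#' @param centers_s Window centers in seconds from the start of `audio`;
#'   defaults to the segment midpoint.
#' @return A list: `f0_hz` (median over harmonic windows, `NA` if none),
#'   `harmonicity` (best peak correlation), and `windows` (per-window data
#'   frame `center_s`, `f0_hz`, `harmonicity`).
#' @export
estimate_f0 <- function(audio, sample_rate = NULL, f_min = 300,
                        f_max = 1500, harmonicity_threshold = 0.5,
                        window_ms = 40, centers_s = NULL) {
  if (is.numeric(audio)) {
    abort_if(is.null(sample_rate), "`sample_rate` required for bare vectors")
    audio <- audio_recording(audio, sample_rate)
  }
  sr <- audio$sample_rate
  abort_if(f_min >= f_max, "`f_min` must be below `f_max`")
  abort_if(f_max >= sr / 4, "`f_max` must be below a quarter of the ",
           "sampling rate")
  x_all <- audio$samples
  dur <- length(x_all) / sr
  centers_s <- centers_s %||% (dur / 2)
  wn <- as.integer(round(window_ms / 1000 * sr))
  lag_min <- max(1L, as.integer(floor(sr / f_max)))
  lag_max <- as.integer(ceiling(sr / f_min))
  abort_if(wn <= lag_max + 2L,
           "analysis window too short for the requested `f_min`")
  per_window <- lapply(centers_s, function(cs) {
    i1 <- max(1L, as.integer(round(cs * sr)) - wn %/% 2L)
    i2 <- min(length(x_all), i1 + wn - 1L)
    x <- x_all[i1:i2]
    n <- length(x)
    if (n <= lag_max + 2L)
      return(data.frame(center_s = cs, f0_hz = NA_real_,
                        harmonicity = NA_real_))
    x <- x - mean(x)
    r0 <- sum(x^2) / n
    if (r0 <= 0)
      return(data.frame(center_s = cs, f0_hz = NA_real_,
                        harmonicity = 0))
    lags <- lag_min:lag_max
    nacf <- vapply(lags, function(l)
      sum(x[1:(n - l)] * x[(1 + l):n]) / (n - l), numeric(1)) / r0
    ## local maxima of the normalized autocorrelation
    k <- length(nacf)
    is_peak <- nacf >= c(nacf[1], nacf[-k]) & nacf >= c(nacf[-1], nacf[k])
    is_peak[c(1L, k)] <- FALSE
    peaks <- which(is_peak)
    if (!length(peaks) || max(nacf[peaks]) < harmonicity_threshold)
      return(data.frame(center_s = cs, f0_hz = NA_real_,
                        harmonicity = if (length(peaks))
                          max(nacf[peaks]) else max(nacf)))
    top <- max(nacf[peaks])
    best <- min(peaks[nacf[peaks] >= 0.95 * top])
    ## parabolic refinement around the chosen peak
    l <- lags[best]
    if (best > 1L && best < k) {
      y1 <- nacf[best - 1L]; y2 <- nacf[best]; y3 <- nacf[best + 1L]
      denom <- y1 - 2 * y2 + y3
      delta <- if (abs(denom) > 1e-12) 0.5 * (y1 - y3) / denom else 0
      delta <- max(min(delta, 0.5), -0.5)
      l <- l + delta
    }
    data.frame(center_s = cs, f0_hz = sr / l, harmonicity = nacf[best])
  })
  win <- do.call(rbind, per_window)
  ok <- !is.na(win$f0_hz)
  list(
    f0_hz = if (any(ok)) median(win$f0_hz[ok]) else NA_real_,
    harmonicity = if (nrow(win)) max(win$harmonicity, na.rm = TRUE)
      else NA_real_,
    windows = win
  )
}
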