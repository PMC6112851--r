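## Synthetic zebra finch song: harmonic-stack and noise syllables with
## trapezoidal envelopes, assembled into motifs, bouts and recording days
## with known ground truth.

#' Syllable specification
#'
#' @param kind `"harmonic"` (stack of sinusoids at multiples of `f0_hz`)
#'   or `"noise"` (band-limited noise burst).
#' @param duration_ms Syllable duration including ramps, ms.
#' @param f0_hz Fundamental frequency (harmonic kind only).
#' @param n_harmonics Number of harmonics including the fundamental.
#' @param peak_amplitude Linear peak amplitude in `[0, 1]`.
#' @param ramp_ms Onset/offset ramp of the trapezoidal envelope, ms. The
#'   sharp trapezoid gives unambiguous threshold crossings for ground
#'   truth.
#' @param noise_band_hz Passband of the noise kind, Hz.
#' @return An object of class `syllable_spec`.
#' @export
syllable_spec <- function(kind = c("harmonic", "noise"), duration_ms,
                          f0_hz = NA_real_, n_harmonics = 3L,
                          peak_amplitude = 0.5, ramp_ms = 5,
                          noise_band_hz = c(1000, 8000)) {
  kind <- match.arg(kind)
  abort_if(!is_number(duration_ms) || duration_ms <= 2 * ramp_ms,
           "`duration_ms` must exceed twice the ramp length")
  if (kind == "harmonic") {
    abort_if(!is_number(f0_hz) || f0_hz <= 0,
             "harmonic syllables need a positive `f0_hz`")
  }
  abort_if(peak_amplitude < 0 || peak_amplitude > 1,
           "`peak_amplitude` must lie in [0, 1]")
  structure(list(kind = kind, duration_ms = duration_ms, f0_hz = f0_hz,
                 n_harmonics = as.integer(n_harmonics),
                 peak_amplitude = peak_amplitude, ramp_ms = ramp_ms,
                 noise_band_hz = noise_band_hz),
            class = "syllable_spec")
}

#' Motif specification
#'
#' @param syllables List of [syllable_spec()] objects, in order.
#' @param gaps_ms Inter-syllable gaps, ms; a scalar is recycled to the
#'   `length(syllables) - 1` gaps. All gaps must be positive.
#' @param noise_floor Linear amplitude of the additive background noise;
#'   must stay below the quietest syllable peak.
#' @return An object of class `motif_spec`.
#' @export
motif_spec <- function(syllables, gaps_ms = 50, noise_floor = 0.005) {
  abort_if(!length(syllables), "`syllables` must be non-empty")
  for (s in syllables) abort_if(!inherits(s, "syllable_spec"),
                                "`syllables` must be syllable_spec objects")
  n_gaps <- max(length(syllables) - 1L, 0L)
  if (length(gaps_ms) == 1L) gaps_ms <- rep(gaps_ms, n_gaps)
  abort_if(length(gaps_ms) != n_gaps,
           "`gaps_ms` must have one entry per inter-syllable gap")
  abort_if(any(gaps_ms <= 0), "gaps must be positive")
  peaks <- vapply(syllables, `[[`, numeric(1), "peak_amplitude")
  abort_if(noise_floor >= min(peaks[peaks > 0], Inf),
           "`noise_floor` must be below the quietest syllable peak")
  structure(list(syllables = syllables, gaps_ms = gaps_ms,
                 noise_floor = noise_floor),
            class = "motif_spec")
}

trapezoid_envelope <- function(n, ramp_n) {
  env <- rep(1, n)
  if (ramp_n > 0L) {
    ramp_n <- min(ramp_n, n %/% 2L)
    up <- seq_len(ramp_n) / ramp_n
    env[seq_len(ramp_n)] <- up
    env[(n - ramp_n + 1L):n] <- rev(up)
  }
  env
}

#' Synthesize one syllable
#'
#' Harmonic syllables are sums of sinusoids at integer multiples of the
#' fundamental (amplitudes decaying geometrically across harmonics) with
#' randomized phases; noise syllables are band-limited Gaussian noise.
#' Both carry a trapezoidal envelope and are scaled to the requested peak
#' amplitude.
#'
#' @param spec A [syllable_spec()].
#' @param sample_rate Sampling rate, Hz; must be at least four times the
#'   highest harmonic to keep it well clear of Nyquist.
#' @param seed Optional seed (phases / noise draw).
#' @return An [audio_recording()].
#' @export
synthesize_syllable <- function(spec, sample_rate = 44100, seed = NULL) {
  abort_if(!inherits(spec, "syllable_spec"),
           "`spec` must be a syllable_spec")
  n <- as.integer(round(spec$duration_ms / 1000 * sample_rate))
  ramp_n <- as.integer(round(spec$ramp_ms / 1000 * sample_rate))
  if (spec$kind == "harmonic") {
    abort_if(sample_rate < 4 * spec$f0_hz * spec$n_harmonics,
             "sample_rate must be >= 4 * f0 * n_harmonics (aliasing)")
    x <- with_seed(seed, {
      t <- (seq_len(n) - 1L) / sample_rate
      phases <- runif(spec$n_harmonics, 0, 2 * pi)
      Reduce(`+`, lapply(seq_len(spec$n_harmonics), function(k) {
        0.8^(k - 1) * sin(2 * pi * k * spec$f0_hz * t + phases[k])
      }))
    })
  } else {
    x <- with_seed(seed, rnorm(n))
    band <- pmin(spec$noise_band_hz, sample_rate / 2 * 0.95)
    bf <- signal::butter(4, band / (sample_rate / 2), type = "pass")
    x <- signal::filtfilt(bf, x)
  }
  x <- x * trapezoid_envelope(n, ramp_n)
  pk <- max(abs(x))
  if (pk > 0) x <- x / pk * spec$peak_amplitude else x <- x * 0
  audio_recording(x, sample_rate)
}

#' Synthesize a motif with ground truth
#'
#' Concatenates the syllables with their gaps, pads both ends, and adds
#' white background noise at the configured floor. Returns the waveform
#' together with the ground-truth segment table (onsets, offsets,
#' durations and fundamental frequencies by construction).
#'
#' @param motif A [motif_spec()].
#' @param sample_rate Sampling rate, Hz.
#' @param seed Optional seed.
#' @param pad_ms Silence (noise floor only) added before and after, ms.
#' @return A list: `audio` ([audio_recording()]) and `segments` (data
#'   frame `syllable`, `kind`, `onset_s`, `offset_s`, `duration_ms`,
#'   `f0_hz`, `peak_amplitude`).
#' @export
synthesize_motif <- function(motif, sample_rate = 44100, seed = NULL,
                             pad_ms = 60) {
  abort_if(!inherits(motif, "motif_spec"), "`motif` must be a motif_spec")
  with_seed(seed, {
    n_syll <- length(motif$syllables)
    pieces <- lapply(motif$syllables, synthesize_syllable,
                     sample_rate = sample_rate, seed = NULL)
    pad_n <- as.integer(round(pad_ms / 1000 * sample_rate))
    gap_n <- as.integer(round(motif$gaps_ms / 1000 * sample_rate))
    chunks <- list(numeric(pad_n))
    onsets <- numeric(n_syll)
    pos <- pad_n
    for (i in seq_len(n_syll)) {
      onsets[i] <- pos / sample_rate
      chunks[[length(chunks) + 1L]] <- pieces[[i]]$samples
      pos <- pos + length(pieces[[i]]$samples)
      if (i < n_syll) {
        chunks[[length(chunks) + 1L]] <- numeric(gap_n[i])
        pos <- pos + gap_n[i]
      }
    }
    chunks[[length(chunks) + 1L]] <- numeric(pad_n)
    x <- unlist(chunks, use.names = FALSE)
    if (motif$noise_floor > 0)
      x <- x + rnorm(length(x), sd = motif$noise_floor)
    segments <- data.frame(
      syllable = seq_len(n_syll),
      kind = vapply(motif$syllables, `[[`, character(1), "kind"),
      onset_s = onsets,
      offset_s = onsets + vapply(motif$syllables, `[[`, numeric(1),
                                 "duration_ms") / 1000,
      duration_ms = vapply(motif$syllables, `[[`, numeric(1),
                           "duration_ms"),
      f0_hz = vapply(motif$syllables, `[[`, numeric(1), "f0_hz"),
      peak_amplitude = vapply(motif$syllables, `[[`, numeric(1),
                              "peak_amplitude")
    )
    list(audio = audio_recording(x, sample_rate), segments = segments)
  })
}

## Scale a motif's syllable durations (and optionally fundamentals) by
## multiplicative factors; ramps and gaps stay fixed.
scale_motif <- function(motif, duration_factor = 1, f0_factor = 1) {
  syl <- lapply(motif$syllables, function(s) {
    s$duration_ms <- max(s$duration_ms * duration_factor,
                         2 * s$ramp_ms + 1)
    if (s$kind == "harmonic") s$f0_hz <- s$f0_hz * f0_factor
    s
  })
  motif_spec(syl, motif$gaps_ms, motif$noise_floor)
}

#' Synthesize one recording day of bouts
#'
#' Produces `n_renditions` motif renditions for a day, applying the
#' day-level duration factor plus independent rendition-to-rendition
#' jitter, and groups them into bouts of 1 to 3 motifs separated by 100 to
#' 450 ms of silence (exercising both sides of the 500 ms bout rule);
#' successive bouts are returned as separate recordings.
#'
#' @param motif A [motif_spec()] (the bird's baseline motif).
#' @param n_renditions Number of motif renditions to generate.
#' @param day_factor Multiplicative duration factor for the day.
#' @param jitter_cv Rendition-to-rendition duration jitter (coefficient of
#'   variation; 0 yields identical renditions).
#' @param f0_factor Multiplicative fundamental-frequency factor.
#' @param f0_jitter_cv Rendition-to-rendition F0 jitter.
#' @param sample_rate Sampling rate, Hz.
#' @param seed Optional seed.
#' @param day_dph Recording day label attached to the output.
#' @return A list of bouts; each bout is a list with `audio` and `truth`
#'   (per-motif ground-truth segment tables with a `rendition` column and
#'   motif start offsets applied).
#' @export
synthesize_day <- function(motif, n_renditions, day_factor = 1,
                           jitter_cv = 0.02, f0_factor = 1,
                           f0_jitter_cv = 0.005, sample_rate = 44100,
                           seed = NULL, day_dph = NA_integer_) {
  abort_if(!inherits(motif, "motif_spec"), "`motif` must be a motif_spec")
  if (n_renditions == 0L) return(list())
  with_seed(seed, {
    rend <- 0L
    bouts <- list()
    while (rend < n_renditions) {
      size <- min(sample(1:3, 1L), n_renditions - rend)
      chunks <- list()
      truths <- list()
      pos_s <- 0
      for (j in seq_len(size)) {
        rend <- rend + 1L
        dj <- day_factor * (1 + if (jitter_cv > 0)
          rnorm(1, sd = jitter_cv) else 0)
        fj <- f0_factor * (1 + if (f0_jitter_cv > 0)
          rnorm(1, sd = f0_jitter_cv) else 0)
        m <- synthesize_motif(scale_motif(motif, dj, fj),
                              sample_rate = sample_rate, seed = NULL)
        tr <- m$segments
        tr$onset_s <- tr$onset_s + pos_s
        tr$offset_s <- tr$offset_s + pos_s
        tr$rendition <- rend
        tr$motif_start_s <- pos_s
        truths[[j]] <- tr
        chunks[[length(chunks) + 1L]] <- m$audio$samples
        pos_s <- pos_s + length(m$audio$samples) / sample_rate
        if (j < size) {
          gap_s <- runif(1, 0.1, 0.45)
          chunks[[length(chunks) + 1L]] <-
            rnorm(as.integer(round(gap_s * sample_rate)),
                  sd = motif$noise_floor)
          pos_s <- pos_s + gap_s
        }
      }
      audio <- audio_recording(unlist(chunks, use.names = FALSE),
                               sample_rate, day_dph = day_dph,
                               rendition = length(bouts) + 1L)
      bouts[[length(bouts) + 1L]] <-
        list(audio = audio, truth = do.call(rbind, truths))
    }
    bouts
  })
}
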