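test_that("RMS envelope matches closed forms", {
  sr <- 44100
  silence <- audio_recording(numeric(sr), sr)
  env0 <- compute_envelope(silence)
  expect_true(all(env0$values < 1e-12))

  tone <- audio_recording(sin(2 * pi * 1000 * (0:(sr - 1)) / sr), sr)
  env1 <- compute_envelope(tone)
  steady <- env1$values[env1$times_s > 0.1 & env1$times_s < 0.9]
  expect_equal(mean(steady), sqrt(0.5), tolerance = 0.01)

  # AM tone: envelope tracks the (slow) modulator
  t <- (0:(sr - 1)) / sr
  modl <- 0.5 + 0.4 * sin(2 * pi * 3 * t)
  am <- audio_recording(modl * sin(2 * pi * 2000 * t), sr)
  env2 <- compute_envelope(am)
  sel <- env2$times_s > 0.05 & env2$times_s < 0.95
  expected <- (0.5 + 0.4 * sin(2 * pi * 3 * env2$times_s[sel])) * sqrt(0.5)
  expect_lt(max(abs(env2$values[sel] - expected) / max(expected)), 0.05)

  expect_error(compute_envelope(audio_recording(rnorm(10), sr)),
               "longer than the recording")
})

test_that("spectrogram uses the 256/128 Hanning parameterization", {
  sr <- 44100
  tone <- audio_recording(sin(2 * pi * 1000 * (0:22049) / sr), sr)
  sp <- compute_spectrogram(tone)
  expect_equal(sp$n, 256L)
  expect_equal(sp$hop, 128L)
  peak_freq <- sp$freq_hz[apply(sp$mag, 2L, which.max)]
  expect_true(all(abs(peak_freq - 1000) < sr / 256))

  zeros <- audio_recording(numeric(1000), sr)
  expect_true(all(compute_spectrogram(zeros)$mag == 0))
  expect_error(compute_spectrogram(audio_recording(rnorm(100), sr)),
               "shorter")
})

test_that("motif detection finds planted template copies", {
  withr::with_seed(11, {
    m <- synthesize_motif(test_motif(), seed = 20)
    tmpl <- motif_template(m$audio)
    sr <- m$audio$sample_rate
    dur <- length(m$audio$samples)
    true_starts <- c(0.5, 2.0, 3.5)
    x <- rnorm(5 * sr, sd = 0.01)
    for (s in true_starts) {
      idx <- round(s * sr) + seq_len(dur)
      x[idx] <- x[idx] + m$audio$samples
    }
    cand <- detect_motif_candidates(audio_recording(x, sr), tmpl)
    expect_equal(nrow(cand), 3L)
    expect_true(all(abs(sort(cand$start_s) - true_starts) < 0.010))

    # pure noise: no detections
    noise <- audio_recording(rnorm(3 * sr, sd = 0.01), sr)
    expect_equal(nrow(detect_motif_candidates(noise, tmpl)), 0L)

    # two copies closer than one template length: one detection
    y <- rnorm(3 * sr, sd = 0.01)
    idx1 <- round(0.5 * sr) + seq_len(dur)
    idx2 <- round((0.5 + 0.3 * dur / sr) * sr) + seq_len(dur)
    y[idx1] <- y[idx1] + m$audio$samples
    y[idx2] <- y[idx2] + 0.8 * m$audio$samples
    cand2 <- detect_motif_candidates(audio_recording(y, sr), tmpl)
    expect_equal(nrow(cand2), 1L)
  })
})

test_that("spectral similarity accepts the template and rejects noise", {
  m <- synthesize_motif(test_motif(), seed = 21)
  tmpl <- motif_template(m$audio)
  self <- data.frame(start_s = 0,
                     end_s = length(m$audio$samples) /
                       m$audio$sample_rate, env_corr = 1)
  out <- filter_by_spectral_similarity(m$audio, self, tmpl)
  expect_equal(out$similarity, 1, tolerance = 1e-9)
  expect_true(out$accepted)

  withr::with_seed(5, {
    noise <- audio_recording(rnorm(length(m$audio$samples), sd = 0.1),
                             m$audio$sample_rate)
    outn <- filter_by_spectral_similarity(noise, self, tmpl)
    expect_lt(outn$similarity, 0.5)
    expect_false(outn$accepted)
  })

  # threshold is configurable, not hard-coded
  loose <- filter_by_spectral_similarity(m$audio, self, tmpl,
                                         threshold = 0.99)
  expect_true(loose$accepted)
})

test_that("similarity and envelope correlation are gain invariant", {
  m <- synthesize_motif(test_motif(), seed = 22)
  tmpl <- motif_template(m$audio)
  louder <- audio_recording(2 * m$audio$samples, m$audio$sample_rate)
  c1 <- detect_motif_candidates(m$audio, tmpl)
  c2 <- detect_motif_candidates(louder, tmpl)
  expect_equal(c1$env_corr, c2$env_corr, tolerance = 1e-6)
  f1 <- filter_by_spectral_similarity(m$audio, c1, tmpl)
  f2 <- filter_by_spectral_similarity(louder, c2, tmpl)
  expect_equal(f1$similarity, f2$similarity, tolerance = 1e-6)
})

test_that("bout segmentation applies the 500 ms silence rule", {
  occ <- function(starts, dur = 0.6)
    data.frame(start_s = starts, end_s = starts + dur)
  one <- segment_bouts(occ(c(0, 1.0)))        # 400 ms gap
  expect_equal(nrow(one$bouts), 1L)
  expect_equal(one$bouts$n_motifs, 2L)
  two <- segment_bouts(occ(c(0, 1.2)))        # 600 ms gap
  expect_equal(nrow(two$bouts), 2L)
  single <- segment_bouts(occ(0.3))
  expect_equal(nrow(single$bouts), 1L)
  expect_equal(single$bouts$start_s, 0.3)
  # exactly 500 ms separates bouts (strict "less than" merges)
  edge <- segment_bouts(occ(c(0, 1.1)))
  expect_equal(nrow(edge$bouts), 2L)
  # partition: every occurrence in exactly one bout
  many <- segment_bouts(occ(c(0, 0.8, 2.5, 3.2, 9)))
  expect_equal(sum(many$bouts$n_motifs), 5L)
  expect_false(anyNA(many$occurrences$bout))
})

test_that("syllable segmentation recovers ground-truth durations", {
  m <- synthesize_motif(test_motif(), seed = 23)
  env <- compute_envelope(m$audio)
  seg <- segment_syllables(env)
  expect_equal(nrow(seg), 3L)
  expect_true(all(abs(seg$duration_ms - m$segments$duration_ms) < 5))
  expect_true(all(abs(seg$onset_s - m$segments$onset_s) < 0.005))
})

test_that("segmentation edge cases behave as documented", {
  sr <- 44100
  silence <- audio_recording(rnorm(sr, sd = 1e-4), sr)
  env <- compute_envelope(silence)
  expect_warning(seg <- segment_syllables(env, threshold = 1),
                 "no segments")
  expect_equal(nrow(seg), 0L)

  # a 3 ms dip inside a syllable is closed by the 5 ms minimum gap
  vals <- rep(0.01, 400)
  vals[100:200] <- 0.5
  vals[150:152] <- 0.001
  env2 <- structure(list(values = vals,
                         times_s = seq(0, by = 0.001,
                                       length.out = length(vals)),
                         rate_hz = 1000, smoothing_ms = 5),
                    class = "envelope")
  seg2 <- segment_syllables(env2, threshold = 0.05)
  expect_equal(nrow(seg2), 1L)
  # a 10 ms dip splits it
  vals3 <- vals
  vals3[150:160] <- 0.001
  env3 <- env2
  env3$values <- vals3
  expect_equal(nrow(segment_syllables(env3, threshold = 0.05)), 2L)
})

test_that("relative amplitude is the ratio of envelope peaks", {
  # single-harmonic syllables: fixed crest factor, so the envelope ratio
  # equals the amplitude ratio
  mot <- motif_spec(list(
    syllable_spec("harmonic", 80, f0_hz = 600, n_harmonics = 1L,
                  peak_amplitude = 0.5),
    syllable_spec("harmonic", 80, f0_hz = 600, n_harmonics = 1L,
                  peak_amplitude = 1.0)),
    gaps_ms = 60, noise_floor = 0.005)
  m <- synthesize_motif(mot, seed = 24)
  env <- compute_envelope(m$audio)
  seg <- relative_amplitude(segment_syllables(env), env)
  expect_equal(nrow(seg), 2L)
  expect_equal(max(seg$rel_amplitude), 1)
  expect_equal(min(seg$rel_amplitude), 0.5, tolerance = 0.05)
  expect_true(all(seg$rel_amplitude <= 1))
})

test_that("autocorrelation F0 recovers harmonic and pure tones", {
  sr <- 44100
  syl <- synthesize_syllable(
    syllable_spec("harmonic", 100, f0_hz = 650, peak_amplitude = 0.8),
    seed = 30)
  est <- estimate_f0(syl)
  expect_lt(abs(est$f0_hz - 650) / 650, 0.01)
  expect_gt(est$harmonicity, 0.5)

  tone <- audio_recording(sin(2 * pi * 500 * (0:8819) / sr), sr)
  est2 <- estimate_f0(tone)
  expect_lt(abs(est2$f0_hz - 500) / 500, 0.005)

  withr::with_seed(6, {
    noise <- audio_recording(rnorm(8820, sd = 0.3), sr)
    est3 <- estimate_f0(noise)
    expect_true(is.na(est3$f0_hz))
  })

  # polarity flip invariance
  flipped <- audio_recording(-syl$samples, sr)
  expect_equal(estimate_f0(flipped)$f0_hz, est$f0_hz)
})

test_that("F0 estimation validates its window and band", {
  sr <- 44100
  tone <- audio_recording(sin(2 * pi * 500 * (0:8819) / sr), sr)
  expect_error(estimate_f0(tone, f_min = 800, f_max = 700), "below")
  expect_error(estimate_f0(tone, f_max = 20000), "quarter")
  expect_error(estimate_f0(tone, f_min = 20, window_ms = 40),
               "too short")
})
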