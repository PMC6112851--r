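test_that("harmonic syllables place spectral peaks at the harmonics", {
  spec <- syllable_spec("harmonic", 200, f0_hz = 600, n_harmonics = 3L,
                        peak_amplitude = 0.8)
  a <- synthesize_syllable(spec, sample_rate = 44100, seed = 3)
  # analyse the flat part of the trapezoid only
  x <- a$samples[500:(length(a$samples) - 500)]
  peaks <- fft_peak_freqs(x, 44100, n_peaks = 3L)
  expect_equal(peaks, c(600, 1200, 1800), tolerance = 0.02)
})

test_that("syllable length and amplitude follow the specification", {
  spec <- syllable_spec("harmonic", 100, f0_hz = 500)
  a <- synthesize_syllable(spec, sample_rate = 44100, seed = 1)
  expect_lte(abs(length(a$samples) - 4410), 1)
  expect_equal(max(abs(a$samples)), 0.5, tolerance = 1e-12)

  silent <- synthesize_syllable(
    syllable_spec("noise", 50, peak_amplitude = 0), seed = 1)
  expect_true(all(silent$samples == 0))
})

test_that("aliasing precondition is enforced", {
  spec <- syllable_spec("harmonic", 100, f0_hz = 800, n_harmonics = 5L)
  expect_error(synthesize_syllable(spec, sample_rate = 8000), "aliasing")
})

test_that("motif assembly matches the arithmetic of its parts", {
  mot <- motif_spec(list(
    syllable_spec("harmonic", 80, f0_hz = 600),
    syllable_spec("noise", 120)), gaps_ms = 50, noise_floor = 0.01)
  m <- synthesize_motif(mot, seed = 2, pad_ms = 60)
  total_ms <- length(m$audio$samples) / 44100 * 1000
  expect_equal(total_ms, 80 + 50 + 120 + 2 * 60, tolerance = 0.1)
  expect_equal(m$segments$duration_ms, c(80, 120))
  expect_equal(m$segments$f0_hz, c(600, NA))
  expect_equal(m$segments$onset_s, c(0.060, 0.060 + 0.080 + 0.050),
               tolerance = 1e-6)
})

test_that("envelope contrast between syllables and gaps is large", {
  m <- synthesize_motif(test_motif(noise_floor = 0.01), seed = 4)
  env <- compute_envelope(m$audio)
  mid <- function(a, b) env$values[which.min(abs(env$times_s - (a + b) / 2))]
  syl_peak <- max(env$values)
  gap_level <- mid(m$segments$offset_s[1], m$segments$onset_s[2])
  expect_gt(syl_peak / gap_level, 20)
})

test_that("motif and gap validation reject degenerate specs", {
  expect_error(syllable_spec("harmonic", 8, f0_hz = 500, ramp_ms = 5),
               "ramp")
  expect_error(motif_spec(list(syllable_spec("noise", 50)),
                          noise_floor = 0.9), "noise_floor")
})

test_that("zero jitter yields identical renditions within a day", {
  mot <- test_motif()
  day <- synthesize_day(mot, n_renditions = 4, jitter_cv = 0,
                        f0_jitter_cv = 0, seed = 8)
  truths <- do.call(rbind, lapply(day, `[[`, "truth"))
  durs <- split(truths$duration_ms, truths$rendition)
  for (d in durs[-1]) expect_equal(d, durs[[1]])
  expect_length(synthesize_day(mot, n_renditions = 0, seed = 1), 0L)
})

test_that("day-level duration factors shift the ground truth", {
  mot <- test_motif()
  day <- synthesize_day(mot, n_renditions = 3, day_factor = 1.12,
                        jitter_cv = 0, f0_jitter_cv = 0, seed = 9)
  truths <- do.call(rbind, lapply(day, `[[`, "truth"))
  base <- vapply(mot$syllables, `[[`, numeric(1), "duration_ms")
  expect_equal(truths$duration_ms[truths$rendition == 1], base * 1.12,
               tolerance = 1e-9)
})

test_that("bout structure keeps intra-bout gaps under 500 ms", {
  day <- synthesize_day(test_motif(), n_renditions = 12, seed = 10)
  sizes <- vapply(day, function(b) length(unique(b$truth$rendition)),
                  integer(1))
  expect_true(all(sizes >= 1 & sizes <= 3))
  expect_equal(sum(sizes), 12L)
  pad_s <- 0.060
  for (b in day) {
    starts <- sort(unique(b$truth$motif_start_s))
    if (length(starts) > 1) {
      rec_ends <- vapply(starts, function(s)
        max(b$truth$offset_s[b$truth$motif_start_s == s]) + pad_s,
        numeric(1))
      gaps <- starts[-1] - head(rec_ends, -1)
      expect_true(all(gaps > 0.05 & gaps < 0.5))
    }
  }
})
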