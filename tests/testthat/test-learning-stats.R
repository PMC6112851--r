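feature_fixture <- function() {
  # two birds, one syllable, deterministic durations per period
  days <- c(55, 56, 58, 59, 60, 61, 62, 63, 90, 91)
  make_bird <- function(bird, group, durs) {
    do.call(rbind, lapply(seq_along(days), function(i)
      data.frame(bird = bird, group = group, day_dph = days[i],
                 rendition = 1:20, syllable = 1L,
                 duration_ms = durs[i] + seq(-0.95, 0.95, length.out = 20))))
  }
  rbind(
    make_bird("b1", "sham", c(100, 100, 102, 102, 104, 104, 104, 104,
                              116, 116)),
    make_bird("b2", "lesion", c(100, 100, 103, 103, 103, 103, 103, 103,
                                107, 107))
  )
}

test_that("periods are assigned by day offset from surgery", {
  f <- data.frame(bird = "b", day_dph = c(55, 56, 58, 60, 63, 70, 90, 91),
                  rendition = 1, syllable = 1, duration_ms = 100)
  out <- assign_periods(f, surgery_day = 57)
  expect_equal(as.character(out$period),
               c("pre", "pre", "post_1_2", "post_3_4", "post_5_6", NA,
                 "crystallization", "crystallization"))
})

test_that("birds without pre-period data are flagged", {
  f <- data.frame(bird = c("a", "a", "b"), day_dph = c(55, 60, 60),
                  rendition = 1, syllable = 1, duration_ms = 100)
  expect_warning(out <- assign_periods(f, surgery_day = 57), "bird")
  expect_equal(attr(out, "flagged_birds"), "b")
})

test_that("period summaries carry mean, SD, CV and n per cell", {
  f <- assign_periods(feature_fixture(), surgery_day = 57)
  s <- period_summary(f)
  cell <- s[s$bird == "b1" & s$period == "pre", ]
  expect_equal(cell$n, 40)
  expect_equal(cell$mean, 100, tolerance = 1e-9)
  expect_equal(cell$cv, cell$sd / cell$mean)
})

test_that("relative change is the absolute percent change from pre", {
  f <- assign_periods(feature_fixture(), surgery_day = 57)
  r <- relative_change(period_summary(f))
  b1 <- r[r$bird == "b1", ]
  expect_equal(b1$rel_change_pct[b1$period == "post_5_6"], 4,
               tolerance = 1e-6)
  expect_equal(b1$rel_change_pct[b1$period == "crystallization"], 16,
               tolerance = 1e-6)
  # absolute value: a decrease counts the same as an increase
  s <- period_summary(f)
  s$mean[s$bird == "b2" & s$period == "crystallization"] <- 88
  r2 <- relative_change(s)
  expect_equal(r2$rel_change_pct[r2$bird == "b2" &
                                   r2$period == "crystallization"], 12,
               tolerance = 1e-6)
})

test_that("relative change and trajectory are unit invariant", {
  f <- assign_periods(feature_fixture(), surgery_day = 57)
  f2 <- f
  f2$duration_ms <- f2$duration_ms / 1000  # express in seconds
  r1 <- relative_change(period_summary(f))
  r2 <- relative_change(period_summary(f2))
  expect_equal(r1$rel_change_pct, r2$rel_change_pct, tolerance = 1e-9)
  expect_equal(learning_trajectory(r1)$trajectory_pct,
               learning_trajectory(r2)$trajectory_pct, tolerance = 1e-9)
})

test_that("learning trajectory is crystallization minus post days 5-6", {
  f <- assign_periods(feature_fixture(), surgery_day = 57)
  tr <- learning_trajectory(relative_change(period_summary(f)))
  expect_equal(tr$trajectory_pct[tr$bird == "b1"], 12, tolerance = 1e-6)
  expect_equal(tr$trajectory_pct[tr$bird == "b2"], 4, tolerance = 1e-6)
})

test_that("coefficient of variation matches the sample-SD oracle", {
  expect_equal(coefficient_of_variation(c(5, 5, 5)), 0)
  expect_equal(coefficient_of_variation(c(90, 100, 110)), 0.1)
  x <- c(3, 7, 9, 12)
  expect_equal(coefficient_of_variation(10 * x),
               coefficient_of_variation(x))
  expect_error(coefficient_of_variation(5), "two values")
  expect_error(coefficient_of_variation(c(-2, 0, 2)), "positive")
})

test_that("normalized imitation is the crystallization/pre ratio", {
  expect_equal(normalized_imitation(0.3, 0.3), 1)
  expect_equal(normalized_imitation(0.3, 0.51), 1.7)
  expect_error(normalized_imitation(0, 0.5), "> 0")
})

test_that("lesion-size correlation matches the covariance formula", {
  rec <- data.frame(pct_intact = c(42, 48, 55, 61, 66, 70, 77, 83, 88,
                                   94),
                    normalized_score = c(1.02, 1.21, 1.08, 1.35, 1.29,
                                         1.40, 1.52, 1.48, 1.66, 1.71))
  res <- lesion_size_correlation(rec)
  x <- rec$pct_intact; y <- rec$normalized_score
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$estimate, r_oracle, tolerance = 1e-12)
  expect_equal(res$n, 10)

  lin <- data.frame(pct_intact = 1:5, normalized_score = 2 * (1:5) + 1)
  expect_equal(lesion_size_correlation(lin)$estimate, 1)
  expect_error(lesion_size_correlation(lin[1:2, ]), "at least 3")
  flat <- data.frame(pct_intact = rep(50, 5), normalized_score = 1:5)
  expect_error(lesion_size_correlation(flat), "variance")
})

test_that("spectrogram similarity score behaves as a matched filter", {
  m <- synthesize_motif(test_motif(), seed = 40)
  sr <- m$audio$sample_rate
  res_self <- spectrogram_similarity_score(list(m$audio), m$audio)
  expect_equal(res_self$mean_score, 1, tolerance = 1e-9)

  # time-shifted copy scores ~1 when the lag matches the shift
  # (shift chosen as a whole number of spectrogram hops so the frame
  # grid lines up)
  shift_n <- 104 * 128
  withr::with_seed(8, {
    shifted <- audio_recording(
      c(rnorm(shift_n, sd = 0.005), m$audio$samples,
        rnorm(50 * 128, sd = 0.005)), sr)
  })
  res_shift <- spectrogram_similarity_score(list(shifted), m$audio)
  expect_gt(res_shift$mean_score, 0.95)

  withr::with_seed(7, {
    noise <- audio_recording(rnorm(length(m$audio$samples), sd = 0.05),
                             sr)
    res_noise <- spectrogram_similarity_score(list(noise), m$audio)
    expect_lt(res_noise$mean_score, 0.3)
  })

  # symmetric under exchanging which input is slid (equal lengths)
  other <- synthesize_motif(test_motif(), seed = 41)$audio
  s_ab <- spectrogram_similarity_score(list(other), m$audio)$mean_score
  s_ba <- spectrogram_similarity_score(list(m$audio), other)$mean_score
  expect_equal(s_ab, s_ba, tolerance = 1e-6)
})

test_that("similarity sampling is seeded and sized", {
  m <- synthesize_motif(test_motif(), seed = 42)
  songs <- rep(list(m$audio), 5)
  r1 <- spectrogram_similarity_score(songs, m$audio, n_sample = 2,
                                     seed = 1)
  expect_length(r1$scores, 2L)
})
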