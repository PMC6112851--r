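test_that("flat PSTH at baseline produces no events", {
  p <- make_psth(rep(50, 100))
  expect_equal(nrow(detect_response_events(p)), 0L)
  expect_equal(classify_profile(detect_response_events(p)), "none")
  expect_true(is.na(first_response_latency(detect_response_events(p))))
})

test_that("a planted supra-threshold run is detected with exact bounds", {
  # bins [10, 14) ms above threshold, then return to baseline
  rate <- rep(50, 100)
  rate[6:7] <- 70  # bin starts 10 and 12 ms
  p <- make_psth(rate)
  ev <- detect_response_events(p)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$polarity, "excitation")
  expect_equal(ev$onset_ms, 10)
  expect_equal(ev$offset_ms, 14)
})

test_that("single isolated excursions never trigger detection", {
  rate <- rep(50, 100)
  rate[10] <- 90
  rate[30] <- 5
  p <- make_psth(rate)
  expect_equal(nrow(detect_response_events(p)), 0L)
})

test_that("detection is invariant to adding a constant to all bins", {
  pl <- plant_events(2, n_bins = 80)
  ev1 <- detect_response_events(pl$psth)
  p2 <- pl$psth
  p2$rate_hz <- p2$rate_hz + 100
  p2$baseline_mean_hz <- p2$baseline_mean_hz + 100
  ev2 <- detect_response_events(p2)
  expect_equal(ev1$onset_ms, ev2$onset_ms)
  expect_equal(ev1$offset_ms, ev2$offset_ms)
  expect_equal(ev1$polarity, ev2$polarity)
  expect_equal(ev1$strength_spikes, ev2$strength_spikes, tolerance = 1e-10)
})

test_that("strict inequality at the threshold counts as non-responsive", {
  rate <- rep(50, 50)
  rate[5:8] <- 50 + 2.5 * 2  # exactly at mean + k*SD
  p <- make_psth(rate)
  expect_equal(nrow(detect_response_events(p)), 0L)
})

test_that("artifact blanking excludes the first bins after the stimulus", {
  rate <- rep(50, 50)
  rate[1:3] <- 200  # bins [0,2), [2,4), [4,6)
  p <- make_psth(rate)
  ev <- detect_response_events(p, artifact_blank_ms = 6)
  expect_equal(nrow(ev), 0L)
  ev2 <- detect_response_events(p, artifact_blank_ms = 2)
  expect_equal(nrow(ev2), 1L)  # bins [2,4) and [4,6) remain visible
  expect_equal(ev2$onset_ms, 2)
})

test_that("response strength integrates excess rate over the event", {
  # rectangular excitation 100 Hz above baseline for 10 ms -> 1.0 spike
  rate <- rep(50, 100)
  rate[11:15] <- 150  # bin starts 20..28 ms, 10 ms total
  p <- make_psth(rate)
  ev <- detect_response_events(p)
  expect_equal(ev$onset_ms, 20)
  expect_equal(response_strength(p, ev), 1.0, tolerance = 1e-12)
  expect_equal(response_strength(p, ev, mode = "total"), 1.0,
               tolerance = 1e-12)
  expect_equal(response_strength(p, NULL), 0)
})

test_that("strength modes select first versus all excitation events", {
  rate <- rep(50, 100)
  rate[11:15] <- 150   # first excitation: 1.0 spike
  rate[41:45] <- 100   # second excitation: 0.5 spike
  p <- make_psth(rate)
  ev <- detect_response_events(p)
  expect_equal(nrow(ev), 2L)
  expect_equal(response_strength(p, ev, "first_excitation"), 1.0,
               tolerance = 1e-12)
  expect_equal(response_strength(p, ev, "total"), 1.5, tolerance = 1e-12)
})

test_that("inhibition-only events give zero strength with a note", {
  rate <- rep(50, 100)
  rate[11:15] <- 10
  p <- make_psth(rate)
  ev <- detect_response_events(p)
  expect_equal(ev$polarity, "inhibition")
  expect_lt(ev$strength_spikes, 0)
  expect_warning(s <- response_strength(p, ev), "no excitatory")
  expect_equal(s, 0)
  expect_equal(classify_profile(ev), "other")
})

test_that("peak rate is taken only inside excitation events", {
  rate <- rep(50, 100)
  rate[11:15] <- c(150, 300, 200, 150, 150)
  rate[60] <- 500  # artifact spike outside any event (single bin)
  p <- make_psth(rate)
  ev <- detect_response_events(p)
  expect_equal(nrow(ev), 1L)
  expect_equal(peak_response_rate(p, ev), 300)
  expect_error(peak_response_rate(p, NULL), "undefined")
})

test_that("first response latency is the earliest event onset", {
  ev <- data.frame(polarity = c("excitation", "inhibition"),
                   onset_ms = c(20, 30), offset_ms = c(28, 40),
                   strength_spikes = c(1, -0.5), peak_hz = c(200, 10))
  expect_equal(first_response_latency(ev), 20)
})

test_that("profile classification matches the observed taxonomy", {
  mk <- function(pol) data.frame(polarity = pol,
                                 onset_ms = seq_along(pol) * 10,
                                 offset_ms = seq_along(pol) * 10 + 5)
  expect_equal(classify_profile(mk("excitation")), "excitation_only")
  expect_equal(classify_profile(mk(c("excitation", "inhibition"))),
               "biphasic")
  expect_equal(classify_profile(mk(c("inhibition", "excitation",
                                     "inhibition"))), "triphasic")
  expect_equal(classify_profile(mk("inhibition")), "other")
  expect_equal(classify_profile(mk(c("inhibition", "excitation"))),
               "other")
})

test_that("adjacent opposite-polarity phases resolve into distinct events", {
  rate <- rep(50, 100)
  rate[11:15] <- 150  # excitation [20, 30)
  rate[16:20] <- 10   # inhibition [30, 40), no in-band gap
  p <- make_psth(rate)
  ev <- detect_response_events(p)
  expect_equal(ev$polarity, c("excitation", "inhibition"))
  expect_equal(ev$onset_ms, c(20, 30))
  expect_equal(ev$offset_ms, c(30, 40))
  expect_equal(classify_profile(ev), "biphasic")
})

test_that("zero baseline SD falls back to the Poisson threshold", {
  rate <- rep(50, 60)
  rate[6:9] <- 120
  p <- make_psth(rate, baseline_sd = 0, n_trials = 100L)
  expect_warning(ev <- detect_response_events(p), "Poisson")
  expect_true(isTRUE(attr(ev, "degenerate")))
  # fallback SD = sqrt(50 / (100 * 0.002)) = 15.8; 120 > 50 + 2.5*15.8
  expect_equal(nrow(ev), 1L)
})

test_that("percent of resting response is a simple ratio", {
  expect_equal(percent_resting_response(0.5, 1.0), 50)
  expect_equal(percent_resting_response(0, 1.0), 0)
  expect_equal(percent_resting_response(1.2, 1.2), 100)
  expect_error(percent_resting_response(0.5, 0), "> 0")
})

test_that("condition comparison handles identical paired samples", {
  x <- c(1.2, 0.8, 1.5, 0.9, 1.1, 1.3)
  expect_warning(res <- compare_conditions(x, x), "zero")
  expect_equal(res$p_value, 1)
  res2 <- compare_conditions(x, x * 0.2)
  expect_lt(res2$p_value, 0.05)
  expect_equal(res2$direction, 1)
})
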