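# Independent oracles used across the suite. These deliberately use
# different algorithms from the package (naive loops, exhaustive
# enumeration, direct FFTs) so that agreement is meaningful.

# Brute-force per-trial, per-bin PSTH rate.
brute_psth_rate <- function(times_s, onsets_s, bin_ms, pre_ms, post_ms) {
  edges <- seq(-pre_ms, post_ms, by = bin_ms)
  counts <- numeric(length(edges) - 1L)
  for (on in onsets_s) {
    for (tt in times_s) {
      rel <- (tt - on) * 1000
      if (rel >= -pre_ms && rel < post_ms) {
        b <- sum(edges <= rel)
        if (b >= 1L && b <= length(counts)) counts[b] <- counts[b] + 1
      }
    }
  }
  counts / (length(onsets_s) * bin_ms / 1000)
}

# Exhaustive two-sided signed-rank p-value (no ties, no zeros).
enum_signed_rank_p <- function(x, y) {
  d <- x - y
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.vector(signs %*% r)
  min(2 * min(mean(Ws <= W), mean(Ws >= W)), 1)
}

# Exhaustive two-sided rank-sum p-value (no ties).
enum_ranksum_p <- function(x, y) {
  stopifnot(!anyDuplicated(c(x, y)))
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  cmb <- utils::combn(nx + ny, nx)
  Ws <- colSums(matrix(seq_len(nx + ny)[cmb], nrow = nx)) -
    nx * (nx + 1) / 2
  min(2 * min(mean(Ws <= W), mean(Ws >= W)), 1)
}

# Frequencies of the strongest local maxima of the magnitude spectrum.
fft_peak_freqs <- function(x, sample_rate, n_peaks = 3L) {
  n <- length(x)
  mag <- Mod(stats::fft(x))[seq_len(n %/% 2)]
  freq <- (seq_len(n %/% 2) - 1L) * sample_rate / n
  is_peak <- mag > c(-Inf, mag[-length(mag)]) &
    mag >= c(mag[-1], -Inf)
  pk <- which(is_peak)
  pk <- pk[order(mag[pk], decreasing = TRUE)][seq_len(n_peaks)]
  sort(freq[pk])
}

# Construct a psth object directly with prescribed post-stimulus rates
# and baseline statistics (for detection tests on planted patterns).
make_psth <- function(rate_post, bin_ms = 2, pre_ms = 50,
                      baseline_mean = 50, baseline_sd = 2,
                      n_trials = 100L) {
  nb_pre <- as.integer(pre_ms / bin_ms)
  rate <- c(rep(baseline_mean, nb_pre), rate_post)
  structure(
    list(rate_hz = rate,
         bin_start_ms = seq(-pre_ms, by = bin_ms,
                            length.out = length(rate)),
         bin_ms = bin_ms, pre_ms = pre_ms,
         post_ms = length(rate_post) * bin_ms, n_trials = n_trials,
         baseline_mean_hz = baseline_mean, baseline_sd_hz = baseline_sd,
         baseline_ms = pre_ms),
    class = "psth"
  )
}

# Plant non-overlapping supra/sub-threshold runs into a flat PSTH.
# Returns the psth and the ground-truth event table. Events are
# separated by at least two in-band bins and start at bin >= 2 (after
# the artifact blank).
plant_events <- function(n_events, n_bins = 100L, bin_ms = 2,
                         baseline_mean = 50, baseline_sd = 2, k = 2.5) {
  rate <- rep(baseline_mean, n_bins)
  truth <- NULL
  cursor <- 2L  # first allowed bin (artifact blank covers bin 1)
  for (i in seq_len(n_events)) {
    gap <- sample(3:6, 1L)  # >= 2 in-band bins between planted events
    len <- sample(2:6, 1L)
    start <- cursor + gap
    if (start + len - 1L > n_bins) break
    pol <- sample(c("excitation", "inhibition"), 1L)
    amp <- runif(1, (k + 1) * baseline_sd, (k + 10) * baseline_sd)
    rate[start:(start + len - 1L)] <- baseline_mean +
      if (pol == "excitation") amp else -amp
    truth <- rbind(truth, data.frame(
      polarity = pol,
      onset_ms = (start - 1L) * bin_ms,
      offset_ms = (start - 1L + len) * bin_ms))
    cursor <- start + len - 1L
  }
  list(psth = make_psth(rate, bin_ms = bin_ms,
                        baseline_mean = baseline_mean,
                        baseline_sd = baseline_sd),
       truth = truth)
}

# Standard three-syllable test motif shared by song-feature tests.
test_motif <- function(noise_floor = 0.01) {
  motif_spec(
    list(
      syllable_spec("harmonic", 80, f0_hz = 650, peak_amplitude = 0.8),
      syllable_spec("noise", 120, peak_amplitude = 0.5),
      syllable_spec("harmonic", 100, f0_hz = 450, peak_amplitude = 1.0)
    ),
    gaps_ms = 50, noise_floor = noise_floor
  )
}
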