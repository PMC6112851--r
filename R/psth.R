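## Spike-train containers and peri-stimulus time histogram construction.

#' Spike train container
#'
#' @param times_s Spike times in seconds. Sorted on construction (with a
#'   warning if the input was unsorted); negative times are rejected.
#' @param unit_id Unit identifier.
#' @param duration_s Session duration; defaults to the last spike time.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times_s, unit_id = "unit", duration_s = NULL) {
  abort_if(!is.numeric(times_s), "`times_s` must be numeric")
  abort_if(any(times_s < 0), "spike times must be non-negative")
  if (is.unsorted(times_s)) {
    warning("spike times were unsorted; sorting", call. = FALSE)
    times_s <- sort(times_s)
  }
  duration_s <- duration_s %||% if (length(times_s)) max(times_s) else 0
  abort_if(length(times_s) > 0 && max(times_s) > duration_s,
           "spike times exceed `duration_s`")
  structure(list(unit_id = unit_id, times_s = as.numeric(times_s),
                 duration_s = duration_s),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %s: %d spikes over %.2f s (%.1f Hz)\n",
              x$unit_id, length(x$times_s), x$duration_s,
              if (x$duration_s > 0) length(x$times_s) / x$duration_s else 0))
  invisible(x)
}

#' Stimulation protocol container
#'
#' @param onsets_s Stimulation onset times in seconds, ascending.
#' @param pulse_ms Pulse duration, ms.
#' @param isi_s Nominal inter-stimulation interval, seconds (optional).
#' @param intensity_ma Stimulation intensity, mA.
#' @param condition Condition label (e.g. `"baseline"`, `"drug"`,
#'   `"washout"`).
#' @return An object of class `stim_protocol`.
#' @export
stim_protocol <- function(onsets_s, pulse_ms = 1, isi_s = NULL,
                          intensity_ma = NA_real_, condition = "baseline") {
  abort_if(!is.numeric(onsets_s) || length(onsets_s) < 1L,
           "`onsets_s` must contain at least one onset")
  abort_if(is.unsorted(onsets_s, strictly = TRUE),
           "stimulation onsets must be strictly ascending")
  structure(list(onsets_s = as.numeric(onsets_s), pulse_ms = pulse_ms,
                 isi_s = isi_s %||% if (length(onsets_s) > 1)
                   min(diff(onsets_s)) else NA_real_,
                 intensity_ma = intensity_ma, condition = condition),
            class = "stim_protocol")
}

#' Spontaneous firing rate in a window
#'
#' @param train A [spike_train()].
#' @param window Length-2 numeric `(start_s, end_s)` with `end > start`.
#' @return Firing rate in Hz (spike count / window length).
#' @export
spontaneous_rate <- function(train, window) {
  abort_if(!inherits(train, "spike_train"), "`train` must be a spike_train")
  abort_if(length(window) != 2L || window[2] <= window[1],
           "`window` must be (start, end) with end > start")
  n <- sum(train$times_s >= window[1] & train$times_s < window[2])
  n / (window[2] - window[1])
}

#' Classify a unit by its spontaneous rate
#'
#' Units firing above 25 Hz are classified as pallidal-like; units below
#' 10 Hz as low-rate (striatal-like, excluded from evoked-response
#' analysis); rates in between are left unclassified.
#'
#' @param rate_hz Spontaneous firing rate, Hz (>= 0).
#' @return One of `"pallidal"`, `"low_rate"`, `"unclassified"`.
#' @export
classify_unit <- function(rate_hz) {
  abort_if(!is_number(rate_hz) || rate_hz < 0, "`rate_hz` must be >= 0")
  if (rate_hz > 25) "pallidal" else if (rate_hz < 10) "low_rate"
  else "unclassified"
}

#' Peri-stimulus time histogram
#'
#' Bins spikes around every stimulation onset, averages counts across
#' trials and converts to firing rate. Baseline mean and SD are computed
#' across the PSTH bins that fall entirely inside the pre-stimulation
#' baseline window. Default bin width is 2 ms (single units in high-rate
#' structures); 10 ms is used for low-rate multiunit recordings to limit
#' bin-to-bin count fluctuations. Default baseline windows are likewise
#' 50 ms (high-rate) or 100 ms (low-rate).
#'
#' @param train A [spike_train()].
#' @param protocol A [stim_protocol()].
#' @param bin_ms Bin width, ms; must divide `pre_ms` and `post_ms`.
#' @param pre_ms,post_ms Analysis window around each onset, ms.
#' @param baseline_ms Baseline window length, ms (counted back from the
#'   stimulation onset; must not exceed `pre_ms`). Defaults to `pre_ms`.
#' @return An object of class `psth` with fields `rate_hz` (one value per
#'   bin), `bin_start_ms` (bin left edges, stimulation onset at 0),
#'   `bin_ms`, `pre_ms`, `post_ms`, `n_trials`, `baseline_mean_hz`,
#'   `baseline_sd_hz`, `baseline_ms`.
#' @export
compute_psth <- function(train, protocol, bin_ms = 2, pre_ms = 50,
                         post_ms = 300, baseline_ms = pre_ms) {
  abort_if(!inherits(train, "spike_train"), "`train` must be a spike_train")
  abort_if(!inherits(protocol, "stim_protocol"),
           "`protocol` must be a stim_protocol")
  abort_if(!divides(bin_ms, pre_ms) || !divides(bin_ms, post_ms),
           "`bin_ms` must divide `pre_ms` and `post_ms`")
  abort_if(baseline_ms > pre_ms, "`baseline_ms` must not exceed `pre_ms`")
  onsets <- protocol$onsets_s
  if (length(onsets) > 1L) {
    abort_if(min(diff(onsets)) < (pre_ms + post_ms) / 1000,
             "stimulation spacing is smaller than the analysis window")
  }
  edges_ms <- seq(-pre_ms, post_ms, by = bin_ms)
  n_bins <- length(edges_ms) - 1L
  counts <- integer(n_bins)
  for (on in onsets) {
    rel_ms <- (train$times_s - on) * 1000
    rel_ms <- rel_ms[rel_ms >= -pre_ms & rel_ms < post_ms]
    if (length(rel_ms)) {
      idx <- findInterval(rel_ms, edges_ms, rightmost.closed = FALSE)
      counts <- counts + tabulate(idx, nbins = n_bins)
    }
  }
  n_trials <- length(onsets)
  rate <- counts / (n_trials * bin_ms / 1000)
  starts <- edges_ms[-length(edges_ms)]
  bl <- starts >= -baseline_ms & (starts + bin_ms) <= 0
  baseline_mean <- mean(rate[bl])
  baseline_sd <- if (sum(bl) > 1) sd(rate[bl]) else 0
  structure(
    list(rate_hz = rate, bin_start_ms = starts, bin_ms = bin_ms,
         pre_ms = pre_ms, post_ms = post_ms, n_trials = n_trials,
         baseline_mean_hz = baseline_mean, baseline_sd_hz = baseline_sd,
         baseline_ms = baseline_ms),
    class = "psth"
  )
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf(
    "<psth> %d bins of %g ms (-%g..%g ms), %d trials\n  baseline %.2f +/- %.2f Hz (%g ms window)\n",
    length(x$rate_hz), x$bin_ms, x$pre_ms, x$post_ms, x$n_trials,
    x$baseline_mean_hz, x$baseline_sd_hz, x$baseline_ms))
  invisible(x)
}
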