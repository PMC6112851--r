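## Simulation of stimulation-locked spike trains: pallidal-like units with
## high spontaneous rates and rectangular excitation/inhibition kernels
## aligned to each stimulation onset. Spikes are drawn from the resulting
## inhomogeneous Poisson process by thinning, which is exact for the
## piecewise-constant rate functions used here.

#' Rectangular evoked-response kernel
#'
#' Describes one phase of a stimulation-evoked response as a rectangular
#' rate change: `amplitude_hz` is added to (excitation) or subtracted from
#' (inhibition) the baseline rate over
#' `[latency_ms, latency_ms + duration_ms)` after each stimulation onset.
#' The rectangular shape makes the expected number of excess spikes per
#' stimulation available in closed form (`amplitude * duration`), which the
#' recovery tests exploit.
#'
#' @param polarity `"excitation"` or `"inhibition"`.
#' @param latency_ms Onset latency after stimulation, ms (>= 0).
#' @param duration_ms Kernel duration, ms (> 0).
#' @param amplitude_hz Magnitude of the rate change, Hz (> 0); the polarity
#'   determines its sign.
#' @return An object of class `response_kernel`.
#' @export
response_kernel <- function(polarity = c("excitation", "inhibition"),
                            latency_ms, duration_ms, amplitude_hz) {
  polarity <- match.arg(polarity)
  abort_if(!is_number(latency_ms) || latency_ms < 0,
           "`latency_ms` must be >= 0")
  abort_if(!is_number(duration_ms) || duration_ms <= 0,
           "`duration_ms` must be > 0")
  abort_if(!is_number(amplitude_hz) || amplitude_hz <= 0,
           "`amplitude_hz` must be > 0")
  structure(list(polarity = polarity, latency_ms = latency_ms,
                 duration_ms = duration_ms, amplitude_hz = amplitude_hz),
            class = "response_kernel")
}

## Signed rate contribution of a kernel.
kernel_sign <- function(k) if (k$polarity == "excitation") 1 else -1

#' Configuration of a simulated stimulation session
#'
#' Defaults follow the stimulation protocol used for single-pulse mapping
#' of evoked responses: 1 ms pulses delivered every 1.6 s.
#'
#' @param baseline_hz Spontaneous firing rate, Hz (>= 0).
#' @param kernels List of [response_kernel()] objects applied after every
#'   stimulation onset.
#' @param n_stim Number of stimulations (>= 1).
#' @param isi_s Inter-stimulation interval, seconds.
#' @param pulse_ms Stimulation pulse duration, ms.
#' @param intensity_ma Stimulation intensity, mA (metadata only).
#' @param pre_ms,post_ms Analysis window the interval must accommodate.
#' @param seed Integer seed for reproducible generation, or `NULL`.
#' @return An object of class `ephys_sim_config`.
#' @export
ephys_sim_config <- function(baseline_hz, kernels = list(), n_stim = 100L,
                             isi_s = 1.6, pulse_ms = 1, intensity_ma = 1,
                             pre_ms = 50, post_ms = 300, seed = NULL) {
  abort_if(!is_number(baseline_hz) || baseline_hz < 0,
           "`baseline_hz` must be >= 0")
  abort_if(!is_number(n_stim) || n_stim < 1, "`n_stim` must be >= 1")
  abort_if(isi_s <= (pre_ms + post_ms) / 1000,
           "`isi_s` must exceed the analysis window (pre + post)")
  if (inherits(kernels, "response_kernel")) kernels <- list(kernels)
  for (k in kernels) {
    abort_if(!inherits(k, "response_kernel"),
             "`kernels` must be a list of response_kernel objects")
    abort_if((k$latency_ms + k$duration_ms) / 1000 > isi_s,
             "kernel extends beyond the inter-stimulation interval")
  }
  cfg <- structure(
    list(baseline_hz = baseline_hz, kernels = kernels,
         n_stim = as.integer(n_stim), isi_s = isi_s, pulse_ms = pulse_ms,
         intensity_ma = intensity_ma, pre_ms = pre_ms, post_ms = post_ms,
         seed = seed),
    class = "ephys_sim_config"
  )
  ## Reject configurations whose instantaneous rate would go negative.
  r <- evoked_rate(cfg, kernel_breakpoints(cfg))
  abort_if(any(r < 0),
           "negative instantaneous rate: inhibition amplitude exceeds ",
           "baseline rate")
  cfg
}

## Time points (s, relative to a stimulation onset) where the piecewise-
## constant rate can change, shifted inside each piece for evaluation.
kernel_breakpoints <- function(config) {
  bp <- c(0, vapply(config$kernels, function(k)
    c(k$latency_ms, k$latency_ms + k$duration_ms) / 1000, numeric(2)))
  sort(unique(c(bp))) + 1e-9
}

## Evoked rate at times `t_rel` (s) after a stimulation onset.
evoked_rate <- function(config, t_rel) {
  r <- rep(config$baseline_hz, length(t_rel))
  for (k in config$kernels) {
    on <- k$latency_ms / 1000
    off <- on + k$duration_ms / 1000
    inside <- t_rel >= on & t_rel < off
    r[inside] <- r[inside] + kernel_sign(k) * k$amplitude_hz
  }
  r
}

#' Simulate a stimulation-locked spike train
#'
#' Draws spikes from an inhomogeneous Poisson process whose rate is the
#' baseline plus the configured kernels aligned to each stimulation onset.
#' Generation uses thinning of a homogeneous Poisson process at the maximal
#' rate, which is exact for piecewise-constant rates. Stimulation onsets
#' are regular, the first one placed a full inter-stimulation interval into
#' the session so that every trial has a complete pre-stimulation baseline.
#'
#' @param config An [ephys_sim_config()].
#' @param seed Overrides `config$seed` when given.
#' @return A list with elements `train` ([spike_train()]) and `protocol`
#'   ([stim_protocol()]).
#' @export
generate_stim_spike_train <- function(config, seed = NULL) {
  abort_if(!inherits(config, "ephys_sim_config"),
           "`config` must be an ephys_sim_config")
  seed <- seed %||% config$seed
  isi <- config$isi_s
  n <- config$n_stim
  onsets <- isi * seq_len(n)
  duration <- isi * (n + 1)
  rmax <- max(evoked_rate(config, kernel_breakpoints(config)))
  times <- with_seed(seed, {
    if (rmax <= 0) numeric(0) else {
      m <- rpois(1L, rmax * duration)
      cand <- sort(runif(m, 0, duration))
      ## kernels apply only after the matching onset (first onset at isi)
      idx <- floor(cand / isi)
      t_rel <- cand - idx * isi
      rate <- ifelse(idx >= 1 & idx <= n, evoked_rate(config, t_rel),
                     config$baseline_hz)
      cand[runif(m) < rate / rmax]
    }
  })
  list(
    train = spike_train(times, unit_id = "sim_unit", duration_s = duration),
    protocol = stim_protocol(onsets, pulse_ms = config$pulse_ms,
                             isi_s = isi, intensity_ma = config$intensity_ma)
  )
}

#' Simulate a pharmacology condition series
#'
#' Generates one session per scale factor, multiplying every kernel
#' amplitude by the factor while leaving the baseline rate unchanged. A
#' factor of 1 reproduces the resting response, 0 models complete blockade;
#' the canonical three-factor series models baseline / drug / washout.
#'
#' @param config An [ephys_sim_config()].
#' @param scale_factors Numeric vector of factors in `[0, 1]`.
#' @param conditions Optional condition labels; defaults to
#'   `baseline/drug/washout` for three factors.
#' @param seed Overrides `config$seed` when given.
#' @return A list of `list(train, protocol)` sessions, one per factor, with
#'   the protocol's `condition` field set.
#' @export
generate_condition_series <- function(config, scale_factors,
                                      conditions = NULL, seed = NULL) {
  abort_if(!inherits(config, "ephys_sim_config"),
           "`config` must be an ephys_sim_config")
  if (length(scale_factors) == 0L) return(list())
  abort_if(any(scale_factors < 0 | scale_factors > 1),
           "`scale_factors` must lie in [0, 1]")
  if (is.null(conditions)) {
    conditions <- if (length(scale_factors) == 3L)
      c("baseline", "drug", "washout")
    else sprintf("condition_%d", seq_along(scale_factors))
  }
  abort_if(length(conditions) != length(scale_factors),
           "`conditions` must match `scale_factors` in length")
  seed <- seed %||% config$seed
  with_seed(seed, {
    lapply(seq_along(scale_factors), function(i) {
      f <- scale_factors[i]
      kern <- lapply(config$kernels, function(k) {
        if (f == 0) return(NULL)
        response_kernel(k$polarity, k$latency_ms, k$duration_ms,
                        k$amplitude_hz * f)
      })
      kern <- Filter(Negate(is.null), kern)
      cfg_i <- ephys_sim_config(config$baseline_hz, kern, config$n_stim,
                                config$isi_s, config$pulse_ms,
                                config$intensity_ma, config$pre_ms,
                                config$post_ms, seed = NULL)
      out <- generate_stim_spike_train(cfg_i, seed = NULL)
      out$protocol$condition <- conditions[i]
      out$scale_factor <- f
      out
    })
  })
}
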