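## Multi-bird lesion/sham cohort generation with known learning-related
## drift. Features (durations, amplitudes, fundamentals) are generated at
## the rendition level so that the learning-statistics pipeline can be
## validated by parameter recovery; waveform rendering is optional and
## reuses the motif synthesizer.

#' Drift model for lesion/sham song trajectories
#'
#' Parameterizes how syllable duration and fundamental frequency drift
#' across the experiment, and how tutor imitation improves, as a function
#' of group (sham vs lesion) and lesion size. Sham and lesion trajectories
#' differ only through these parameters. Trajectory means and SDs default
#' to the group-level values measured in juvenile lesion experiments
#' (duration learning trajectory about 12% in sham vs 4% in lesioned
#' birds; fundamental-frequency trajectories below 3% in both), used here
#' as generator settings. The mapping from lesion size to imitation
#' improvement is linear in the fraction of the lateral DCN left intact —
#' no quantitative form for this mapping is established, so it is an
#' explicit modelling choice of the generator.
#'
#' @param sham_traj_pct,sham_traj_sd Mean and SD (percent points, across
#'   syllables) of the sham duration learning trajectory.
#' @param lesion_traj_pct,lesion_traj_sd Same for the lesion group.
#' @param sham_acute_pct,lesion_acute_pct Mean acute duration drift over
#'   post days 1-6, percent.
#' @param acute_sd SD of the per-syllable acute drift, percent points.
#' @param duration_cv Rendition-to-rendition duration variability
#'   (coefficient of variation).
#' @param f0_sham_traj_pct,f0_sham_traj_sd,f0_lesion_traj_pct,f0_lesion_traj_sd
#'   Fundamental-frequency trajectory parameters, percent points.
#' @param f0_cv Rendition-to-rendition F0 variability.
#' @param imitation_pre_mean,imitation_pre_sd Pre-surgery imitation score
#'   distribution.
#' @param imitation_base,imitation_slope Normalized imitation score =
#'   `base + slope * intact_fraction + noise`; the slope carries the
#'   lesion-size dependence.
#' @param imitation_sd SD of the normalized-score noise.
#' @return An object of class `drift_model`.
#' @export
drift_model <- function(sham_traj_pct = 12.1, sham_traj_sd = 1.9,
                        lesion_traj_pct = 4.0, lesion_traj_sd = 2.7,
                        sham_acute_pct = 1.5, lesion_acute_pct = 3.0,
                        acute_sd = 1.5, duration_cv = 0.02,
                        f0_sham_traj_pct = 2.7, f0_sham_traj_sd = 1.9,
                        f0_lesion_traj_pct = 1.6, f0_lesion_traj_sd = 1.5,
                        f0_cv = 0.005,
                        imitation_pre_mean = 0.30, imitation_pre_sd = 0.03,
                        imitation_base = 0.55, imitation_slope = 1.15,
                        imitation_sd = 0.10) {
  out <- as.list(environment())
  abort_if(any(unlist(out[c("duration_cv", "f0_cv")]) < 0),
           "variability parameters must be >= 0")
  structure(out, class = "drift_model")
}

#' Cohort configuration
#'
#' Defaults mirror the juvenile lesion experiment design: 10 lesion and 6
#' sham birds, surgery around 57 days post hatch, recordings on the two
#' pre-surgery days, post days 1-6, and the crystallization days 90-91,
#' with roughly 500 motif renditions per day.
#'
#' @param n_lesion,n_sham Group sizes.
#' @param surgery_dph Surgery day (days post hatch).
#' @param recording_days Days (dph) with recordings; the default covers
#'   pre (2 days), post 1-6 and days 90-91.
#' @param renditions_per_day Motif renditions recorded per day.
#' @param n_syllables Syllables per motif (4-6 typical).
#' @param n_harmonic Number of harmonic-stack syllables among them.
#' @param intact_range Range (percent) of lateral DCN left intact for
#'   lesion birds; sham birds are 100% intact.
#' @param drift A [drift_model()].
#' @param seed Integer seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_lesion = 10L, n_sham = 6L, surgery_dph = 57L,
                          recording_days = NULL, renditions_per_day = 500L,
                          n_syllables = 5L, n_harmonic = 3L,
                          intact_range = c(40, 95), drift = drift_model(),
                          seed = NULL) {
  recording_days <- recording_days %||%
    c(surgery_dph - 2L, surgery_dph - 1L, surgery_dph + 1:6, 90L, 91L)
  abort_if(!inherits(drift, "drift_model"),
           "`drift` must be a drift_model")
  abort_if(n_harmonic > n_syllables,
           "`n_harmonic` cannot exceed `n_syllables`")
  structure(
    list(n_lesion = as.integer(n_lesion), n_sham = as.integer(n_sham),
         surgery_dph = as.integer(surgery_dph),
         recording_days = as.integer(recording_days),
         renditions_per_day = as.integer(renditions_per_day),
         n_syllables = as.integer(n_syllables),
         n_harmonic = as.integer(n_harmonic),
         intact_range = intact_range, drift = drift, seed = seed),
    class = "cohort_config"
  )
}

## Per-day duration (or F0) factor for a syllable: 1 pre-surgery,
## 1 + acute during post days, 1 + acute + trajectory at crystallization.
day_factor <- function(day, surgery, acute_frac, traj_frac) {
  if (day < surgery) 1
  else if (day >= 90) 1 + acute_frac + traj_frac
  else 1 + acute_frac
}

#' Generate a lesion/sham cohort with known ground truth
#'
#' Draws per-bird motifs (baseline syllable durations, fundamentals and
#' amplitudes), applies the drift model across recording days, and emits a
#' rendition-level feature table plus per-bird lesion records carrying the
#' ground-truth imitation scores. Lesion birds receive a lesion size drawn
#' uniformly from `intact_range`; imitation improvement correlates with
#' lesion size through the drift model's linear mapping. With
#' `render_audio = TRUE`, bout waveforms are synthesized for each bird and
#' day (expensive; intended for small cohorts).
#'
#' @param config A [cohort_config()].
#' @param what Outputs to generate: any of `"records"`, `"features"`,
#'   `"audio"`.
#' @param sample_rate Sampling rate for rendered audio.
#' @param seed Overrides `config$seed` when given.
#' @return A list with `records` (one row per bird: `bird`, `group`,
#'   `surgery_dph`, `pct_intact`, `imitation_score_pre`,
#'   `imitation_score_cryst`, `normalized_score`), `features` (one row per
#'   syllable rendition: `bird`, `group`, `day_dph`, `rendition`,
#'   `syllable`, `kind`, `duration_ms`, `rel_amplitude`, `f0_hz`), `truth`
#'   (per-bird per-syllable generating parameters) and optionally `audio`.
#' @export
generate_cohort <- function(config, what = c("records", "features"),
                            sample_rate = 44100, seed = NULL) {
  abort_if(!inherits(config, "cohort_config"),
           "`config` must be a cohort_config")
  what <- match.arg(what, c("records", "features", "audio"),
                    several.ok = TRUE)
  dm <- config$drift
  n_birds <- config$n_lesion + config$n_sham
  groups <- rep(c("lesion", "sham"), c(config$n_lesion, config$n_sham))
  with_seed(seed %||% config$seed, {
    records <- vector("list", n_birds)
    feats <- vector("list", n_birds)
    truths <- vector("list", n_birds)
    audio <- if ("audio" %in% what) list() else NULL
    for (b in seq_len(n_birds)) {
      bird <- sprintf("bird%02d", b)
      group <- groups[b]
      intact <- if (group == "lesion")
        runif(1, config$intact_range[1], config$intact_range[2]) else 100
      ns <- config$n_syllables
      kind <- rep(c("harmonic", "noise"),
                  c(config$n_harmonic, ns - config$n_harmonic))
      base_dur <- runif(ns, 50, 180)
      base_f0 <- ifelse(kind == "harmonic", runif(ns, 400, 800), NA_real_)
      amp <- runif(ns, 0.5, 1)
      amp[sample.int(ns, 1L)] <- 1
      acute_pct <- if (group == "lesion") dm$lesion_acute_pct
        else dm$sham_acute_pct
      traj_pct <- if (group == "lesion") dm$lesion_traj_pct
        else dm$sham_traj_pct
      traj_sd <- if (group == "lesion") dm$lesion_traj_sd
        else dm$sham_traj_sd
      f0_traj_pct <- if (group == "lesion") dm$f0_lesion_traj_pct
        else dm$f0_sham_traj_pct
      f0_traj_sd <- if (group == "lesion") dm$f0_lesion_traj_sd
        else dm$f0_sham_traj_sd
      acute <- pmax(rnorm(ns, acute_pct, dm$acute_sd), 0) / 100
      traj <- pmax(rnorm(ns, traj_pct, traj_sd), 0) / 100
      f0_acute <- pmax(rnorm(ns, 0.5, 0.5), 0) / 100
      f0_traj <- pmax(rnorm(ns, f0_traj_pct, f0_traj_sd), 0) / 100
      truths[[b]] <- data.frame(
        bird = bird, group = group, pct_intact = intact,
        syllable = seq_len(ns), kind = kind, base_duration_ms = base_dur,
        base_f0_hz = base_f0, acute_frac = acute, traj_frac = traj,
        f0_traj_frac = f0_traj)
      if ("features" %in% what || "audio" %in% what) {
        day_rows <- lapply(config$recording_days, function(day) {
          nr <- config$renditions_per_day
          dfac <- vapply(seq_len(ns), function(s)
            day_factor(day, config$surgery_dph, acute[s], traj[s]),
            numeric(1))
          ffac <- vapply(seq_len(ns), function(s)
            day_factor(day, config$surgery_dph, f0_acute[s], f0_traj[s]),
            numeric(1))
          dur <- rep(base_dur * dfac, each = nr) *
            (1 + rnorm(nr * ns, sd = dm$duration_cv))
          f0 <- rep(base_f0 * ffac, each = nr) *
            (1 + rnorm(nr * ns, sd = dm$f0_cv))
          ra <- pmin(rep(amp, each = nr) *
                       (1 + rnorm(nr * ns, sd = 0.02)), 1)
          data.frame(bird = bird, group = group, day_dph = day,
                     rendition = rep(seq_len(nr), times = ns),
                     syllable = rep(seq_len(ns), each = nr),
                     kind = rep(kind, each = nr),
                     duration_ms = dur, rel_amplitude = ra, f0_hz = f0)
        })
        feats[[b]] <- do.call(rbind, day_rows)
      }
      if ("audio" %in% what) {
        syl_specs <- lapply(seq_len(ns), function(s) {
          if (kind[s] == "harmonic")
            syllable_spec("harmonic", duration_ms = base_dur[s],
                          f0_hz = base_f0[s], peak_amplitude = amp[s])
          else syllable_spec("noise", duration_ms = base_dur[s],
                             peak_amplitude = amp[s])
        })
        mot <- motif_spec(syl_specs, gaps_ms = 50)
        audio[[bird]] <- lapply(config$recording_days, function(day) {
          synthesize_day(mot, n_renditions = config$renditions_per_day,
                         day_factor = day_factor(day, config$surgery_dph,
                                                 mean(acute), mean(traj)),
                         jitter_cv = dm$duration_cv,
                         f0_factor = day_factor(day, config$surgery_dph,
                                                mean(f0_acute),
                                                mean(f0_traj)),
                         f0_jitter_cv = dm$f0_cv,
                         sample_rate = sample_rate, day_dph = day)
        })
        if (!is.null(audio[[bird]]))
          names(audio[[bird]]) <- as.character(config$recording_days)
      }
      pre <- max(rnorm(1, dm$imitation_pre_mean, dm$imitation_pre_sd),
                 0.05)
      norm_score <- max(dm$imitation_base +
                          dm$imitation_slope * intact / 100 +
                          rnorm(1, sd = dm$imitation_sd), 0.05)
      records[[b]] <- data.frame(
        bird = bird, group = group, surgery_dph = config$surgery_dph,
        pct_intact = intact, imitation_score_pre = pre,
        imitation_score_cryst = pre * norm_score,
        normalized_score = norm_score)
    }
    out <- list(records = do.call(rbind, records),
                truth = do.call(rbind, truths),
                config = config)
    if ("features" %in% what) out$features <- do.call(rbind, feats)
    if ("audio" %in% what) out$audio <- audio
    out
  })
}
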