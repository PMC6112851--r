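## End-to-end orchestration: each subcommand composes the module functions
## on file inputs/outputs, logs per-stage counts, and writes a manifest
## that makes the run reproducible (config snapshot, seed, checksums).

pipeline_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

write_manifest <- function(out_dir, command, config, files) {
  manifest <- list(
    command = command,
    software = paste0("finchsong ",
                      as.character(utils::packageVersion("finchsong"))),
    seed = config$seed %||% NA,
    config = config,
    outputs = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f))))
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  manifest
}

default_run_config <- function() {
  list(
    seed = 1L,
    ephys = list(baseline_hz = 35, n_stim = 100L, isi_s = 1.6,
                 pulse_ms = 1, intensity_ma = 1,
                 kernels = list(list(polarity = "excitation",
                                     latency_ms = 20, duration_ms = 10,
                                     amplitude_hz = 100))),
    psth = list(bin_ms = 2, pre_ms = 50, post_ms = 300, k = 2.5,
                artifact_blank_ms = 2, search_ms = c(0, 300)),
    song = list(peak_threshold = 0.6, similarity_threshold = 0.5,
                smoothing_ms = 5, f_min = 300, f_max = 1500,
                harmonicity_threshold = 0.5),
    cohort = list(n_lesion = 10L, n_sham = 6L, surgery_dph = 57L,
                  renditions_per_day = 500L),
    stats = list(correction = "holm")
  )
}

#' Load a pipeline run configuration
#'
#' Reads a YAML configuration and merges it over the package defaults, so
#' a config file only needs to state what it changes.
#'
#' @param path YAML file, or `NULL` for the defaults.
#' @return A nested configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- modifyList(cfg, user)
  }
  cfg
}

kernels_from_config <- function(klist) {
  lapply(klist, function(k)
    response_kernel(k$polarity, k$latency_ms, k$duration_ms,
                    k$amplitude_hz))
}

#' Run a pipeline subcommand
#'
#' Composes the package modules into file-based stages:
#' * `simulate-ephys`: simulate a stimulation session, write spike and
#'   stimulation CSVs plus ground truth JSON.
#' * `analyze-ephys`: read spike/stimulation CSVs, build PSTHs, detect and
#'   classify responses, write a per-unit/condition response table.
#' * `simulate-cohort`: generate a lesion/sham cohort feature table and
#'   records.
#' * `report-learning`: summarize features into periods, relative changes,
#'   trajectories and group statistics.
#' * `analyze-song`: segment WAV recordings against a template motif and
#'   write the syllable feature table.
#'
#' Every command writes its outputs plus a `manifest.json` (config
#' snapshot, seed, output checksums) into `out_dir`; identical config and
#' seed reproduce identical outputs.
#'
#' @param command Subcommand name (see above).
#' @param config Configuration list from [read_run_config()] (or a YAML
#'   path).
#' @param out_dir Output directory (created if needed).
#' @param inputs Named list of input paths, as required per command:
#'   `spikes`, `stims` (analyze-ephys); `features`, `cohort`
#'   (report-learning); `audio` (directory) and `template` (WAV)
#'   (analyze-song).
#' @return The run manifest, invisibly.
#' @export
run_pipeline <- function(command, config = NULL, out_dir = ".",
                         inputs = list()) {
  if (is.character(config)) config <- read_run_config(config)
  config <- config %||% default_run_config()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  if (command == "simulate-ephys") {
    ec <- config$ephys
    cfg <- ephys_sim_config(ec$baseline_hz,
                            kernels_from_config(ec$kernels),
                            n_stim = ec$n_stim, isi_s = ec$isi_s,
                            pulse_ms = ec$pulse_ms,
                            intensity_ma = ec$intensity_ma,
                            seed = config$seed)
    sim <- generate_stim_spike_train(cfg)
    pipeline_log(command, "%d spikes, %d stimulations",
                 length(sim$train$times_s), length(sim$protocol$onsets_s))
    files <- c(
      write_spike_csv(sim$train, file.path(out_dir, "spikes.csv")),
      write_stim_csv(sim$protocol, file.path(out_dir, "stims.csv")))
    truth_path <- file.path(out_dir, "ground_truth.json")
    jsonlite::write_json(list(kernels = ec$kernels,
                              baseline_hz = ec$baseline_hz),
                         truth_path, auto_unbox = TRUE, digits = NA)
    files <- c(files, truth_path)
  } else if (command == "analyze-ephys") {
    trains <- read_spike_csv(inputs$spikes)
    protocols <- read_stim_csv(inputs$stims)
    pc <- config$psth
    rows <- list()
    for (uid in names(trains)) {
      for (cond in names(protocols)) {
        psth <- compute_psth(trains[[uid]], protocols[[cond]],
                             bin_ms = pc$bin_ms, pre_ms = pc$pre_ms,
                             post_ms = pc$post_ms)
        ev <- detect_response_events(psth, k = pc$k,
                                     artifact_blank_ms =
                                       pc$artifact_blank_ms,
                                     search_window_ms = pc$search_ms)
        rows[[paste(uid, cond)]] <- data.frame(
          unit_id = uid, condition = cond,
          label = classify_profile(ev),
          latency_ms = first_response_latency(ev),
          strength_spikes = response_strength(psth, ev),
          peak_hz = if (any(ev$polarity == "excitation"))
            peak_response_rate(psth, ev) else NA_real_,
          spontaneous_hz = psth$baseline_mean_hz)
      }
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    pipeline_log(command, "%d unit x condition responses", nrow(tab))
    files <- write_table_csv(tab, file.path(out_dir, "responses.csv"))
  } else if (command == "simulate-cohort") {
    cc <- config$cohort
    cfg <- cohort_config(n_lesion = cc$n_lesion, n_sham = cc$n_sham,
                         surgery_dph = cc$surgery_dph,
                         renditions_per_day = cc$renditions_per_day,
                         seed = config$seed)
    coh <- generate_cohort(cfg)
    pipeline_log(command, "%d birds, %d feature rows",
                 nrow(coh$records), nrow(coh$features))
    files <- c(
      write_table_csv(coh$features, file.path(out_dir, "features.csv")),
      write_table_csv(coh$records, file.path(out_dir, "cohort.csv")),
      write_table_csv(coh$truth, file.path(out_dir, "truth.csv")))
  } else if (command == "report-learning") {
    feats <- read_features_csv(inputs$features)
    cohort <- read_cohort_csv(inputs$cohort)
    sday <- setNames(cohort$surgery_dph, cohort$bird)
    grp <- setNames(cohort$group, cohort$bird)
    feats$group <- unname(grp[as.character(feats$bird)])
    feats <- assign_periods(feats, sday)
    summ <- period_summary(feats)
    rel <- relative_change(summ)
    traj <- learning_trajectory(rel)
    stats <- run_test(traj$trajectory_pct[traj$group == "lesion"],
                      traj$trajectory_pct[traj$group == "sham"],
                      kind = "wilcoxon_ranksum")
    if (all(c("pct_intact", "normalized_score") %in% names(cohort))) {
      stats <- rbind(stats[, c("test", "statistic", "p_value", "n")],
                     lesion_size_correlation(
                       cohort[cohort$group == "lesion", , drop = FALSE]
                     )[, c("test", "statistic", "p_value", "n")])
    }
    if (identical(config$stats$correction, "holm"))
      stats <- holm_adjust(stats)
    pipeline_log(command, "%d summary cells, %d trajectories",
                 nrow(summ), nrow(traj))
    files <- c(
      write_table_csv(summ, file.path(out_dir, "period_summary.csv")),
      write_table_csv(rel, file.path(out_dir, "relative_change.csv")),
      write_table_csv(traj, file.path(out_dir, "trajectories.csv")),
      write_table_csv(stats, file.path(out_dir, "stats.csv")))
    report <- file.path(out_dir, "report.json")
    jsonlite::write_json(
      list(n_birds = nrow(cohort), n_trajectories = nrow(traj),
           group_test = as.list(stats[1L, ])),
      report, auto_unbox = TRUE, digits = NA)
    files <- c(files, report)
  } else if (command == "analyze-song") {
    sc <- config$song
    template <- motif_template(read_wav(inputs$template),
                               smoothing_ms = sc$smoothing_ms)
    wavs <- sort(list.files(inputs$audio, pattern = "\\.wav$",
                            full.names = TRUE))
    rows <- list()
    for (w in wavs) {
      audio <- read_wav(w)
      cand <- detect_motif_candidates(audio, template,
                                      peak_threshold = sc$peak_threshold)
      cand <- filter_by_spectral_similarity(
        audio, cand, template, threshold = sc$similarity_threshold)
      acc <- cand[cand$accepted, , drop = FALSE]
      env <- compute_envelope(audio, smoothing_ms = sc$smoothing_ms)
      for (i in seq_len(nrow(acc))) {
        seg <- segment_syllables(env, c(acc$start_s[i], acc$end_s[i]))
        if (nrow(seg) == 0L) next
        seg <- relative_amplitude(seg, env, c(acc$start_s[i],
                                              acc$end_s[i]))
        sr <- audio$sample_rate
        f0 <- vapply(seq_len(nrow(seg)), function(j) {
          i1 <- max(1L, as.integer(round(seg$onset_s[j] * sr)))
          i2 <- min(length(audio$samples),
                    as.integer(round(seg$offset_s[j] * sr)))
          est <- estimate_f0(audio$samples[i1:i2], sample_rate = sr,
                             f_min = sc$f_min, f_max = sc$f_max,
                             harmonicity_threshold =
                               sc$harmonicity_threshold)
          est$f0_hz
        }, numeric(1))
        rows[[length(rows) + 1L]] <- data.frame(
          file = basename(w), motif = i, syllable = seq_len(nrow(seg)),
          onset_s = seg$onset_s, offset_s = seg$offset_s,
          duration_ms = seg$duration_ms,
          rel_amplitude = seg$rel_amplitude, f0_hz = f0)
      }
      pipeline_log(command, "%s: %d candidates, %d accepted",
                   basename(w), nrow(cand), nrow(acc))
    }
    tab <- if (length(rows)) do.call(rbind, rows) else
      data.frame(file = character(0))
    files <- write_table_csv(tab, file.path(out_dir, "segments.csv"))
  } else {
    stop("unknown pipeline command: ", command, call. = FALSE)
  }
  invisible(write_manifest(out_dir, command, config, files))
}
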