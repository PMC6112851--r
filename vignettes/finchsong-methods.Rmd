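---
title: "Methods: evoked-response detection and song-learning analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evoked-response detection and song-learning analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finchsong)
```

`finchsong` bundles two analysis chains that are usually run together in
studies of the songbird cerebello-basal-ganglia circuit: (i) detection
and quantification of electrical-stimulation-evoked responses in
extracellular recordings from the song-related basal ganglia (Area X)
and its downstream nuclei, and (ii) quantification of juvenile song
learning from continuous audio recordings. Because in-vivo recordings of
this kind are rarely deposited, the package ships a fully seeded
synthetic-data generator whose ground truth lets every stage be
validated by parameter recovery. This vignette describes the models,
the tunable parameters and the design decisions.

## Evoked-response analysis

### The PSTH and the baseline band

All evoked-response measures derive from the peri-stimulus time
histogram (PSTH): spikes are binned around every stimulation onset,
counts are averaged over trials and converted to rate. The bin width is
2 ms for single units in structures with high spontaneous rates (Area X
pallidal-like neurons, RA) and 10 ms for low-rate multiunit recordings
(LMAN, MMAN), where wider bins limit bin-to-bin count fluctuations. The
baseline mean and SD are computed *across the PSTH bins* that fall
entirely inside the pre-stimulation baseline window — 50 ms for the
high-rate case, 100 ms for the low-rate case.

A response is a run of at least two consecutive bins strictly above
(excitation) or below (inhibition) the baseline mean ± 2.5 SD, and it
ends on the return of two consecutive bins inside that band. Ties at
exactly the threshold count as non-responsive. Three consequences of
this rule are worth spelling out:

* **Adjacent phases.** Biphasic and triphasic responses have phases
  that run directly into each other with no return to the baseline
  band in between. Under a literal reading of the end rule such an
  event would never end inside the opposite excursion, so the detector
  also terminates an event when a run of `min_consecutive` bins beyond
  the *opposite* threshold begins, opening a new event of the opposite
  polarity at that bin. Isolated single bins of either polarity never
  start, end or split an event.
* **Merging.** Two same-polarity excursions separated by a *single*
  in-band bin are one event — the end rule needs two consecutive
  in-band bins. This is intended: brief dips inside a sustained
  response do not fragment it.
* **False events.** With 2 ms bins, a 300 ms search window holds 150
  bins, and the baseline SD is estimated from only 25 bins; downward
  noise in that estimate occasionally admits a spurious two-bin event.
  The search window (`search_window_ms`, default 0–300 ms, chosen to
  cover latencies up to the late ~125 ms LMAN peak plus offsets) should
  be set to cover the latencies that are physiologically plausible for
  the preparation; the profile-classification validation uses 0–100 ms
  for kernels that all end by 75 ms.

Detection ignores bins starting within `artifact_blank_ms` (default
2 ms) after the stimulus onset; stimulation artifacts produce a blind
period whose exact extent depends on the recording chain, so the value
is configurable. When a silent baseline makes the SD zero, the
threshold falls back to the Poisson standard error of the baseline rate
estimate, `sqrt(mean / (n_trials * bin_s))`, and the result is flagged
degenerate.

### Response measures

* **Latency**: time from stimulation onset to the onset of the first
  (excitatory or inhibitory) event.
* **Strength**: sum over the response bins of (rate − baseline mean) ×
  bin width, i.e. excess spikes per stimulation. For single units the
  first excitatory peak only is integrated (`mode =
  "first_excitation"`); for low-rate multiunit recordings with bimodal
  responses all excitatory peaks are summed (`mode = "total"`).
  Inhibition-only responses are computed with negative strength but
  classified as `"other"`; whether such responses should enter strength
  summaries is left to the caller.
* **Peak rate**: maximal PSTH value inside the excitatory events.
* **Profile**: the ordered polarity sequence mapped onto
  `excitation_only` / `biphasic` (excitation → inhibition) /
  `triphasic` (inhibition → excitation → inhibition); everything else
  is `other`.
* **Percent of resting response**: condition strength as a percentage
  of the resting strength, the standard summary for local drug
  application (blockade, dispersion controls, washout).

Condition comparisons use the paired Wilcoxon signed-rank test (same
units under both conditions). Identical paired samples (all-zero
differences) return p = 1 with a warning rather than an error, so null
comparisons are reported rather than silently dropped.

### The spike-train generator

Synthetic sessions draw spikes from an inhomogeneous Poisson process:
baseline rate plus rectangular excitation/inhibition kernels aligned to
each stimulation onset. Rectangular kernels were chosen because their
expected strength has the closed form amplitude × duration, giving
analytic targets for recovery tests (a 100 Hz × 10 ms kernel adds
exactly 1.0 spikes per stimulation). Spikes are generated by thinning a
homogeneous process at the maximal rate, which is exact for
piecewise-constant rates. Configurations whose instantaneous rate would
go negative (inhibition deeper than baseline) are rejected at
construction. The default protocol mirrors single-pulse mapping
experiments: 1 ms pulses every 1.6 s. The first onset is placed one
full interval into the session so every trial has a complete baseline.

## Song analysis

### Envelope, motifs and bouts

The amplitude envelope is the RMS of the waveform over a sliding 5 ms
window, evaluated on a 1 kHz grid. The window length is a compromise:
it must resolve inter-syllable gaps down to ~10 ms while rejecting
carrier ripple for fundamentals of 400 Hz and above; it is
configurable.

Putative motifs are local maxima of the normalized (Pearson) sliding
cross-correlation between the recording's envelope and the envelope of
a clean, pre-selected template motif, above a configurable threshold
(default 0.6), with non-maximum suppression over one template length so
overlapping candidates produce a single detection. Candidates are then
sorted by spectral similarity: the peak over time lag of the normalized
2-D cross-correlation between candidate and template spectrograms
(256-point Hanning windows, 128-point steps), computed on
log-magnitudes with the per-frame mean removed so that the measure
reflects spectral shape rather than loudness and is invariant to global
gain. The acceptance threshold (default 0.5) is an experimenter-set
configuration value, not a constant of the method. Accepted occurrences
separated by less than 500 ms of silence are grouped into song bouts; a
gap of exactly 500 ms starts a new bout.

### Syllable segmentation

Within a motif window, the segmentation threshold derives from the
quietest point of the smoothed envelope — the deepest inter-syllable
gap, i.e. the smallest amplitude in the motif — inflated by a 10%
margin and floored at 3 × the background level (default: 5th percentile
of the envelope). The margin and floor make the minimum-envelope rule
robust to recording noise; both factors are configurable, and an
absolute threshold can be supplied instead. Syllable boundaries are the
threshold crossings (linearly interpolated between envelope samples);
intervals are half-open `[onset, offset)` in seconds from recording
start. Sub-threshold dips shorter than 5 ms are closed and
supra-threshold runs shorter than 10 ms discarded — both suppress
threshold chatter and are configurable. Relative syllable amplitude is
the peak envelope in the syllable divided by the peak envelope over the
motif.

Because segmentation is threshold-based, measured durations inherit a
small bias from envelope smoothing (the RMS window spreads energy
±2.5 ms at the defaults); on synthesized motifs with 5 ms trapezoid
ramps the recovered durations stay within 5 ms of ground truth, which
is the tolerance the validation suite enforces.

### Fundamental frequency

F0 is estimated per syllable from the normalized autocorrelation over
lags corresponding to a 300–1500 Hz search band (the zebra finch
harmonic-stack range), in one 40 ms window centered in the segment by
default; syllables with several sub-syllabic elements of distinct
fundamental can be measured by passing several window centers. The
fundamental is the inverse of the lag of the highest autocorrelation
peak, refined by parabolic interpolation; when several peaks come
within 5% of the maximum the shortest lag wins, which suppresses octave
errors for strictly periodic signals. A window whose peak correlation
falls below 0.5 of the zero-lag value is considered non-harmonic and
yields `NA` — noise syllables are thus excluded automatically. The
estimate is invariant to polarity flips.

### The song synthesizer

Synthetic syllables are either harmonic stacks (sums of sinusoids at
integer multiples of F0, amplitudes decaying by 0.8 per harmonic,
random phases) or band-limited noise bursts, both under a trapezoidal
envelope with 5 ms ramps — sharp enough to give unambiguous
threshold-crossing ground truth. Motifs concatenate syllables with
fixed gaps, pad both ends, and add white background noise. Recording
days generate renditions with a day-level duration factor plus
independent rendition jitter, grouped into bouts of 1–3 motifs with
intra-bout silences drawn from 100–450 ms — deliberately exercising
both sides of the 500 ms bout rule.

What the generator does *not* emulate: cage noise and wing flaps,
amplitude modulation within syllables, frequency sweeps, vocal-tract
resonances, or any biophysics of song production. Passing recovery
tests therefore demonstrates the correctness of the analysis chain on
well-posed inputs, not its robustness to every artifact of real
recordings; the configurable thresholds exist precisely because real
data need tuning.

## Learning statistics

### Periods, relative change, trajectory

Feature rows are grouped into two-day periods relative to each bird's
surgery day: `pre` (the two days before surgery), `post_1_2`,
`post_3_4`, `post_5_6`, and `crystallization` (days 90–91 post hatch).
The relative change of a feature is `100 × |post_mean / pre_mean − 1|`
— an absolute percent change. The absolute value is used because drift
direction is idiosyncratic per syllable; the signed ratio is also
emitted for audit. The learning trajectory is the signed difference
between the relative change at crystallization and at post days 5–6
(the acute post-surgery period is excluded so the trajectory reflects
learning-related change, not transient surgery effects). Both measures
are invariant to the feature's units. Rendition-to-rendition
variability is summarized by the coefficient of variation (sample
SD/mean).

Group contrasts (lesion vs sham syllables) use the Wilcoxon rank-sum
test: the groups contain different birds, so the paired variant is not
applicable. Rank tests use the exact small-sample null when the sample
is small and untied, and a tie-corrected normal approximation
otherwise. Families of tests can be Holm-adjusted; the family is
declared by the caller (the pipeline's default family is the
group-contrast plus the lesion-size correlation).

### Imitation and lesion-size correlation

Tutor-imitation quality is summarized by the normalized imitation
score: score at crystallization divided by the pre-surgery score.
The scorer itself is pluggable; the package provides a spectrogram
cross-correlation similarity (peak over time lag of the normalized
correlation between log-magnitude spectrograms), with seeded random
sampling when more bouts are available than requested (50–100 clean
bouts is typical practice). The association between lesion extent and
imitation improvement is the Pearson correlation between the percentage
of the lateral DCN left intact and the normalized score, with the
p-value for the null hypothesis of no correlation.

### The cohort generator

The cohort generator produces per-bird, per-rendition feature tables
(and optionally audio) under a drift model. Design choices, several of
which fill gaps no published quantitative model covers:

* Duration learning trajectories are drawn per syllable from group
  level normal distributions — sham 12.1 ± 1.9%, lesion 4.0 ± 2.7%
  (mean ± SD across syllables); F0 trajectories 2.7 ± 1.9% vs
  1.6 ± 1.5%. These group values match published juvenile
  lesion-cohort measurements and act as generator settings.
* Acute drift (post days 1–6) is small (1.5% sham, 3% lesion ± 1.5)
  and separate from the trajectory, so the post 5–6 baseline and the
  crystallization endpoint are controlled independently.
* Duration drift is applied multiplicatively to all syllables of a
  bird, matching the pooling of syllable types after normalization.
* Rendition-to-rendition noise defaults to CV 0.02 for duration and
  0.005 for F0 — the stereotypy range of crystallizing zebra finch
  song.
* The mapping from lesion size to imitation improvement has no
  established functional form; the generator uses a linear model,
  normalized score = 0.55 + 1.15 × (fraction intact) + N(0, 0.10),
  which yields sham scores near 1.7 and a strong positive correlation
  (r ≈ 0.85 across 10 lesion birds with 40–95% intact). This is an
  explicit modelling choice, not an estimate from data.
* Default design: 10 lesion and 6 sham birds, surgery at 57 days post
  hatch, recordings on the two pre days, post days 1–6 and days 90–91,
  500 renditions per day.

`generate_cohort(what = "records")` skips feature generation for
Monte-Carlo studies that only need the per-bird records; audio
rendering (`what = "audio"`) reuses the motif synthesizer and is
intended for small cohorts.

## Numerical choices and problem sizes

* All randomness flows through per-call seeds (`withr::with_seed`), so
  fixed seeds give byte-identical outputs and generators never disturb
  the caller's RNG state.
* Bin divisibility is checked to 1e-8 relative tolerance; envelope
  crossings and autocorrelation peaks are refined by linear and
  parabolic interpolation respectively.
* The validation suite sizes its simulations to run on a single CPU in
  minutes: 200 random PSTH instances against a brute-force counter,
  100 planted-event constructions, 20 × 500-trial kernel-recovery
  sessions, 100 profile-classification runs, 10,000 null rank-test
  simulations, a 200-rendition six-syllable corpus, 50 effect and 200
  null cohorts, and 100 correlation cohorts. The acceptance script
  reports the same quantities at moderately reduced sizes (10 recovery
  seeds, 60 classification runs, 4,000 null simulations, 60
  renditions).

## Known limitations

* The detector's two-bin rule with a 2.5 SD band has a non-trivial
  false-event rate over long search windows when the baseline SD is
  estimated from few bins; restrict the search window or raise `k` for
  exploratory scans.
* Syllable types are matched positionally within accepted motifs; no
  spectral clustering of syllable types across renditions is
  attempted.
* The imitation scorer is a single-feature spectral similarity; it is
  a stand-in interface for richer published scorers that combine
  acoustic and sequencing similarity, and the normalized-score
  analysis accepts any external scorer's output.
* WAV support covers mono PCM-16 and float-32 only.
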