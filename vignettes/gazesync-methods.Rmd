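---
title: "Dual-EEG analysis of gaze-onset synchrony: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-EEG analysis of gaze-onset synchrony: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazesync)
```

## The scientific problem

During naturalistic infant–caregiver interaction, either partner may shift
gaze towards the other. Each such *gaze onset* defines two roles: the
**sender** (who shifts) and the **receiver** (whose gaze state is unchanged
at that moment), and two types: **mutual** (the receiver was already looking
at the sender) or **non-mutual**. A long-standing hypothesis holds that
mutual-gaze onsets reset the ongoing oscillatory phase in *both* brains,
thereby creating inter-brain synchrony. Testing this requires simultaneous
(hyperscanning) EEG from both partners, time-locked analyses around
naturally occurring onsets, and careful null distributions, because phase
statistics are biased by data quantity, evoked transients and eye-movement
artifacts.

`gazesync` implements that full analysis stack — preprocessing,
time–frequency decomposition, three synchrony statistics, surrogate and
permutation inference, ERP measurement, and cohort-level pipelines —
together with a synthetic dyadic-EEG generator with controllable ground
truth, so every stage is testable without access to human recordings.

## The synthetic world

`sim_config()` describes one dyad. Its defaults state the study conditions:

* **Behaviour.** Gaze is coded at 50 Hz over three states (partner, puppet,
  inattentive). Each partner follows an independent semi-Markov chain:
  dwell times are truncated normal (floor 0.2 s, preventing implausibly
  brief fixations), and the embedded chain switches uniformly among the
  other states. With uniform switching, occupancy is proportional to mean
  dwell, so the default dwell means are scaled to hit the reported occupancy
  (infant 34/31/35%, adult 62/31/7%) while matching the reported onset
  counts (about 31 infant and 44 adult partner-look onsets per 386 s
  session, of which roughly 62% / 34% respectively are mutual). Dwell SDs
  default to mean/3, the ratio of the reported mutual-look statistics
  (2.7 s, SD 0.9 s).
* **EEG.** 32 channels (10–20 layout) at 512 Hz: `1/f` noise (spectral
  synthesis) plus per-band oscillators (defaults 4 and 8 Hz — one inside
  each analysis band) whose phase drifts as a random walk
  (`osc_drift_sd` = 1.5 rad/sqrt(s), giving phase decorrelation over a few
  seconds, long enough that 1-s windows see quasi-stationary phase, short
  enough that dyads decorrelate between looks).
* **Ground-truth responses.** At each sender onset the sender's occipital
  channels may receive an additive ERP template (Gaussian components:
  +5 µV at 120 ms, −6 µV at 290 ms, +4 µV at 450 ms for infants; 100 ms
  earlier for adults — fixture conventions within the populations' component
  windows, not empirical claims) and/or a phase reset. The reset pulls the
  oscillator phase toward a target angle with weight `reset_strength`,
  interpolated circularly over a 50 ms ramp. The ramp matters: an abrupt
  phase jump creates an amplitude discontinuity that a wavelet reads as
  broadband power change, confounding inter-trial coherence with an evoked
  artifact. `mutual_reset_strength` resets *both* partners at mutual onsets
  only — the dual phase-resetting mechanism under test.
* **Coupling.** `coupling = list(type = "directed", from, lag, gain)` adds a
  lagged, scaled copy of one partner's central-channel signal into the
  other's (a Granger-causal ground truth); `type = "common_driver"` adds a
  shared oscillator to both (optionally during mutual gaze only).
* **Artifacts.** Optional biphasic frontal transients within ±150 ms of
  sender onsets mimic saccade potentials.

What the generator does **not** emulate: behavioural contingency between
partners (timelines are independent, so non-mutual time is more plentiful
than in real interactions, where partners react to each other), volume
conduction and ocular dipoles, non-stationary noise, and developmental
differences beyond ERP latencies. A green test therefore establishes that
the *analysis machinery* behaves correctly in a controlled world, not that
the biological conclusions transfer.

## Preprocessing

The cleaning rules are deterministic and order-stable:

* `bandpass_filter()` — zero-phase frequency-domain filter, unity gain in
  1–20 Hz with raised-cosine transitions (`[low/2, low]`, `[high, 1.5·high]`),
  ≥ 20 dB down one octave outside the band; signals are reflection-padded.
  Analyses use 2–18 Hz wavelets inside the 1–20 Hz cleaning band.
* `robust_average_reference()` — subtracts the per-sample cross-channel
  median.
* `interpolate_bad_channels()` — a channel correlating below 0.7 with the
  leave-one-out median of the others is replaced by the mean of its four
  nearest good neighbours (montage distance). More than half flagged aborts.
* `reject_highpower_segments()` — non-overlapping 1-s epochs are rejected
  when more than 70% of channels exceed their own mean epoch power + 5 SD.
  The printed rule does not say whether the 5-SD statistic is per-channel or
  pooled; this implementation is per-channel with the 70%-of-channels vote,
  and the choice is surfaced here deliberately. The resulting mask is
  honoured by every downstream epoching/segmentation call.
* `extract_event_epochs()` — −2.5 to +2.5 s around each onset, both partners
  sliced at identical clock samples (`round(onset × fs)`); trials touching
  an edge or a masked sample are dropped and logged.
* `segment_by_gaze_state()` / `match_condition_counts()` — per-look segments
  for mutual (both on partner) and non-mutual (exactly one) gaze; the larger
  condition is truncated to the first *n* samples/trials of the smaller,
  reading the 1:n subsampling rule literally (truncation, not random
  subsampling, so the operation is deterministic and idempotent).

## Time–frequency decomposition

`morlet_decompose()` convolves with complex Morlet wavelets on the study
grid: 2–18 Hz in 17 linear steps, 3→10 cycles log-spaced, support truncated
at ±4σ_t. Kernels are amplitude-calibrated (scaled by `2/sum(envelope)`) so
a unit sinusoid at a matched frequency yields unit coefficient magnitude —
this, rather than unit-energy scaling, makes the amplitude-recovery contract
testable; phases are unaffected by either choice. An `edge_valid` mask
excludes half a wavelet length at each boundary. Note the cycle ramp makes
σ_t fall steeply at low frequencies but flatten near the top of the grid
(10/18 ≈ 3/5.4), so temporal smearing decreases up the grid with a flat
tail. Band summaries (`band_average()`) are unweighted grid means with
inclusive edges: 6 Hz belongs to both theta (3–6 Hz) and alpha (6–9 Hz), as
the band definitions overlap in print.

## Synchrony statistics

* **PLV** (`plv_windowed()`, `event_locked_plv()`): magnitude of the mean
  unit phasor of phase differences — within non-overlapping 1-s windows for
  the non-event-locked form, across trials at each (frequency, time) point
  for the event-locked form (the across-trial reading; the windowed-within-
  trial alternative is not in the main-text description).
* **PDC** (`pdc_from_var()` and friends): column-normalised partial directed
  coherence, `|Ā_ij(f)| / sqrt(Σ_m |Ā_mj(f)|²)` with
  `Ā(f) = I − Σ_k A_k e^(−i2πfk/fs)`, from least-squares bivariate VAR fits.
  The printed formula for this quantity mixes bivariate and univariate
  coefficients and cannot be evaluated as written; the standard
  Baccalá–Sameshima form is used. Model order defaults to 5 (the
  BIC-selected value of the study); `select_var_order_bic()` re-estimates it
  with `BIC(p) = log det(Σ_ML) + p·d²·log(T)/T`, averaging per-segment
  orders.
* **ITC** (`itc()`): magnitude of the mean unit phasor of phase angles over
  trials — the phase-resetting index.

All three live in [0, 1]; PLV and ITC are provably amplitude-invariant
(they see only coefficient angles).

## Inference

* **Dyad-pairing surrogates** (`surrogate_dyad_null()`): the group-mean
  metric over real pairs is compared with 1000 means over random
  *derangements* (no infant keeps its own partner — "randomly paired" is
  under-specified and derangements avoid diluting the null with real pairs).
  P-values use the z-score-to-Gaussian rule (`zscore_pvalue()`), one-sided
  upper because synchrony has a directional alternative, Bonferroni-corrected
  over the 12 planned comparisons. Two caveats are inherent to this
  procedure and documented rather than hidden: the derangement pool slightly
  underestimates the observed mean's variance (the true type-I rate sits
  near 0.06 rather than 0.05), and the Gaussian approximation requires
  enough dyads for the group mean to normalise.
* **Random-event surrogates** (`surrogate_event_onsets()`,
  `surrogate_event_null()`): pseudo-onsets drawn uniformly over the
  edge-safe, unmasked span, count-matched per participant.
* **Cluster permutation** (`cluster_permutation_test()`): pointwise
  statistics thresholded at a forming alpha of 0.05 (z against the surrogate
  distribution for baseline tests; two-sided paired t across participants
  for contrasts), 4-connected (frequency, time) clusters scored by mass, and
  family-wise correction by the permutation distribution of the maximum
  cluster mass — at alpha 0.025 for inter-brain and ERP families, 0.05 for
  ITC, as in the study. The connected-component labelling is compiled (C++)
  because calibration tests label ~10^5 maps.
* **Condition effects**: 2×2 repeated-measures ANOVA (`rm_anova_2x2()`;
  every 1-df effect's F equals the squared paired t of its contrast, which
  is also how it is tested), Tukey–Kramer-adjusted pairwise cell
  comparisons, and JZS Bayes factors (`jzs_bayes_factor_paired()`, Cauchy
  prior scale √2/2 — the conventional default, as only the toolbox is named
  in print) for the gaze-type contrast. Degrees of freedom are reported as
  n−1; the study prints F(1, 55) with N = 55, an unexplained convention this
  package does not imitate.
* **Power**: `power_from_r2()` converts r² to Cohen's d = 2r/√(1−r²) and
  evaluates two-sided paired-t power via the noncentral t distribution.

## ERP measurement

ERPs are occipital-cluster averages (PO3, PO4, O1, Oz, O2), baseline
corrected to −1000…−700 ms. `component_amplitudes()` finds P1, N170/N290 and
P300/P400 peaks in population-specific windows (infants 100–300, 200–400,
300–600 ms; adults 100 ms earlier), measures the *adaptive mean* (average
over peak ± 10 ms) and peak-to-peak amplitudes against the preceding
component (P1, having none, is measured against zero). Peak *latencies* are
located on a 30 ms-Gaussian-smoothed copy of the waveform: the raw argmax of
a broad, low-amplitude component (a σ = 60 ms P400 at 4 µV) jitters by tens
of milliseconds under residual noise at the component's own timescale,
whereas component-scale smoothing pins it to within a few milliseconds
without displacing well-separated peaks; amplitudes are always read off the
unsmoothed waveform.

`erp_onset_permutation_test()` asks whether the post-onset deflection could
arise if the data were unrelated to onset timing: the observed statistics
are the adaptive means around the grand ERP's maximum and minimum in
0–500 ms, compared against permuted-ERP statistics via the z-score rule,
with the pair of statistics corrected at alpha 0.025. Two permutation
schemes are provided. Literal time-point shuffling (the printed procedure)
whitens each permuted ERP; on band-limited EEG the observed smooth peak
neighbourhood then systematically beats the null, and simulation shows
receiver-level false positives. The circular-shift scheme preserves
autocorrelation and is calibrated, so the cohort pipeline defaults to it
(`erp_perm_method = "circular"`); the literal scheme remains available and
is exact for temporally unstructured data.

## Cohort pipelines

`simulate_cohort()` + `cohort_config()` + the three `run_*_analysis()`
functions orchestrate the analysis families with the study's inclusion rule
(≥ 5 onsets per condition, `min_onsets`), per-dyad count matching, full
inclusion bookkeeping, and end-to-end seed determinism (every stochastic
step derives its seed from `cfg$seed`).

Two implementation choices deserve emphasis:

* **Windows within looks.** Non-event-locked 1-s windows never span
  concatenation boundaries, and windows are paired by index between the two
  partners' series. Windowing the raw concatenation instead would bias the
  pairing surrogate: segment boundaries are aligned within a real dyad but
  misaligned across surrogate pairs, deflating only the surrogate PLV
  (z-scores up to ~3 on uncoupled dyads in simulation).
* **Event-locked PDC windows** (1 s, stepped 250 ms by default, trials
  pooled per window with lags never crossing trials) are this package's
  construction — the study defers those details to supplementary material.
  The pooled fits are computed from cumulative lagged crossproducts so the
  200-permutation surrogate maps stay tractable.

Reports are machine-readable lists (data frames plus cluster objects);
`save_report()` writes CSV tables and a JSON manifest. File interchange uses
plain text (TSV for EEG/gaze/events, JSON for configs) — no EDF/YAML
backend exists in the supported dependency set, and the formats carry the
same information losslessly.

## Numerical and testing choices

* Tolerances: oracle agreement for PLV/ITC/PDC formulas is asserted at
  1e−12; estimator checks use Monte-Carlo tolerances stated per test.
* Degenerate inputs: zero-variance contrasts give F = 0, p = 1; flat ERPs
  give zero amplitudes with a flag; unstable or ill-conditioned VAR windows
  are skipped and counted; empty epoch sets are valid objects.
* Simulation sizes in the test suite are scaled for runtime (128 Hz, 240 s
  recordings, 100–500 permutations) while keeping the study's design
  parameters; statistical thresholds are never relaxed. The calibration
  check uses 60 s of paired data per dyad, matching the study's mean
  mutual-gaze data (66.1 s).
* A single-cohort "qualitative reproduction" run involves ~26 true-null
  significance tests, so the acceptance test bounds each null family by its
  binomial 97.5% count at the nominal alpha (for example at most 2 of 12
  baseline cluster tests at alpha 0.025) instead of demanding zero
  rejections, which no correct implementation would reliably produce; the
  strong sender effects are asserted strictly.

## Known limitations

* Bivariate PDC only (channel-pair, not multivariate); no generalised or
  renormalised variants, no coherence/PPC alternatives.
* No ICA or ocular-artifact regression: inputs are assumed pre-cleaned or
  synthetic (the generator's saccade transients exist to *stress* analyses,
  not to be removed).
* The behavioural generator cannot produce contingent gaze dynamics, so
  descriptives that depend on partner reactivity (e.g. the real data's short
  total non-mutual time) are not reproduced — only occupancy, dwell and
  onset-rate statistics are.
* Topographic plotting, source analysis and BIDS ingestion are out of scope.

## A worked micro-example

```{r example, eval = FALSE}
cohort <- simulate_cohort(8, sim_config(duration = 150, fs = 128,
                                        erp_scale = 1, reset_strength = 0.8),
                          seed = 1)
cfg <- cohort_config(seed = 1, n_perm_pairing = 500, n_perm_event = 200,
                     min_onsets = 3, max_cond_seconds = 12)
rne <- run_nonevent_analysis(cohort, cfg)
head(rne$surrogate_tests)
rib <- run_intrabrain_analysis(cohort, cfg)
rib$erp$infant_sender_mutual$onset_test$p_max
```
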