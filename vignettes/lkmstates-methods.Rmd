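---
title: "Methods: microstates, asymmetry and autonomic responses to a self-compassion induction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microstates, asymmetry and autonomic responses to a self-compassion induction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lkmstates)
```

# What this package computes

`lkmstates` implements the analysis chain for a study paradigm in which
trauma survivors listen to an ~11-minute loving-kindness meditation (LKM)
directing compassion first toward others (minutes 1–5) and then toward the
self (minutes 6–11), with one-minute eyes-closed resting baselines before and
after, while EEG, ECG and skin conductance are recorded. The chain has five
stages:

1. **Self-report scoring and grouping.** The 17-item PCL-C is scored into a
   total (17–85) and per-cluster symptom counts (intrusion items 1–5,
   avoidance/numbing 6–12, hyperarousal 13–17). Participants are classified
   as full PTSD (intrusion ≥ 1, avoidance/numbing ≥ 3, hyperarousal ≥ 2
   symptoms *and* total > 44), subsyndromal PTSD (intrusion criterion plus at
   least one of the other two, full PTSD taking precedence), or no PTSD (no
   cluster criterion met and total < 44). SCS-SF, DASS and FSCSR are scored
   with their published keys; demographic group comparisons use the
   uncorrected Pearson chi-square.
2. **EEG conditioning.** Linked-mastoid re-referencing, 1–40 Hz zero-phase
   band-pass, 4-s epochs with 50% overlap per annotated minute, rejection of
   any epoch with a sample exceeding ±100 µV, per-minute acceptance
   accounting, and exclusion of subjects with more than 75% rejection in any
   analyzed minute (strictly more: a minute at exactly 75% is kept).
3. **Alpha asymmetry.** Per accepted epoch, a Hamming-window FFT of the
   distal 50% (final 2 s, giving 0.5-Hz bins with no zero padding); bin
   powers averaged over epochs and over the 8–13 Hz band to a power density;
   channel densities averaged within fixed anterior and posterior left/right
   clusters; the score is `ln(right) − ln(left)`. Focus-phase means average
   LKM minutes 1–5 (other) and 6–11 (self).
4. **Microstates.** Data are average-referenced, filtered 1–30 Hz,
   downsampled to 125 Hz. The 100 highest-GFP peak topographies per subject
   and minute are concatenated across the cohort and clustered with a
   polarity-invariant modified k-means (assignment by squared spatial
   correlation; prototype update as the dominant eigenvector of the assigned
   maps' outer products; best of 50 restarts by GFP-weighted global explained
   variance). The k = 4 model is aligned to built-in canonical A–D templates
   by exhaustive optimal assignment, backfitted winner-takes-all (per-sample
   argmax of |spatial correlation|, no temporal smoothing), and summarized as
   per-minute mean durations and the *duration response* (minute duration
   minus baseline duration, per state).
5. **Autonomic measures and statistics.** Heart rate is the mean of
   60000/RR per minute; HF-HRV is the 0.15–0.4 Hz band power of the RR
   series linearly resampled at 4 Hz (mean-detrended, plain periodogram),
   expressed as percent deviation from the session mean; tonic skin
   conductance is range-corrected per minute as `(mean − min)/(max − min)`.
   Group-level inference uses a split-plot mixed ANOVA (between = group,
   within = focus) with partial eta squared, Bonferroni-corrected pairwise
   tests, Kruskal–Wallis, Spearman correlations, and both-ways stepwise
   regression.

# The synthetic cohort: what it emulates and what it does not

Raw data from this paradigm cannot be shared, so the package ships a
generator whose outputs have *recoverable ground truth*; every stage of the
chain is validated by parameter recovery rather than against reference
recordings.

A synthetic EEG minute is built from a hidden microstate sequence: run
lengths are geometric at the 125 Hz analysis rate with state-specific means
(defaults 40/60/80/100 ms, configurable per minute, with an optional planted
lengthening during induction minutes) and a 2-sample (16 ms) minimum;
transitions are drawn from a zero-diagonal row-stochastic matrix. The active
state's unit-norm topography is multiplied by an oscillatory carrier: a
~21 Hz (fs/24) cosine inside flat-topped per-run windows that ramp to zero at
every state transition, under a slow log-normal gain. This carrier was chosen
deliberately:

* transitions coincide with field minima, and consecutive GFP peaks carry the
  same potential shape with alternating polarity — the phenomenology
  polarity-invariant segmentation is built on;
* the windowed oscillation has no DC content, so the 1-Hz edge of the
  1–30 Hz analysis filter does not hollow out long runs (a rectified
  low-passed envelope, an alternative we evaluated, loses most of its power
  below 1 Hz and degrades winner-takes-all labelling to chance inside runs
  even without noise);
* the cosine's zeros are phase-locked to fall between the samples kept by
  the 4:1 decimation, so every analyzed sample carries at least half the
  carrier amplitude and label flips at amplitude dips are rare.

On top of the map process, alpha-band (8–13 Hz) oscillations are added to
the 20 asymmetry-cluster electrodes in homologous left/right pairs, the
right channel an exactly scaled copy of its left partner so that the cluster
ln(right/left) power ratio equals the configured offset *exactly* (the
generator records realized per-channel alpha variances so this can be
verified by direct band-power computation). White sensor noise is added at a
configurable map-signal-to-noise ratio (default 5 dB per channel). Default
alpha amplitude is 10 µV RMS per cluster channel, the magnitude typical of
eyes-closed recordings such as these.

The questionnaire generator draws PCL-C items from per-group categorical
profiles constructed so the three groups are recoverable by the
classification rules (the no-PTSD profile never reaches the symptomatic
range; the full-PTSD profile satisfies all criteria and the caseness cutoff;
the subsyndromal profile has high intrusion and hyperarousal but low
avoidance/numbing), plus item-level SCS-SF/DASS/FSCSR draws around per-group
targets and demographic categories with per-group probabilities resembling a
civilian trauma cohort of 17/20/19. RR series carry a sinusoidal
respiratory-band modulation (default 0.25 Hz) with closed-form HF power; SCL
traces are a drifting tonic level with exponential-recovery arousal events
locked to configured minutes.

**What the generator does not emulate:** volume-conducted sources, ocular,
muscle or cardiac artifacts (the paradigm's ICA cleaning step is therefore
out of scope and amplitude rejection operates on artifact-controlled data),
channel dropout, non-stationary alpha reactivity, ectopic-beat physiology
beyond simple outliers, and any coupling between the EEG, autonomic and
questionnaire channels. Passing recovery tests therefore demonstrates that
the *estimators* are correct and unbiased under the stated signal model, not
that they are robust to real-world artifact structure.

# Numerical and design choices

* **"Distal 50%"** of a 4-s epoch is read as its final 2 s — the natural
  reading of "distal" relative to epoch onset — giving 0.5-Hz resolution
  without zero padding. Spectra are window-power-normalized so a
  unit-amplitude sinusoid integrates to amplitude²/2 over its band.
* **Cluster averaging order:** channel power densities are averaged within a
  cluster first, then log-transformed. The alternative (log before average)
  differs only by Jensen-gap terms; the implemented order matches the
  pipeline's description of averaging electrode sites and then
  log-transforming.
* **Symptom threshold:** an item counts as a present symptom when its score
  is ≥ 4 ("above 3"), the paradigm's literal rule; `symptom_min = 3`
  selects the conventional moderate-or-above variant. Classification is
  total and deterministic; cases satisfying neither group definition are
  reported as `unclassified` and can be resolved only by an explicit
  override, mirroring manual clinical reassignment without guessing a rule.
* **Filters** are zero-phase forward–backward Butterworth (order 4 each
  direction), which meet the stated amplitude contracts (pass-band within
  5%, ≥ 20 dB at twice the upper edge); the decimation step samples
  decimation-block centers. Anti-alias filtering at 0.4 × target rate is
  inserted when the band's upper edge does not already provide it.
* **Microstate fitting** concatenates peak maps from all subjects and
  minutes (one cohort-level model), weights GEV by peak GFP, reseeds empty
  clusters from the worst-fitted map, declares convergence on stable
  assignment or relative GEV change < 1e-6, and keeps the best of 50
  restarts under a single documented seed. The k = 2..10 scan reports GEV
  per k but never auto-selects; four classes is the field's convention.
* **Canonical templates** are idealized synthetic geometries (two mirrored
  diagonal gradients, an occipital focal pattern, a fronto-central focal
  pattern) built from approximate 10-10 electrode positions and symmetrically
  (Löwdin) orthogonalized. They are stand-ins: no empirical grand-average
  maps ship with the package. Orthogonality matters beyond aesthetics —
  with correlated templates, the instant a transition's field mixture
  crosses between two states it can resemble a *third* template, producing
  spurious one-sample insertions that corrupt run-length statistics.
* **Boundary runs** at annotation edges are included in duration means
  (conserving labelled time); `drop_boundary_runs = TRUE` excludes them.
  States absent from a minute are recorded as missing, never zero.
* **Mixed ANOVA** is restricted to the paradigm's two-level within factor,
  where sphericity is trivial and the classical decomposition (between on
  subject means, within/interaction on subject differences) is exact; Type
  III sums of squares are used for unbalanced groups. Assumption checks
  (Shapiro–Wilk, Levene) are reported, never enforced — analyses proceed
  with a warning, as is conventional for this design.
* **Stepwise regression** starts from the empty model and alternates
  forward/backward moves under AICc (BIC available as the strict variant);
  every step is logged and collinear candidates are screened by condition
  number.
* **RR artifact handling** replaces an unreproducible template-correlation
  procedure with a transparent rule: a beat deviating more than 30% from the
  9-beat local median is flagged and linearly interpolated; the corrected
  fraction is always reported (clean recordings in this paradigm run well
  under 5%) and fractions above 25% flag the subject for review.
* **Percent-deviation reference** for HF-HRV is the mean over all analyzed
  minutes of the session (configurable), making the transformed values
  average to zero over the session by construction.
* **Minute exclusion:** the first induction minute is excluded from EEG
  analyses by default (acceptance rates there are systematically lower as
  participants settle), as a configurable list applied to EEG stages only.

# Problem sizes used in validation

The validation suites run at deliberately chosen sizes: microstate recovery
uses 12 subjects × 2 annotated minutes at 500 Hz (baseline plus one
induction minute with a planted +20 ms lengthening of state B, 5 dB map
SNR); asymmetry recovery uses 20 subjects × 2 minutes with offsets
±0.3 and 0 at 10 dB; calibration of the mixed ANOVA uses 400 null cohorts of
54 subjects; stepwise recovery uses 100 replicates at n = 200 with 7
candidates. These sizes keep every recovery quantity's sampling error well
inside its tolerance while remaining quick to re-run.

# Known limitations

* Mean durations of the shortest state (40 ms target) carry a small upward
  bias (≈ 9% under the 5 dB benchmark) because 16-ms runs sit near the
  resolution limit of a 1–30 Hz field sampled at 125 Hz; longer states are
  recovered within a few percent.
* The asymmetry estimator is mildly attenuated toward zero (recovery slope
  ≈ 0.96) by symmetric broadband power inside the alpha band; with the
  default eyes-closed alpha amplitude this stays well inside the ±0.05
  recovery tolerance.
* The EDF writer/reader supports the continuous 16-bit subset of the format
  used here (integer sampling rates, whole-second recordings); annotations
  and ground truth travel in a JSON sidecar rather than EDF+ annotations.
* The statistical battery reproduces the paradigm's *procedures*; the
  original study's F statistics depend on unavailable raw data and are not
  reproduction targets. The demographic chi-square statistics, which depend
  only on printed counts, are reproduced exactly.
* This is an analysis library: its interfaces are the exported functions,
  the test suites, and `scripts/acceptance.R`; there is no separate
  command-line front end.

# A worked miniature

```{r example, eval = FALSE}
# three-subject cohort, baseline + two induction minutes
cfg <- cohort_config(n_per_group = c(nPTSD = 1, sPTSD = 1, fPTSD = 1),
                     seed = 42, n_lkm_minutes = 2, post = FALSE)
cohort <- simulate_cohort(cfg)

# classify from the questionnaire table
classified <- classify_cohort(cohort$questionnaires)
table(classified$group, classified$group_true)

# cohort microstate model and duration responses
recs <- lapply(cohort$subjects, `[[`, "recording")
groups <- vapply(cohort$subjects, `[[`, "", "group")
fit <- fit_cohort_microstates(recs, groups, seed = 1)
fit$model$labels
head(fit$responses)

# per-subject asymmetry time course
asymmetry_timecourse(recs[[1]])$phase_means
```
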