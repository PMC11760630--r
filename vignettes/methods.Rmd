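---
title: "Models and methods: simulating and analysing distractor predictability under load"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predistract)
```

This vignette describes the generative models, analysis procedures and
design decisions behind `predistract`, in the spirit of a methods section:
what is assumed, which parameters matter, what the synthetic data do and do
not emulate, and where the numerically delicate choices lie.

## The experiment being modelled

A dual-stream auditory spatial n-back task: two streams of spoken numbers
(1–8, split into two disjoint four-number groups) play simultaneously to the
two ears at a 2-s onset-to-onset interval, 120 pairs per block. The listener
attends one side and presses a button when the current target matches the
target one or two positions back. Three two-level factors are crossed —
perceptual load (target-to-distractor SNR 0 vs −10 dB), memory load (1- vs
2-back) and distractor predictability — giving 8 conditions, each run twice
(16 blocks) with the number-group roles and the attended side swapped
between repeats.

`build_experiment()` generates and `validate_experiment_plan()` checks this
design. Distractor sequences implement the stated transition structure
exactly: predictable blocks cycle a random four-number pattern (transition
probability 1); unpredictable blocks draw each number uniformly from the
alternatives that differ from the previous and penultimate item, so position
2 has three admissible alternatives (p = 1/3) and later positions two
(p = 0.5). `empirical_transition_stats()` and `admissible_choice_freq()`
verify these probabilities empirically.

**n-back event placement.** "20% of presented numbers are n-back events" is
implemented as `round(rate × scoreable positions)` events placed uniformly
at random among positions with at least *n* predecessors; at the study's
block length both readings of the 20% (of 120 presented, or of 119/118
scoreable items) equal 24 events, so the distinction is immaterial here.
Unintended repeats are prevented at the block's own lag only: a 1-back block
may contain accidental 2-back repeats, since only the task-relevant lag is
behaviourally meaningful. Sequences are built by direct constrained
construction — flag positions first, then fill left to right, sampling
non-events from the numbers that do not match at lag *n* — which is always
feasible and uniform over admissible sequences given the flags, so no
rejection sampling or retry cap is needed. Block order is a seeded uniform
permutation; no block-order counterbalancing is imposed because none is part
of the design being modelled.

## The behavioural generator and its inverse

`simulate_responses()` is the generative inverse of the equal-variance
signal-detection analysis: per condition cell with parameters (d′, c),

- P(press | n-back target) = Φ(d′/2 − c),
- P(press | non-target) = Φ(−d′/2 − c),

with reaction times uniform in (0, 2]. `sdt_metrics()` inverts this:
d′ = z(H) − z(FA) and c = −(z(H) + z(FA))/2, the sign convention under which
positive c is conservative (targets are missed rather than falsely
reported). Extreme rates are corrected by 1/(2n), where n is the trial count
entering each rate — target count for hits, non-target count for false
alarms, pooled over the two blocks of a condition.

The z-based estimators carry the well-known small-sample bias of
inverse-normal transforms: with 48 targets per condition cell, exact
binomial enumeration puts the d′ bias at +0.07 for the default 1-back
parameters (d′ = 3) and below +0.03 elsewhere — inside the package's stated
±0.1 recovery bound, and the reason that bound is not tighter.

Default generative values (one choice, not tuned): d′ = 3.0 under 1-back and
2.0 under 2-back (a large memory-load cost, as n-back studies of this kind
show); criterion 0.35 under 1-back and 0.65 under 2-back (conservative bias
growing with load), with the single easiest cell (0 dB, 1-back, predictable)
at 0.18 — a small predictability-induced relaxation of bias confined to the
low-load condition. These reproduce the qualitative behavioural structure
the analysis is meant to detect: strong load effects, no SNR effect on
sensitivity, and a small bias effect in the easy cell.

## The EEG generator

`simulate_eeg_epochs()` builds each epoch (−1 to 1 s around pair onset) from
three parts.

**1/f background.** Gaussian noise shaped in the frequency domain by
|f|^(−β/2) with β = 1 and an 8 µV standard deviation per channel,
independent across trials and channels. This approximates the broadband EEG
background; it contains no ocular or muscle artefacts, no line noise and no
spatial correlation, which is why ICA-style artefact removal is out of
scope.

**Lateralised alpha.** A 10-Hz sinusoid at the 12 posterior electrode pairs,
with random phase per trial *and* channel, log-normal trial-to-trial
amplitude jitter (σ_log = 0.2) and hemispheric amplitude gains
√(1 + a(t)) ipsilateral and √(1 − a(t)) contralateral to the attended side.
Because sinusoid power scales with the squared gain, the ideal
lateralisation index of the oscillation equals a(t) exactly:
(g²ᵢ − g²c)/(g²ᵢ + g²c) = a. The target time course a(t) holds configured
per-window values — by default 0 (predictable) and −0.1 (unpredictable) in
T1 (−0.5 to −0.35 s) and +0.2 in T2 (0.3–0.5 s) — with raised-cosine ramps
to zero in between and a per-subject Gaussian offset (SD 0.05) shared across
windows.

Two generator choices matter numerically:

- *Plateau extension.* Moving-window spectral estimates average power over
  a 500-ms window, so a gain plateau covering only the nominal window would
  be smeared by the Hann taper and attenuate the measured window-mean ALI by
  roughly a quarter. The gain plateaus therefore extend past each nominal
  window by half the spectral window (0.25 s), so that every window centred
  inside the nominal interval sees the full plateau and the window-mean ALI
  equals the target.
- *Per-channel random phase.* With incoherent alpha across channels,
  average re-referencing subtracts a common signal that is essentially
  orthogonal to each channel's oscillation, leaving power ratios — and hence
  AMI/ALI — intact up to order 1/n_channels. Coherent alpha would make the
  average reference severely distort lateralisation indices in this
  synthetic world.

The default alpha amplitude (8 µV) makes posterior alpha dominate the 1/f
background within 8–12 Hz, the typical picture in eyes-on-task EEG with a
clear alpha peak. Residual in-band noise still dilutes measured indices by a
factor S/(S + 2N) ≈ 0.85, so a configured ALI of 0.2 is recovered near
0.17 — inside the package's stated ±0.05 recovery tolerance, and the reason
that tolerance is not tighter.

**Evoked components.** P1 (50 ms), N1 (100 ms) and P2 (185 ms) are
Gaussian-windowed deflections; the frontal negativity is a plateau from 0.4
to 0.8 s with raised-cosine edges. Scalp topographies are fixed Gaussian
profiles (SD 0.35 in schematic montage coordinates) centred on FCz (early
components) and Fz (frontal negativity) — sensor-level structure only, no
volume conduction. Amplitudes are linear in centred effect codes
(−0.5/+0.5 for −10/0 dB, 1-/2-back, predictable/unpredictable): the P2 is
larger for 0 dB (+0.6 µV), 2-back (+0.25 µV) and unpredictable distractors
(+0.4 µV); the frontal negativity is more negative for 0 dB and 1-back with
a load × predictability interaction (−0.6 µV) that makes predictability
deepen it under low load and weakly reverse under high load. Per-subject,
per-component offsets (SD 1 µV) create the random-intercept structure the
mixed models assume.

## Preprocessing

Deterministic epoch-level operations mirroring standard ERP practice:
zero-phase Butterworth band-pass (2nd-order high-pass at 0.1 Hz after
explicit demeaning — an IIR high-pass this slow cannot settle within a 2-s
epoch — and 6th-order low-pass at 100 Hz, clipped with a warning at low
sampling rates), trial rejection at 160 µV absolute amplitude, average or
mastoid (TP9/TP10) re-referencing, baseline correction (−0.2 to 0 s), and
removal of the block-initial trials that have no n-back reference. Baseline
correction and re-referencing are both linear and commute; rejection only
masks trials, keeping metadata aligned. Visual bad-channel screening is
replaced by a deterministic flat/extreme-variance detector with within-row
neighbour averaging (`repair_bad_channels()`).

## Statistical machinery

- `rm_anova()`: fully within-subject ANOVA, each effect tested against its
  own subject × effect stratum, partial η² = F·df₁/(F·df₁ + df₂). All
  factors here have two levels, so sphericity is trivially satisfied and no
  correction is applied. Unbalanced input is an error, not a silent drop.
- `paired_t()`: two-sided paired t with Cohen's d = |t|/√n.
- `fdr_bh()`: Benjamini–Hochberg step-up mask.
- `effect_size_r()`: r = √(t²/(t² + df)), the standardised partial effect
  size for mixed-model terms.
- `fit_component_lmm()`: REML fit with participant random intercept,
  Satterthwaite df, two-sided p and r per term. Centred effect coding makes
  "main effects" marginal across the other factors; the factor coding is a
  package choice since conventions differ. Singular fits (random-intercept
  variance estimated at zero, common in small simulations) are flagged,
  never dropped. Trials from both attend sides are pooled, as the model has
  no side term.

## Time–frequency analysis

`tfr_fft()` computes Hann-tapered moving-window power (500 ms) per trial.
A 500-ms window has native 2-Hz resolution; windows are zero-padded to 1 s
to evaluate the 1-Hz grid. The padding interpolates the spectrum — adjacent
1-Hz bins are not independent — which is accepted and documented; power is
calibrated so an on-bin sinusoid of amplitude A yields A². Window centres
whose support would leave the epoch are excluded rather than padded. Power
is computed per trial and averaged within attend-side and condition *before*
any index is formed: AMI and ALI are ratios of averaged power, not averages
of ratios, and ROI/band averaging precedes the ALI ratio. TP9 is part of the
posterior ROI even though it doubles as a mastoid reference site; after
average re-referencing it carries signal. Window selection runs paired
t-tests of left- vs right-electrode AMI at every time point, applies
Benjamini–Hochberg across time points, and returns contiguous significant
runs; the canonical windows T1 (−0.5 to −0.35 s) and T2 (0.3–0.5 s) are the
package defaults for window-mean ALI and the 2×2×2×2 repeated-measures
ANOVA.

## Reproducibility and problem sizes

Every stochastic function takes a seed; `make_subseeds()` derives
per-subject, per-stage sub-seeds from one master seed so subjects can be
processed in any order with identical results, and `run_pipeline()` is
byte-deterministic given its config. The generator default is 250 Hz
sampling (500 samples per 2-s epoch); all windows are specified in seconds,
so analyses are rate-invariant, and the package's simulation studies run at
100 Hz with reduced channel sets and block lengths: the alpha-recovery study
uses 50 replicates of 33 subjects × 16 blocks × 8 pairs on the 24 ROI
channels; P2 sign recovery uses 20 replicates of 16 subjects × 16 blocks ×
96 pairs on an 8-channel fronto-central set (sized so the fitted
predictability contrast has t ≈ 3, since single-trial amplitude noise is
realistically large — the per-subject condition difference carries a
standard error near 0.5 µV); mixed-model type-I calibration uses 200
replicates of 6 subjects × 16 blocks × 12 pairs. In these replicate studies
the per-subject designs are held fixed while each replicate redraws the
EEG — the regression null conditions on the design — which keeps the
studies affordable at desk scale.

## What passing tests do and do not show

The synthetic data reproduce the statistical structure the analysis assumes
— per-condition SDT behaviour, 1/f background, band-limited lateralised
alpha, condition-scaled evoked components with subject-level offsets — and
parameter recovery on them verifies the full chain of definitions and code.
They do not emulate artefacts, volume conduction, correlated noise,
oscillatory non-stationarity beyond amplitude jitter, reaction-time
structure, or learning across blocks; recovery on this generator therefore
validates the pipeline's correctness, not the robustness of the analysis to
real-data pathologies. Group-level F and p values obtained from real
participants reflect between-subject variability this generator only
sketches (Gaussian ALI offsets and component intercepts), so simulated
group statistics should be compared with real ones qualitatively, not
numerically.

## Known limitations

- No HDF5/EDF persistence: epochs live in memory; tables are TSV, summaries
  JSON.
- The 0.1-Hz high-pass on 2-s epochs is effectively a demean plus gentle
  roll-off; filtering continuous data before epoching, as acquisition
  pipelines do, is out of scope.
- `find_component_window()` snaps windows to the sample grid; at 250 Hz the
  canonical 185-ms peak lies between samples, so grids of 200 or 1000 Hz
  reproduce the 160–210 ms window exactly.
- The rejection threshold never triggers on the artefact-free generator
  defaults; the operation is exercised by dedicated tests instead.
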