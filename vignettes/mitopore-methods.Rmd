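---
title: "Models and methods behind mitopore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mitopore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitopore)
```

`mitopore` analyzes single-channel recordings of the mitochondrial
permeability transition pore (PTP / mitochondrial megachannel) and the
bulk assays that accompany them, and ships simulators that generate every
input with known ground truth. This vignette explains the models, the
analysis conventions, the tunable parameters, and the choices made where
the conventions of the field leave the details open.

## The gating simulator

A channel is modelled as a continuous-time Markov chain (CTMC) over a
small set of conductance states (a closed state at 0 pS, optional
subconductance states, and a full open state). The generator matrix `Q`
holds transition rates in s⁻¹; off-diagonal entries are non-negative and
rows sum to zero. Paths are sampled by **exact exponential jumps** — the
dwell in state *i* is Exp(−q_ii), the successor is drawn proportionally to
q_ij — and then rasterized onto the sampling grid. Sampling jumps exactly
(rather than per-sample Euler stepping) means the simulated dwell times
are exact, which is what makes oracle tests possible: the truth path is
attached to every simulated trace.

Current is assembled as

> I(t) = baseline + G(state) · V_h / 1000 + drift · t + ε(t),

with G in pS, V_h in mV, I in pA, and ε white Gaussian noise
(`noise_sd`, default 0.6 pA in the presets). Openings are positive
deflections at V_h = +20 mV, consistent with G = I/V for positive
conductances. Defaults follow the standard mitoplast protocol: 10 kHz
sampling, 500 Hz low-pass filtering, 90-s traces with the blocker added at
60 s (so the 30-s pre-blocker window used by G_mean is always available).

Interventions (blockers and agonists) are **instantaneous rate
multipliers**: from their timestamp onward, every ordered state-pair rate
is scaled by a factor ≥ 0. A factor of zero abolishes a transition; the
packaged blockers zero every opening transition so the channel drains into
the closed state and stays there, matching the observation that pore
closure rapidly follows blocker addition. No wash-in kinetics are
modelled. Because the chain is memoryless, the dwell in progress at an
intervention is truncated and resampled under the new generator, which is
statistically exact.

The low-pass filter is a **zero-phase Gaussian FIR kernel** with −3 dB at
the cutoff (σ_t = √(ln 2)/(2π f_c), a 10–90% step rise time of ≈ 0.66 ms
at 500 Hz). It is symmetric (no phase distortion), has no ringing, and is
analytically characterizable, so tests can reason about transition
durations. Edges are padded by sample replication, making the filter
exactly transparent to DC — a constant segment keeps its mean.

## Presets and their calibration

`make_preset()` packages six models. Two are anchored to reported
per-genotype statistics and are used by the acceptance checks:

- `wt_hela_ptp`: closed + substates at 300/600 pS + full level at 827 pS;
  targets G_max 827 pS, G_mean 703 pS, Q_4s 48 pC.
- `dg_atr_ant`: the ANT-mediated channel unmasked by atractylate in cells
  lacking an assembled F-ATP synthase; closed + 310 pS substate + 620 pS
  full level; targets G_max 620 pS, G_mean 434 pS, Q_4s 47 pC.

The others (`wt_hap1_ptp`, `ant_channel`, `full_mmc`, `null_closed`) encode
the phenotype families (full megachannel conductance in the 1.3–1.5 nS
range, ANT channels in the 0.3–0.6 nS range, a channel locked closed) with
no printed statistics attached.

Dwell-time statistics and open probability are not reported for these
channels, so kinetics are free parameters. We fix them with a two-step
construction: the stationary occupancy π is prescribed directly through a
reversible generator (q_ij = s_ij π_j with symmetric exchange rates s),
and the exchange timescales s are then the only remaining dials.
Occupancy sets G_mean exactly (it is the activity-conditional mean of the
level conductances); the timescales set how tightly the best 4-s window
concentrates around the stationary mean, i.e. Q_4s. For `wt_hela_ptp`,
total exit rates around 10–25 s⁻¹ (dwells of 40–100 ms, well above the
20-ms stability dwell) put the best-window mean near 600 pS and hence
Q_4s near 48 pC; for `dg_atr_ant` a sticky full state (mean dwell ≈ 2.5 s)
produces occasional long fully-open episodes that carry the charge maximum
while most activity sits in the substate, reproducing the G_mean 434 /
Q_4s 47 combination. These constants were calibrated once by simulating
batches through the full pipeline and then frozen; the round-trip means
land within ~1% of the targets with no per-run tuning.

Reported statistics are means ± SEM across experiments, so the presets add
**between-experiment dispersion**: per seed, all open-state conductances
are jointly rescaled by a factor drawn from N(1, 0.1) (CV ≈ 10%).
Recovery tests therefore exercise dispersion, and batch SEMs are
meaningful.

What the simulator deliberately does not model: PTP biophysics (Ca²⁺
binding, voltage dependence), correlated (1/f) noise, seal instability,
capacitive transients, and multi-channel patches. Passing recovery tests
shows the analysis is correct for the stated generative model, not that it
is robust to every artifact of real recordings.

## Idealization

The amplitude distribution is fitted with a Gaussian mixture by EM, with
the number of components (k ≤ 6) selected by BIC (`mclust`). Fitting works
on **raw samples** rather than binned counts, avoiding bin-width bias; the
0.2-pA histogram is kept for reporting, and a binned fitting mode exists
for comparison with purely histogram-based analyses. Long traces are
decimated deterministically to ≤ 20 000 evenly spaced samples — gating
dwells span hundreds of samples, so decimation preserves occupancy — and
the fit is deterministic for a given trace (hierarchical model-based
initialization on a fixed subset, no random restarts).

Components merge into the baseline when their mean lies within
`event_threshold_sigmas` (default 3) baseline SDs of the closed peak:
noise shoulders never become conductance states. Surviving components
become levels with G = (µ − baseline)/V_h.

Samples are assigned to levels by **nearest level with hysteresis**: a
switch requires crossing the midpoint between two levels by more than
`hysteresis_fraction` (default 0.25) of their gap, suppressing chatter at
midpoints. Dwells shorter than `min_stable_dwell_ms` (default 20 ms,
about 30× the filter rise time) are merged into the flanking level with
the nearer current, shortest first. "Stable state" is thus
operationalized as a dwell criterion; whether the original analyses
defined stability by dwell time or histogram peak occupancy is not
documented, so the dwell is exposed in `analysis_config()` rather than
asserted as the canonical definition.

Transition durations are measured on the filtered current as the
**10–90% crossing time** between the two level currents around each
segment boundary: an instantaneous gating step filtered at 500 Hz measures
≈ 0.7 ms, a 20-ms linear ramp measures 16 ms. The convention "transition
duration < 10 ms" only fixes a threshold, not a measurement rule; 10–90%
is the conventional, noise-robust choice.

Offset correction is one global rule reused by every statistic: a
piecewise-linear baseline through the mean current of each closed dwell
(constant extrapolation at the ends, constant offset when fewer than two
closed dwells exist), subtracted before any conductance conversion.

## Conductance statistics

- `compute_gmax()`: max |ΔG| over events with duration < 10 ms. No
  qualifying event → `NA` ("no current activity"), deliberately distinct
  from 0 pS and propagated as such everywhere (the reporting layer prints
  the note, never a zero).
- `compute_gmean()`: mean of baseline-corrected current over non-baseline
  samples in [blocker − 30 s, blocker), divided by V_h. Activity samples
  are pooled across the window ("the average of the mean conductance
  during activity" is read as a pooled activity average; a per-episode
  average would weight brief episodes equally with long ones, and the
  alternative of including closed time is exposed via
  `gmean_include_closed`). Windows reaching before the trace start are
  truncated and flagged.
- `compute_q4s()`: the 4-s window is **contiguous and chosen by maximizing
  the trapezoidal integral** of corrected current — "at the maximal
  activity" made deterministic, with the chosen window reported.
- Post-blocker G_max excludes a 1-s settling period after addition: the
  closing staircase that immediately follows a block would otherwise
  register as large "post-blocker" transitions and mask the suppression
  the paired comparison is meant to detect.
- `blocker_effect()` / `group_compare()` wrap the two-sided paired and
  two-sample Student's t-tests (pooled variance by default, Welch as an
  option). Degenerate inputs (identical pairs, both groups constant and
  equal) return t = 0, p = 1; constant groups with different means raise
  an error rather than reporting an unbounded statistic.

## Bulk assays

- **Swelling**: fraction = (A₀ − A_eval)/(A₀ − A_ala), clamped to [0, 1],
  with A_eval 9 min after the Ca²⁺ bolus and A_ala the alamethicin
  (maximal-swelling) plateau. The normalization follows the standard
  swelling-assay protocol literature and is documented here as this
  package's convention; it is affine-invariant, which the tests exercise.
- **CRC**: a pulse is retained when fluorescence returns below its
  pre-pulse baseline + 3× the pre-assay noise SD before the next pulse
  (the same 3σ convention as the channel event threshold; with noiseless
  input the tolerance falls back to 1% of the spike height). CRC =
  retained pulses × 2.5 µM / 0.4 mg/ml, in nmol Ca²⁺ per mg protein.
- **OCR**: plateau means use the last three samples before the next event
  (robust to injection transients); rotenone/antimycin-insensitive
  respiration is subtracted from everything, making the summaries
  invariant to a constant offset.
- **Timecourses**: per ROI, background-subtracted and normalized to the
  pre-addition mean (first-frame normalization is available via the
  `normalize` argument; which of the two the original quantification used
  is not stated, and the pre-addition mean is the less noisy reference).
  Readout at +8 min; SEM is computed across ROIs pooled over experiments,
  matching how figure legends count n.

## Numerical choices and degenerate inputs

Simulations restore the caller's RNG state; identical seeds give
bit-identical outputs, and the CLI records seeds and a configuration hash
beside every output. Histogram bins are edge-aligned multiples of the bin
width so counts conserve the sample count. Ties in the short-dwell merge
go to the left flank; the Q_4s window reports the first maximizing
position. Traces shorter than 4 s refuse Q_4s; fewer than 200 samples
refuse a mixture fit; a zero V_h refuses conductance conversion.
`null_closed` is formally a two-state model (a generator needs at least
two states) with all rates zero, so it can never leave the closed state.

## Problem sizes used by the packaged checks

The acceptance checks simulate 20 recordings of 90 s per anchored preset
(10 kHz, ≈ 0.9 M samples each) and verify that batch means of
G_max/G_mean/Q_4s fall within 2 SEM of the preset targets; occupancy
versus the analytic stationary distribution is checked by χ² on 300-s
traces subsampled at 1 Hz (α = 0.01); the t-test engine is verified
against first-principles formulas to 1e-10 and its type-I rate over 200
null contrasts of 5 paired experiments each. These sizes keep the full
suite within a few minutes on one CPU while leaving the Monte-Carlo
margins comfortably wider than the residual calibration bias (≈ 1%).

## Known limitations

Idealization is amplitude-threshold based, not a hidden-Markov decoder:
there is no missed-event correction, so dwell-time *kinetics* should not
be inferred from the idealization (conductance statistics are insensitive
to this at the default filter settings). Only constant-V_h protocols are
supported (no ramps). The imaging module consumes ROI intensity tables —
segmentation and microscope metadata are out of scope — and no calcium
calibration of indicator fluorescence is attempted. Group comparisons are
single pairwise t-tests without multiple-testing correction, mirroring
how such panels are conventionally reported.
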