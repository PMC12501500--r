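---
title: "Corticomuscular coherence and beta bursts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Corticomuscular coherence and beta bursts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmcbursts)
```

# The scientific problem

During an isometric grip, oscillations in the 13–30 Hz (beta) band of the
motor cortex are partially coherent with the surface EMG of the gripping
muscle. This corticomuscular coherence (CMC) indexes the functional
integrity of the corticospinal pathway, and cortical beta activity itself
is organized in short bursts whose rate, duration and amplitude carry
information that a trial-averaged power value cannot. `cmcbursts`
implements the full analysis chain for epoched gripper-task MEG/EMG
recordings — multitaper CMC spectra, Morlet beta power, Hilbert-envelope
burst detection, behavioural metrics from the force channel, and
nonparametric group inference — together with a synthetic two-group cohort
generator with known ground truth, so that every stage can be verified
quantitatively without access to human data.

# The epoch model

All analyses operate on an `epoch_set`: a `trials x channels x samples`
array at 250 Hz with a half-open time axis $[-1, +5)$ s around the "grip"
trigger, i.e. exactly 1500 samples. Channels carry a role (`parcel`,
`emg`, `force`) and a side. The half-open convention avoids the classic
off-by-one: 6 s × 250 Hz is exactly 1500 samples, and the trigger sample
sits exactly at $t = 0$.

Filtering is 5th-order IIR Butterworth applied forward and backward
(zero-phase). The source material does not state phase handling; we fix
zero-phase because burst *timing* statistics are compared across groups
and a causal filter's group delay would bias every onset estimate. The
price, a doubled effective order, is immaterial here. Line noise is
removed with 3rd-order Butterworth band-stops of ±1 Hz around 50 and
100 Hz (≥20 dB at the line frequency, <1 dB three Hz away — verified by
direct sinusoid probes in the test suite).

Bad-epoch rejection uses a generalized ESD (Rosner) outlier test at
$\alpha = 0.05$ on per-trial log variance, separately per channel role.
"Variability metrics" was the only stated constraint; GESD was chosen
because it is deterministic, handles multiple simultaneous outliers, and
its null behaviour is testable (the suite checks the false-rejection rate
against $\alpha$).

Evoked subtraction implements $X(t) = U(t) - M(t)$: the across-trial mean
is removed at every time point, leaving induced activity. It is applied
separately to cortical and EMG channels before CMC estimation, after
which the EMG is full-wave rectified — rectification demodulates the
beta-band drive carried by the EMG amplitude envelope, which is what
makes CMC recoverable from surface recordings.

# CMC estimation

Coherence is magnitude-squared,
$C_{xy}(f) = |S_{xy}(f)|^2 / (S_{xx}(f)\,S_{yy}(f))$, estimated by the
multitaper method with DPSS tapers (time-bandwidth product 2, 3 tapers)
on 200-sample segments at 50% overlap within the 2–4 s epoch window (the
1–3 s post-trigger contraction plateau). The 200-sample window gives the
natural DFT grid of 1.25 Hz spacing; bins with centres in 8–40 Hz are
kept. Cross-spectra are averaged over tapers, then segments, then trials
*before* the coherence ratio is formed — coherence of averages, never an
average of coherences. The tapers are computed from the standard
symmetric tridiagonal eigenproblem and are orthonormal to machine
precision.

Two calibration facts anchor the estimator and are enforced in tests:

* with $y = x$, $C_{xy} = 1$ at every bin to $10^{-10}$ (Cauchy–Schwarz
  equality);
* with independent noise, the estimator's expectation is the known small-
  sample bias $\approx 1/L$ for $L$ independent averaged segments. The
  bias checks run with zero segment overlap so that $L$ is exactly the
  taper × segment × trial count; with 50% overlap neighbouring segments
  are correlated and $L$ would overstate the effective averages.

Contralateral CMC pairs the left motor channel with the right EMG and
vice versa; ipsilateral pairs same sides; the hemisphere label names the
cortex side. The whole-brain variant averages coherence across 13–30 Hz
per (parcel, EMG) pair, producing a topography whose maximum should sit
on the driving parcel — a localization property the simulator can verify.

The printed cluster bounds in human studies of this design (e.g. a
9.9 Hz edge) do not sit on a 1.25 Hz grid anchored at 0 Hz; since the
anchoring convention of any particular study is unknowable from the
outside, the grid here is the natural DFT grid and is not forced onto
foreign cluster edges.

# Beta power and bursts

Morlet power uses unit-energy complex wavelets with 7 cycles (a common
default; the width matters little for band-averaged power) on z-scored,
evoked-subtracted data; the per-participant beta power time course is the
mean over 13–30 Hz and trials. "Un-baselined" beta power keeps the evoked
response (z-scoring only) and averages the −1–5 s and −1–0 s windows.

Burst detection is deliberately the simplest defensible chain: bandpass
13–30 Hz → Hilbert envelope (computed on a 0.5 s mirror-extended series
so edge artefacts fall outside the epoch) → divide by the trial's mean
envelope → threshold at the 75th percentile → drop runs shorter than one
cycle of 13 Hz (1/13 s; at 250 Hz an event must span ≥ 20 samples, with
strict `<` exclusion on the duration in seconds). Two scope decisions
were open and are now fixed (both exposed as arguments):

* **Threshold scope** — the percentile is computed on the normalized
  envelope pooled across all trials of a task (per channel, per
  participant), not per trial. Pooling keeps the trial-level fractional
  occupancy informative: with a per-trial threshold every trial would be
  forced toward 25% occupancy by construction.
* **Burst amplitude** — the peak normalized envelope within the event.

A structural consequence worth stating: a pooled 75th-percentile
threshold pins the *total* supra-threshold time at 25% of the scored
samples before the duration rule. Ground-truth burst statistics are
therefore only recoverable when the true envelope is bimodal (bursts
clearly above background) and overall burst occupancy sits below 25%, so
that the percentile falls in the amplitude gap between background and
bursts. The simulator's defaults are chosen to respect this (below); on
real data with near-continuous envelope distributions, detected
occupancy is partly an artefact of the threshold convention, and
between-group comparisons — not absolute occupancy values — are the
meaningful quantity.

Burst timing carries an intrinsic resolution limit: any detector that
band-limits to 13–30 Hz smears envelope edges over roughly the
reciprocal bandwidth (tens of milliseconds). When the threshold sits at
the background level, run boundaries land on that smear; when it sits
mid-edge, boundaries are recovered to the sample. The test suite checks
both regimes explicitly.

# The synthetic cohort generator

The generator emulates the gripper-task structure: three tasks
(bilateral 120 trials, unilateral left/right 60 each by default), 6 s
epochs, a trapezoidal force profile targeting 12–17 N with lognormal
reaction time (median 0.4 s) and release at 3 s + jitter, left/right
motor parcels, optional task-inactive parcels, and bipolar EMG per side.

Cortical channels are a sum of

1. 1/f background noise (slope −1, the canonical aperiodic exponent of
   task MEG);
2. a tonic beta oscillation whose envelope follows the movement profile —
   a desynchronization dip after the trigger, recovery during the hold, a
   rebound bump after release;
3. discrete bursts from an inhomogeneous Poisson process (thinning), each
   a cosine-tapered plateau (Tukey window, 20 ms edges) at a frequency
   drawn within 16–28 Hz, with lognormal duration (median 0.25 s) and
   jittered amplitude.

Burst waveform choice: a *full* raised-cosine envelope would make true
duration unrecoverable by any threshold detector — a Hann-shaped burst
spends about half its support below any mid-level threshold. The
plateau-with-tapered-edges shape is equally band-limited but gives the
event a well-defined boundary, which is what a recovery oracle needs.
Overlapping bursts are merged into one truth interval (amplitude = max)
because no envelope detector can separate them.

Rates are movement-modulated: baseline 1.0 bursts/s, ×0.25 during the
0.1–0.9 s desynchronization window, 0.9/s during the 1–3 s hold, ×1.6 in
a 1 s rebound window from 3.3 s. With the 0.25 s median duration this
puts overall epoch occupancy near 0.23 — under the 25% threshold ceiling,
as required for recovery (see above), and within the range reported for
sensorimotor beta bursts.

The EMG is broadband noise gated by the grip envelope and
amplitude-modulated by $1 + \kappa\,d(t - \delta)$, where $d$ is the
normalized noise-free cortical beta drive, $\delta = 20$ ms a conduction
delay and $\kappa \ge 0$ the coupling strength; a small baseline floor is
always present. This Rayleigh-envelope carrier is exactly the kind of
signal whose rectification recovers beta coupling; it makes no claim to
motor-unit physiology. Estimated beta CMC is zero-coupling-calibrated
(at the 1/L bias floor for $\kappa = 0$) and strictly increasing in
$\kappa$ — both enforced in tests.

The patient-like group applies signed deltas to the control parameters:
coupling ×0.5, hold-window burst rate ×0.6, burst amplitude ×1.3,
desynchronization depth ×0.5, rebound delayed +0.4 s. The directions
mirror the group effects the pipeline is meant to detect (reduced
contralateral CMC, reduced fractional occupancy, raised burst amplitude,
blunted desynchronization, delayed rebound); magnitudes are free
parameters. Covariates (age, sex, a missing-MRI flag, synthetic clinical
scores) are drawn per participant so the confound machinery has
non-trivial inputs.

What the generator does *not* emulate: raw multichannel MEG, head
geometry and source leakage, motor-unit EMG structure, non-stationary
artefacts, or realistic clinical-score/physiology correlations. Passing
recovery tests therefore demonstrates the correctness of the analysis
chain, not its robustness to every property of real recordings.

# Inference

Group comparisons use two permutation engines, both authored here:

* **Cluster-based permutation test** on 1-D (time or frequency) or 2-D
  (time × frequency) grids: pooled-variance two-sample t per grid point,
  two-sided cluster-forming threshold at point-wise $\alpha = 0.05$,
  orthogonal adjacency, cluster mass = sum of t, null = permutation
  distribution of the maximum absolute cluster mass over random
  relabellings. $p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + B)$, so
  $p > 0$ always; when the number of distinct relabellings is at most the
  requested permutations, the enumeration is exhaustive and $p$ counts
  the identity relabelling instead of adding it.
* **Permutation GLM with max-t correction**: OLS per outcome, COPE =
  contrast · coefficients, $t = \text{COPE}/\text{SE}$. Confounds (age,
  sex, missing-MRI) are handled by the Freedman–Lane scheme: the
  confound-only model is fitted, its residuals are row-permuted, the full
  model is refitted, and the maximum |t| across outcomes per permutation
  builds the corrected null. Freedman–Lane is the standard choice when a
  permutation package is named but the scheme is not; it is known to be
  close to exact for this design family.

Family conventions mirror the study design: Bonferroni ×(tasks ×
hemispheres) for motor-CMC cluster tests, ×(tasks × 4 metrics) for
behaviour, max-t across metrics (and across tasks/hemispheres/regions
for topography). Welch's t, the Pearson chi-squared and Pearson
correlations are delegated to base R (`t.test`-equivalent closed form,
`chisq.test(correct = FALSE)`, `cor.test`); only the summary-statistic
Welch form is computed in-package because base R has no interface for it.

Calibration is enforced empirically: both engines hold their nominal 5%
type-I error within Monte-Carlo tolerance over 500 null simulations, and
both agree with exhaustive enumeration on small cohorts.

# Problem sizes and numerical choices

The simulation-based checks run at deliberate desk scale: recovery uses
20 cohorts of 10+10 participants × 60 trials; calibration uses 500 null
datasets × 500 permutations; direction checks use 50 end-to-end runs of
6+6 participants × 30 bilateral trials with 50 permutations (directions
are group-mean signs and need no permutation resolution). These sizes
give Monte-Carlo error comfortably inside the asserted tolerances while
keeping a full verification run in minutes on one core. Production
analyses should use the study-scale defaults (5000 permutations,
120-trial bilateral blocks).

Other numerical details: degenerate-variance grid points get $t = 0$
rather than NaN; zero-power coherence bins are defined as 0 with a
warning; confound columns with no variance in a small cohort are dropped
from the design (they carry no information and would break full rank);
all RNG flows from a single master seed through deterministic
per-participant/per-task sub-seeds, so every simulation, permutation and
CSV is bit-reproducible.

# Known limitations

* Parcels are whatever cortical channels the input provides; there is no
  source reconstruction, leakage correction or atlas handling.
* The text session store is plain CSV/JSON; it favours transparency and
  portability over speed and is not meant for hundreds of sessions.
* Detected burst amplitude is in units of the per-trial mean envelope;
  comparing amplitudes across channels with very different background
  levels conflates background with burst strength, as it does in any
  per-trial-normalized convention.
* The simulator's clinical covariates are uncorrelated with its
  neurophysiology by construction, so correlation analyses on synthetic
  cohorts are null calibrations, not effect demonstrations.

# A minimal run

```{r example, eval = FALSE}
cfg <- run_config(n_per_group = 6,
                  tasks = list(task_spec("bilateral", n_trials = 30)),
                  n_perm = 1000, seed = 1)
report <- run_analysis(cfg, out_dir = "results/run1")
report$directions          # signed ALS-minus-HC group mean differences
report$glm_tests$bilateral # max-t corrected burst-metric comparisons
```
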