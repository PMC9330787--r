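---
title: "Decoding turning intention during walking: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding turning intention during walking: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turnintent)
```

This vignette documents the science behind the package: the models each
stage implements, the tunable parameters and their defaults, what the
synthetic data generator does and does not emulate, and the choices made
where the design was genuinely open.

## The decoding problem

A walking subject spontaneously decides to turn. The trunk-worn IMU records
when the body actually turns; the EEG, in the seconds before, carries the
intention. The pipeline discriminates two mental states — *monotonous walk*
(steady walking, no intention) and *intention to turn* — and must do so
causally, epoch by epoch, as a real-time interface would.

Time zero of every repetition is the IMU-detected change instant. Training
windows are fixed relative to it: the walk class at $[-6.0, -4.8)$ s (far
enough before the turn that no preparation is plausible) and the intent
class at $[-1.4, -0.2)$ s (late enough that preparation is underway, ending
0.2 s early to keep motor-execution signals out). Both windows are 1.2 s =
600 samples at 500 Hz, matching the sliding-epoch length used online.

## IMU turn detection

The trunk orientation enters as two direction cosines $X_z, Y_z$ sampled at
50 Hz. The zenith-plane heading is
$\theta = \tan^{-1}(X_z / Y_z) \cdot 180 / \pi$, implemented with the
two-argument arctangent and unwrapping: the naive quotient is undefined at
$Y_z = 0$ and flips sign across quadrants, while `atan2` plus unwrapping is
identical in the operating range ($|\theta| < 90^\circ$) and robust outside
it.

Smoothing is an order-0 local regression (kernel-weighted moving average)
with a Gaussian kernel spanning 2% of the series length. Within that span
the kernel shape is free; we use a Gaussian truncated at $5\sigma$, i.e.
$\sigma$ = one tenth of the span. A narrow kernel matters: the detector
locates the maximum-curvature sample, and over-smoothing both widens and
shifts the curvature peaks of a step. With the $5\sigma$ truncation the
detector recovers 98–99% of synthetic turns within $\pm 0.5$ s.

Detection takes the second difference of the smoothed angle and tests the
thresholds $f \cdot \mathrm{mean}(|\Delta^2\theta|)$ for
$f = 6, 5, \ldots, 1$, stopping at the first factor with any exceeding
sample and returning the earliest such sample. Exact ties and multiple
candidates resolve to the earliest index. A numerically linear segment (all
curvature below $10^{-10}$ of the signal scale) raises a no-turn error
rather than returning noise.

The earliest-crossing rule anchors the detection at the *onset* of the
turn, not its midpoint. The synthetic generator therefore places its
ground-truth time at the sigmoid onset, with the midpoint half a rise time
later — the intention window should end where monotonous walking ends.

Direction labeling subtracts the pre-change mean and calls the repetition
*right* if the post-change mean is positive, *left* otherwise.

### Repetition quality control

Two printed criteria are ambiguous in direction; both are implemented the
only way their stated purpose admits, and both thresholds are arguments:

* walking time between the third-step mark and the change must be **at
  least** 6 s (shorter repetitions leave the walk-class window without
  data), so `walk_time_s < 6` discards;
* the net angle increment must deviate from the direction-class mean by
  **no more than** 25° (outlier discard), so deviation > 25° discards.

"Angle increment" is read as the net pre/post step size (not the peak
excursion). Profiles are aligned on the detected change sample and
referenced to their pre-change mean before correlating with the class mean;
correlation below 0.9 flags a mislabel. A direction with fewer than two
members cannot define a class mean, so its correlation criterion is
suppressed with a warning rather than inventing one.

## Artifact filtering

Both filters run on the broadband recording *before* band isolation — the
artifact estimate should see the artifact's full spectrum — and both are
strictly causal.

**H∞.** For each channel, the reference vector
$r_t = [\mathrm{vEOG}, \mathrm{hEOG}, 1]$ (vEOG = VU−VD, hEOG = HR−HL, the
conventional bipolar pairing) is adaptively regressed out by the
γ-suboptimal H∞ recursion — a worst-case-robust recursive least squares in
which the inverse-covariance state is inflated by $\gamma^{-2} r r^\top$
before each gain computation and perturbed by process noise $qI$ after.
The bias term absorbs slow drift. Defaults $\gamma = 1.15$, $q = 10^{-10}$
follow the convention of the method's literature; $\gamma \le 1$ is
rejected. "Epoch-by-epoch" application is interpreted as continuous
sample-wise state updating with no reset — a reset rule would discard the
converged weights the 15 s basal period exists to provide. One property of
this recursion worth knowing: its gain anneals roughly like $1/t$ toward a
floor set by $q$, so the filter's near-identity behaviour on clean data
sharpens with recording length.

**ASR.** Calibration eigendecomposes the covariance of a ≥ 60 s standing
baseline (shorter baselines are an error) and records per-component RMS
statistics over 0.5 s windows; the rejection threshold is mean +
`cutoff_k` standard deviations, with a conservative default
`cutoff_k = 20`. Processing steps a 0.5 s window every 0.2 s,
eigendecomposes the window covariance, flags window components whose
variance exceeds the calibration thresholds rotated into their direction,
and reconstructs the window from the retained subspace, emitting only the
new 0.2 s chunk. Samples before the first complete window pass through.

**Band filters** are order-2 Butterworth band-passes realized as
direct-form II transposed state variables. The state is carried across
chunks, so streaming 0.2 s chunks reproduces one-shot filtering to machine
precision; no zero-phase filtering is used anywhere. The five standard
bands are 8–14, 15–22, 23–30, 31–40 and 8–40 Hz; anything else requires
`custom_band = TRUE`.

## Covariance features and Riemannian classification

Each window's feature is its sample covariance matrix on the mean-centered
window, $X^\top X / (n-1)$. If rank-deficient, a ridge
$\varepsilon I$ with $\varepsilon = 10^{-10} \cdot \mathrm{tr}(S)/p$
(floored at $10^{-12}$) restores positive definiteness; the event is
recorded in an attribute.

SPD matrices are compared with the affine-invariant metric
$d(A,B) = \|\log(A^{-1/2} B A^{-1/2})\|_F$, which is invariant to common
linear mixing of the channels — the property that lets covariance
classifiers skip baseline correction. Class prototypes are Karcher means,
computed by the standard fixed-point iteration (log maps averaged at the
current estimate, exponential map back), tolerance $10^{-8}$ on the
gradient norm, at most 50 iterations, error on non-convergence with the
last iterate attached.

The four classifiers:

* **mdm** — nearest class mean under the metric; ties go to *walk*, the
  safe class for an assistive device (no spurious command).
* **mdm_filter** — geodesic-filtered MDM: project to the tangent space at
  the grand mean, keep only the component along the (shrinkage-regularized)
  Fisher discriminant direction, map back, then MDM. The "MDM with filter"
  construction is not uniquely defined in the literature we follow; the
  rank-one geodesic filter is the simplest supervised variant and is
  documented as such.
* **ts_lda** — tangent-space vectors ($\sqrt2$-weighted upper triangle of
  the log map at the grand mean) classified by LDA whose pooled covariance
  is shrunk toward scaled identity with a Ledoit–Wolf-style automatic
  intensity; necessary because the tangent dimension $p(p+1)/2 = 378$
  exceeds typical epoch counts.
* **ts_svm** — linear-kernel soft-margin SVM on the same vectors, cost
  $C = 1$, no scaling. Kernel and cost are not prescribed by the study we
  model; linear/1 is the field's default for tangent-space features.

Electrode subsets operate on the principal submatrix of every covariance,
consistently at train and predict time.

### Electrode ranking

$V = |\overline{C}_{\mathrm{intent}} - \overline{C}_{\mathrm{walk}}|$
entrywise, with **arithmetic** class means — the ranking visualizes a plain
difference map; Riemannian means are reserved for classification. The
upper triangle of $V$ (including the diagonal) is walked in decreasing
order, appending both electrodes of each entry until the subset sizes (15,
10, 5 by default) are filled, so subsets are nested. A diagonal-only
ordering is available via `entries = "diagonal"` since the source
description ("from the diagonal array, the highest pairs") admits both
readings. Identical class means produce an all-zero $V$; the ranking is
then flagged degenerate.

## Evaluation protocols

**Offline.** Leave-one-trial-out over the first eight trials (one for
testing, seven for the model), pooling test predictions.
$\mathrm{Acc} = 100 \cdot \mathrm{correct}/\mathrm{total}$; the balance
$b = 100 \cdot |\mathrm{Acc}_{\mathrm{intent}} -
\mathrm{Acc}_{\mathrm{total}}| / \mathrm{Acc}_{\mathrm{intent}}$ filters
one-sided classifiers at $b > 10$; the chance level is the adjusted-Wald
bound $0.5 + 1.96\sqrt{0.5^2/(n_{\mathrm{valid}}+4)}$. The squared
constant is read as $0.5^2$ (the Wald variance term), not $0.52$ — the
printed form is typographically ambiguous — and is switchable via the
`p0` argument. `AccTotal` is computed over pooled test windows; with the
protocol's one-walk-one-intent windows per repetition the classes are
balanced and pooling equals the unweighted class mean.

**Pseudo-online.** The model trains on trials 1–8 and replays trials 9–10:
1.2 s epochs every 0.2 s, classification evaluated only between the
third-step mark and the change. A command fires at every epoch whose last
5 consecutive evaluated predictions are all intent (any walk prediction
resets the run). A command within $[{\rm change} - 0.4\,{\rm s},
{\rm change}]$ is a TP and halts the repetition; other commands are FPs,
counted only if 2 s have passed since the last counted FP. The refractory
period suppresses *counting*, not prediction, and does not reset the run —
the simplest causal reading. FP/min divides counted FPs by the summed
evaluated intervals; this denominator convention is fixed here because no
single convention reproduces every published FP/min figure exactly.
Consequences of the geometry: the earliest sample that can contribute to a
valid TP lies $1.2 + 4 \times 0.2 + 0.4 = 2.4$ s before the change, and an
always-intent classifier is refractory-limited to exactly 30 FP/min.

**Online replay.** Mode 4 and a 0.6 s margin. Phase 1: 4 s of walking
where any command fails the trial instantly, then 8 s where commands are
logged as FPs and also fail. Phase 2, reached only on a clean phase 1: a
command in $[{\rm change} - 0.6, {\rm change}]$ is a TP; earlier or after
the IMU detection is an FP. For each TP the first and last classification
of the run are $1.2 + 3 \times 0.2 = 1.8$ s apart, which fixes the
first-command anticipation given the last.

## The synthetic generator

The generator emulates exactly the assumptions the analysis rests on, and
nothing more:

* **IMU**: a heading staircase with logistic steps of ±45°, 10–90% rise
  time 0.6 s, walking segments uniform on 8–10 s, a 15 s standing basal
  prefix, sinusoidal gait sway (2° at 0.9 Hz) while walking, and white
  sensor noise (0.3°). Directions alternate by default.
* **EEG**: 27 channels drawn iid from a class covariance — `cov_walk`
  everywhere, `cov_intent` in the 1.4 s before each turn (configurable via
  `intent_onset_s`; when the neural change actually begins is unknown, so
  it is set to the earliest extent of the intent window). The default
  class pair sits at affine-invariant distance 1.5, scaled to 10 µV RMS.
* **Artifacts**: blinks as 200 ms raised-cosine lobes on VU (with a
  counter-lobe on VD), saccades as 0.8 s opposed steps on HR/HL, mixed
  into the EEG with gains decaying front to back; optional 0.1 Hz drift;
  optional Poisson bursts (0.5 s, ~300 µV on three random channels) for
  ASR to remove. None of this is biophysical; it exists to give each
  filter a ground-truthed artifact.
* **Session**: a 60 s artifact-free walk-statistics baseline plus
  `n_trials` trials with markers and ground truth attached.

Everything is deterministic under a seed, and `make_spd_pair` places its
two matrices at an exact requested geodesic distance, which the
recovery-versus-separation tests exploit.

**What this does not show.** Real EEG epochs are not iid draws from a
fixed class covariance: covariances drift within and across trials, the
intent onset varies, and class overlap is intrinsic. Because our epochs
*are* iid, offline accuracy saturates near 100% already at moderate
separations (in 378 tangent dimensions even small mean differences are
separable), where real subjects score 60–90%. Passing tests therefore
validate the *machinery* — window placement, causality, geometry, decision
logic, metric arithmetic — not the attainable accuracy on real recordings.
The pseudo-online TP rate is informative in a way offline accuracy is not:
sliding epochs straddle the class boundary, so even a perfect classifier
detects only a fraction of turns inside the strict margin, as live systems
do.

## Numerical choices and degenerate inputs

* Sample indexing is 0-based with half-open windows $[t_0, t_1)$; all
  times in seconds; EEG in microvolts; IMU cosines dimensionless.
* EEG and IMU streams share $t_0$ and are index-aligned at the exact 10:1
  rate ratio; skew beyond one IMU period is a sync error.
* Sessions are stored as CSV (17 significant digits, hence lossless round
  trips) plus a JSON marker sidecar; the manifest carries MD5 checksums,
  so equal generator seeds give byte-identical layouts.
* Non-finite samples are rejected at ingestion; zero-variance channels
  regularize with a warning; both-zero IMU cosines are an undefined-angle
  error; empty trial lists write a valid, empty session.
* Problem sizes in the test suite are scaled to the structure each check
  needs (e.g. 5–8-dimensional covariances for geometry oracles, 13 trials
  × 8 repetitions for the detector-recovery property, 40 000 samples for
  the H∞ identity check), chosen as the smallest sizes at which the
  property is meaningfully exercised.

## Known limitations

* The H∞ and ASR variants are faithful causal implementations of their
  published recursions' structure, but hyperparameters the source study
  never printed (γ, q, cutoff, window) carry field-conventional defaults.
* The geodesic filter in `mdm_filter` is rank-one; richer supervised
  filters exist.
* The online replay drives phase timing from the trial's markers; it
  replays recorded or synthetic streams and does not model feedback to the
  subject.
* Step detection is out of scope: third-step marks are inputs.
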