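# turnintent

Decoding the intention to turn during walking from EEG spatial covariance
matrices, with the physical turn instant labeled from a back-worn IMU.

## The problem

Asynchronous lower-limb brain–machine interfaces must detect a user's
*intention* before the movement happens, causally, from EEG alone. This
package implements a complete pipeline for the two-class problem
**monotonous walk** vs **intention to turn**:

1. **IMU turn labeling.** The trunk sensor's direction cosines give the
   zenith-plane heading angle via the quadrant-aware inverse tangent; after
   Gaussian kernel smoothing, the change instant is the earliest sample whose
   second difference (curvature) exceeds an iteratively lowered multiple of
   the mean curvature, and the post-change mean sign labels the turn left or
   right. A quality-control stage discards repetitions with an atypical angle
   profile (correlation with the direction-class mean < 0.9, net increment
   deviating > 25°) or with less than 6 s of walking before the turn.
2. **Artifact mitigation**, causal by construction: an adaptive H∞ filter
   regresses the bipolar EOG derivations and a drift-tracking bias out of
   every channel, or artifact subspace reconstruction (ASR) removes
   high-variance components relative to a 60 s standing baseline, stepped
   every 0.2 s.
3. **Band isolation** by causal order-2 Butterworth state-variable filters
   into 8–14, 15–22, 23–30, 31–40 or 8–40 Hz.
4. **Riemannian classification.** Each 1.2 s epoch is summarized by its
   sample covariance matrix (SCM), a symmetric positive-definite (SPD)
   matrix. Under the affine-invariant metric,
   `d(A, B) = sqrt(sum(log^2(eig(solve(A) %*% B))))`, classes are modeled by
   their geodesic (Karcher) means — minimum distance to mean (MDM), a
   geodesic-filtered MDM, and tangent-space LDA/SVM variants.
5. **Evaluation.** Leave-one-trial-out cross-validation with a chance-level
   filter `0.5 + 1.96 * sqrt(0.25 / (n_valid + 4))` and a class-balance
   filter `b = 100 * |Acc_intent − Acc_total| / Acc_intent <= 10`; a causal
   pseudo-online replay (command after 5 consecutive intent epochs, true
   positive within 0.4 s of the turn, 2 s refractory between counted false
   positives, TP%, FP/min, FPRatio, TPnoFP); and a two-phase online replay
   (mode 4, 0.6 s margin) with per-trial command anticipations.

Because no recordings are distributed for this paradigm, a synthetic session
generator reproduces the statistical structure the pipeline assumes —
gait-modulated heading staircases with ±45° sigmoidal turns, EEG drawn from
class-dependent spatial covariances, EOG-mixed ocular artifacts, drift and
bursts — so that every stage is testable end to end.

## Worked example

```r
library(turnintent)

ses <- gen_session(seed = 42, n_trials = 10)   # ~8 turns x 10 trials
cfg <- run_config(artifact_filter = "hinf", band = "8-40",
                  classifier = "mdm")

head(detect_turn_events(ses$trials[[1]]), 3)
#> # A tibble: 3 x 6
#>   repetition change_sample change_time_s direction pre_mean_deg post_mean_deg
#>        <int>         <int>         <dbl> <chr>            <dbl>         <dbl>
#> 1          1          1185          23.7 left           -0.0679         -36.0
#> 2          2          1614          32.3 right         -45.0             34.7
#> 3          3          2035          40.7 left           -0.0146         -35.5

loto_cv(ses, cfg)
#> <cv_result> Acc 100.0% (walk 100.0, intent 100.0), b 0.0, chance 62.1%,
#>             62 valid repetitions -> valid

ep  <- lapply(ses$trials[1:8], function(tr) {
  q <- qc_repetitions(tr, detect_turn_events(tr))
  extract_class_epochs(preprocess_trial(tr, cfg), q, cfg)
})
mod <- fit_riemann(dplyr::bind_rows(ep), "mdm", config = cfg)
pseudo_online(ses, mod, cfg)   # trials 9-10 held out
#> <detection_timeline> 16 repetitions: TP 37.5%, 0.0 FP/min,
#>                      FPRatio 0.0%, TPnoFP 37.5%
```

Reading the output: every detected turn sits within half a second of the
generator's ground truth and directions alternate as scripted. Offline
accuracy saturates on this idealized synthetic family (see the vignette for
why), clearing the 62.1% chance bound with perfect class balance. In the
causal replay only 37.5% of turns produce a command inside the strict 0.4 s
window — sliding epochs straddling the class boundary dilute consecutive
intent runs — which is the same order as live asynchronous operation.

Result objects are tibble-friendly: `tidy()` returns per-fold or per-event
tables, `glance()` one-row summaries, and `autoplot()` draws detection
timelines and electrode-ranking maps.

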