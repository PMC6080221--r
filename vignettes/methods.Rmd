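---
title: "Methods: the myograsp grasp-force pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the myograsp grasp-force pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myograsp)
```

`myograsp` implements an end-to-end myoelectric grasp-force pipeline:
synthetic 8-channel sEMG/force acquisition, time-domain features over
overlapping windows, PCA reduction, a stacked-sparse-autoencoder (SAE)
level classifier with per-level force regressors, and a simulated fuzzy
grasp loop. This vignette documents the models, the tunable parameters
and their defaults, the numerical choices, and what the synthetic data
do and do not establish.

## The task and the level scheme

Grip force during a three-finger pinch is regulated in eight discrete
levels spanning 0–40 N, i.e. 5 N per level; discrete levels keep
grasping stable and match what vibrotactile feedback can convey. Bins
are half-open `[lo, hi)` with the top bin closed, so 0 N is level 1,
5 N is level 2 and 40 N is level 8; the shared-edge convention is
arbitrary but fixed and tested. A window's label is the quantized mean
of its synchronized force window.

## Synthetic acquisition model

No public recordings exist for this protocol, so the generator is a
first-class, tested module. A session is: 1 s rest, a 50 ms ramp, a
hold of uniform 4–6 s at a plateau drawn uniformly *inside* the
requested level's bin (inset by 5% of the bin width from each edge),
a 50 ms release, 1 s rest. The plateau carries AR(1)-smoothed tremor
(SD 0.3 N). Drawing the plateau inside the bin (rather than at its
center) keeps labels recoverable by quantization while exercising the
full bin; the small inset keeps tremor from flipping labels at bin
edges and avoids near-zero holds at level 1.

Each sEMG channel is zero-mean white noise multiplied by a
deterministic envelope

\[ \mathrm{env}_c(t) = b + g_c\, j_c\, m(F(t)), \qquad
   m(F) = m_0 + (1 - m_0)\,(F/F_{\max})^{q},\; m(0)=0 , \]

with rest envelope `b = 0.008` (signal units), per-subject channel
gains \(g_c \sim \mathrm{LogNormal}(0, 0.25)\), per-trial gain jitter
\(j_c\) (SD 2%), an activation floor \(m_0 = 0.05\) capturing the
recruitment jump at grip onset, and exponent \(q = 2\) for the
superlinear amplitude–force growth commonly seen in EMG. The envelope
is a monotone function of the *instantaneous* force, so ramps are
consistent with holds.

The default carrier is amplitude-stabilized broadband noise,
`sign * |1 + cv·z|` with `cv = 0.08` and `z` standard normal: white
(flat spectrum), zero-mean, but with a steady short-window amplitude,
emulating the conditioned output of consumer armbands whose envelope is
stable at constant force. A raw Gaussian carrier is available
(`carrier = "gaussian"`), but its 50 ms windows carry ~8% relative
amplitude-estimation noise at 8 channels
(\(1/\sqrt{2\cdot 10\cdot 8}\)), which no classifier can overcome at
the upper force levels; the stabilized carrier is calibrated once so
that the ideal single-window force resolution (~0.2 N at the top level)
supports the 8-level discrimination this class of pipeline demonstrates
on real subjects. Spectral shaping is deliberately absent: at 200 Hz
only amplitude statistics matter to time-domain features.

What the generator does *not* emulate: motor-unit physiology, electrode
shift and donning variability, fatigue, and cross-channel correlation.
Passing tests therefore show pipeline correctness and statistical
adequacy under the stated signal model, not performance on real sEMG.

All randomness flows from one integer master seed through a documented
affine splitting scheme (`split_seed`): per-subject seeds, per-session
seeds and per-model initialization seeds are derived, never drawn from
a shared stream, so results are independent of evaluation order.

## Segmentation, windows, features

Activity is detected by summing the per-window MAV of all channels and
comparing with a threshold; a segment opens at the first window at or
above threshold and closes before the first window below it. The
threshold is not fixed in absolute units: the default is 3× the summed
MAV of a known rest stretch (the first 0.5 s), which is scale-free
across subjects and gains. Windows are 50 ms advanced by 25 ms (10 and
5 samples at 200 Hz), anchored at the segment start; trailing partial
windows are discarded (the feature formulas assume fixed N), and by
default one window is trimmed at each segment end to drop
onset/release transients. Whether windows should be anchored to
detected onsets or to the raw recording is an open choice; anchoring to
onsets is used because the rest periods carry no force information.

Features per channel and window, in fixed order MAV, RMS, SD
(denominator N−1), WL, laid out channel-major — the ordering is part of
the model contract since PCA loadings and network weights are bound to
column identity. Three-channel subsets are supported by explicit
listing only; no automatic channel selector is provided.

## PCA

Rows are centered, by default z-scored (WL and MAV live on different
scales; without standardization WL dominates the covariance —
configurable off), and projected on the top-k eigenvectors of the
covariance. `k = 8` by default (32 → 8), `k < n` enforced.
Zero-variance columns get scale 1 and contribute nothing. Axes are
oriented so each one's largest-magnitude loading is positive, making
serialized models reproducible; eigenvalues are kept in full for
variance accounting. PCA is fitted per subject, matching the
per-participant analysis; pooled fitting is a config choice away.

## The stacked sparse autoencoder

Two sigmoid hidden layers of 200 units. Inputs are min-max scaled to
[0, 1] per feature using training-set ranges (sigmoid reconstruction
needs bounded targets). The autoencoder cost is

\[ J = \tfrac12 \sum_{i}\lVert \hat x_i - x_i\rVert^2
     + \tfrac{\lambda}{2}\sum W^2
     + \beta \sum_j \mathrm{KL}(\rho\,\Vert\,\hat\rho_j), \]

with \(\rho = 0.1\), \(\lambda = 3\times10^{-3}\), \(\beta = 1\), and
\(\hat\rho_j\) the batch-mean activation of hidden unit j, clamped to
\([10^{-6}, 1-10^{-6}]\) before the logarithms. The data term is
summed, not averaged, over the batch: these coefficient values balance
the three terms only under that convention — with a batch-averaged
data term the collapsed autoencoder (hidden pinned at \(\rho\),
reconstruction by bias alone) becomes the global optimum for 8-dim
inputs and fine-tuning then starts at an exact saddle; both facts are
verified numerically in the test suite's training-dynamics checks.

Training is deterministic: symmetric-uniform fan-scaled seeded
initialization, full-batch L-BFGS-B (no stochastic minibatches), 100
iterations per stage by default — the costs are smooth and converge
well before that at the default problem sizes. Greedy layer-wise
pretraining (layer 2 trains on layer 1's activations) is followed by a
convex softmax-head fit (zero-initialized) and end-to-end fine-tuning
of encoder plus head; training costs are recorded and non-finite costs
abort with diagnostics. Argmax ties break toward the lower level — the
weaker grip is the safer default in a control context.

Force prediction is classify-then-regress: one regressor per level,
same architecture with a scalar linear head (forces in newtons are
unbounded regression targets; outputs are clipped to [0, 40] N at
predict time), each initialized from the same pretrained stack and
fine-tuned on its level's training rows. The regressors consume the
same 8 PCA components as the classifier.

## Evaluation protocol

Per subject: 6 repetitions per level give ≥ 800 windows per level; the
windows of each level are shuffled (seeded) into a 400-group training
pool and a 400-group testing pool (disjoint by construction), of which
200 + 200 are sampled — 6400 groups per subject in total. PCA and all
models are fitted on the training groups only. Reported quantities:
accuracy per level per subject, its mean and sample SD over subjects
(the between-subject SD), the pooled confusion matrix, and the mean
recognition rate defined as the mean over subjects of each subject's
mean accuracy over levels. `compare_configs` re-runs the pipeline on
an identical cohort (shared generator seed enforced) for paired
channel/feature/dimension comparisons.

Default problem sizes were chosen so the full 15-subject experiment
runs in a few minutes on one CPU: hidden layers of 200, 100 L-BFGS
iterations per stage, 1600 training rows per subject. The test suite
uses smaller cohorts (reduced pools, 30-unit layers) for everything
except the headline end-to-end check.

## The fuzzy grasp loop

The predicted force is the setpoint of a Mamdani controller over force
error (universe ±40 N) and error change (±5 N/step): five evenly
spaced triangular terms per variable, shouldered at the ends so every
input activates at least one term; the 25-rule PD-style rulebase
`out = clamp(i + j − 3, 1, 5)`; min-AND, max-aggregation; and *exact*
centroid defuzzification — the aggregate membership is piecewise
linear, so integrating over a partition refined at term knots, clip
corners and pairwise crossings is exact (the suite cross-checks against
a dense-grid oracle). The controller outputs command increments
(universe ±0.04 actuator units/step); the command integrates, which
removes steady-state offset. The continuous predicted force is
regulated by default; regulating the bin midpoint of the predicted
level is available (`setpoint_mode = "midpoint"`).

The plant is a first-order lag (τ = 0.15 s, 40 N per unit command,
force floored at 0) — the simplest model that exercises the loop; the
FSR sensor adds optional Gaussian noise. Commands are clipped to
[0, 1.5] units and the loop starts at the plant's equilibrium command.
Settling is first entry into the ±5% band (floor 0.25 N) without later
exit; steady-state error is the mean absolute error over the final 10%
of the trace. Sensed force, clipped to [0, 40] N, quantizes to the
vibration level with frequency 50 + 25·(L−1) Hz — the mapping is an
arbitrary documented convention; only its strict monotonicity matters.

## Serialization

Sessions are CSV (one row per sample: `time_s`, `emg_1..emg_C`,
`force_N`; 0-based sample indexing, time = index / rate) with a JSON
sidecar declaring shape and metadata; cohorts add a JSON manifest.
Models are JSON bundles holding every weight matrix at 17 significant
digits, which round-trips IEEE doubles exactly — reloaded models
predict bit-identically, and the suite asserts it. Schema versions are
embedded and checked. sEMG units are arbitrary armband units and are
treated as such throughout.

## Known limitations

- The synthetic cohort is the only data source; all accuracy figures
  are surrogate figures under the stated signal model.
- The SAE optimizer is full-batch; dataset sizes beyond a few thousand
  rows per subject would warrant minibatching, which is out of scope.
- The fuzzy controller's memberships and rulebase are a conventional
  design, not fitted to any plant identification.
- Electrode-shift robustness, fatigue and amputee-specific signal
  properties are not modeled.
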