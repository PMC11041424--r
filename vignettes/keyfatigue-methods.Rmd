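---
title: "Detecting mental fatigue from keystroke dynamics: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting mental fatigue from keystroke dynamics: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(keyfatigue)
```

## The problem

Mental fatigue degrades fine motor control: typing slows and becomes more
variable. Because keystroke press/release timestamps can be collected
passively on commodity keyboards, typing rhythm is an attractive,
unobtrusive digital biomarker for fatigue. keyfatigue implements a complete
detection pipeline for this signal: per-key timing features, a recurrent
typing-pattern embedding, a metric-learning fatigue adaptation stage, a
pairwise change/no-change evaluator, a sequential (CUSUM) active detector,
and an hourly trend estimator for unlabeled real-world streams. A synthetic
typist simulator stands in for the proprietary cohorts this class of study
uses, so the whole pipeline runs and is tested without any external data.

## Timing representation

Each session is reduced to four per-key features, all in seconds: hold
(release − press of one key), flight (press-to-press of consecutive keys),
inter-key latency (previous release to next press; negative under rollover,
when a key goes down before the previous one is released), and
inter-release latency. The first key of a window has no predecessor, so its
latency features are zero — this keeps matrices rectangular and matches the
zero-padding semantics of the model input. Windows are fixed at 150 keys:
shorter sequences are zero-padded (and masked downstream), longer ones
truncated to their first 150 keys. Seconds are the only normalization:
natural typing latencies sit in roughly 0.05–1 s, which keeps inputs near
unit scale for the recurrent layers without any dataset-dependent scaling.
Negative latencies are preserved (rollover is informative); an optional
symmetric clip (`clip = 5` seconds) guards against clock glitches.

Long supervised sessions (15 minutes contain thousands of keys) are sliced
into consecutive non-overlapping 150-key windows; a trailing fragment is
kept only if it has at least `minWindowKeys = 30` keys. This windowing is
what turns two labeled sessions per state into the many per-participant
samples the triplet sampler and the pair evaluator need. Continuous
real-world streams are split into sessions wherever the inter-press gap
exceeds 60 s (configurable; logged in the session metadata).

## Typing-pattern backbone

The embedding network v(x) is two LSTM layers of 128 units (recurrent
dropout 0.2, dropout 0.5 between layers, both active only during training),
with masking so that padded rows contribute neither to the embedding nor to
any gradient; the embedding is the final layer's output at the last valid
timestep. The LSTM forward pass and backpropagation through time are
implemented in vectorized R on BLAS matrix operations, verified against
finite-difference gradients in the test suite.

Pretraining uses identity triplets — anchor and positive are windows of one
typist, the negative comes from another — with the hinge triplet loss

\[ \ell = \max(0,\; d(v_A, v_P) - d(v_A, v_N) + \alpha), \]

on Euclidean distances, so same-typist windows cluster. This is a
desk-scale stand-in for pretraining on an internet-scale sentence-typing
corpus: the transfer design only requires *a* typing-pattern embedding, and
`loadWeights()` accepts externally produced checkpoints of matching shape.
Defaults: 40–200 synthetic users, 10–15 sessions of about 70 keys, Adam at
learning rate 0.001 decayed linearly to 10% (the 0.005 rate used for the
adaptation head diverges when training the LSTM from scratch at this
scale), margin α = 1.5. On the bundled simulator this yields held-out
identity-verification AUC above 0.8, including on typists never seen in
pretraining — enough identity structure for the fatigue stage to adapt.

## Fatigue adaptation

The backbone is frozen — asserted bit-identical before and after — and a
single dense 128-unit relu layer g(·) is trained on top of the fixed
embeddings, again with the triplet loss, but with *fatigue state* as the
class and all three samples drawn from the same participant (this keeps
inter-individual typing differences out of the contrast). Anchor/positive
are distinct windows of one class, the negative is a window of the other
class; sampling is uniform (no hard-negative mining). Training follows the
published transfer recipe: Adam (0.005, β₁ 0.9, β₂ 0.999, ε 1e−8), 30
epochs × 100 batches × 64 triplets by default; the schedule is reducible
through `adaptationConfig()` and the desk-scale tests run 6 × 40 × 48.
The margin value is not printed in the source study; α = 1.5 follows the
upstream typing-network convention and is config-exposed.

Evaluation is subject-independent throughout: a leave-one-participant-out
protocol trains one head per held-out participant (their samples are
excluded from the training triplets by construction, and a canary test
verifies that corrupting held-out labels cannot change the trained head).
The held-out participant's windows form intra-participant pairs; the pair
score is the Euclidean distance in g-space, and a score above threshold
calls a *change* (fatigue→rest or rest→fatigue). ROC analysis is pooled
across folds or vertically averaged per participant on a common
false-positive grid; the operating point is the closest-to-(0,1) ROC
corner, ties toward higher sensitivity. Comparison arms: a softmax head
(same frozen-backbone regime, binary cross-entropy), and random forest /
Gaussian-kernel SVM / k-NN on 20 summary statistics per sample (mean,
median, SD, 25th, 75th percentile of each timing feature — the statistic
set is this package's choice, as the source study does not enumerate its
"statistical keystroke features"). The baselines run either on the same
150-key windows or on full 5-minute spans (≈1100 keys), under the same
leave-one-out folds.

## Active (sequential) detection

For real-time monitoring each session's fatigue embedding is reduced to a
scalar score. The default projection is the signed coordinate along the
unit vector from the rest centroid to the fatigue centroid of the training
folds (deterministic and inductive); a seeded one-dimensional t-SNE is
retained as the historically faithful option, with the caveat that 1-D
t-SNE is transductive and seed-sensitive. Class densities f_R and f_F are
Gaussian kernel density estimates (Silverman bandwidth) of rest and
fatigue scores, and each new session contributes a log-likelihood ratio
L_j = ln f_F(score_j) − ln f_R(score_j), accumulated by a clamped
Page-style CUSUM

\[ S_j = \max(0,\, S_{j-1} + L_j), \]

which idles near zero while the typist is rested and climbs once
consecutive sessions look fatigued; an alarm fires when S reaches a
threshold τ.

Density source matters. Fitting f_R/f_F from the *participant's own*
remaining scores (the default) absorbs the strong participant-specific
score offsets that this family of models exhibits; fitting them from the
training participants only (`densitySource = "training"`) is fully
subject-independent but leaves those offsets in, and measurably degrades
the detector on the synthetic cohorts. Both modes are provided; the mode
used is part of the run configuration. Densities are fitted on the
participant's labeled window scores as a pool — with ~30 scores per
participant, strict per-session leave-one-out would change one kernel in a
30-sample estimate.

Calibration sweeps τ over 200 values spanning the observed cumulative-score
range, on simulated monitoring sequences built by concatenating 15 rest
then 15 fatigue windows per held-out participant: PFD is the fraction of
sequences alarming before the change, PND the fraction never alarming after
it, and ADD the mean sessions from change to first alarm. ADD censors
non-detections at the sequence end; the mean over only-detected sequences
(also reported) is not monotone in τ, because slow sequences drop out of
the detected subset as τ rises. The operating threshold is the PFD = PND
crossing (equal error rate), found by linear interpolation on the grid.

### Numerical choices

- Density evaluations are floored at 1e−12 so log-likelihood ratios stay
  finite outside the kernel support.
- Kernel density estimates of a log-density are only trustworthy where the
  class has data: beyond ~2–3 SD from a class's scores the KDE-based L has
  order-one error regardless of bandwidth (tail variance plus the floor),
  so the LLR convergence test is meaningful in the central region between
  the class means, not at the extremes.
- The CUSUM recursion is exactly equivalent to the clamped maximum over
  suffix sums; the tests assert this against a brute-force oracle.
- Degenerate inputs error early: all-equal scores (zero bandwidth), fewer
  than 5 scores per class (with a pointer to pooled-cohort fallback),
  coincident projection centroids, single-class ROC input.

## Real-world trend estimation

Unlabeled streams are scored per participant on consecutive-session pairs
less than 2 hours apart within the same day (longer gaps and
midnight-crossing pairs are artifact-prone and excluded). Each eligible
session is compared against the participant's *running reference*, the mean
of all their earlier session embeddings — users act as their own controls.
The default pair score is the signed component of the deviation from that
reference along the supervised cohort's rest→fatigue centroid axis:
slowing beyond the personal baseline raises the score, unusually brisk
typing lowers it. The plain Euclidean distance to the reference is
available (`scoreType = "distance"`) but is structurally U-shaped around
the running mean — any atypicality raises it, in both directions — and on
the simulated circadian stream it recovers the injected daily profile much
more weakly (hourly rank correlation ≈ 0.6 versus ≈ 0.95 for the signed
score). Scores are binned by hour of day of the later session; bins report
the mean, a bootstrap 95% CI, and the pair count; hours without eligible
pairs are missing, not zero.

## The typist simulator

The simulator exists so that every stage has a measurable ground truth.
Hold times and inter-key latencies are log-normal (positive,
right-skewed, medians 0.1 s and 0.2 s), with rollover producing negative
latencies at a configurable rate. Fatigue acts multiplicatively: at latent
level ℓ ∈ [0,1], log-means shift by ℓ·log(meanScale) and log-SDs inflate by
1 + ℓ·(sdScale − 1) — slowed *and* more variable output. Per-typist
parameters come from population hyper-priors, including a log-normal
spread on the fatigue effect so cohorts contain weak responders and the
intra-participant pairing logic is genuinely exercised. Three protocols are
emulated: a supervised cohort (14 participants, 2 rest + 2 fatigue
sessions of 15 minutes; the desk-scale tests use 6-minute sessions), a
pretraining corpus (hundreds of users, ~70-key sessions), and a daily
stream (~3-minute unlabeled sessions, hourly over waking hours 07–23, with
latent fatigue following a sharpened cosine peaked at the acrophase —
alertness dominates most of the day, fatigue concentrates around the peak —
plus a post-lunch dip bump and noise).

What the simulator does *not* emulate: linguistic or key-identity
structure (keycodes are discarded by design), session-level
non-stationarity such as warm-up or pauses within a session, device and
keyboard heterogeneity, and any physiological model of sleep inertia — the
fatigue effect is a parametric timing shift, not an estimate of the real
phenomenon's effect size. Passing recovery tests therefore demonstrates
that the pipeline's machinery works end to end under its stated
assumptions, not that the printed performance numbers of any real cohort
are reproduced; the real supervised databases in this literature are not
publicly packaged.

## Problem sizes and reproducibility

The bundled tests and the acceptance script run on deliberately desk-scale
configurations: a 40-typist pretraining corpus (10 × ~70-key sessions
each), 10 × 20 × 32 pretraining triplet batches, 14-participant cohorts
with 6-minute sessions, 6 × 40 × 48 adaptation batches per fold, 15 + 15
session monitoring sequences, and a 6-typist, 2-day hourly stream. Every
stochastic step is seeded: generators, triplet samplers, dropout masks,
subsampling and bootstraps all derive from explicit seeds, and identical
seeds give bit-identical results on a given platform.

## Known limitations

- The backbone is trained at desk scale; its embeddings carry far less
  typing structure than an internet-scale pretraining would provide. The
  weight-loading hook exists precisely to swap in a stronger checkpoint.
- 1-D t-SNE projections change with the point set (transductive) and the
  seed; the centroid-axis projection is the stable default.
- Within-participant density fitting uses the held-out participant's
  labels for calibration, as the original design implies; the fully
  subject-independent mode is provided and measurably weaker.
- Hourly trend CIs bootstrap scores within a bin and ignore the
  participant-level clustering of pairs.
- The simulator's i.i.d. log-normal keystrokes have no serial
  autocorrelation within a window, which likely makes identity and fatigue
  signals somewhat easier to read than in natural typing. A visible
  consequence: the advantage of 5-minute over 150-key samples that real
  cohorts show for the statistical baselines does not emerge here — with
  i.i.d. keystrokes, 150-key summary statistics are already nearly
  sufficient, and the 5-minute arm simply has fewer training samples.
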