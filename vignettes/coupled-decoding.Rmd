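---
title: "Coupled multi-task decoding of valence, arousal and dominance from EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled multi-task decoding of valence, arousal and dominance from EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(eegcouple)
```

## The problem and the model

Affective state is conventionally described by three dimensions — valence
(pleasantness), arousal (intensity) and dominance (sense of control) — each
binarized here to high/low. Most EEG decoders treat the three dimensions as
independent classification problems, ignoring what affect theory and
neurophysiology say about their coupling: the circumplex structure of the
valence–arousal plane, the co-variation of arousal intensity and dominance,
and the statistical tendency of positive affect to accompany high control
(with exceptions such as anger: negative valence, high dominance).

`eegcouple` implements a hard-parameter-sharing multi-task decoder that makes
these couplings part of the training objective. The architecture is:

* a **shared encoder**: a patch embedding over the (channels x samples)
  segment followed by four visual state-space (VSS) blocks at constant
  resolution, producing a unified token grid `F_sh`;
* three **task branches** (valence, arousal, dominance), each one VSS block
  followed by three downsample-plus-VSS stages (channel width doubles at
  each downsample, ending at 8x the embedding width), producing `F_V`,
  `F_A`, `F_D`;
* per branch, a **classifier head** (norm, adaptive average pooling to 1x1,
  flatten, fully connected, sigmoid) giving probabilities `P_V`, `P_A`,
  `P_D`, and a **feature head** (norm, global average pooling, linear
  reduction) giving embeddings `f_V`, `f_A`, `f_D` of width `d_f` that are
  used only by the coupling losses, never for classification.

The joint objective combines per-dimension binary cross-entropy with three
coupling constraints:

* **V–A circular**: `1 - cos(V_p, V_t)` between the predicted probability
  vector `V_p = (P_V, P_A)` and the binary label direction
  `V_t = (y_V, y_A)`, with an `eps`-guarded denominator. It pulls the
  prediction vector toward its label quadrant in the circumplex plane.
* **A–D energy alignment**: `(||f_A|| - ||f_D||)^2`, matching the activation
  intensity of the arousal and dominance embeddings.
* **V–D correlation**: `1 - cos(f_V, f_D)` with a `tau`-guarded denominator,
  encouraging the valence and dominance embeddings to stay correlated.

The total is `lambda * (L_V + L_A + L_D) + lambda1 * L_VA + lambda2 * L_AD +
lambda3 * L_VD` with defaults `(1.0, 0.15, 0.1, 0.1)` — the calibrated
operating point of the method, which we adopt as-is.

## Design decisions in the loss system

Several details are deliberately fixed and documented rather than left
implicit:

* **Label reading of the V–A target.** The circular constraint's target
  vector uses the raw binary labels. In the `(0, 0)` label cell the
  numerator is zero, making the term a constant 1 with zero gradient: the
  constraint is *inert* for all-low samples rather than remapped. An opt-in
  `{-1, +1}` remapping is not provided in the default pipeline because it
  changes the geometry the constraint is meant to enforce.
* **Scope of the A–D term.** The energy-alignment formula is unconditional,
  but the physiological motivation speaks of high-arousal states. The
  default applies the term to all samples (formula-faithful);
  `ad_mask = "high_arousal_only"` restricts its batch mean to samples with
  `y_A = 1` (an empty mask contributes 0).
* **Batch reduction.** Every term is the arithmetic mean of per-sample
  values, so the weights are batch-size independent.
* **Guards.** `eps = tau = 1e-8`: small enough not to bias cosines of
  O(1) vectors, large enough to keep the terms differentiable at zero
  norms. Probabilities are clamped to `[1e-7, 1 - 1e-7]` before logarithms,
  so the cross-entropy is always finite; the cross-entropy gradient is
  taken through the unclamped sigmoid (the standard numerically stable
  form).
* **`d_f = 64`** for the feature-head embeddings by default; the coupling
  losses only need enough width for norms and angles to be informative.

## The state-space blocks

The VSS block follows the established visual-state-space design: layer
norm, a gated linear expansion (`expansion = 2`), a depthwise 3x3
convolution with SiLU, then four directional selective scans over the token
grid (row-major left-to-right and right-to-left, column-major top-to-bottom
and bottom-to-top). Each scan runs the recurrence
`h_t = exp(delta_t A) h_{t-1} + delta_t B_t u_t`, `y_t = C_t h_t + D u_t`
with input-conditioned `delta_t`, `B_t`, `C_t` (zero-order-hold
discretization of the continuous state-space model; the input term uses the
standard first-order simplification). The four directional outputs are
summed, normalized, gated, projected back to the block width, and added
residually.

Numerical and initialization choices:

* The recurrence is implemented sequentially in compiled code and is the
  reference semantics; there is no parallel-scan approximation. The forward
  pass caches the discretization factors `exp(delta A)` so the backward
  pass only replays multiply-adds.
* All gradients are computed by hand-derived backpropagation (the test
  suite validates every layer and the end-to-end model against central
  finite differences at relative error below 1e-4).
* Projections initialize truncated-normal (sd 0.02, clipped at 2 sd); each
  block's output projection starts at zero, so the whole network begins as
  the identity map on the token grid — training starts from a stable
  residual stream. The state matrix uses `A = -exp(A_log)` with
  `A_log = log(1..N)` per channel, and the step bias is drawn so the
  initial `delta` lies log-uniformly in `[1e-3, 1e-1]`.
* `patch 4x4, embed_dim 32, state_dim 8, expansion 2` are the default
  widths, chosen so a 32 x 128 segment (an 8 x 32 token grid) survives
  three downsamplings; they are explicit configuration, not claims about
  any particular published instantiation.
* Odd grid edges are zero-padded, never truncated, in both the patch
  embedding and the 2x2 patch-merging downsample.
* A `lite` block variant replaces the four scans with a depthwise separable
  convolution under the same outer contract. It exists to keep bookkeeping
  tests fast on CPU; every result about the method itself is produced with
  the `ss2d` variant.

## Data handling

DEAP-layout subjects (40 trials x 40 channels x 8064 samples at 128 Hz,
ratings 1–9) keep the first 32 channel rows (the EEG montage) and the first
three rating columns (valence, arousal, dominance; a liking column is
ignored). DREAMER-layout recordings (18 trials x 14 channels, variable
length, ratings 1–5) are stored ragged — no truncation to a common length.
On-disk, both dialects are RDS containers documented in the reader help
pages; the package's fixture writers emit them.

Ratings binarize by strict `rating > threshold` (threshold 5 on 1–9, 3 on
1–5): a rating exactly at the threshold is the low class. This tie rule is
deterministic and matches the "high vs low" split at the scale midpoint.

Segmentation uses 1 s (128-sample) windows. The stride defaults to the
window (non-overlapping): with the documented 3 s leading-baseline drop, a
DEAP-layout trial of 8064 samples yields exactly 60 windows and a subject
40 x 60 = 2400 segments — the arithmetic the pipeline is anchored on.
Overlapping windows are available through the stride argument. Decision
thresholding at evaluation counts `P == threshold` as class 0.

Per-segment, per-channel z-scoring (variance floor 1e-8) is the default
normalization in the CLI preprocessing: amplitude scales vary by subject
and session in real recordings. One consequence worth knowing: z-scoring
converts absolute band-amplitude effects into *relative* spectral-fraction
effects. For the synthetic generator's planted signatures this preserves
near-perfect linear separability (band-power AUC ~1.0 for all three
dimensions on z-scored segments) but makes the arousal contrast — a small
low-frequency residual on gamma-dominated channels — far subtler than the
raw 3x amplitude difference it started as. The synthetic-recovery
experiments therefore train on unnormalized segments, where each planted
effect is carried by the band amplitudes the generative design actually
manipulates; the periodogram oracle confirms separability under both
conventions, so the choice affects learning speed, not information
content.

## The synthetic generator

The generator produces coupled V–A–D datasets so every stage of the
pipeline is testable without any external download. Labels are drawn i.i.d.
from a configurable joint distribution over the eight (y_V, y_A, y_D)
cells; the default concentrates mass on the high-V/high-A/high-D "joy" cell
(0.35) and gives the "anger" cell — low valence, high arousal, high
dominance — substantial probability (0.15), with the remaining mass spread
so every cell is populated.

Each trial is pink (1/f) background noise on all channels plus random-phase
band-limited oscillations on role-assigned channels:

* left-frontal alpha (8–13 Hz), amplitude `base * (1 + alpha_gain)` for low
  valence and `base / (1 + alpha_gain)` for high valence — frontal alpha
  desynchronization under positive affect;
* central gamma (30–45 Hz), amplitude scaled by `(1 + gamma_gain * y_A)`;
* posterior beta (13–30 Hz), amplitude scaled by `(1 + beta_gain * y_D)`.

Oscillations are random-phase processes, not sinusoids, so no classifier
can key on phase. Effects are multiplicative on band amplitude. The
defaults — gains 2, `noise_sd` 0.3, 4 subjects x 40 trials x 8 channels x
5 s — are the package's standard study conditions: at these settings an
independent periodogram (band-power) oracle separates each dimension's
classes with AUC >= 0.9, so a working decoder has headroom to learn them.
Ratings are written at the scale extremes so binarization recovers the
planted labels exactly regardless of the threshold choice within the scale.
Per-trial random streams derive from (seed, subject, trial), making
regeneration order-independent and bit-reproducible.

What the generator does *not* emulate: volume conduction and channel
correlation from a head model, non-stationarity within trials,
subject-specific spectral idiosyncrasies, artifacts (ocular, muscular), and
label noise. Passing the recovery experiments therefore demonstrates that
the architecture and losses can extract band-power signatures planted at
realistic frequencies — not that the reported benchmark numbers on real
recordings would reproduce. The package deliberately does not claim the
latter; real-data experiments need the original corpora and much longer
training.

## Training protocol and scaled-down study sizes

Training uses AdamW (decoupled weight decay 0.01 on weight matrices only)
at a fixed learning rate with no schedule, batch size 128 by default,
global gradient-norm clipping at 1.0, and evaluates the final epoch's
model (no early stopping). The reference operating point is 200 epochs at
learning rate 0.025; desk-scale runs in the tests and acceptance script
use a tiny model (embed 16, state 4) on ~800 synthetic segments for 30
epochs at learning rate 0.01, batch 32 and Adam beta2 = 0.99 — at this
width and data size the reference rate oscillates without converging, and
beta2 = 0.99 makes convergence robust across initialization seeds. These
sizes and settings are the package's choices for its own reproducible
experiments.

One initialization choice deserves its own note. A common convention for
residual token mixers is to zero the output projection of every block so
the network starts as the identity. At desk-scale widths this proved
actively harmful: whether a run escaped the resulting identity plateau
within 30 epochs depended on the data partition and seed — identical
configurations converged on one split and sat at chance on another. Blocks
therefore initialize their output projections truncated-normal (sd 0.02):
near-identity, but contributing features from the first step. The
identity-at-zero-projection property remains part of the block's tested
contract.

Cross-validation defaults to segment-granularity folds (the within-subject
reading of the 10-fold protocol, consistent with its contrast to
leave-one-subject-out evaluation); trial- and subject-granularity folds are
selectable to expose exactly the leakage difference between protocols — a
trial's windows are highly correlated, so segment-level folding is the
easier setting. Leave-one-subject-out plans key folds by subject id. Every
fold re-initializes parameters from `seed + fold`.

The constraint flags remove a disabled term from both the loss and the
gradient entirely, so a flags-off run is bit-identical to a run whose
constraint weights are zero — this reduction is asserted in the tests, and
is also why ablation rows are directly comparable.

The ablation harness mirrors the standard grid: a single-task baseline
(three independent single-branch models, each trained with only its own
cross-entropy) plus the eight on/off combinations of the three constraints
in the multi-task model. The single-branch models reuse the same encoder
topology with one branch attached.

## Known limitations

* The sequential scan is O(L) per direction and CPU-bound; the package
  targets desk-scale studies, not GPU-scale benchmark reproduction.
* The circular constraint is inert for (0, 0)-labelled samples (see above);
  datasets dominated by all-low labels receive little signal from it.
* Synthetic validation covers planted spectral effects only; see the
  generator section for what that does and does not show.
* The DREAMER-layout average segment yield depends on each corpus's exact
  clip-portion convention; the reader preserves whatever lengths are in the
  file and does not target a particular yield.
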