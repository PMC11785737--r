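---
title: "Geometric emotion-mimicry feedback: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric emotion-mimicry feedback: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facemimic)
```

## The problem

Emotion-mimicry training asks a user to reproduce an avatar's facial
expression in front of a camera while a recognition model scores the
attempt and returns graded feedback. `facemimic` implements the
computational core of such a closed-loop system: geometric feature
extraction from 478-point 3D face-mesh landmark frames, a compact
expression classifier, the windowed feedback session engine with retry
logic, the inter-process command handshake, and the evaluation statistics a
feasibility study of the system reports. Landmark *estimation* itself
(face detection, mesh fitting, video decoding) is out of scope: frames
enter the package as point clouds.

## Feature model

Each frame holds 478 points $p_i = (x_i, y_i, z_i)$ in normalized image
space. A *feature table* names landmark pairs and triples; the default
configuration has 10 pairs and 5 triples (15 features), and an extended one
appends the pair (18, 106) that sharpens surprise (16 features).

For a pair, the 3D Euclidean distance $d_n$ is computed on both the
subject's **neutral reference frame** (captured once per session) and the
current frame, and the feature is the ratio $R_n = d_{n,\mathrm{ref}} /
d_{n,\mathrm{cur}}$. Putting the reference in the numerator means a pair
that moves apart during an expression (a widening mouth) drives its ratio
*below* 1. Because both frames belong to the same subject, facial
proportions cancel, which is the point of reference normalization.

For a triple, the angle at the middle landmark between the rays to its
neighbors is computed on the current frame only, from the two-argument
arctangent of each ray's planar $(\Delta y, \Delta x)$, and the difference
is wrapped to $(-180°, 180°]$. Using `atan2` per ray rather than a plain
arctangent of slopes removes the quadrant ambiguity while agreeing with the
slope formulation wherever the latter is well defined. Angles are kept in
degrees: the wrap interval and the session logs stay human-readable.
Distances are deliberately 3D while angles are deliberately planar.

Two conventions were genuinely open and are fixed as configuration:
landmark indices are 0-based (the estimator's native convention), and a
table file may declare `index_base: 1` to shift; and the canonical table's
index parse is config-driven, so any alternative reading of a pair or
triple is a one-line change in YAML rather than code. No feature
standardization is applied before classification; the PCA in the evaluation
module z-scores first (below).

## Classifier

The recognition model is intentionally small: input $\to$ one dense layer
of 10 sigmoid units $\to$ softmax over two classes. The seven expression
labels collapse to negative = {anger, disgust, fear, sadness} and positive
= {happiness, surprise, neutral}; seven-class names are kept in logs for
per-expression reporting. Training defaults reproduce the recipe the
architecture was published with: 200 epochs of mini-batch Adam, batch size
128, initial learning rate 0.01, on a stratified 90/10 split.

Pieces the recipe leaves open are resolved conventionally and recorded
here: the loss is categorical cross-entropy (the standard pairing with a
softmax head); initialization is seeded Glorot-uniform; there is no early
stopping or learning-rate schedule; prediction ties break toward the first
class in scheme order (`negative`) for determinism. The split draws
validation rows per binary stratum with largest-remainder apportionment, so
an $n = 2190$ dataset yields exactly 219 validation and 1971 training rows;
subject-wise splitting is not needed for the synthetic cohorts but the
stratification column can be swapped by passing a `binary` column directly.
Training is bit-reproducible for a fixed seed: the seed governs both
initialization and epoch shuffling, and the RNG state of the caller is
restored afterwards. Models serialize to a single JSON document (weights,
architecture, label scheme, config) for language-neutral round-trips.

## Session engine

Time in the engine is frame-driven, not wall-clock: the 5 s mimicry window
at the system's observed ~3.2 Hz recognition rate becomes
`round(5 × 3.2) = 16` frames, which makes session replays deterministic and
testable. Each window frame is feature-extracted and classified; the
attempt's mean accuracy is the fraction of frame predictions equal to the
binary image of the avatar's expression (the deployed model is two-class,
so frame correctness is judged on the binary label while logs keep the
seven-class name). Feedback is "Great Job!" at mean accuracy ≥ 0.80,
"Good Job!" in [0.50, 0.80), "Try Again!" below — both boundaries
inclusive on their lower side, as specified.

A "Try Again!" attempt re-enqueues its expression at the end of the current
lineup, to at most 3 total attempts. Feedback is logged for *every*
attempt including a final failed one, so per-class try-again counts are
counts of feedback events. "Face not recognized" is modeled as a frame
validity predicate (all-zero or non-finite cloud, the estimator's sentinel)
rather than a detector; invalid frames are skipped, logged, and excluded
from the mean-accuracy denominator — extending the window instead would be
equally defensible, but exclusion keeps the window a fixed frame budget.
If every frame of a window is invalid the attempt raises a
face-not-recognized error. The 3 s cooldown is recorded as metadata; it has
no computational effect in frame-driven time.

## Protocol bridge

The deployed system ran its GUI and its recognition engine as separate
processes exchanging one-line text commands through two append-only files.
The package models this as a pure state machine over phases idle →
awaiting_capture → captured → recognizing → cooldown → terminated:
`Initialize <user>` answers `initialization complete` then `Ready01`;
`Capture` answers `Ready02`; `Start ER <class>` enters recognition;
`Wait`/`Ready` is the cooldown exchange; `Next` returns to the captured
phase; `Stop` answers `Terminating code` and terminates (legal from any
non-idle phase, since a session can be aborted mid-recognition).
Verbs match case-sensitively and payloads are space-separated suffixes, for
bit-exact interoperability. The feedback strings are not protocol verbs, so
recognition end is represented by the `Wait` exchange that follows it. Two
transports implement the same interface — an in-memory queue for tests and
the two-file mechanism — and must produce identical traces; the documented
latencies of the original system (milliseconds to seconds) are metadata,
never enforced. `FaceNotRecognized` is modeled as a single verb legal only
during recognition; its printed spelling as a transmitted command is not
fixed anywhere, so one spelling is chosen and kept.

## Evaluation statistics

*Confusion matrices* count true class (rows) against prediction (columns).
*Metrics* aggregate per-class precision, recall and F1 with **support
weights** (each class weighted by its true-label count). Support weighting
is chosen because it makes weighted recall algebraically identical to
true-positive accuracy — the signature of the identity visible when a
study reports equal accuracy and recall. A class never predicted has
undefined precision; it contributes 0 and sets a warning flag.

*Repetition statistics* express each class's try-again count as a
percentage of `participants × max_attempts` (24 per class for 8
participants and a 3-attempt cap). The median and quartiles of the
per-class percentages use **Hazen (midpoint) interpolation**, the sorted
position $h = np + 0.5$: among the common quantile definitions this is the
one that reproduces 26.04 / 46.87 as the quartiles of the seven percentages
{0, 25, 29.17, 37.5, 37.5, 50, 66.67}, and it is available directly as
`quantile(type = 5)`. Quartiles are computed per class (not per
participant), which is the reading consistent with all four summary
numbers. Percentages are carried at full precision and rounded to two
decimals only for display; tests compare at 0.01 absolute on the percent
scale.

*PCA maps* z-score each feature before projecting onto the leading
components, dropping zero-variance features with a warning. Whether to
standardize was open; ratios (dimensionless, near 1) and angles (degrees,
order 100) live on incommensurate scales, so correlation-matrix PCA is the
defensible choice.

## Synthetic faces

The generator exists so every module is exercisable without external image
databases, and it defines the package's study conditions. A canonical
neutral layout places the feature table's landmark indices at anatomically
plausible relative positions in a unit box (mouth corners, inner lips,
brows, nose, jaw); the other indices fill deterministic face-shaped
ellipses. Subjects are seeded Gaussian jitters (sd 0.004 units) of that
layout plus a global scale in [0.9, 1.1].

Each emotion is a fixed displacement field scaled by an intensity in
[0, 1]: positive expressions open or widen the mouth region (happiness
spreads the corners, surprise drops the jaw and raises the brows), negative
ones compress mouth and brow distances (pressed lips, narrowed mouth,
lowered or knitted brows); neutral is the identity. Magnitudes are set so
that intensity 1 moves the affected current-frame distances by roughly
20–100%, comfortably above the default coordinate noise (isotropic
Gaussian, sd 0.0015 units, emulating estimator jitter) — this margin is
what makes the binary classes linearly separable at intensity ≥ 0.5 and
hence makes the end-to-end training check well-posed. The default cohort —
10 subjects × 7 expressions × 29 frames = 2030 frames, intensities uniform
in [0.5, 1] (strong portrayals) — was sized to match the order of the
2190-image dataset the published recipe was trained on while keeping a
full generate–train–evaluate cycle around ten seconds on one CPU.

Session streams emulate a participant with a per-emotion skill probability:
each window frame portrays the requested expression with probability
`skill`, otherwise a confuser from the opposite binary class, so try-again
rates are controllable. All generator operations are deterministic under
seeds, with derived seeds reduced modulo $2^{31}-1$.

What the generator does **not** emulate — real face-mesh topology,
correlated (non-isotropic) estimator noise, head pose, illumination,
idiosyncratic or weak expressions, and the actual geometry of human action
units — bounds what passing tests show: they validate the pipeline's
mechanics and its statistical identities, not the published recognition
accuracies on real image databases, which are reachable only with those
databases.

## Numerical choices and limitations

Degenerate geometry fails loudly: zero-length angle rays and non-positive
distances raise classed errors naming the offending pair. Ratios require
strictly positive distances in both frames. The angle wrap is half-open so
opposite rays give exactly +180°. The softmax clamps log-probabilities at
$10^{-12}$ in the loss only. The two-class head means the engine cannot
distinguish confusions *within* a binary class (mimicking anger while shown
fear scores as correct); that is a property of the deployed design, not of
this implementation. Recognition accuracies on real face databases are out
of reach without those databases; this package reports only synthetic
equivalents, computed at run time by its tests and acceptance script.
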