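---
title: "Methods: descriptive gaze measures, window segmentation and gaze-based prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: descriptive gaze measures, window segmentation and gaze-based prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazecourse)
```

# Scope and data model

`gazecourse` analyses screen-based eye-tracking recordings that arrive as
two comma-separated exports: a *samples* file (one row per tracker sample:
time, best point of gaze in normalized screen fractions, per-eye validity
flags, per-eye pupil diameters in millimetres, blink markers, optionally an
AOI label) and a *fixations* file (one row per detected fixation: id, start,
duration, normalized position, optional AOI label). Fixation detection
itself is the tracker's job and deliberately out of scope; the package
consumes the fixation stream as given. Vendor header names are mapped
through an alias table, so both Gazepoint-style headers (`TIME`, `BPOGX`,
`LPMM`, `FPOGS`, ...) and the package's canonical names parse identically.
Timestamps that look like absolute clock time (first row at 3600 s or
later) are re-based so every recording starts at zero.

# Pre-processing

De-noising applies seven rejection rules in a **fixed order**, and logs each
removed row once, under the first rule it violates: both-eyes-invalid,
negative values, off-screen coordinates, one-eye-only rows, missing
coordinates, pupil diameter outside a plausibility window, and
between-eye pupil asymmetry (anisocoria). The fixed precedence makes the
audit deterministic: `rows_in = rows_kept + Σ reason counts` holds for any
input, and cleaning is idempotent.

The defaults encode adult physiology: pupils of roughly 2–4 mm in bright
light and 4–8 mm in darkness motivate the default [2, 8] mm window, and
anisocoria beyond 1 mm is rare enough to treat as artifact. Because the
anisocoria figure is usually cited as a population observation rather than
an explicit filter, the check is a configuration flag; we default it to on
(rejection) so that pupil-based measures are conservative, and populations
with known physiological anisocoria can switch it off.

# Saccade kinematics

A saccade is the movement between consecutive fixations: saccade *k* spans
from the end of fixation *k* (`start + duration`) to the start of fixation
*k+1*. Its magnitude is the Euclidean pixel distance between the two
fixation positions, and its duration the inter-fixation gap. Overlapping
fixation records (non-positive gaps, which some trackers emit) are clamped
to zero duration and flagged rather than dropped.

Pixel distances convert to visual angle with the exact subtended-angle
formula `2·atan(d·pitch / (2·D))`, where the pixel pitch derives from the
monitor diagonal and resolution (default 24″, 1920×1080, square pixels)
and `D` is the viewing distance (default 650 mm, a typical remote-tracker
operating distance; configurable because amplitude and velocity scale with
it). Mean velocity is amplitude over duration. Peak velocity is estimated
from the raw samples inside the saccade span as the maximum of
central-difference angular speeds smoothed with a 3-sample moving average —
a documented approximation, since sample-level velocity estimation admits
many filter choices; it is reported missing when fewer than three samples
fall inside the span.

Directions are computed after flipping the screen's downward-growing y
axis, so 0° points right and 90° up; absolute direction lies in [0, 360)
and the relative direction between consecutive saccades is the turn angle
folded into [0, 180] (a turn has a size but no sign). The first saccade has
no relative direction; undefined values are always explicit `NA`, never 0,
so downstream feature matrices stay honest.

Every value channel is summarized by the same six statistics — sum, mean,
median, SD, minimum, maximum — with the sample (n−1) SD estimator, the
convention in behavioural statistics (a singleton has SD 0).

# AOI analytics

Stationary entropy is the Shannon entropy (base 2, so all entropies are in
bits; an optional normalization divides by `log2(k)`) of the fixation-count
distribution across AOIs. Transition entropy is the conditional entropy of
the next AOI given the current one, weighting each source AOI by its share
of observed transitions. Weighting by observed transition origins (rather
than by fixation counts or a fitted stationary distribution) keeps the
measure self-consistent with the count matrix; the alternative weighting is
exposed as an argument. Note the mathematical guarantee is
`H(next|current) ≤ H(next)` — the bound involves the *destination*
marginal; for long sequences source and destination marginals coincide and
the familiar "conditioning reduces entropy relative to the stationary
distribution" reading applies.

Transition counts are order-sensitive (A→B ≠ B→A) and include
self-transitions on the diagonal; proportions are reported both including
and excluding the diagonal. Unlabelled fixations are excluded from
sequences and transitions but remain in the denominators of per-AOI
fixation-count and duration proportions, which are defined relative to
*all* fixations captured.

Scanpath sequences use one symbol per AOI-labelled fixation; the collapsed
form removes adjacent repeats and is idempotent. Pattern mining enumerates
**contiguous** substrings of length 2–5 (configurable) with overlapping
occurrences counted — the verifiable core of subsequence mining; gapped
pattern families are out of scope. Group statistics per pattern: total
occurrences (frequency), share of sequences containing it (support),
occurrences per sequence (mean pattern frequency) and share of all mined
pattern occurrences (proportional pattern frequency, summing to 1). AOI
sets beyond single letters are handled by token sequences joined with a
separator.

# Window segmentation

All windows are half-open `[start, end)` with time zero at recording start,
a boundary-ownership rule needed to make contiguous tumbling layouts like
[0, 30), [30, 60) unambiguous. An item (fixation or sample) belongs to a
window iff its *start* time falls inside — the simplest rule that
partitions items exactly once under tumbling windows; splitting items
across overlapping windows was rejected for auditability.

* **Tumbling** (size `W`): [0, W), [W, 2W), ... to the end of the
  recording; the final partial window is emitted by default (a minimum-fill
  fraction is configurable).
* **Expanding** (step `s`): [0, s), [0, 2s), ..., the last window always
  covering the full recording.
* **Hopping** (size `W`, hop `h`): [kh, kh + W) while the start lies in the
  recording, ends clamped. `h = W` reproduces tumbling exactly, a property
  the tests enforce on random configurations. Window boundaries tolerate
  ~1 ns of floating-point slack so that a duration recomputed from
  round-tripped CSVs cannot spawn a spurious extra window.
* **Session** (timeout `t`, cap `M`, baseline period `B`): a per-person
  baseline is the mean of a feature channel over [0, B); every later
  observation strictly above `multiplier × baseline` (default multiplier 1:
  "higher in value") is an irregular gaze event. A window opens at the
  first event, each event within `t` of the previous renews the timeout,
  and the window closes at `last event + t` or `open + M`, whichever is
  earlier; the next window opens at the next event after the close, so
  windows never overlap.

Event channels: saccade magnitude, saccade direction (as the absolute turn
angle, since a raw angle has no "higher" ordering — an interpretation we
document), left/right/average pupil diameter, fixation duration, and blink
rate evaluated on a rolling 60 s horizon (a rate needs a horizon; length
configurable). Session-window DGMs are computed over the whole window span,
not only event-adjacent data — the span is what the researcher inspects.

Per-window DGM records carry the window's index, bounds and an `empty`
flag; empty windows produce all-`NA` records rather than disappearing, so
stage-wise feature matrices stay aligned.

# Prediction layer

Feature matrices have one row per (participant, window); all-missing
columns are dropped with a warning and remaining missing values are imputed
with the column median (mask retained; imputation can be disabled, in which
case missingness is an error). The model registry preserves a full
published enumeration of 46 classification and 31 regression model names;
each maps to the nearest native family in R's modelling stack (entropy-split
`rpart` for the C4.5-style tree, linear-kernel SVM for
sequential-minimal-optimization, `nnet` for the perceptron, generic
bootstrap/vote/subspace constructions for the ensemble wrappers, and so
on). Names that only make sense in their original ecosystem —
text-specific or incrementally-updateable variants and several meta
wrappers — remain registered with `available = FALSE` and raise a clear
error on use; we prefer an honest refusal to a silently different model.

Evaluation uses stratified k-fold cross-validation (default 10 folds):
within each class, shuffled instances are dealt round-robin, so per-fold
class counts deviate by at most one. When several windows per participant
enter the matrix, instance-level stratification can leak a participant
across folds; `cv = "grouped"` therefore assigns all of a participant's
rows to one fold. The stratified instance-level protocol remains the
default because it is the standard evaluation convention for this kind of
tool; the grouped option is the safe choice for multi-window designs and
is what the package's own end-to-end example uses. The Zero Rule baseline
(majority class / training mean) is always evaluated. Classification is
scored by accuracy, regression by RMSE with Pearson correlation alongside.
Model pairs are compared with paired t-tests on per-fold scores,
Bonferroni-multiplied by the number of pairs and clamped at 1; since
CV folds share training data, a variance-corrected resampled-t variant
(inflating the variance by `1/k + 1/(k−1)`) is available as an option.
Every report records its seed and fold assignment; identical matrix and
seed reproduce identical reports for deterministic families.

# Synthetic sessions

The generator is first-class, tested code, not a fixture. It simulates:

* a **first-order Markov scanpath** over rectangular AOIs — chosen so the
  entropy measures have analytically known targets (the default symmetric
  matrix with 0.1 self-transition over four AOIs has a uniform stationary
  distribution, hence 2 bits stationary entropy and
  `−0.1·log2 0.1 − 0.9·log2 0.3 ≈ 1.895` bits conditional entropy),
* **log-normal fixation durations** (default mean 250 ms, SD 100 ms —
  typical free-viewing values), parameterized by the target mean/SD on the
  seconds scale,
* 20–50 ms inter-fixation gaps and **smoothstep saccade traversals**, whose
  symmetric velocity profile guarantees peak velocity exceeds mean velocity
  (1.5× for the ideal profile), exercising the kinematics contract,
* a **Poisson blink process** (default 12 blinks/min, within the normal
  adult range) marking 150 ms blink ids on the sample stream,
* per-eye **pupil traces** as baseline + slow sinusoidal drift + Gaussian
  noise (defaults 3.5 mm, 0.2 mm drift, 0.05 mm noise),
* **injected artifacts** (invalid flags, off-screen coordinates, 12 mm
  pupil spikes) on *distinct* rows, so the rejection log must reproduce
  the injected counts exactly, reason by reason.

All randomness flows from the recipe's single seed, and the generator
restores the caller's RNG state. A recording that ends mid-fixation
truncates that fixation at the session boundary, as a tracker would.

What the generator does **not** emulate: saliency-driven or task-driven
gaze, smooth pursuit, microsaccades, head movement, tracker-specific noise
spectra, or correlated artifact bursts. Passing parameter-recovery tests
therefore demonstrates that the analysis code computes what it claims on
data with known structure — not that any scientific conclusion about real
populations follows.

# Problem sizes and numerical choices

The test suite and the acceptance script run on synthetic sessions of
30–400 s at 60 Hz (up to ~1000 fixations and 24,000 samples), 100–1000
random instances for the brute-force oracle comparisons, and 20 label
permutations for the chance-level check — sizes at which the distributional
recovery tolerances (2 standard errors for means, 3σ for Poisson counts,
0.05 per transition-matrix cell at ≥500 transitions) are meaningful.
Statistics match brute-force oracles to 1e-9 relative; geometric
invariances (hull translation/rotation) to 1e-6. Degenerate inputs follow
one rule: empty in, explicitly-missing out (never silent zeros), and
undefined ratios (no saccade time) are `NA`.

# Known limitations

* Fixation detection, calibration and live device streaming are out of
  scope; the analysis replays recorded rows.
* Peak velocity is a sample-level approximation, not a reconstruction of
  any specific published velocity algorithm.
* Registry model names without native equivalents are registered but
  unavailable; ensemble constructions (bagging, voting, random subspace)
  are generic re-implementations over native base learners, not
  hyperparameter-faithful ports.
* Pattern mining is restricted to contiguous substrings with overlap
  counting; gapped sequential-pattern families and scanpath similarity
  metrics (edit distance and relatives) are not provided.
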