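# gazecourse

Descriptive and predictive gaze analytics for screen-based eye tracking.

Researchers in human–computer interaction, behavioural physiology, aviation
and education increasingly record eye movements with remote desktop trackers
and need to turn the raw exports into interpretable measures — and, from
those measures, into predictions about the person behind the gaze.
`gazecourse` covers that pipeline end to end:

1. **Ingestion and de-noising** of Gazepoint-style CSV exports (an
   all-samples file and a fixations file), with a deterministic, auditable
   rejection log (validity flags, negative and off-screen coordinates,
   one-eye rows, implausible pupil diameters, anisocoria).
2. **Descriptive gaze measures (DGMs)**: saccades are derived as the
   movements between consecutive fixations, and a fixed vocabulary of
   measures is computed — fixation and saccade counts plus six-number
   statistics (sum, mean, median, SD, min, max) of fixation duration,
   saccade magnitude/duration/amplitude/velocity/peak velocity and
   relative/absolute direction, convex-hull dispersion, blink rate, pupil
   means and baseline-relative dilation, fixation-to-saccade ratio,
   scanpath duration, and AOI analytics (below).
3. **AOI analytics**: stationary entropy
   `H = -Σ p_i log2 p_i` over the distribution of fixations across areas of
   interest; transition entropy `H_t = Σ_i π_i (-Σ_j p_ij log2 p_ij)` over
   the row-normalized transition matrix; order-sensitive transition counts
   and proportions with or without self-transitions; scanpath sequence
   strings in expanded and collapsed form (`ACCDEABAAAABC → ACDEABABC`);
   and overlapping contiguous subsequence patterns with frequency, support,
   mean and proportional pattern frequency.
4. **Window segmentation** for temporal analyses: tumbling, expanding and
   hopping windows, plus event-driven session windows that open on an
   irregular gaze event (a feature-channel value exceeding a per-person
   baseline established during an initial observation period), renew a
   timeout with every further event and close at a maximum duration.
5. **Prediction**: windowed DGM feature matrices joined with outcome
   labels, evaluated over a registry of 46 classification and 31 regression
   model names under stratified (or participant-grouped) k-fold
   cross-validation, with a Zero Rule baseline and Bonferroni-corrected
   paired t-tests between models.
6. **Synthetic sessions**: a seeded generator (first-order Markov scanpath
   over AOIs, log-normal fixation durations, smooth saccade traversals,
   Poisson blinks, drifting noisy pupils, injectable artifacts) whose
   ground truth makes every stage testable without recorded data.

## Worked example

```r
library(gazecourse)

recipe <- session_recipe(duration_s = 180, blink_rate_per_min = 15,
                         pupil_spike_rate = 0.005, seed = 7)
ses   <- generate_session(recipe)
clean <- denoise(ses$samples)
clean$counts[clean$counts > 0]
#> pupil_out_of_range
#>                 54

dgms <- summative_dgms(ses$fixations, clean$samples)
round(unlist(dgms[c("fixation_count", "fixation_duration_mean",
  "saccade_magnitude_mean", "blink_rate_per_min",
  "stationary_entropy_bits", "transition_entropy_bits")]), 3)
#>          fixation_count  fixation_duration_mean  saccade_magnitude_mean
#>                 636.000                   0.248                 852.508
#>      blink_rate_per_min stationary_entropy_bits transition_entropy_bits
#>                  16.333                   1.998                   1.877
```

The generator was asked for 250 ms mean fixations over four equally visited
AOIs: the recovered mean fixation duration (0.248 s), near-uniform
stationary entropy (1.998 of 2 bits) and the 54 logged pupil artifacts
(0.5 % of 10,800 rows) all match the recipe. Per-minute blink rate (16.3)
sits within Poisson noise of the requested 15. A temporal view of the same
session:

```r
w <- windowed_dgms(ses$fixations, clean$samples,
                   window_spec("tumbling", size_s = 60))
w[, c("window", "window_start_s", "window_end_s", "fixation_count")]
#>       window window_start_s window_end_s fixation_count
#>  tumbling_w1              0           60            206
#>  tumbling_w2             60          120            207
#>  tumbling_w3            120          180            223
```

Windowed records from several participants feed `assemble_features()` and
`evaluate_models()`; `run_descriptive()` / `run_predictive()` (or the
`inst/cli/gazecourse` script with a JSON config) orchestrate whole batches
with manifests.

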