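Package: gazecourse
Title: Descriptive and Predictive Gaze Analytics with Temporal Window Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reads and de-noises Gazepoint-style eye-tracker exports, derives
    saccades from fixation streams, and computes a full catalogue of
    descriptive gaze measures (saccade kinematics, fixation statistics,
    convex-hull dispersion, blink rate, pupillometry, AOI stationary and
    transition entropies, scanpath sequences and subsequence patterns).
    Recordings can be segmented with tumbling, expanding, hopping, or
    event-driven session windows with per-person baselines and irregular
    gaze-event detection. Windowed measures feed a prediction layer that
    evaluates a registry of classification and regression model families
    under stratified cross-validation with Bonferroni-corrected paired
    t-tests. Includes a synthetic-session generator with known ground truth
    for end-to-end testing, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    e1071,
    nnet,
    rpart,
    randomForest,
    class,
    MASS,
    glmnet,
    kernlab,
    caret
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
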