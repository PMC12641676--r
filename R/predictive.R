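# Feature assembly, cross-validated model evaluation and corrected testing.

#' Assemble a windowed-DGM feature matrix
#'
#' Turns DGM records (one row per participant x window) plus per-participant
#' outcome labels into a model-ready feature matrix. Non-measure columns are
#' kept as row metadata so every instance stays traceable to its
#' (participant, window). All-missing measure columns are dropped with a
#' warning; remaining missing values are imputed (default: column median)
#' with the missingness mask retained as an attribute, or raise an error
#' when imputation is off.
#'
#' @param records A `dgm_record` data.frame (rows from [summative_dgms()] /
#'   [windowed_dgms()], possibly row-bound across participants).
#' @param labels Named vector (participant -> outcome) or data.frame with
#'   columns `participant`, `label`.
#' @param task `"classification"` (labels become a factor, >= 2 classes
#'   required) or `"regression"` (numeric labels).
#' @param impute `"median"` or `"none"`.
#' @return A list of class `feature_matrix`: `X` (numeric data.frame),
#'   `y`, `meta` (participant / window columns), `mask` (logical missing
#'   mask), `task`.
#' @export
assemble_features <- function(records, labels,
                              task = c("classification", "regression"),
                              impute = c("median", "none")) {
  task <- match.arg(task)
  impute <- match.arg(impute)
  if (is.data.frame(labels)) {
    labels <- stats::setNames(labels$label, labels$participant)
  }
  meta_cols <- intersect(c("participant", "window", "aoi", "window_index",
                           "window_start_s", "window_end_s", "empty"),
                         names(records))
  unlab <- setdiff(unique(records$participant), names(labels))
  if (length(unlab)) {
    stop("assemble_features: no label for participant(s): ",
         paste(unlab, collapse = ", "))
  }
  y <- labels[records$participant]
  if (task == "classification") {
    y <- factor(unname(y))
    if (nlevels(y) < 2) {
      stop("assemble_features: classification needs >= 2 classes")
    }
  } else {
    y <- as.numeric(y)
  }
  X <- records[, setdiff(names(records), meta_cols), drop = FALSE]
  X <- X[, vapply(X, is.numeric, logical(1)), drop = FALSE]
  all_na <- vapply(X, function(col) all(is.na(col)), logical(1))
  if (any(all_na)) {
    warning("dropping all-missing feature column(s): ",
            paste(names(X)[all_na], collapse = ", "))
    X <- X[, !all_na, drop = FALSE]
  }
  mask <- as.data.frame(lapply(X, is.na))
  if (any(unlist(mask))) {
    if (impute == "none") {
      stop("assemble_features: missing values present and imputation is off")
    }
    for (j in seq_along(X)) {
      med <- stats::median(X[[j]], na.rm = TRUE)
      X[[j]][is.na(X[[j]])] <- med
    }
  }
  structure(list(X = X, y = y,
                 meta = records[, meta_cols, drop = FALSE],
                 mask = mask, task = task),
            class = "feature_matrix")
}

# Stratified fold assignment: within each class, shuffled instances are
# dealt round-robin, so per-fold class counts deviate by at most 1.
.stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- ((seq_along(idx) - 1L) %% k) + 1L
  }
  fold
}

.plain_folds <- function(n, k, seed) {
  set.seed(seed)
  idx <- sample.int(n)
  fold <- integer(n)
  fold[idx] <- ((seq_len(n) - 1L) %% k) + 1L
  fold
}

# Grouped assignment: all windows of one participant share a fold.
.grouped_folds <- function(groups, y, k, seed) {
  set.seed(seed)
  g <- unique(groups)
  gy <- if (is.factor(y)) {
    vapply(g, function(gi) as.character(y[groups == gi][1]), character(1))
  } else rep("all", length(g))
  gfold <- integer(length(g))
  for (cl in unique(gy)) {
    idx <- sample(which(gy == cl))
    gfold[idx] <- ((seq_along(idx) - 1L) %% k) + 1L
  }
  gfold[match(groups, g)]
}

#' Evaluate models under cross-validation
#'
#' Runs each selected (and available) registry model through k-fold
#' cross-validation: stratified by class for classification, plain folds for
#' regression, or grouped by participant (`cv = "grouped"`) so that no
#' participant's windows are split across training and test folds. The Zero
#' Rule baseline is always evaluated. Classification is scored by held-out
#' accuracy; regression by RMSE (with the Pearson correlation reported
#' alongside). The seed and the fold assignment are recorded in the report.
#'
#' @param features A `feature_matrix` from [assemble_features()].
#' @param models Character vector of registry names, or `"all"` for every
#'   available model of the task.
#' @param folds Number of folds (default 10); reduced with a warning when a
#'   class has fewer members than folds.
#' @param seed Integer seed fixing the fold assignment and any stochastic
#'   model family.
#' @param cv `"stratified"` (instance-level, the default evaluation
#'   protocol) or `"grouped"` (participant-level, leakage-safe).
#' @return A list of class `evaluation_report`: `report` (model x fold
#'   scores), `summary` (mean, sd per model), `folds`, `fold_assignment`,
#'   `seed`, `task`, `score`.
#' @export
evaluate_models <- function(features, models = "all", folds = 10, seed = 1,
                            cv = c("stratified", "grouped")) {
  cv <- match.arg(cv)
  task <- features$task
  reg <- model_registry(task)
  if (identical(models, "all")) {
    models <- reg$registry_name[reg$available]
  }
  unknown <- setdiff(models, reg$registry_name)
  if (length(unknown)) {
    stop("evaluate_models: not in the ", task, " registry: ",
         paste(unknown, collapse = ", "))
  }
  unavailable <- models[!reg$available[match(models, reg$registry_name)]]
  if (length(unavailable)) {
    stop("evaluate_models: model(s) registered but not available in this ",
         "implementation: ", paste(unavailable, collapse = ", "))
  }
  zero_name <- "Zero Rule"
  models <- union(zero_name, models)
  X <- features$X
  y <- features$y
  n <- nrow(X)
  if (n < folds) {
    stop("evaluate_models: ", n, " instances is fewer than ", folds,
         " folds; reduce `folds`")
  }
  if (task == "classification") {
    min_class <- min(table(y))
    if (min_class < folds) {
      folds <- max(2, min_class)
      warning("smallest class has ", min_class,
              " members; folds reduced to ", folds)
    }
  }
  fold <- if (cv == "grouped") {
    .grouped_folds(features$meta$participant, y, folds, seed)
  } else if (task == "classification") {
    .stratified_folds(y, folds, seed)
  } else {
    .plain_folds(n, folds, seed)
  }
  fam <- reg$family[match(models, reg$registry_name)]
  rows <- list()
  for (mi in seq_along(models)) {
    for (f in seq_len(folds)) {
      test <- fold == f
      if (!any(test) || !any(!test)) next
      if (task == "classification" && length(unique(y[!test])) < 2 &&
          fam[mi] != "zero_rule") next
      fit <- .fit_family(fam[mi], X[!test, , drop = FALSE], y[!test],
                         seed = seed + f)
      pred <- .predict_family(fit, X[test, , drop = FALSE])
      if (task == "classification") {
        acc <- mean(as.character(pred) == as.character(y[test]))
        rows[[length(rows) + 1]] <-
          data.frame(model = models[mi], fold = f, score = acc,
                     stringsAsFactors = FALSE)
      } else {
        err <- pred - y[test]
        rmse <- sqrt(mean(err^2))
        cc <- if (length(pred) > 2 && stats::sd(pred) > 0 &&
                  stats::sd(y[test]) > 0) {
          stats::cor(pred, y[test])
        } else NA_real_
        rows[[length(rows) + 1]] <-
          data.frame(model = models[mi], fold = f, score = rmse,
                     correlation = cc, stringsAsFactors = FALSE)
      }
    }
  }
  report <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(report, report$model), function(d) {
    data.frame(model = d$model[1], mean = mean(d$score),
               sd = stats::sd(d$score), n_folds = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  structure(list(report = report, summary = summary, folds = folds,
                 fold_assignment = fold, seed = seed, task = task,
                 score = if (task == "classification") "accuracy"
                         else "rmse"),
            class = "evaluation_report")
}

#' Pairwise corrected model comparison
#'
#' Paired t-tests on the per-fold scores of every model pair, with the
#' p-values Bonferroni-corrected by the number of pairwise comparisons and
#' clamped at 1. Pairs with identical fold scores get a test statistic of 0
#' and p = 1. Optionally applies the variance-corrected resampled t-test
#' (Nadeau-Bengio style correction for the train/test overlap of CV folds).
#'
#' @param report An `evaluation_report` from [evaluate_models()].
#' @param correction `"bonferroni-t"` (plain paired t) or `"corrected-t"`
#'   (fold-variance corrected paired t; same Bonferroni factor).
#' @return data.frame `model_a`, `model_b`, `t_stat`, `p_raw`,
#'   `p_corrected`, `bonferroni_factor`.
#' @export
compare_models <- function(report,
                           correction = c("bonferroni-t", "corrected-t")) {
  correction <- match.arg(correction)
  d <- report$report
  models <- unique(d$model)
  if (length(models) < 2) stop("compare_models: need >= 2 evaluated models")
  scores <- lapply(models, function(m) {
    s <- d[d$model == m, c("fold", "score")]
    s[order(s$fold), ]
  })
  names(scores) <- models
  nf <- vapply(scores, nrow, integer(1))
  if (length(unique(nf)) != 1) {
    stop("compare_models: models evaluated on mismatched fold structures")
  }
  pairs <- utils::combn(models, 2)
  n_pairs <- ncol(pairs)
  k <- nf[1]
  out <- lapply(seq_len(n_pairs), function(j) {
    a <- scores[[pairs[1, j]]]$score
    b <- scores[[pairs[2, j]]]$score
    diffs <- a - b
    if (all(abs(diffs) < .Machine$double.eps^0.5) ||
        stats::sd(diffs) == 0) {
      tt <- 0; p <- 1
    } else if (correction == "corrected-t") {
      # resampled-CV variance correction: test fraction ~ 1/k of the data
      corr_var <- stats::var(diffs) * (1 / k + 1 / (k - 1))
      tt <- mean(diffs) / sqrt(corr_var)
      p <- 2 * stats::pt(-abs(tt), df = k - 1)
    } else {
      ht <- stats::t.test(a, b, paired = TRUE)
      tt <- unname(ht$statistic); p <- ht$p.value
    }
    data.frame(model_a = pairs[1, j], model_b = pairs[2, j], t_stat = tt,
               p_raw = p, p_corrected = min(1, p * n_pairs),
               bonferroni_factor = n_pairs, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
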