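# Model registry, feature assembly, cross-validated evaluation.

# small feature table: n instances, informative or pure-noise features
make_feature_records <- function(n = 60, informative = TRUE, seed = 1) {
  set.seed(seed)
  y <- rep(c("hi", "lo"), length.out = n)
  x1 <- stats::rnorm(n) + if (informative) ifelse(y == "hi", 3, -3) else 0
  x2 <- stats::rnorm(n)
  rec <- data.frame(participant = paste0("p", seq_len(n)),
                    window = "summative", aoi = "all",
                    f1 = x1, f2 = x2, stringsAsFactors = FALSE)
  list(records = rec, labels = stats::setNames(y, rec$participant))
}

test_that("registries enumerate the full published model lists", {
  cls <- model_registry("classification")
  reg <- model_registry("regression")
  expect_equal(nrow(cls), 46)
  expect_equal(nrow(reg), 31)
  expect_equal(anyDuplicated(cls$registry_name), 0)
  expect_equal(anyDuplicated(reg$registry_name), 0)
  expect_true("Zero Rule" %in% cls$registry_name)
  expect_true("Zero Rule" %in% reg$registry_name)
  expect_true(all(c("C4.5 Decision Tree", "Random Forest",
                    "Sequential Minimal Optimization (for Support Vector Machines)")
                  %in% cls$registry_name))
  # unavailable names error cleanly instead of silently running something else
  f <- make_feature_records()
  feats <- assemble_features(f$records, f$labels, "classification")
  expect_error(evaluate_models(feats, "K* (K-Star)", folds = 5),
               "not available")
  expect_error(evaluate_models(feats, "No Such Model", folds = 5),
               "registry")
})

test_that("feature assembly counts rows, drops dead columns, imputes", {
  ses <- lapply(1:3, function(i) demo_session(seed = i, duration_s = 110))
  recs <- do.call(rbind, lapply(seq_along(ses), function(i) {
    r <- windowed_dgms(ses[[i]]$fixations, ses[[i]]$samples,
                       window_spec("tumbling", size_s = 30),
                       scope = paste0("p", i))
    r
  }))
  labels <- c(p1 = "a", p2 = "b", p3 = "a")
  f <- assemble_features(recs, labels, "classification")
  expect_equal(nrow(f$X), 12)                       # 3 participants x 4 windows
  expect_false(any(is.na(as.matrix(f$X))))
  expect_true(all(c("participant", "window_index") %in% names(f$meta)))
  # unlabelled participant -> error naming it
  expect_error(assemble_features(recs, labels[-2], "classification"), "p2")
  # single class -> error
  expect_error(assemble_features(recs, c(p1 = "a", p2 = "a", p3 = "a"),
                                 "classification"), "2 classes")
  # all-missing column dropped with warning; imputation off -> error
  recs2 <- recs
  recs2$dead_col <- NA_real_
  expect_warning(assemble_features(recs2, labels, "classification"),
                 "dead_col")
  recs3 <- recs
  recs3$fixation_duration_mean[1] <- NA
  expect_error(assemble_features(recs3, labels, "classification",
                                 impute = "none"), "imputation is off")
})

test_that("stratified folds balance classes within one instance", {
  set.seed(51)
  for (i in 1:25) {
    n <- sample(30:120, 1)
    y <- factor(sample(c("a", "b", "c"), n, replace = TRUE,
                       prob = c(0.5, 0.3, 0.2)))
    k <- sample(3:10, 1)
    if (min(table(y)) < k) next
    fold <- gazecourse:::.stratified_folds(y, k, seed = i)
    for (cl in levels(y)) {
      per_fold <- table(factor(fold[y == cl], levels = 1:k))
      expect_lte(max(per_fold) - min(per_fold), 1)
    }
  }
})

test_that("Zero Rule scores the held-out majority frequency exactly", {
  f <- make_feature_records(n = 100, informative = FALSE, seed = 2)
  # imbalanced 70/30 labels
  y <- c(rep("maj", 70), rep("min", 30))
  feats <- assemble_features(f$records, stats::setNames(y, f$records$participant),
                             "classification")
  ev <- evaluate_models(feats, "Zero Rule", folds = 10, seed = 3)
  zr <- ev$report[ev$report$model == "Zero Rule", ]
  fold <- ev$fold_assignment
  # oracle: per fold, the training majority scored on the held-out labels
  for (k in zr$fold) {
    train <- feats$y[fold != k]
    maj <- names(sort(table(train), decreasing = TRUE))[1]
    expect_equal(zr$score[zr$fold == k],
                 mean(as.character(feats$y[fold == k]) == maj))
  }
  expect_equal(mean(zr$score), 0.70, tolerance = 0.01)
})

test_that("separable data is learned; permuted labels fall to chance", {
  f <- make_feature_records(n = 60, informative = TRUE, seed = 4)
  feats <- assemble_features(f$records, f$labels, "classification")
  ev <- evaluate_models(feats, c("C4.5 Decision Tree", "Logistic Regression"),
                        folds = 5, seed = 5)
  s <- ev$summary
  expect_gte(s$mean[s$model == "C4.5 Decision Tree"], 0.95)
  expect_gte(s$mean[s$model == "Logistic Regression"], 0.95)
  # label permutation destroys the signal: mean accuracy near 0.5
  set.seed(6)
  perm_acc <- replicate(20, {
    yp <- sample(f$labels)
    names(yp) <- names(f$labels)
    fp <- assemble_features(f$records, yp, "classification")
    evp <- evaluate_models(fp, "C4.5 Decision Tree", folds = 5,
                           seed = sample.int(1e6, 1))
    evp$summary$mean[evp$summary$model == "C4.5 Decision Tree"]
  })
  expect_lt(abs(mean(perm_acc) - 0.5), 0.05)
})

test_that("evaluation is deterministic in matrix + seed", {
  f <- make_feature_records(n = 40, seed = 7)
  feats <- assemble_features(f$records, f$labels, "classification")
  e1 <- evaluate_models(feats, "Random Forest", folds = 5, seed = 9)
  e2 <- evaluate_models(feats, "Random Forest", folds = 5, seed = 9)
  expect_equal(e1$fold_assignment, e2$fold_assignment)
  expect_equal(e1$report, e2$report)
  expect_equal(e1$seed, 9)
})

test_that("regression families predict and Zero Rule matches its closed form", {
  set.seed(8)
  n <- 50
  rec <- data.frame(participant = paste0("p", 1:n), window = "summative",
                    aoi = "all", f1 = stats::rnorm(n), f2 = stats::rnorm(n))
  y <- 2 * rec$f1 + stats::rnorm(n, sd = 0.1)
  feats <- assemble_features(rec, stats::setNames(y, rec$participant),
                             "regression")
  ev <- evaluate_models(feats, c("Linear Regression", "Random Forest"),
                        folds = 5, seed = 10)
  s <- ev$summary
  expect_lt(s$mean[s$model == "Linear Regression"],
            s$mean[s$model == "Zero Rule"])       # rmse: smaller is better
  # Zero Rule fold RMSE = held-out spread around the training mean
  zr <- ev$report[ev$report$model == "Zero Rule", ]
  fold <- ev$fold_assignment
  for (k in zr$fold) {
    mu <- mean(feats$y[fold != k])
    expect_equal(zr$score[zr$fold == k],
                 sqrt(mean((feats$y[fold == k] - mu)^2)))
  }
})

test_that("pairwise comparisons are Bonferroni-corrected over all pairs", {
  f <- make_feature_records(n = 60, seed = 11)
  feats <- assemble_features(f$records, f$labels, "classification")
  ev <- evaluate_models(feats, c("C4.5 Decision Tree", "Naive Bayes"),
                        folds = 5, seed = 12)
  cmp <- compare_models(ev)
  expect_equal(nrow(cmp), 3)                        # 3 models -> 3 pairs
  expect_equal(unique(cmp$bonferroni_factor), 3)
  expect_true(all(cmp$p_corrected >= cmp$p_raw - 1e-12))
  expect_true(all(cmp$p_corrected <= 1))
  # identical fold scores -> t = 0, p clamps to 1
  fake <- ev
  fake$report <- rbind(
    data.frame(model = "m1", fold = 1:5, score = c(.6, .7, .8, .6, .7)),
    data.frame(model = "m2", fold = 1:5, score = c(.6, .7, .8, .6, .7)))
  cmp2 <- compare_models(fake)
  expect_equal(cmp2$t_stat, 0)
  expect_equal(cmp2$p_corrected, 1)
  # corrected-t variant returns valid p-values too
  cmp3 <- compare_models(ev, correction = "corrected-t")
  expect_true(all(cmp3$p_raw >= 0 & cmp3$p_raw <= 1))
})
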