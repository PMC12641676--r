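# Model registry and fit/predict glue for the prediction layer.
#
# The registry preserves the full published enumeration of model names.
# Each name maps to the nearest native family available in R (e.g. the
# sequential-minimal-optimization SVM maps to a linear-kernel SVM, the C4.5
# tree to an entropy-split recursive partition). Names that only make sense
# inside their original ecosystem (text-specific or incrementally-updateable
# variants, several meta wrappers) stay registered with `available = FALSE`
# and raise a clear error on use.

.classification_registry <- function() {
  reg <- rbind(
    c("Zero Rule", "zero_rule"),
    c("Bayesian Network", NA),
    c("Naive Bayes", "naive_bayes"),
    c("Naive Bayes Multinomial Text", NA),
    c("Naive Bayes Updateable", NA),
    c("Naive Bayes Multinomial", NA),
    c("Naive Bayes Multinomial Updateable", NA),
    c("Logistic Regression", "logistic"),
    c("Multilayer Perceptron", "mlp"),
    c("Stochastic Gradient Descent", NA),
    c("Stochastic Gradient Descent Text", NA),
    c("Simple Logistic Regression", "logistic"),
    c("Sequential Minimal Optimization (for Support Vector Machines)",
      "svm_linear"),
    c("Voted Perceptron", NA),
    c("Instance-Based k (k-Nearest Neighbors)", "knn"),
    c("K* (K-Star)", NA),
    c("Locally Weighted Learning", NA),
    c("Adaptive Boosting Method 1", NA),
    c("Attribute Selected Classifier", NA),
    c("Bootstrap Aggregating", "bagging"),
    c("Classification via Regression", NA),
    c("Cross-Validation Parameter Selection", NA),
    c("Filtered Classifier", NA),
    c("Iterative Classifier Optimizer", NA),
    c("Logistic Boosting", NA),
    c("Multi-Class Classifier", "logistic"),
    c("Multi-Class Classifier Updateable", NA),
    c("Multi-Scheme", NA),
    c("Random Committee", NA),
    c("Randomizable Filtered Classifier", NA),
    c("Random Subspace", "random_subspace"),
    c("Stacking", NA),
    c("Vote", "vote"),
    c("Weighted Instances Handler Wrapper", NA),
    c("Input Mapped Classifier", NA),
    c("Decision Table", NA),
    c("Repeated Incremental Pruning to Produce Error Reduction (RIPPER)", NA),
    c("One Rule", NA),
    c("Partial Decision Trees", NA),
    c("Decision Stump", "stump"),
    c("Hoeffding Tree", NA),
    c("C4.5 Decision Tree", "tree_entropy"),
    c("Logistic Model Trees", NA),
    c("Random Forest", "random_forest"),
    c("Random Tree", "random_tree"),
    c("Reduced Error Pruning Tree", "tree_pruned")
  )
  data.frame(registry_name = reg[, 1], task = "classification",
             family = reg[, 2], available = !is.na(reg[, 2]),
             stringsAsFactors = FALSE)
}

.regression_registry <- function() {
  reg <- rbind(
    c("Zero Rule", "zero_rule_reg"),
    c("Gaussian Processes", "gp_reg"),
    c("Linear Regression", "lm"),
    c("Multilayer Perceptron", "mlp_reg"),
    c("Simple Linear Regression", "simple_lm"),
    c("Sequential Minimal Optimization for Regression", "svm_reg"),
    c("Bootstrap Aggregating", "bagging_reg"),
    c("Cross-Validation Parameter Selection", NA),
    c("Regression By Discretization", NA),
    c("Multiple Scheme", NA),
    c("Random Committee", NA),
    c("Randomizable Filtered Classifier", NA),
    c("Random Subspace", "random_subspace_reg"),
    c("Stacked Generalization", NA),
    c("Voting", "vote_reg"),
    c("Weighted Instances Handler Wrapper", NA),
    c("Decision Table", NA),
    c("M5 Rules", NA),
    c("M5 Prime", NA),
    c("Reduced Error Pruning Tree", "tree_reg"),
    c("Instance-Based k-Nearest Neighbors", "knn_reg"),
    c("K* (K-Star)", NA),
    c("Locally Weighted Learning", NA),
    c("Decision Stump", "stump_reg"),
    c("Random Forest", "rf_reg"),
    c("Additive Regression", NA),
    c("Attribute Selected Classifier", NA),
    c("Elastic Net", "elastic_net"),
    c("Isotonic Regression", "isotonic"),
    c("Least Median of Squares", "lms_reg"),
    c("Iterative Absolute Error Regression", NA)
  )
  data.frame(registry_name = reg[, 1], task = "regression",
             family = reg[, 2], available = !is.na(reg[, 2]),
             stringsAsFactors = FALSE)
}

#' The model registry
#'
#' Every supported model name for the given task, with its native family
#' mapping and availability flag. The classification registry enumerates 46
#' names, the regression registry 31; "Zero Rule" (the majority-class /
#' mean baseline) appears in both.
#'
#' @param task `"classification"` or `"regression"`.
#' @return data.frame `registry_name`, `task`, `family`, `available`.
#' @export
model_registry <- function(task = c("classification", "regression")) {
  task <- match.arg(task)
  if (task == "classification") .classification_registry()
  else .regression_registry()
}

# ---- fit / predict dispatch --------------------------------------------

.fit_family <- function(family, X, y, seed = 1) {
  set.seed(seed)
  X <- as.data.frame(X)
  switch(
    family,
    # classification ------------------------------------------------
    zero_rule = {
      tab <- table(y)
      list(kind = "zero_rule", majority = names(tab)[which.max(tab)],
           levels = levels(y))
    },
    naive_bayes = list(kind = "e1071_nb",
                       fit = e1071::naiveBayes(X, y)),
    logistic = list(kind = "multinom",
                    fit = nnet::multinom(y ~ ., data = cbind(X, y = y),
                                         trace = FALSE, maxit = 200)),
    mlp = list(kind = "nnet",
               fit = nnet::nnet(X, nnet::class.ind(y), size = 5,
                                decay = 0.1, maxit = 300, trace = FALSE),
               levels = levels(y)),
    svm_linear = list(kind = "svm",
                      fit = e1071::svm(X, y, kernel = "linear")),
    knn = list(kind = "knn", X = X, y = y, k = min(3, nrow(X))),
    stump = list(kind = "rpart_class",
                 fit = rpart::rpart(y ~ ., data = cbind(X, y = y),
                                    control = rpart::rpart.control(
                                      maxdepth = 1, cp = 0, minsplit = 2))),
    tree_entropy = list(kind = "rpart_class",
                        fit = rpart::rpart(y ~ ., data = cbind(X, y = y),
                                           parms = list(split = "information"),
                                           control = rpart::rpart.control(
                                             cp = 0.01, minsplit = 5))),
    tree_pruned = list(kind = "rpart_class",
                       fit = rpart::rpart(y ~ ., data = cbind(X, y = y))),
    random_forest = list(kind = "rf",
                         fit = randomForest::randomForest(X, y,
                                                          ntree = 200)),
    random_tree = list(kind = "rf",
                       fit = randomForest::randomForest(X, y, ntree = 1)),
    bagging = {
      fits <- lapply(seq_len(15), function(b) {
        idx <- sample.int(nrow(X), replace = TRUE)
        rpart::rpart(y ~ ., data = cbind(X, y = y)[idx, , drop = FALSE])
      })
      list(kind = "bag_class", fits = fits, levels = levels(y))
    },
    vote = {
      base <- list(.fit_family("naive_bayes", X, y, seed),
                   .fit_family("logistic", X, y, seed),
                   .fit_family("tree_pruned", X, y, seed))
      list(kind = "vote_class", fits = base, levels = levels(y))
    },
    random_subspace = {
      p <- ncol(X)
      fits <- lapply(seq_len(10), function(b) {
        keep <- sort(sample.int(p, max(1, floor(p / 2))))
        list(cols = keep,
             fit = rpart::rpart(y ~ .,
                                data = cbind(X[, keep, drop = FALSE], y = y)))
      })
      list(kind = "subspace_class", fits = fits, levels = levels(y))
    },
    # regression ----------------------------------------------------
    zero_rule_reg = list(kind = "zero_rule_reg", mean = mean(y)),
    lm = list(kind = "lm", fit = stats::lm(y ~ ., data = cbind(X, y = y))),
    simple_lm = {
      # best single predictor by in-sample correlation
      r <- vapply(X, function(col) {
        if (stats::sd(col) == 0) 0 else abs(stats::cor(col, y))
      }, numeric(1))
      j <- which.max(r)
      d <- data.frame(x = X[[j]], y = y)
      list(kind = "simple_lm", col = names(X)[j],
           fit = stats::lm(y ~ x, data = d))
    },
    mlp_reg = list(kind = "nnet_reg",
                   fit = nnet::nnet(X, y, size = 5, decay = 0.1,
                                    linout = TRUE, maxit = 300,
                                    trace = FALSE)),
    svm_reg = list(kind = "svm",
                   fit = e1071::svm(X, y, kernel = "linear")),
    gp_reg = list(kind = "gp", fit = {
      fit <- NULL
      # gausspr chats about sigma estimation on stdout; keep runs quiet
      invisible(utils::capture.output(
        fit <- suppressMessages(kernlab::gausspr(as.matrix(X), y,
                                                 kpar = "automatic"))))
      fit
    }),
    knn_reg = list(kind = "knn_reg",
                   fit = caret::knnreg(as.matrix(X), y,
                                       k = min(3, nrow(X)))),
    elastic_net = {
      m <- as.matrix(X)
      list(kind = "glmnet", fit = glmnet::glmnet(m, y, alpha = 0.5),
           lambda = {
             cv <- try(glmnet::cv.glmnet(m, y, alpha = 0.5,
                                         nfolds = min(5, nrow(m))),
                       silent = TRUE)
             if (inherits(cv, "try-error")) 0.01 else cv$lambda.min
           })
    },
    isotonic = {
      r <- vapply(X, function(col) {
        if (stats::sd(col) == 0) 0 else abs(stats::cor(col, y))
      }, numeric(1))
      j <- which.max(r)
      sgn <- sign(stats::cor(X[[j]], y))
      if (is.na(sgn) || sgn == 0) sgn <- 1
      iso <- stats::isoreg(sgn * X[[j]], y)
      list(kind = "isotonic", col = names(X)[j], sign = sgn,
           fun = stats::as.stepfun(iso))
    },
    lms_reg = list(kind = "lms",
                   fit = MASS::lqs(y ~ ., data = cbind(X, y = y),
                                   method = "lms")),
    tree_reg = list(kind = "rpart_reg",
                    fit = rpart::rpart(y ~ ., data = cbind(X, y = y))),
    stump_reg = list(kind = "rpart_reg",
                     fit = rpart::rpart(y ~ ., data = cbind(X, y = y),
                                        control = rpart::rpart.control(
                                          maxdepth = 1, cp = 0,
                                          minsplit = 2))),
    rf_reg = list(kind = "rf_reg",
                  fit = randomForest::randomForest(X, y, ntree = 200)),
    bagging_reg = {
      fits <- lapply(seq_len(15), function(b) {
        idx <- sample.int(nrow(X), replace = TRUE)
        rpart::rpart(y ~ ., data = cbind(X, y = y)[idx, , drop = FALSE])
      })
      list(kind = "bag_reg", fits = fits)
    },
    vote_reg = {
      base <- list(.fit_family("lm", X, y, seed),
                   .fit_family("tree_reg", X, y, seed),
                   .fit_family("rf_reg", X, y, seed))
      list(kind = "vote_reg", fits = base)
    },
    random_subspace_reg = {
      p <- ncol(X)
      fits <- lapply(seq_len(10), function(b) {
        keep <- sort(sample.int(p, max(1, floor(p / 2))))
        list(cols = keep,
             fit = rpart::rpart(y ~ .,
                                data = cbind(X[, keep, drop = FALSE], y = y)))
      })
      list(kind = "subspace_reg", fits = fits)
    },
    stop("unknown model family: ", family)
  )
}

.majority_vote <- function(preds, levels) {
  factor(apply(do.call(cbind, lapply(preds, as.character)), 1, function(r) {
    names(sort(table(r), decreasing = TRUE))[1]
  }), levels = levels)
}

.predict_family <- function(model, X) {
  X <- as.data.frame(X)
  switch(
    model$kind,
    zero_rule = factor(rep(model$majority, nrow(X)), levels = model$levels),
    e1071_nb = stats::predict(model$fit, X),
    multinom = stats::predict(model$fit, newdata = X),
    nnet = {
      pr <- stats::predict(model$fit, X)
      factor(model$levels[max.col(pr)], levels = model$levels)
    },
    svm = stats::predict(model$fit, X),
    knn = class::knn(model$X, X, model$y, k = model$k),
    rpart_class = stats::predict(model$fit, X, type = "class"),
    rf = stats::predict(model$fit, X),
    bag_class = .majority_vote(
      lapply(model$fits, function(f) stats::predict(f, X, type = "class")),
      model$levels),
    vote_class = .majority_vote(
      lapply(model$fits, function(f) .predict_family(f, X)), model$levels),
    subspace_class = .majority_vote(
      lapply(model$fits, function(f) {
        stats::predict(f$fit, X[, f$cols, drop = FALSE], type = "class")
      }), model$levels),
    zero_rule_reg = rep(model$mean, nrow(X)),
    lm = as.numeric(stats::predict(model$fit, newdata = X)),
    simple_lm = as.numeric(stats::predict(
      model$fit, newdata = data.frame(x = X[[model$col]]))),
    nnet_reg = as.numeric(stats::predict(model$fit, X)),
    gp = as.numeric(kernlab::predict(model$fit, as.matrix(X))),
    knn_reg = as.numeric(stats::predict(model$fit, as.matrix(X))),
    glmnet = as.numeric(stats::predict(model$fit, as.matrix(X),
                                       s = model$lambda)),
    isotonic = model$fun(model$sign * X[[model$col]]),
    lms = as.numeric(stats::predict(model$fit, newdata = X)),
    rpart_reg = as.numeric(stats::predict(model$fit, X)),
    rf_reg = as.numeric(stats::predict(model$fit, X)),
    bag_reg = rowMeans(do.call(cbind, lapply(model$fits, function(f) {
      as.numeric(stats::predict(f, X))
    }))),
    vote_reg = rowMeans(do.call(cbind, lapply(model$fits, function(f) {
      .predict_family(f, X)
    }))),
    subspace_reg = rowMeans(do.call(cbind, lapply(model$fits, function(f) {
      as.numeric(stats::predict(f$fit, X[, f$cols, drop = FALSE]))
    }))),
    stop("unknown fitted model kind: ", model$kind)
  )
}
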