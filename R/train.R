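#' Model configuration: learner, grid-search space, inner CV
#'
#' @param learner one of `"xgboost"`, `"svm_linear"`, `"svm_rbf"`,
#'   `"random_forest"`, `"naive_bayes"`, `"lda"`, `"adaboost"`.
#' @param grid data frame of candidate hyperparameter combinations (one row
#'   per grid point); `NULL` picks [default_grid()] for the learner. For
#'   xgboost the columns are `max_depth`, `eta`, `nrounds`, `gamma` (minimum
#'   split loss, the leaf-count penalty) and `lambda` (L2 penalty on leaf
#'   weights).
#' @param folds inner stratified cross-validation folds used by the grid
#'   search (>= 2).
#' @param seed seed for fold assignment and any stochastic learner.
#' @return object of class `model_config`.
#' @export
model_config <- function(learner = "xgboost", grid = NULL, folds = 3,
                         seed = 1) {
  learner <- match.arg(learner, c("xgboost", "svm_linear", "svm_rbf",
                                  "random_forest", "naive_bayes", "lda",
                                  "adaboost"))
  if (is.null(grid)) grid <- default_grid(learner)
  grid <- as.data.frame(grid)
  if (nrow(grid) < 1L) stop("grid must be non-empty", call. = FALSE)
  stopifnot_scalar_number(folds, "folds", lower = 2)
  structure(list(learner = learner, grid = grid, folds = as.integer(folds),
                 seed = seed),
            class = "model_config")
}

#' Default grid-search spaces per learner
#'
#' Small, desk-scale grids. The xgboost grid spans tree depth, learning rate,
#' tree count and both regularizers of the boosted-tree objective (gamma on
#' the number of leaves, lambda on the squared leaf weights).
#'
#' @param learner learner name as in [model_config()].
#' @return data frame, one row per grid point.
#' @export
default_grid <- function(learner) {
  switch(learner,
    xgboost = expand.grid(max_depth = c(3, 5, 7), eta = c(0.05, 0.1, 0.3),
                          nrounds = c(100, 300), gamma = c(0, 1),
                          lambda = c(1, 10)),
    svm_linear = data.frame(cost = c(0.1, 1, 10)),
    svm_rbf = expand.grid(cost = c(1, 10), gamma = c(0.01, 0.1, 1)),
    random_forest = data.frame(ntree = c(100, 300)),
    naive_bayes = data.frame(laplace = 0),
    lda = data.frame(.unused = 0),
    adaboost = expand.grid(n_rounds = 50, max_depth = c(1, 2)),
    stop("unknown learner: ", learner, call. = FALSE)
  )
}

#' Train a yield classifier on a split plan with grid search
#'
#' Performs grid search by stratified inner cross-validation on the training
#' plots only (test plots never influence model selection), then refits the
#' winning grid point on the full training set. Deterministic given the
#' configuration seed. Single-row grids skip the inner CV.
#'
#' @param features a `feature_table`.
#' @param plan a `split_plan`.
#' @param config a [model_config()].
#' @return object of class `yield_model`: the fitted learner, the chosen grid
#'   point (`$params`), the CV table (`$cv`) and the feature columns used.
#' @export
train_classifier <- function(features, plan, config = model_config()) {
  check_split_plan(plan, features)
  if (!inherits(config, "model_config")) {
    stop("`config` must be a `model_config`", call. = FALSE)
  }
  fc <- attr(features, "feature_cols")
  tr <- features$plot_id %in% plan$train_plots
  if (!any(tr)) stop("training set is empty", call. = FALSE)
  X <- as.matrix(features[tr, fc, drop = FALSE])
  y <- factor(features$class[tr], levels = levels(features$class))
  if (nlevels(droplevels(y)) < 2L) {
    stop("training error: only one class present in the training set",
         call. = FALSE)
  }

  grid <- config$grid
  cv_acc <- rep(NA_real_, nrow(grid))
  if (nrow(grid) > 1L) {
    folds <- with_seed(child_seed(config$seed, 1),
                       stratified_folds(y, config$folds))
    for (gp in seq_len(nrow(grid))) {
      correct <- 0L
      for (f in seq_len(config$folds)) {
        hold <- folds == f
        fit <- fit_learner(config$learner, X[!hold, , drop = FALSE],
                           y[!hold], grid[gp, , drop = FALSE],
                           seed = child_seed(config$seed, 100 + f))
        pred <- predict_learner(fit, X[hold, , drop = FALSE])
        correct <- correct + sum(pred == y[hold])
      }
      cv_acc[gp] <- correct / length(y)
    }
    best <- which.max(cv_acc) # ties: first grid row, deterministic
  } else {
    best <- 1L
  }
  fit <- fit_learner(config$learner, X, y, grid[best, , drop = FALSE],
                     seed = child_seed(config$seed, 2))
  structure(list(learner = config$learner, fit = fit,
                 params = grid[best, , drop = FALSE],
                 cv = cbind(grid, cv_accuracy = cv_acc),
                 feature_cols = fc, levels = levels(y)),
            class = "yield_model")
}

#' @export
predict.yield_model <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else
    as.matrix(newdata[, object$feature_cols, drop = FALSE])
  predict_learner(object$fit, X)
}

# per-class round-robin fold assignment after a shuffle
stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    if (length(idx) == 0L) next
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

fit_learner <- function(learner, X, y, params, seed = 1) {
  lv <- levels(y)
  fit <- switch(learner,
    xgboost = {
      dtr <- xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L)
      booster <- with_seed(seed, xgboost::xgb.train(
        params = list(objective = "multi:softprob", num_class = length(lv),
                      max_depth = params$max_depth, eta = params$eta,
                      gamma = params$gamma, lambda = params$lambda,
                      nthread = 1, verbosity = 0),
        data = dtr, nrounds = params$nrounds))
      list(booster = booster)
    },
    svm_linear = list(model = with_seed(seed, e1071::svm(
      X, y, kernel = "linear", cost = params$cost, scale = FALSE))),
    svm_rbf = list(model = with_seed(seed, e1071::svm(
      X, y, kernel = "radial", cost = params$cost, gamma = params$gamma,
      scale = FALSE))),
    random_forest = list(model = with_seed(seed, randomForest::randomForest(
      X, y, ntree = params$ntree))),
    naive_bayes = list(model = e1071::naiveBayes(
      X, y, laplace = params$laplace)),
    lda = {
      # drop features with zero pooled within-group variance, which the
      # discriminant scaling cannot invert
      within_var <- vapply(seq_len(ncol(X)), function(j) {
        sum(vapply(levels(y), function(cl) {
          v <- X[y == cl, j]
          if (length(v) > 1L) stats::var(v) * (length(v) - 1L) else 0
        }, numeric(1)))
      }, numeric(1))
      keep <- which(within_var > 1e-12)
      if (length(keep) == 0L) {
        stop("training error: no feature varies within classes", call. = FALSE)
      }
      # collinear index features are expected (many share anchors); lda's
      # tolerance handles them, so silence its advisory warning
      list(model = suppressWarnings(
        MASS::lda(X[, keep, drop = FALSE], grouping = y)),
        keep = keep)
    },
    adaboost = list(model = with_seed(seed, fit_samme(
      X, y, n_rounds = params$n_rounds, max_depth = params$max_depth))),
    stop("unknown learner: ", learner, call. = FALSE)
  )
  fit$learner <- learner
  fit$levels <- lv
  fit
}

predict_learner <- function(fit, X) {
  lv <- fit$levels
  pred <- switch(fit$learner,
    xgboost = {
      p <- predict(fit$booster, xgboost::xgb.DMatrix(X))
      lv[max.col(matrix(p, nrow = nrow(X)), ties.method = "first")]
    },
    svm_linear = ,
    svm_rbf = as.character(predict(fit$model, X)),
    random_forest = as.character(predict(fit$model, X)),
    naive_bayes = as.character(predict(fit$model, X)),
    lda = as.character(predict(fit$model, X[, fit$keep, drop = FALSE])$class),
    adaboost = predict_samme(fit$model, X),
    stop("unknown learner: ", fit$learner, call. = FALSE)
  )
  factor(pred, levels = lv)
}

# Multiclass AdaBoost (SAMME) over shallow CART trees.
fit_samme <- function(X, y, n_rounds = 50, max_depth = 1) {
  df <- data.frame(X)
  df$.y <- y
  n <- nrow(df)
  K <- nlevels(y)
  w <- rep(1 / n, n)
  trees <- list(); alphas <- numeric(0)
  for (m in seq_len(n_rounds)) {
    tree <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                         control = rpart::rpart.control(
                           maxdepth = max_depth, cp = 0, xval = 0,
                           minsplit = 2, minbucket = 1))
    pred <- predict(tree, df, type = "class")
    miss <- pred != y
    err <- sum(w * miss) / sum(w)
    if (err <= 0) { # perfect stump: dominate the vote and stop
      trees[[length(trees) + 1L]] <- tree
      alphas <- c(alphas, log(1e12) + log(K - 1))
      break
    }
    if (err >= 1 - 1 / K) break # no better than chance; stop adding rounds
    alpha <- log((1 - err) / err) + log(K - 1)
    trees[[length(trees) + 1L]] <- tree
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
  }
  if (length(trees) == 0L) { # degenerate: keep the single weak tree
    trees <- list(tree)
    alphas <- 1
  }
  list(trees = trees, alphas = alphas, levels = levels(y))
}

predict_samme <- function(model, X) {
  df <- data.frame(X)
  votes <- matrix(0, nrow(df), length(model$levels),
                  dimnames = list(NULL, model$levels))
  for (m in seq_along(model$trees)) {
    pred <- as.character(predict(model$trees[[m]], df, type = "class"))
    votes[cbind(seq_len(nrow(df)), match(pred, model$levels))] <-
      votes[cbind(seq_len(nrow(df)), match(pred, model$levels))] +
      model$alphas[m]
  }
  model$levels[max.col(votes, ties.method = "first")]
}
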