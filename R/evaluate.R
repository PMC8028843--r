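#' Confusion matrix over the fixed class set
#'
#' @param truth,pred vectors coercible to factors over `levels`.
#' @param levels class levels defining matrix order (default A, B, C).
#' @return square integer matrix, rows = truth, columns = predicted.
#' @export
confusion_matrix <- function(truth, pred, levels = c("A", "B", "C")) {
  t <- factor(truth, levels = levels)
  p <- factor(pred, levels = levels)
  if (anyNA(t) || anyNA(p)) {
    stop("labels outside the declared class levels", call. = FALSE)
  }
  unclass(table(truth = t, predicted = p))
}

#' Per-class precision and recall from a confusion matrix
#'
#' `precision_k = cm[k, k] / colSums(cm)[k]` (defined as 0 when nothing was
#' predicted as class k) and `recall_k = cm[k, k] / rowSums(cm)[k]` (0 when
#' class k has no true samples).
#'
#' @param cm square confusion matrix (rows = truth).
#' @return list with numeric vectors `precision`, `recall` and scalar
#'   `accuracy`.
#' @export
precision_recall <- function(cm) {
  cm <- as.matrix(cm)
  d <- diag(cm)
  col_tot <- colSums(cm)
  row_tot <- rowSums(cm)
  precision <- ifelse(col_tot > 0, d / col_tot, 0)
  recall <- ifelse(row_tot > 0, d / row_tot, 0)
  names(precision) <- names(recall) <- colnames(cm)
  list(precision = precision, recall = recall,
       accuracy = sum(d) / sum(cm))
}

#' Evaluate a fitted model on a split plan's test plots
#'
#' @param model a `yield_model` from [train_classifier()].
#' @param features the `feature_table` the plan indexes into.
#' @param plan the `split_plan` whose test plots are scored.
#' @param condition optional tag (e.g. "with_lodging") carried into reports.
#' @return object of class `eval_report`: the 3 x 3 confusion matrix
#'   (`$confusion`), per-class `$precision` and `$recall`, `$accuracy`,
#'   `$n_test` and bookkeeping fields.
#' @export
evaluate <- function(model, features, plan, condition = NA_character_) {
  check_split_plan(plan, features)
  te <- features$plot_id %in% plan$test_plots
  if (!any(te)) stop("test set is empty", call. = FALSE)
  truth <- features$class[te]
  pred <- predict(model, features[te, , drop = FALSE])
  cm <- confusion_matrix(truth, pred, levels = levels(features$class))
  pr <- precision_recall(cm)
  structure(list(plan_id = plan$id, mode = plan$mode, condition = condition,
                 learner = model$learner, confusion = cm,
                 precision = pr$precision, recall = pr$recall,
                 accuracy = pr$accuracy, n_test = sum(te)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation of plan %s (%s, %s): accuracy %.3f on %d samples\n",
              x$plan_id, x$learner,
              if (is.na(x$condition)) "-" else x$condition,
              x$accuracy, x$n_test))
  print(x$confusion)
  invisible(x)
}

#' Lodging ablation: with, without and lodging-only feature sets
#'
#' For every split plan, learner and condition, trains and evaluates a
#' classifier and collects per-class precision/recall. Conditions:
#' `with_lodging` uses the full fused table, `without_lodging` the paired
#' table lacking the lodging column, `lodging_only` the single lodging-index
#' column. The same grid space is used for the paired with/without runs so
#' the comparison is not confounded by model selection.
#'
#' @param features_with `feature_table` including the lodging index.
#' @param features_without paired `feature_table` without it (same rows,
#'   same labels).
#' @param plans list of `split_plan`s.
#' @param config a [model_config()]; its learner is replaced by each entry
#'   of `learners` in turn.
#' @param learners character vector of learner names.
#' @param conditions subset of
#'   `c("with_lodging", "without_lodging", "lodging_only")`.
#' @return object of class `ablation_report`: `$reports` (list of
#'   `eval_report`s), `$summary` (one row per plan x learner x condition x
#'   class) and `$averages` (mean precision/recall/accuracy per learner x
#'   condition x class).
#' @export
run_ablation <- function(features_with, features_without, plans,
                         config = model_config(),
                         learners = "xgboost",
                         conditions = c("with_lodging", "without_lodging",
                                        "lodging_only")) {
  conditions <- match.arg(conditions, several.ok = TRUE)
  if (nrow(features_with) != nrow(features_without) ||
      !identical(features_with$plot_id, features_without$plot_id) ||
      !identical(as.character(features_with$class),
                 as.character(features_without$class))) {
    stop("pairing error: feature tables disagree in rows or labels",
         call. = FALSE)
  }
  if (!"lodging_index" %in% attr(features_with, "feature_cols")) {
    stop("`features_with` lacks the lodging_index column", call. = FALSE)
  }
  lodging_only <- features_with
  attr(lodging_only, "feature_cols") <- "lodging_index"
  tables <- list(with_lodging = features_with,
                 without_lodging = features_without,
                 lodging_only = lodging_only)

  reports <- list()
  rows <- list()
  for (lrn in learners) {
    cfg <- model_config(learner = lrn,
                        grid = if (lrn == config$learner) config$grid,
                        folds = config$folds, seed = config$seed)
    for (plan in plans) {
      for (cond in conditions) {
        tab <- tables[[cond]]
        model <- train_classifier(tab, plan, cfg)
        rep <- evaluate(model, tab, plan, condition = cond)
        reports[[length(reports) + 1L]] <- rep
        rows[[length(rows) + 1L]] <- data.frame(
          plan_id = plan$id, mode = plan$mode, learner = lrn,
          condition = cond, class = names(rep$precision),
          precision = as.numeric(rep$precision),
          recall = as.numeric(rep$recall),
          accuracy = rep$accuracy,
          stringsAsFactors = FALSE)
      }
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  averages <- stats::aggregate(
    summary[, c("precision", "recall", "accuracy")],
    by = summary[, c("learner", "condition", "class")], FUN = mean)
  structure(list(reports = reports, summary = summary, averages = averages),
            class = "ablation_report")
}

#' Write an ablation report as JSON + CSV summary
#'
#' @param report an `ablation_report`.
#' @param path output directory.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    lapply(report$reports, function(r) {
      list(plan_id = r$plan_id, mode = r$mode, condition = r$condition,
           learner = r$learner, confusion = as.data.frame(as.table(r$confusion)),
           precision = as.list(r$precision), recall = as.list(r$recall),
           accuracy = r$accuracy, n_test = r$n_test)
    }), file.path(path, "reports.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$summary, file.path(path, "summary.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' @export
print.ablation_report <- function(x, ...) {
  cat(sprintf("Ablation report: %d evaluations\n", length(x$reports)))
  print(x$averages, digits = 3)
  invisible(x)
}
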