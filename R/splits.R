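#' Intraline split plans: leave one replicate out
#'
#' Generalization across field position: for each replicate index r, the test
#' set holds replicate r of every line and the training set the remaining
#' replicates. With 3 replicates this yields 3 plans; every plot appears in a
#' test set exactly once across plans (a superset of picking a single random
#' two-vs-one split, and deterministic).
#'
#' @param fieldmap a `field_map`.
#' @return list of `split_plan` objects (fields: `id`, `mode`,
#'   `train_plots`, `test_plots`, `test_lines`).
#' @export
make_intraline_splits <- function(fieldmap) {
  reps_per_line <- table(fieldmap$line_id)
  if (length(unique(as.integer(reps_per_line))) != 1L) {
    stop("design error: lines have unequal replicate counts", call. = FALSE)
  }
  reps <- sort(unique(fieldmap$replicate))
  lapply(seq_along(reps), function(i) {
    r <- reps[i]
    test <- fieldmap$plot_id[fieldmap$replicate == r]
    structure(list(
      id = sprintf("intraline_rep%s", r), mode = "intraline",
      train_plots = setdiff(fieldmap$plot_id, test), test_plots = test,
      test_lines = unique(fieldmap$line_id)
    ), class = "split_plan")
  })
}

#' Interline split plans: leave one line per class out
#'
#' Generalization to unseen cultivars: every plan holds out one whole line
#' (all replicates) from each yield class as the test set and trains on all
#' plots of the remaining lines. The plans enumerate the Cartesian product
#' over classes, so with class sizes 2/7/4 there are 2 x 7 x 4 = 56 plans.
#'
#' @param fieldmap a `field_map`.
#' @return list of `split_plan` objects.
#' @export
make_interline_splits <- function(fieldmap) {
  line_class <- unique(fieldmap[, c("line_id", "class")])
  by_class <- split(line_class$line_id, line_class$class)
  by_class <- by_class[c("A", "B", "C")]
  if (any(vapply(by_class, length, integer(1)) == 0L) || anyNA(names(by_class))) {
    stop("design error: every class needs at least one line", call. = FALSE)
  }
  combos <- expand.grid(A = by_class$A, B = by_class$B, C = by_class$C,
                        stringsAsFactors = FALSE)
  lapply(seq_len(nrow(combos)), function(i) {
    test_lines <- unlist(combos[i, ], use.names = FALSE)
    test <- fieldmap$plot_id[fieldmap$line_id %in% test_lines]
    structure(list(
      id = sprintf("interline_%03d", i), mode = "interline",
      train_plots = setdiff(fieldmap$plot_id, test), test_plots = test,
      test_lines = test_lines
    ), class = "split_plan")
  })
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("Split plan %s (%s): %d train / %d test plots\n",
              x$id, x$mode, length(x$train_plots), length(x$test_plots)))
  invisible(x)
}

check_split_plan <- function(plan, features) {
  if (!inherits(plan, "split_plan")) {
    stop("`plan` must be a `split_plan`", call. = FALSE)
  }
  if (length(intersect(plan$train_plots, plan$test_plots)) > 0L) {
    stop("design error: train and test plots overlap", call. = FALSE)
  }
  known <- unique(features$plot_id)
  missing <- setdiff(c(plan$train_plots, plan$test_plots), known)
  if (length(missing) > 0L) {
    stop("design error: plan references plots absent from the feature table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(plan)
}
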