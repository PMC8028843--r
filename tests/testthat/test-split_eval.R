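test_that("intraline plans partition the plots by held-out replicate", {
  sim <- simulate_field(sim_config(), seed = 51)
  plans <- make_intraline_splits(sim$fieldmap)
  expect_length(plans, 3L)
  for (p in plans) {
    expect_length(p$test_plots, 13L)
    expect_length(intersect(p$train_plots, p$test_plots), 0L)
  }
  all_test <- unlist(lapply(plans, `[[`, "test_plots"))
  expect_equal(anyDuplicated(all_test), 0L)
  expect_setequal(all_test, sim$fieldmap$plot_id)
})

test_that("unequal replicate counts are a design error", {
  fm <- simulate_field(sim_config(), seed = 52)$fieldmap
  expect_error(make_intraline_splits(fm[-1, ]), "unequal replicate")
})

test_that("interline plans enumerate one held-out line per class", {
  sim <- simulate_field(sim_config(), seed = 53)
  plans <- make_interline_splits(sim$fieldmap)
  expect_length(plans, 2L * 7L * 4L) # 56 permutations
  for (p in plans[c(1, 28, 56)]) {
    expect_length(p$test_lines, 3L)
    cls <- sim$fieldmap$class[match(p$test_lines, sim$fieldmap$line_id)]
    expect_setequal(cls, c("A", "B", "C"))
    expect_length(p$test_plots, 9L) # 3 lines x 3 replicates
    test_lines_in_train <- sim$fieldmap$line_id[
      sim$fieldmap$plot_id %in% p$train_plots]
    expect_length(intersect(p$test_lines, test_lines_in_train), 0L)
  }
})

test_that("interline plan count equals the product of class sizes", {
  # exhaustive check for all class partitions with sizes <= 4
  for (a in 1:4) for (b in 1:4) for (cc in 1:4) {
    n <- a + b + cc
    fm <- data.frame(
      plot_id = sprintf("p%02d", seq_len(n)),
      line_id = sprintf("L%02d", seq_len(n)),
      replicate = 1L,
      class = rep(c("A", "B", "C"), times = c(a, b, cc)),
      stringsAsFactors = FALSE)
    plans <- make_interline_splits(fm)
    expect_length(plans, a * b * cc)
    combos <- unique(t(vapply(plans, function(p) sort(p$test_lines),
                              character(3))))
    expect_equal(nrow(combos), a * b * cc) # all plans distinct
  }
})

test_that("single-line classes give exactly one interline plan", {
  fm <- data.frame(plot_id = c("p1", "p2", "p3"),
                   line_id = c("L1", "L2", "L3"), replicate = 1L,
                   class = c("A", "B", "C"), stringsAsFactors = FALSE)
  expect_length(make_interline_splits(fm), 1L)
  expect_error(make_interline_splits(fm[fm$class != "B", ]), "design error")
})

test_that("precision and recall match brute-force counting over pairs", {
  # hand-built confusion matrix
  cm <- matrix(c(5, 0, 0, 2, 3, 0, 0, 0, 4), 3, byrow = TRUE,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  pr <- precision_recall(cm)
  expect_equal(unname(pr$precision["A"]), 5 / 7)
  expect_equal(unname(pr$recall["A"]), 1)
  expect_equal(unname(pr$precision["B"]), 1)
  expect_equal(unname(pr$recall["B"]), 3 / 5)
  expect_equal(pr$accuracy, 12 / 14)

  # brute force over random labelled pairs
  set.seed(54)
  for (i in 1:5) {
    truth <- sample(c("A", "B", "C"), 60, replace = TRUE)
    pred <- sample(c("A", "B", "C"), 60, replace = TRUE)
    cm2 <- confusion_matrix(truth, pred)
    expect_equal(sum(cm2), 60)
    pr2 <- precision_recall(cm2)
    for (k in c("A", "B", "C")) {
      tp <- sum(truth == k & pred == k)
      brute_prec <- if (sum(pred == k) == 0) 0 else tp / sum(pred == k)
      brute_rec <- if (sum(truth == k) == 0) 0 else tp / sum(truth == k)
      expect_equal(unname(pr2$precision[k]), brute_prec)
      expect_equal(unname(pr2$recall[k]), brute_rec)
    }
  }
})

test_that("zero-column precision convention and perfect predictions", {
  cm_perfect <- diag(c(4, 5, 6))
  colnames(cm_perfect) <- rownames(cm_perfect) <- c("A", "B", "C")
  pr <- precision_recall(cm_perfect)
  expect_equal(unname(pr$precision), c(1, 1, 1))
  expect_equal(unname(pr$recall), c(1, 1, 1))
  cm_noA <- matrix(c(0, 3, 0, 0, 5, 0, 0, 1, 4), 3, byrow = TRUE,
                   dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_equal(unname(precision_recall(cm_noA)$precision["A"]), 0)
})

test_that("grid-searched training is deterministic and separates by class", {
  sim <- small_sim(seed = 55)
  ft <- extract_features(sim, n_samples = 20, margin_px = 1, seed = 7)
  plans <- make_intraline_splits(sim$fieldmap)
  cfg <- model_config("xgboost",
                      grid = expand.grid(max_depth = c(2, 4), eta = 0.3,
                                         nrounds = 30, gamma = 0, lambda = 1),
                      seed = 9)
  m1 <- train_classifier(ft, plans[[1]], cfg)
  m2 <- train_classifier(ft, plans[[1]], cfg)
  expect_identical(predict(m1, ft), predict(m2, ft))
  # chosen grid point comes from the declared grid
  expect_true(nrow(merge(m1$params, cfg$grid)) >= 1)
  # training accuracy: classes are separable by lodging + class offsets here
  tr <- ft$plot_id %in% plans[[1]]$train_plots
  expect_gte(mean(predict(m1, ft[tr, ])[] == ft$class[tr]), 0.99)
})

test_that("linearly separable features give perfect training accuracy", {
  # synthetic feature table with a perfectly separating feature
  n <- 90
  cls <- rep(c("A", "B", "C"), each = n / 3)
  ft <- data.frame(plot_id = rep(sprintf("p%d", 1:9), each = n / 9),
                   line_id = rep(sprintf("L%d", 1:9), each = n / 9),
                   replicate = 1L,
                   sep = as.integer(factor(cls)) + rnorm(n, 0, 0.01),
                   noise = rnorm(n),
                   class = factor(cls, levels = c("A", "B", "C")))
  attr(ft, "feature_cols") <- c("sep", "noise")
  class(ft) <- c("feature_table", "data.frame")
  plan <- structure(list(id = "p", mode = "intraline",
                         train_plots = sprintf("p%d", c(1:2, 4:5, 7:8)),
                         test_plots = sprintf("p%d", c(3, 6, 9)),
                         test_lines = character(0)), class = "split_plan")
  m <- train_classifier(ft, plan, fast_xgb_config())
  tr <- ft$plot_id %in% plan$train_plots
  expect_equal(mean(predict(m, ft[tr, ]) == ft$class[tr]), 1)
  rep <- evaluate(m, ft, plan)
  expect_gte(rep$accuracy, 0.9)
  expect_equal(sum(rep$confusion), rep$n_test)
})

test_that("single-class training sets are rejected", {
  sim <- small_sim(seed = 56)
  ft <- extract_features(sim, n_samples = 10, margin_px = 1, seed = 1)
  one_line <- sim$fieldmap$plot_id[sim$fieldmap$line_id == "L01"]
  plan <- structure(list(id = "bad", mode = "interline",
                         train_plots = one_line,
                         test_plots = setdiff(sim$fieldmap$plot_id, one_line),
                         test_lines = c("L02", "L03")), class = "split_plan")
  expect_error(train_classifier(ft, plan, fast_xgb_config()),
               "only one class")
})

test_that("baseline learners train and predict on the fixed class set", {
  sim <- small_sim(seed = 57)
  ft <- extract_features(sim, n_samples = 15, margin_px = 1, seed = 4)
  plan <- make_intraline_splits(sim$fieldmap)[[1]]
  for (lrn in c("svm_linear", "svm_rbf", "random_forest", "naive_bayes",
                "lda", "adaboost")) {
    cfg <- model_config(lrn, grid = utils::head(default_grid(lrn), 1),
                        seed = 3)
    m <- train_classifier(ft, plan, cfg)
    rep <- evaluate(m, ft, plan, condition = "with_lodging")
    expect_s3_class(rep, "eval_report")
    expect_equal(sum(rep$confusion), rep$n_test)
    expect_true(all(rep$precision >= 0 & rep$precision <= 1))
    expect_true(all(rep$recall >= 0 & rep$recall <= 1))
  }
})

test_that("ablation bookkeeping covers plans x conditions x learners", {
  sim <- small_sim(seed = 58)
  fw <- extract_features(sim, n_samples = 15, margin_px = 1, seed = 5)
  fo <- extract_features(sim, n_samples = 15, margin_px = 1, seed = 5,
                         with_lodging = FALSE)
  plans <- make_intraline_splits(sim$fieldmap)[1:2]
  ab <- run_ablation(fw, fo, plans, fast_xgb_config(),
                     conditions = c("with_lodging", "without_lodging"))
  expect_length(ab$reports, 2L * 2L)
  expect_equal(nrow(ab$summary), 2L * 2L * 3L)
  expect_equal(nrow(ab$averages), 2L * 3L)
  dir <- withr::local_tempdir()
  write_eval_report(ab, dir)
  expect_true(file.exists(file.path(dir, "reports.json")))
  expect_true(file.exists(file.path(dir, "summary.csv")))
})

test_that("pure-noise features score near the majority-class rate", {
  set.seed(59)
  accs <- vapply(1:5, function(s) {
    n <- 120
    cls <- rep(c("A", "B", "C"), each = n / 3)
    ft <- data.frame(plot_id = rep(sprintf("p%d", 1:12), each = n / 12),
                     line_id = rep(sprintf("L%d", 1:12), each = n / 12),
                     replicate = 1L,
                     f1 = rnorm(n), f2 = rnorm(n),
                     class = factor(cls, levels = c("A", "B", "C")))
    attr(ft, "feature_cols") <- c("f1", "f2")
    class(ft) <- c("feature_table", "data.frame")
    plan <- structure(list(id = "p", mode = "intraline",
                           train_plots = sprintf("p%d", c(1:3, 5:7, 9:11)),
                           test_plots = sprintf("p%d", c(4, 8, 12)),
                           test_lines = character(0)), class = "split_plan")
    m <- train_classifier(ft, plan, fast_xgb_config(seed = s))
    evaluate(m, ft, plan)$accuracy
  }, numeric(1))
  # majority-class rate is 1/3; binomial 3 sigma over 5 x 30 test samples
  p <- 1 / 3
  expect_lt(abs(mean(accs) - p), 3 * sqrt(p * (1 - p) / (5 * 30)) + 0.05)
})

test_that("no test plot leaks into training or model selection", {
  sim <- small_sim(seed = 60, n_lines = 6, class_sizes = c(2, 2, 2))
  ft <- extract_features(sim, n_samples = 12, margin_px = 1, seed = 6)
  plan <- make_interline_splits(sim$fieldmap)[[1]]
  # poisoning the test rows must not change the fitted model's predictions
  ft_poison <- ft
  te <- ft_poison$plot_id %in% plan$test_plots
  fc <- attr(ft, "feature_cols")
  ft_poison[te, fc] <- ft_poison[te, fc] * 100 + 7
  cfg <- model_config("xgboost",
                      grid = expand.grid(max_depth = c(2, 3), eta = 0.3,
                                         nrounds = 20, gamma = 0, lambda = 1),
                      seed = 2)
  m_clean <- train_classifier(ft, plan, cfg)
  m_poison <- train_classifier(ft_poison, plan, cfg)
  tr_rows <- ft[!te, , drop = FALSE]
  expect_identical(predict(m_clean, tr_rows), predict(m_poison, tr_rows))
  expect_identical(m_clean$params, m_poison$params)
})
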