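# independent metric oracle: naive loops over every record
brute_force_confusion <- function(y, s, cutoff) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(y)) {
    if (s[i] >= cutoff) {
      if (y[i] == 1) tp <- tp + 1L else fp <- fp + 1L
    } else {
      if (y[i] == 1) fn <- fn + 1L else tn <- tn + 1L
    }
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

test_that("metrics match a brute-force confusion table on random score sets", {
  withr::with_seed(21, {
    for (i in 1:15) {
      n <- sample(10:60, 1)
      y <- rbinom(n, 1, 0.5)
      if (length(unique(y)) < 2) next
      s <- runif(n)
      cutoff <- runif(1, 0.2, 0.8)
      m <- evaluate_metrics(y, s, cutoff)
      bf <- brute_force_confusion(y, s, cutoff)
      expect_equal(c(tp = m$tp, fp = m$fp, tn = m$tn, fn = m$fn), bf)
      expect_equal(m$precision, bf["tp"] / (bf["tp"] + bf["fp"]),
                   ignore_attr = TRUE)
      expect_equal(m$recall, bf["tp"] / (bf["tp"] + bf["fn"]),
                   ignore_attr = TRUE)
      expect_equal(m$accuracy, (bf["tp"] + bf["tn"]) / n, ignore_attr = TRUE)
      expect_equal(m$n, n)
    }
  })
})

test_that("rank-statistic AUC agrees with the pROC oracle", {
  skip_if_not_installed("pROC")
  withr::with_seed(33, {
    for (i in 1:10) {
      y <- rbinom(40, 1, 0.5)
      if (length(unique(y)) < 2) next
      s <- round(runif(40), 2)  # ties exercised via rounding
      ours <- evaluate_metrics(y, s)$roc_auc
      oracle <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                               direction = "<")))
      expect_equal(ours, oracle, tolerance = 1e-12)
    }
  })
})

test_that("AUC is 0.5 in expectation for uninformative scores and 1 for perfect", {
  withr::with_seed(5, {
    y <- rbinom(4000, 1, 0.5)
    s <- runif(4000)
    expect_equal(evaluate_metrics(y, s)$roc_auc, 0.5, tolerance = 0.05)
  })
  expect_equal(evaluate_metrics(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))$roc_auc, 1)
  expect_equal(evaluate_metrics(c(1, 1, 0, 0), c(0.1, 0.2, 0.8, 0.9))$roc_auc, 0)
})

test_that("undefined metrics come back NA with a classed warning", {
  expect_warning(m <- evaluate_metrics(c(0, 1), c(0.1, 0.2), cutoff = 0.9),
                 class = "amidescreen_undefined_metric")
  expect_true(is.na(m$precision))
  expect_warning(m2 <- evaluate_metrics(c(1, 1), c(0.2, 0.9)),
                 class = "amidescreen_undefined_metric")
  expect_true(is.na(m2$roc_auc))
  expect_error(evaluate_metrics(numeric(), numeric()),
               class = "amidescreen_empty_input")
  expect_error(evaluate_metrics(c(0, 2), c(0.1, 0.2)),
               class = "amidescreen_invalid_input")
})

test_that("the network separates two Gaussian blobs", {
  b <- make_blobs(n = 200, gap = 4, seed = 2)
  model <- train_classifier(b$X, b$y, quick_config())
  s <- predict_scores(model, b$X)
  expect_true(all(s >= 0 & s <= 1))
  expect_gte(mean((s >= 0.5) == (b$y == 1)), 0.95)
})

test_that("training and scoring are deterministic given the config seed", {
  b <- make_blobs(n = 80, seed = 3)
  m1 <- train_classifier(b$X, b$y, quick_config(seed = 9))
  m2 <- train_classifier(b$X, b$y, quick_config(seed = 9))
  expect_identical(predict_scores(m1, b$X), predict_scores(m2, b$X))
  m3 <- train_classifier(b$X, b$y, quick_config(seed = 10))
  expect_false(identical(predict_scores(m1, b$X), predict_scores(m3, b$X)))
})

test_that("duplicated feature rows receive identical scores", {
  b <- make_blobs(n = 60, seed = 4)
  model <- train_classifier(b$X, b$y, quick_config())
  X2 <- rbind(b$X[1, ], b$X[1, ])
  s <- predict_scores(model, X2)
  expect_equal(s[1], s[2])
})

test_that("degenerate training inputs are refused", {
  b <- make_blobs(n = 40, seed = 6)
  expect_error(train_classifier(b$X, rep(1L, nrow(b$X))),
               class = "amidescreen_degenerate_training")
  Xna <- b$X; Xna[1, 1] <- NA
  expect_error(train_classifier(Xna, b$y), class = "amidescreen_data_error")
  model <- train_classifier(b$X, b$y, quick_config())
  expect_error(predict_scores(model, b$X[, 1, drop = FALSE]),
               class = "amidescreen_incompatible_features")
  expect_error(model_config(n_hidden_layers = 4),
               class = "amidescreen_invalid_config")
  expect_error(model_config(dropout = 1), class = "amidescreen_invalid_config")
})

test_that("deeper configs are accepted and grow the parameter count", {
  b <- make_blobs(n = 60, seed = 7)
  cfg3 <- model_config(n_hidden_layers = 3, units = c(16, 8, 4), epochs = 5,
                       batch_size = 64, learning_rate = 5e-3)
  m <- train_classifier(b$X, b$y, cfg3)
  expect_length(predict_scores(m, b$X), nrow(b$X))
  expect_gt(mlp_param_count(2, c(16, 8, 4)), mlp_param_count(2, 16))
  # hand count for a 2-16-1 net: 2*16+16 weightsbias + 16*1+1 output
  expect_equal(mlp_param_count(2, 16), (2 * 16 + 16) + (16 + 1))
})

test_that("nnet cross-check: both learners solve the same separable problem", {
  skip_if_not_installed("nnet")
  b <- make_blobs(n = 150, gap = 5, seed = 8)
  ours <- predict_scores(train_classifier(b$X, b$y, quick_config()), b$X)
  ref <- withr::with_seed(1, nnet::nnet(b$X, b$y, size = 4, decay = 1e-4,
                                        maxit = 200, trace = FALSE))
  ref_s <- as.numeric(stats::predict(ref, b$X))
  expect_gte(mean((ours >= 0.5) == (b$y == 1)), 0.95)
  expect_gte(mean((ref_s >= 0.5) == (b$y == 1)), 0.95)
  # the two learners agree on nearly every point of a separable problem
  expect_gte(mean((ours >= 0.5) == (ref_s >= 0.5)), 0.95)
})

test_that("label shuffling preserves counts, is deterministic, and breaks order", {
  y <- c(rep(1L, 30), rep(0L, 70))
  s1 <- shuffle_labels(y, seed = 4)
  expect_equal(sum(s1), sum(y))
  expect_equal(length(s1), length(y))
  expect_identical(s1, shuffle_labels(y, seed = 4))
  expect_false(identical(s1, y))
  # expected fixed-point fraction of a random permutation of a 30/70 vector
  # is 0.3^2 + 0.7^2 = 0.58; check the mean over seeds sits near it
  fps <- vapply(1:50, function(sd) mean(shuffle_labels(y, sd) == y), 0)
  expect_equal(mean(fps), 0.58, tolerance = 0.05)
})

test_that("hyperparameter tuning returns the sane config over a broken one", {
  b <- make_blobs(n = 120, gap = 4, seed = 12)
  space <- list(n_hidden_layers = 1L, units = 16L, dropout = 0,
                learning_rate_range = c(5e-3, 5e-3),
                epochs = c(0L, 40L), batch_size = 64L)
  tuned <- tune_hyperparameters(b$X, b$y, space, budget = 6, seed = 2)
  expect_equal(tuned$best_config$epochs, 40L)
  expect_gte(tuned$best_accuracy, 0.9)
  expect_equal(nrow(tuned$trials), 6)
  expect_error(tune_hyperparameters(b$X, b$y, budget = 0),
               class = "amidescreen_invalid_budget")
})

test_that("a budget of one trains exactly one configuration", {
  b <- make_blobs(n = 80, seed = 13)
  tuned <- tune_hyperparameters(b$X, b$y, quick_space(), budget = 1, seed = 3)
  expect_equal(nrow(tuned$trials), 1)
  expect_s3_class(tuned$best_config, "model_config")
})

test_that("tidy and glance expose the classifier in broom shape", {
  b <- make_blobs(n = 60, seed = 14)
  m <- train_classifier(b$X, b$y, quick_config(), feature_set = "blobs")
  td <- tidy(m)
  gl <- glance(m)
  expect_s3_class(td, "tbl_df")
  expect_s3_class(gl, "tbl_df")
  expect_equal(nrow(gl), 1)
  expect_true(all(c("n_params", "n_train") %in% names(gl)))
  expect_output(print(m), "trained_classifier")
})
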