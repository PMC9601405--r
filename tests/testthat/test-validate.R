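# a labelled campaign shared across the protocol tests
labelled_campaign <- function(seed = 2, n_points = 9) {
  syn <- generate_library(synthetic_config(seed = seed),
                          grid = build_condition_grid(n_points))
  list(d = label_outcomes(syn$dataset), reagents = syn$reagents)
}

test_that("random splits are stratified 60/40 within one record per class", {
  d <- labelled_campaign()$d
  dn <- d[d$label != "missing", ]
  y <- dn$label == "successful"
  plan <- make_random_splits(d, n_splits = 3, seed = 5)
  expect_equal(nrow(plan), 3)
  for (i in 1:3) {
    tr <- plan$train_idx[[i]]; te <- plan$test_idx[[i]]
    expect_length(intersect(tr, te), 0)
    expect_setequal(c(tr, te), seq_len(nrow(dn)))
    for (cls in c(TRUE, FALSE)) {
      idx <- which(y == cls)
      expect_equal(sum(tr %in% idx), round(0.6 * length(idx)))
    }
  }
  expect_identical(make_random_splits(d, seed = 5)$train_idx,
                   plan$train_idx)
  expect_false(identical(make_random_splits(d, seed = 6)$train_idx[[1]],
                         plan$train_idx[[1]]))
  expect_error(make_random_splits(d, train_frac = 1),
               class = "amidescreen_invalid_split")
})

test_that("leave-one-amine-out test sets partition the records", {
  d <- labelled_campaign()$d
  dn <- d[d$label != "missing", ]
  plan <- make_loao_splits(d)
  expect_equal(nrow(plan), 5)
  tests <- unlist(plan$test_idx)
  expect_setequal(tests, seq_len(nrow(dn)))
  expect_equal(length(tests), nrow(dn))  # no overlap
  for (i in seq_len(nrow(plan))) {
    am <- plan$held_out_amine[i]
    expect_true(all(dn$amine_id[plan$test_idx[[i]]] == am))
    expect_true(all(dn$amine_id[plan$train_idx[[i]]] != am))
  }
  one <- d[d$amine_id == "B1", ]
  expect_error(make_loao_splits(one), class = "amidescreen_too_few_amines")
})

test_that("the protocol trains 16 models per feature set: 8 true + 8 shuffled", {
  lc <- labelled_campaign()
  spec <- feature_set_spec("cond", "conditions")
  ledger <- run_cv_protocol(lc$d, list(cond = spec), budget = 1,
                            seed = 11, search_space = quick_space())
  expect_s3_class(ledger, "model_ledger")
  expect_equal(nrow(ledger), 16)
  expect_equal(sum(ledger$label_mode == "true"), 8)
  expect_equal(sum(ledger$label_mode == "shuffled"), 8)
  expect_equal(sum(ledger$kind == "random_60_40"), 6)
  expect_equal(sum(ledger$kind == "leave_one_amine_out"), 10)
  expect_setequal(na.omit(unique(ledger$held_out_amine)), paste0("B", 1:5))
  # the synthetic campaign has real condition signal: the true models beat
  # their shuffled twins decisively on the hold-on AUC
  expect_gt(mean(ledger$roc_auc[ledger$label_mode == "true"]), 0.7)
  expect_lt(abs(mean(ledger$roc_auc[ledger$label_mode == "shuffled"]) - 0.5),
            0.15)
  best <- select_best_model(ledger)
  expect_equal(best$feature_set, "cond")
  expect_s3_class(best$config, "model_config")

  # the temporal campaign must never enter selection
  two <- lc$d
  two$campaign_id[1:10] <- "campaign_2"
  expect_error(run_cv_protocol(two, list(cond = spec), budget = 1,
                               search_space = quick_space()),
               class = "amidescreen_leakage")
})

fake_ledger <- function(df) {
  df$config <- purrr::map(seq_len(nrow(df)), ~quick_config())
  structure(df, class = c("model_ledger", class(df)))
}

test_that("model selection ranks by precision, then AUC, then feature width", {
  base <- tidyr::expand_grid(feature_set = c("fsA", "fsB", "fsC"),
                             label_mode = c("true", "shuffled"))
  led <- fake_ledger(dplyr::mutate(base,
    precision = dplyr::case_when(
      label_mode == "shuffled" ~ 0.4,
      feature_set == "fsA" ~ 0.9, feature_set == "fsB" ~ 0.9, TRUE ~ 0.7),
    recall = 0.5, accuracy = 0.5,
    roc_auc = dplyr::case_when(
      label_mode == "shuffled" ~ 0.5,
      feature_set == "fsA" ~ 0.80, feature_set == "fsB" ~ 0.95, TRUE ~ 0.99),
    n_features = 10))
  expect_equal(select_best_model(led)$feature_set, "fsB")  # AUC breaks the tie
  led2 <- fake_ledger(dplyr::mutate(base,
    precision = ifelse(label_mode == "shuffled", 0.4, 0.9),
    recall = 0.5, accuracy = 0.5, roc_auc = ifelse(label_mode == "shuffled", 0.5, 0.9),
    n_features = dplyr::case_when(feature_set == "fsA" ~ 50,
                                  feature_set == "fsB" ~ 20, TRUE ~ 90)))
  expect_equal(select_best_model(led2)$feature_set, "fsB")  # narrowest wins
  led3 <- fake_ledger(dplyr::mutate(base,
    precision = ifelse(label_mode == "shuffled", 0.6, 0.5),
    recall = 0.5, accuracy = 0.5, roc_auc = 0.5, n_features = 10))
  expect_error(select_best_model(led3), class = "amidescreen_no_signal")
})

test_that("temporal evaluation scores an unseen campaign and guards leakage", {
  cfg <- synthetic_config(seed = 3)
  first <- generate_library(cfg)
  second <- generate_library(cfg, grid = build_condition_grid(9)[c(4, 9), ],
                             campaign_id = "campaign_2",
                             acid_ids = paste0("A", 1:6),
                             amine_ids = paste0("B", 1:5))
  d1 <- label_outcomes(first$dataset)
  d2 <- label_outcomes(second$dataset)
  spec <- feature_set_spec("cond", "conditions")
  vocab <- condition_vocabulary(d1)
  fx <- assemble_features(d1, spec, vocab = vocab)
  model <- train_classifier(fx$X, fx$y, quick_config(),
                            feature_set = "cond",
                            standardizer = fx$standardizer,
                            campaign_ids = d1$campaign_id)
  ev <- evaluate_temporal(model, d2, spec, vocab = vocab)
  expect_equal(nrow(ev$scores), sum(d2$label != "missing"))
  expect_true(all(ev$scores$score >= 0 & ev$scores$score <= 1))
  expect_equal(ev$metrics$n, nrow(ev$scores))
  # condition signal transfers across campaigns built from one ground truth
  expect_gt(ev$metrics$roc_auc, 0.65)
  expect_error(evaluate_temporal(model, d1, spec, vocab = vocab),
               class = "amidescreen_leakage")
})

test_that("prioritization tallies match a hand-worked six-experiment table", {
  scores <- c(0.9, 0.2, 0.85, 0.4, 0.6, 0.1)
  labels <- c(1, 0, 1, 0, 0, 1)
  prods <- c("P1", "P1", "P2", "P2", "P3", "P3")
  tab <- prioritization_analysis(scores, labels, prods,
                                 thresholds = c(0, 0.5))
  t0 <- tab[tab$selector == "score>=0.0", ]
  expect_equal(unlist(t0[, c("n_experiments", "n_success", "n_fail",
                             "n_products_success", "n_products_fail")]),
               c(n_experiments = 6, n_success = 3, n_fail = 3,
                 n_products_success = 3, n_products_fail = 0))
  t5 <- tab[tab$selector == "score>=0.5", ]
  expect_equal(unlist(t5[, c("n_experiments", "n_success", "n_fail",
                             "n_products_success", "n_products_fail")]),
               c(n_experiments = 3, n_success = 2, n_fail = 1,
                 n_products_success = 2, n_products_fail = 1))
  hp <- tab[tab$selector == "highest_score_per_product", ]
  expect_equal(hp$n_experiments, 3)  # exactly one per product
  expect_equal(hp$n_success, 2)
  expect_equal(hp$n_products_fail, 1)
})

test_that("prioritization counts are monotone non-increasing in the threshold", {
  withr::with_seed(17, {
    for (i in 1:5) {
      n <- 100
      scores <- runif(n); labels <- rbinom(n, 1, 0.5)
      prods <- sample(paste0("P", 1:20), n, TRUE)
      tab <- prioritization_analysis(scores, labels, prods,
                                     thresholds = seq(0, 0.9, by = 0.1),
                                     highest_per_product = FALSE)
      expect_true(all(diff(tab$n_experiments) <= 0))
      expect_true(all(diff(tab$n_success) <= 0))
      expect_true(all(diff(tab$n_products_success) <= 0))
      expect_equal(tab$n_experiments[1], n)  # threshold 0, inclusive
      expect_equal(tab$n_experiments, tab$n_success + tab$n_fail)
    }
  })
})

test_that("the highest-score selector breaks ties deterministically", {
  scores <- c(0.7, 0.7, 0.7)
  labels <- c(1, 0, 0)
  prods <- rep("P1", 3)
  # harsher condition wins the score tie
  tab <- prioritization_analysis(scores, labels, prods, thresholds = numeric(),
                                 harshness_rank = c(1, 3, 2),
                                 agent_id = c("CA1", "CA2", "CA3"))
  expect_equal(tab$n_experiments, 1)
  expect_equal(tab$n_success, 0)  # row 2 (rank 3) was picked, a failure
  # equal rank: lexicographically first agent wins
  tab2 <- prioritization_analysis(scores, labels, prods, thresholds = numeric(),
                                  harshness_rank = c(2, 2, 2),
                                  agent_id = c("CA9", "CA1", "CA5"))
  expect_equal(tab2$n_success, 0)  # row 2 again, agent CA1
  # strict thresholds drop the boundary scores
  strict <- prioritization_analysis(scores, labels, prods, thresholds = 0.7,
                                    highest_per_product = FALSE,
                                    inclusive = FALSE)
  expect_equal(strict$n_experiments, 0)
})

test_that("autoplot produces a ggplot without evaluation errors", {
  tab <- prioritization_analysis(c(0.9, 0.1), c(1, 0), c("P1", "P2"))
  p <- ggplot2::autoplot(tab)
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  expect_gt(nrow(built$data[[1]]), 0)
})
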