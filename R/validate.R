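# dual cross-validation, shuffled-label twins, model selection, temporal
# evaluation and score-guided prioritization.

derive_seed <- function(seed, ...) {
  k <- c(...)
  as.integer((abs(seed) * 48271 + sum(k * 2654435761)) %% 2147483629)
}

nonmissing <- function(dataset) {
  check_labelled(dataset)
  filter(dataset, .data$label != "missing")
}

#' Random stratified train/test splits
#'
#' Splits the non-missing records of a labelled dataset into outer-training
#' and hold-on test sets (default 60/40), stratified by outcome label so both
#' classes appear on each side. Per class, the training count is
#' `round(train_frac * n_class)`, so the overall training share is within one
#' record of `train_frac`.
#'
#' @param dataset A labelled dataset.
#' @param n_splits Number of random splits; default 3.
#' @param train_frac Training fraction in (0, 1); default 0.6.
#' @param seed Integer seed; identical seeds give identical splits.
#' @return A `split_plan` tibble: `split_id`, `kind`, `held_out_amine`
#'   (`NA` here), and list-columns `train_idx` / `test_idx` of row indices
#'   into the non-missing records (in dataset order).
#' @export
make_random_splits <- function(dataset, n_splits = 3, train_frac = 0.6, seed = 1) {
  d <- nonmissing(dataset)
  if (nrow(d) < 10) abort("Need at least 10 non-missing records.",
                          class = "amidescreen_too_few_records")
  if (train_frac <= 0 || train_frac >= 1) {
    abort("`train_frac` must be in (0, 1).", class = "amidescreen_invalid_split")
  }
  y <- d$label == "successful"
  if (min(sum(y), sum(!y)) < 2) {
    abort("Too few records in one class to stratify.",
          class = "amidescreen_too_few_records")
  }
  rows <- purrr::map(seq_len(n_splits), function(s) {
    withr::with_seed(derive_seed(seed, 11, s), {
      train <- integer()
      for (cls in c(TRUE, FALSE)) {
        idx <- which(y == cls)
        train <- c(train, sample(idx, round(train_frac * length(idx))))
      }
      train <- sort(train)
      tibble(split_id = paste0("random_", s), kind = "random_60_40",
             held_out_amine = NA_character_,
             train_idx = list(train),
             test_idx = list(setdiff(seq_len(nrow(d)), train)))
    })
  })
  out <- bind_rows(rows)
  attr(out, "seed") <- seed
  class(out) <- c("split_plan", class(out))
  out
}

#' Leave-one-amine-out splits
#'
#' One split per amine: all of that amine's experiments form the hold-on test
#' set and the other amines' experiments the training set. This probes
#' generalisation to unseen nucleophiles, the hard case for a small library.
#'
#' @param dataset A labelled dataset.
#' @return A `split_plan` tibble; the union of test sets partitions the
#'   non-missing records.
#' @export
make_loao_splits <- function(dataset) {
  d <- nonmissing(dataset)
  amines <- sort(unique(d$amine_id))
  if (length(amines) < 2) abort("Need at least 2 amines for leave-one-amine-out.",
                                class = "amidescreen_too_few_amines")
  out <- bind_rows(purrr::map(amines, function(am) {
    te <- which(d$amine_id == am)
    tibble(split_id = paste0("loao_", am), kind = "leave_one_amine_out",
           held_out_amine = am,
           train_idx = list(setdiff(seq_len(nrow(d)), te)), test_idx = list(te))
  }))
  class(out) <- c("split_plan", class(out))
  out
}

#' Run the dual cross-validation model-selection protocol
#'
#' For every feature set and every split (3 random 60/40 + one
#' leave-one-amine-out per amine), tunes hyperparameters by inner stratified
#' k-fold cross-validation on the outer-training set, trains the best
#' configuration, and evaluates it on the hold-on test set - once with the
#' true labels and once with a shuffled-label twin that goes through the
#' identical tuning. With 5 amines this yields 16 entries per feature set
#' (8 true + 8 shuffled). Property standardizers are fitted on the training
#' side of each split only; the condition vocabulary is fixed from the full
#' campaign so widths agree across splits. Datasets spanning more than one
#' campaign are refused: the temporal campaign must never enter selection.
#'
#' @param dataset A labelled single-campaign dataset.
#' @param feature_specs Named list of [feature_set_spec()]s (e.g. a subset of
#'   [feature_set_registry()]).
#' @param reagents,properties Passed to [assemble_features()] as needed.
#' @param budget Tuning trials per model; default 8.
#' @param inner_k Inner folds; default 3.
#' @param seed Master seed; every stochastic element (splits, trial sampling,
#'   weight init, label shuffling) derives from it.
#' @param search_space See [default_search_space()].
#' @return A `model_ledger` tibble: one row per (feature set, split, label
#'   mode) with hold-on `precision`, `recall`, `accuracy`, `roc_auc`, the
#'   inner-CV accuracy, the feature width and the chosen config (list-column).
#' @export
run_cv_protocol <- function(dataset, feature_specs, reagents = NULL,
                            properties = NULL, budget = 8, inner_k = 3,
                            seed = 1, search_space = default_search_space()) {
  d <- nonmissing(dataset)
  if ("campaign_id" %in% names(d) && dplyr::n_distinct(d$campaign_id) > 1) {
    abort("Dataset spans multiple campaigns; temporal data must not enter model selection.",
          class = "amidescreen_leakage")
  }
  if (inherits(feature_specs, "feature_set_spec")) feature_specs <- list(feature_specs)
  vocab <- condition_vocabulary(d)
  splits <- bind_rows(make_random_splits(d, seed = derive_seed(seed, 1)),
                      make_loao_splits(d))
  rows <- list()
  for (spec in feature_specs) {
    for (si in seq_len(nrow(splits))) {
      tr_rows <- d[splits$train_idx[[si]], , drop = FALSE]
      te_rows <- d[splits$test_idx[[si]], , drop = FALSE]
      tr <- assemble_features(tr_rows, spec, reagents, properties, vocab = vocab)
      te <- assemble_features(te_rows, spec, reagents, properties,
                              vocab = vocab, standardizer = tr$standardizer)
      for (mode in c("true", "shuffled")) {
        sd_i <- derive_seed(seed, si, match(mode, c("true", "shuffled")),
                            match(spec$name, names(feature_specs) %||% spec$name,
                                  nomatch = 1L))
        y_tr <- tr$y
        if (mode == "shuffled") y_tr <- shuffle_labels(y_tr, seed = sd_i)
        tuned <- tune_hyperparameters(tr$X, y_tr, search_space = search_space,
                                      budget = budget, inner_k = inner_k,
                                      seed = sd_i)
        model <- train_classifier(tr$X, y_tr, tuned$best_config,
                                  feature_set = spec$name,
                                  standardizer = tr$standardizer)
        m <- withCallingHandlers(
          evaluate_metrics(te$y, predict_scores(model, te$X)),
          warning = function(w) {
            if (inherits(w, "amidescreen_undefined_metric"))
              invokeRestart("muffleWarning")
          })
        rows[[length(rows) + 1]] <- tibble(
          feature_set = spec$name, split_id = splits$split_id[si],
          kind = splits$kind[si], held_out_amine = splits$held_out_amine[si],
          label_mode = mode, inner_accuracy = tuned$best_accuracy,
          precision = m$precision, recall = m$recall, accuracy = m$accuracy,
          roc_auc = m$roc_auc, n_features = ncol(tr$X),
          n_train = nrow(tr$X), n_test = nrow(te$X),
          config = list(tuned$best_config))
      }
    }
  }
  out <- bind_rows(rows)
  attr(out, "seed") <- seed
  class(out) <- c("model_ledger", class(out))
  out
}

config_signature <- function(cfg) {
  paste(cfg$n_hidden_layers, paste(cfg$units, collapse = "x"), cfg$dropout,
        signif(cfg$learning_rate, 3), cfg$epochs, cfg$batch_size, sep = "|")
}

#' Select the best feature set and configuration from a CV ledger
#'
#' Feature sets are ranked by the mean hold-on precision of their true-label
#' models (precision is preferred over recall: the goal is to maximise the
#' share of attempted experiments that succeed). Ties are broken by mean ROC
#' AUC, then by smaller feature width. The winner must beat the mean
#' precision of its own shuffled-label twins; if no feature set beats its
#' null, a no-signal error is raised. The returned configuration is the modal
#' best config among the winner's true-label entries.
#'
#' @param ledger A `model_ledger` from [run_cv_protocol()].
#' @return A list: `feature_set`, `config`, and `ranking` (per-feature-set
#'   mean metrics).
#' @export
select_best_model <- function(ledger) {
  stopifnot(inherits(ledger, "model_ledger"))
  ranking <- ledger |>
    group_by(.data$feature_set, .data$label_mode) |>
    summarise(precision = mean(.data$precision, na.rm = TRUE),
              roc_auc = mean(.data$roc_auc, na.rm = TRUE),
              n_features = .data$n_features[1], .groups = "drop") |>
    tidyr::pivot_wider(names_from = "label_mode",
                       values_from = c("precision", "roc_auc")) |>
    arrange(dplyr::desc(.data$precision_true), dplyr::desc(.data$roc_auc_true),
            .data$n_features)
  beats <- ranking |> filter(.data$precision_true > .data$precision_shuffled)
  if (nrow(beats) == 0) {
    abort("No feature set beats its shuffled-label null on precision.",
          class = "amidescreen_no_signal")
  }
  winner <- beats$feature_set[1]
  cfgs <- ledger |> filter(.data$feature_set == winner, .data$label_mode == "true")
  sigs <- vapply(cfgs$config, config_signature, "")
  modal <- names(sort(table(sigs), decreasing = TRUE))[1]
  list(feature_set = winner, config = cfgs$config[[which(sigs == modal)[1]]],
       ranking = ranking)
}

#' Evaluate the final model on the temporal (held-out campaign) test set
#'
#' Scores every non-missing record of a later campaign with a model trained
#' on an earlier one and reports the metric suite. The model's recorded
#' training campaigns are checked against the temporal dataset's; any overlap
#' raises a leakage error - the temporal set must play no part in training,
#' tuning, standardization or selection.
#'
#' @param model A [train_classifier()] fit carrying its training campaigns.
#' @param temporal_dataset A labelled dataset from the unseen campaign.
#' @param spec The winning [feature_set_spec()].
#' @param reagents,properties Passed to [assemble_features()].
#' @param vocab The condition vocabulary fixed before modelling (it must span
#'   both campaigns' levels).
#' @return A list: `metrics` (one-row tibble) and `scores` (per-experiment
#'   tibble with `score`, `label01` and `product_id`).
#' @export
evaluate_temporal <- function(model, temporal_dataset, spec, reagents = NULL,
                              properties = NULL,
                              vocab = condition_vocabulary(temporal_dataset)) {
  stopifnot(inherits(model, "trained_classifier"))
  d <- nonmissing(temporal_dataset)
  camps <- unique(as.character(d$campaign_id %||% "temporal"))
  if (length(model$campaign_ids) && any(camps %in% model$campaign_ids)) {
    abort("Temporal dataset overlaps the model's training campaigns.",
          class = "amidescreen_leakage")
  }
  fx <- assemble_features(d, spec, reagents, properties, vocab = vocab,
                          standardizer = model$standardizer)
  scores <- predict_scores(model, fx$X)
  list(metrics = evaluate_metrics(fx$y, scores),
       scores = dplyr::bind_cols(fx$row_keys,
                                 tibble(product_id = paste(fx$row_keys$acid_id,
                                                           fx$row_keys$amine_id,
                                                           sep = "."),
                                        score = scores, label01 = fx$y)))
}

#' Score-threshold experiment prioritization
#'
#' Mirrors the "which experiments would the model have told us to run"
#' analysis: for each score threshold t, the experiments with score >= t are
#' selected (the comparison is inclusive; set `inclusive = FALSE` for strict)
#' and tallied - selected experiments, experimental successes and failures
#' among them, unique products with at least one selected success, and unique
#' products that were selected but never succeeded among the selected
#' experiments. The `highest_score_per_product` selector instead picks exactly
#' one experiment per product: its maximum-score experiment, ties broken by
#' harsher condition first and then lexicographic coupling-agent id.
#'
#' @param scores Classifier scores.
#' @param labels Binary outcomes (1 = experimental success).
#' @param product_ids Product identifier per experiment.
#' @param thresholds Score thresholds; default 0, 0.3, ..., 0.9.
#' @param highest_per_product Include the highest-score-per-product row.
#' @param harshness_rank,agent_id Optional vectors used for deterministic
#'   tie-breaking in the highest-score selector.
#' @param inclusive Use score >= t (default) or strict >.
#' @return A `prioritization` tibble: `selector`, `n_experiments`,
#'   `n_success`, `n_fail`, `n_products_success`, `n_products_fail`.
#' @export
prioritization_analysis <- function(scores, labels, product_ids,
                                    thresholds = c(0, 0.3, 0.5, 0.8, 0.9),
                                    highest_per_product = TRUE,
                                    harshness_rank = NULL, agent_id = NULL,
                                    inclusive = TRUE) {
  n <- length(scores)
  stopifnot(length(labels) == n, length(product_ids) == n)
  labels <- as.integer(labels)
  tally <- function(sel, selector) {
    s <- labels[sel] == 1
    prods_succ <- unique(product_ids[sel][s])
    prods_all <- unique(product_ids[sel])
    tibble(selector = selector, n_experiments = sum(sel),
           n_success = sum(s), n_fail = sum(!s),
           n_products_success = length(prods_succ),
           n_products_fail = length(setdiff(prods_all, prods_succ)))
  }
  rows <- purrr::map(thresholds, function(t) {
    sel <- if (inclusive) scores >= t else scores > t
    tally(sel, sprintf("score>=%.1f", t))
  })
  if (highest_per_product) {
    ord <- order(product_ids, -scores,
                 if (!is.null(harshness_rank)) -harshness_rank else seq_len(n),
                 if (!is.null(agent_id)) agent_id else rep("", n))
    first <- ord[!duplicated(product_ids[ord])]
    sel <- rep(FALSE, n); sel[first] <- TRUE
    rows <- c(list(tally(sel, "highest_score_per_product")), rows)
  }
  out <- bind_rows(rows)
  class(out) <- c("prioritization", class(out))
  out
}

#' Plot a prioritization table
#'
#' Grouped bars per selector: failed/successful experiment counts and
#' failed/successful unique-product counts.
#'
#' @param object A `prioritization` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot prioritization
#' @export
autoplot.prioritization <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(c("n_fail", "n_success", "n_products_fail",
                          "n_products_success"),
                        names_to = "quantity", values_to = "count") |>
    mutate(selector = factor(.data$selector, levels = unique(object$selector)),
           quantity = factor(.data$quantity,
                             levels = c("n_fail", "n_success",
                                        "n_products_fail", "n_products_success"),
                             labels = c("experiments failed",
                                        "experiments succeeded",
                                        "products failed",
                                        "products succeeded")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$selector, y = .data$count,
                                     fill = .data$quantity)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::scale_fill_manual(values = c("firebrick3", "steelblue3",
                                          "goldenrod2", "springgreen4"),
                               name = NULL) +
    ggplot2::labs(x = NULL, y = "count") +
    ggplot2::theme_minimal(base_size = 10) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
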