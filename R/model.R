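#' Configure the feed-forward outcome classifier
#'
#' The outcome model is a small feed-forward network with 1-3 hidden ReLU
#' layers and a sigmoid output emitting a success score in \[0, 1\].
#'
#' @param n_hidden_layers Number of hidden layers, 1-3.
#' @param units Hidden units per layer; recycled to `n_hidden_layers`.
#' @param dropout Dropout rate in \[0, 1).
#' @param learning_rate Adam learning rate (> 0).
#' @param epochs Training epochs (>= 0; 0 leaves the network at its random
#'   initialisation).
#' @param batch_size Minibatch size (>= 1).
#' @param seed Integer seed controlling weight initialisation, shuffling and
#'   dropout masks.
#' @return A `model_config` list.
#' @export
model_config <- function(n_hidden_layers = 1, units = 32, dropout = 0,
                         learning_rate = 1e-3, epochs = 50, batch_size = 32,
                         seed = 1) {
  if (!n_hidden_layers %in% 1:3) {
    abort("`n_hidden_layers` must be 1, 2 or 3.", class = "amidescreen_invalid_config")
  }
  if (dropout < 0 || dropout >= 1) {
    abort("`dropout` must be in [0, 1).", class = "amidescreen_invalid_config")
  }
  if (learning_rate <= 0 || epochs < 0 || batch_size < 1) {
    abort("Invalid learning rate, epochs or batch size.",
          class = "amidescreen_invalid_config")
  }
  units <- rep_len(as.integer(units), n_hidden_layers)
  structure(list(n_hidden_layers = as.integer(n_hidden_layers), units = units,
                 dropout = dropout, learning_rate = learning_rate,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Train the outcome classifier
#'
#' Fits the feed-forward network on a feature matrix and binary label vector.
#' Training is deterministic given the config's seed. The returned object
#' carries a fingerprint of its training data (hash and size) plus the
#' campaigns it was trained on, so that later evaluation can refuse data that
#' leaked into training.
#'
#' @param X Numeric feature matrix (no missing values).
#' @param y Binary labels (0/1), both classes present.
#' @param config A [model_config()].
#' @param feature_set Name of the feature set that produced `X`.
#' @param standardizer The standardizer fitted during [assemble_features()],
#'   kept for reuse on new data.
#' @param campaign_ids Campaign identifiers of the training records.
#' @return A `trained_classifier`.
#' @export
train_classifier <- function(X, y, config = model_config(),
                             feature_set = NA_character_,
                             standardizer = NULL, campaign_ids = NULL) {
  stopifnot(inherits(config, "model_config"))
  X <- as.matrix(X)
  if (nrow(X) != length(y) || nrow(X) < 2) {
    abort("`X` and `y` must align, with at least 2 rows.",
          class = "amidescreen_invalid_training")
  }
  if (anyNA(X) || anyNA(y)) {
    abort("Missing values in the training data.", class = "amidescreen_data_error")
  }
  if (length(unique(y)) < 2) {
    abort("Training labels contain a single class.",
          class = "amidescreen_degenerate_training")
  }
  fit <- mlp_fit(X, y, hidden = config$units, dropout = config$dropout,
                 learning_rate = config$learning_rate, epochs = config$epochs,
                 batch_size = config$batch_size, seed = config$seed)
  structure(list(fit = fit, config = config, feature_set = feature_set,
                 standardizer = standardizer,
                 training_fingerprint = list(hash = rlang::hash(list(X, y)),
                                             n = nrow(X)),
                 campaign_ids = sort(unique(as.character(campaign_ids %||% character())))),
            class = "trained_classifier")
}

#' Score experiments with a trained classifier
#'
#' @param model A [train_classifier()] fit.
#' @param X Feature matrix with the model's feature width.
#' @return Numeric scores in \[0, 1\], one per row.
#' @export
predict_scores <- function(model, X) {
  stopifnot(inherits(model, "trained_classifier"))
  mlp_predict(model$fit, X)
}

#' Classification metrics at a score cutoff
#'
#' Confusion counts at the cutoff (score >= cutoff predicts success) plus
#' precision = TP/(TP+FP), recall = TP/(TP+FN), accuracy = (TP+TN)/n, and the
#' ROC AUC computed cutoff-free by the Mann-Whitney rank statistic (mid-ranks
#' for ties). Precision is `NA` when nothing is predicted positive; AUC is
#' `NA` when only one class is present - both flagged with a warning rather
#' than silently zeroed.
#'
#' @param y_true Binary labels (0/1).
#' @param scores Classifier scores in \[0, 1\].
#' @param cutoff Score cutoff; default 0.5.
#' @return A one-row tibble: `tp`, `fp`, `tn`, `fn`, `precision`, `recall`,
#'   `accuracy`, `roc_auc`, `cutoff`, `n`.
#' @examples
#' evaluate_metrics(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1))
#' @export
evaluate_metrics <- function(y_true, scores, cutoff = 0.5) {
  if (length(y_true) == 0) abort("Empty input.", class = "amidescreen_empty_input")
  if (length(y_true) != length(scores)) {
    abort("`y_true` and `scores` must have equal length.",
          class = "amidescreen_invalid_input")
  }
  y <- as.integer(y_true)
  if (!all(y %in% c(0L, 1L))) abort("`y_true` must be binary 0/1.",
                                    class = "amidescreen_invalid_input")
  pred <- as.integer(scores >= cutoff)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  if (is.na(precision)) warn("No positive predictions: precision undefined.",
                             class = "amidescreen_undefined_metric")
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    warn("Single-class labels: ROC AUC undefined.",
         class = "amidescreen_undefined_metric")
    auc <- NA_real_
  } else {
    r <- rank(scores)
    auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  tibble(tp = tp, fp = fp, tn = tn, fn = fn,
         precision = precision, recall = recall,
         accuracy = (tp + tn) / length(y), roc_auc = auc,
         cutoff = cutoff, n = length(y))
}

#' Permute outcome labels for a null model
#'
#' Deterministically permutes the label vector, preserving the class counts.
#' Models trained on shuffled labels establish the chance-level baseline that
#' any real model must beat.
#'
#' @param y Label vector.
#' @param seed Integer seed.
#' @return The permuted vector.
#' @export
shuffle_labels <- function(y, seed = 1) {
  if (length(y) == 0) abort("`y` is empty.", class = "amidescreen_empty_input")
  withr::with_seed(as.integer(seed) %% .Machine$integer.max,
                   y[sample.int(length(y))])
}

#' Default hyperparameter search space
#'
#' Layers 1-3; units 16/32/64/128; dropout 0/0.2/0.5; learning rate
#' log-uniform on \[1e-4, 1e-2\]; epochs 20/50/100; batch size 16/32/64.
#'
#' @return A list understood by [tune_hyperparameters()].
#' @export
default_search_space <- function() {
  list(n_hidden_layers = 1:3, units = c(16L, 32L, 64L, 128L),
       dropout = c(0, 0.2, 0.5), learning_rate_range = c(1e-4, 1e-2),
       epochs = c(20L, 50L, 100L), batch_size = c(16L, 32L, 64L))
}

sample_config <- function(space, seed) {
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    L <- sample(space$n_hidden_layers, 1)
    lr <- if (!is.null(space$learning_rate_range)) {
      exp(runif(1, log(space$learning_rate_range[1]),
                log(space$learning_rate_range[2])))
    } else sample(space$learning_rate, 1)
    model_config(n_hidden_layers = L,
                 units = sample(space$units, L, replace = TRUE),
                 dropout = sample(space$dropout, 1),
                 learning_rate = lr,
                 epochs = sample(space$epochs, 1),
                 batch_size = sample(space$batch_size, 1),
                 seed = seed)
  })
}

stratified_fold_ids <- function(y, k, seed) {
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    ids <- integer(length(y))
    for (cls in unique(y)) {
      rows <- which(y == cls)
      ids[rows] <- sample(rep_len(seq_len(k), length(rows)))
    }
    ids
  })
}

#' Hyperparameter search with inner stratified k-fold cross-validation
#'
#' Randomly samples `budget` configurations from the search space and scores
#' each by its mean inner-fold binary accuracy at cutoff 0.5 (classes in these
#' screens are roughly balanced, so plain accuracy is an adequate selection
#' metric). Inner folds are stratified by label and shared across trials.
#' Ties are broken by smaller parameter count, then by earlier trial. If a
#' fold ends up single-class the data are refolded with a fresh seed, erroring
#' after three attempts.
#'
#' @param X,y Training features and binary labels.
#' @param search_space See [default_search_space()].
#' @param budget Number of sampled configurations (>= 1).
#' @param inner_k Number of inner folds; default 3.
#' @param seed Master seed for sampling and folding.
#' @return A list: `best_config` (a [model_config()]), `best_accuracy`, and
#'   `trials` (a tibble logging every trial's config summary and accuracy).
#' @export
tune_hyperparameters <- function(X, y, search_space = default_search_space(),
                                 budget = 20, inner_k = 3, seed = 1) {
  if (budget < 1) abort("`budget` must be >= 1.", class = "amidescreen_invalid_budget")
  X <- as.matrix(X)
  folds <- NULL
  for (attempt in 1:3) {
    cand <- stratified_fold_ids(y, inner_k, seed + 7919 * attempt)
    ok <- all(vapply(seq_len(inner_k),
                     function(f) length(unique(y[cand != f])) == 2, TRUE))
    if (ok) { folds <- cand; break }
  }
  if (is.null(folds)) {
    abort("Could not build inner folds with both classes after 3 attempts.",
          class = "amidescreen_degenerate_fold")
  }
  trials <- vector("list", budget)
  for (t in seq_len(budget)) {
    cfg <- sample_config(search_space, seed + 104729 * t)
    accs <- vapply(seq_len(inner_k), function(f) {
      tr <- folds != f
      fit <- mlp_fit(X[tr, , drop = FALSE], y[tr], hidden = cfg$units,
                     dropout = cfg$dropout, learning_rate = cfg$learning_rate,
                     epochs = cfg$epochs, batch_size = cfg$batch_size,
                     seed = cfg$seed)
      p <- mlp_predict(fit, X[!tr, , drop = FALSE])
      mean((p >= 0.5) == (y[!tr] == 1))
    }, 0)
    trials[[t]] <- tibble(
      trial = t, n_hidden_layers = cfg$n_hidden_layers,
      units = paste(cfg$units, collapse = "x"), dropout = cfg$dropout,
      learning_rate = cfg$learning_rate, epochs = cfg$epochs,
      batch_size = cfg$batch_size,
      n_params = mlp_param_count(ncol(X), cfg$units),
      inner_accuracy = mean(accs), config = list(cfg))
  }
  log <- bind_rows(trials)
  best <- log |>
    arrange(dplyr::desc(.data$inner_accuracy), .data$n_params, .data$trial) |>
    dplyr::slice(1)
  list(best_config = best$config[[1]], best_accuracy = best$inner_accuracy,
       trials = select(log, -"config"))
}

#' @export
print.trained_classifier <- function(x, ...) {
  cat("<trained_classifier>\n")
  cat("  feature set:", x$feature_set, "\n")
  cat("  hidden layers:", paste(x$config$units, collapse = " x "), "\n")
  cat("  trained on", x$training_fingerprint$n, "records",
      if (length(x$campaign_ids)) paste0("(campaigns: ",
                                         paste(x$campaign_ids, collapse = ", "), ")"),
      "\n")
  invisible(x)
}

#' Tidy and glance methods for trained classifiers
#'
#' `tidy()` returns one row per hyperparameter; `glance()` a one-row summary
#' of the fit (training size, feature width, parameter count, final training
#' loss).
#'
#' @param x A `trained_classifier`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy trained_classifier
#' @export
tidy.trained_classifier <- function(x, ...) {
  cfg <- x$config
  tibble(term = c("n_hidden_layers", "units", "dropout", "learning_rate",
                  "epochs", "batch_size", "seed"),
         value = c(cfg$n_hidden_layers, paste(cfg$units, collapse = "x"),
                   cfg$dropout, cfg$learning_rate, cfg$epochs, cfg$batch_size,
                   cfg$seed))
}

#' @rdname tidy.trained_classifier
#' @method glance trained_classifier
#' @export
glance.trained_classifier <- function(x, ...) {
  tibble(n_train = x$training_fingerprint$n,
         n_features = x$fit$n_features,
         n_params = mlp_param_count(x$fit$n_features, x$config$units),
         final_loss = if (length(x$fit$loss_history))
           x$fit$loss_history[length(x$fit$loss_history)] else NA_real_,
         feature_set = x$feature_set)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
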