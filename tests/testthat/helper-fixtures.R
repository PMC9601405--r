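# shared fixtures: all built in code at test time

reagent_table <- function(role, ids, smiles = NA_character_) {
  dplyr::bind_rows(purrr::map2(ids, rep_len(smiles, length(ids)),
                               ~reagent_spec(.x, role, smiles = .y)))
}

# a tiny labelled dataset with hand-set responses
toy_dataset <- function() {
  grid <- build_condition_grid(3)
  acids <- reagent_table("acid", c("A1", "A2"))
  amines <- reagent_table("amine", c("B1", "B2"))
  agents <- reagent_table("coupling_agent", c("CA1", "CA2"))
  plans <- enumerate_experiments(acids, amines, agents, grid)
  plans$campaign_id <- "toy"
  plans$response_area_pct <- rep_len(c(55, 2, 8, 12, 30, 1), nrow(plans))
  plans$status <- "ok"
  plans$is_area <- 100
  plans$product_area <- plans$response_area_pct * 10
  label_outcomes(plans)
}

# small search space so tuning stays fast in tests
quick_space <- function(epochs = 15L) {
  list(n_hidden_layers = 1L, units = 16L, dropout = 0,
       learning_rate_range = c(5e-3, 5e-3), epochs = epochs, batch_size = 64L)
}

quick_config <- function(seed = 1) {
  model_config(n_hidden_layers = 1, units = 16, epochs = 25, batch_size = 64,
               learning_rate = 5e-3, seed = seed)
}

# two separable Gaussian blobs in 2-D
make_blobs <- function(n = 200, gap = 4, seed = 1) {
  withr::with_seed(seed, {
    n1 <- n %/% 2
    X <- rbind(matrix(rnorm(2 * n1), ncol = 2),
               matrix(rnorm(2 * (n - n1), mean = gap), ncol = 2))
    list(X = X, y = c(rep(0L, n1), rep(1L, n - n1)))
  })
}
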