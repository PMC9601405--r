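test_that("ground-truth probabilities reproduce logistic hand calculations", {
  # all effects silenced: p = plogis(intercept + agent effect) exactly
  cfg <- synthetic_config(agent_effects = c(X = 0, Y = log(4)),
                          temperature_slope = 0, time_slope = 0,
                          acid_sd = 0, amine_sd = 0, pair_sd = 0,
                          intercept = 0)
  cond <- tibble::tibble(temperature_C = 120, reaction_time_s = 360)
  expect_equal(ground_truth_probability(cfg, "A1", "B1", "X", cond), 0.5)
  expect_equal(ground_truth_probability(cfg, "A1", "B1", "Y", cond), 0.8)
  expect_error(ground_truth_probability(cfg, "A1", "B1", "Z", cond),
               class = "amidescreen_invalid_reagent")
})

test_that("success probability is monotone in temperature along the grid", {
  cfg <- synthetic_config(acid_sd = 0, amine_sd = 0, pair_sd = 0)
  grid <- build_condition_grid(9)
  scaling <- condition_scaling(grid)
  p <- vapply(seq_len(9), function(i) {
    ground_truth_probability(cfg, "A1", "B1", "PyCIU", grid[i, ], scaling)
  }, 0)
  expect_true(all(diff(p) > 0))
  # and ordered by the configured agent strengths at fixed conditions
  pa <- vapply(c("PyCIU", "TCFH", "HATU", "T3P"), function(ag) {
    ground_truth_probability(cfg, "A1", "B1", ag, grid[5, ], scaling)
  }, 0)
  expect_true(all(diff(pa) < 0))
})

test_that("a default campaign has the factorial size and valid responses", {
  syn <- generate_library(synthetic_config(seed = 10))
  expect_equal(nrow(syn$dataset), 900)
  ok <- syn$dataset$status == "ok"
  expect_true(all(syn$dataset$response_area_pct[ok] >= 0 &
                    syn$dataset$response_area_pct[ok] <= 100))
  expect_true(all(is.na(syn$dataset$response_area_pct[!ok])))
  expect_equal(nrow(syn$truth$per_record), 900)
  expect_true(all(syn$truth$per_record$p > 0 & syn$truth$per_record$p < 1))
  expect_equal(nrow(syn$reagents), 5 + 5 + 4)
})

test_that("generation is deterministic in the seed and campaigns share reagent effects", {
  cfg <- synthetic_config(seed = 21)
  a <- generate_library(cfg)
  b <- generate_library(cfg)
  expect_identical(a$dataset, b$dataset)
  c <- generate_library(synthetic_config(seed = 22))
  expect_false(identical(a$dataset$response_area_pct,
                         c$dataset$response_area_pct))
  # a later campaign reuses the effects of the amines it shares
  later <- generate_library(cfg, campaign_id = "campaign_2",
                            acid_ids = paste0("A", 1:6))
  expect_equal(later$truth$amine_effects, a$truth$amine_effects)
  expect_equal(later$truth$acid_effects[paste0("A", 1:5)],
               a$truth$acid_effects)
})

test_that("dropout count sits inside a binomial 99.9% interval over seeds", {
  rate <- 64 / 900
  counts <- vapply(1:6, function(sd) {
    sum(generate_library(synthetic_config(seed = sd))$dataset$status ==
          "instrument_failure")
  }, 0L)
  bounds <- qbinom(c(5e-4, 1 - 5e-4), 900, rate)
  expect_true(all(counts >= bounds[1] & counts <= bounds[2]))
  none <- generate_library(synthetic_config(dropout_rate = 0, seed = 1))
  expect_true(all(none$dataset$status == "ok"))
})

test_that("with zero noise the labels equal the latent indicator 100p >= 10", {
  cfg <- synthetic_config(response_noise_sd = 0, dropout_rate = 0, seed = 8)
  syn <- generate_library(cfg)
  d <- label_outcomes(syn$dataset)
  expect_equal(d$label == "successful", 100 * syn$truth$per_record$p >= 10)
})

test_that("labelled outcomes depend on temperature but not time by design", {
  # time and temperature are confounded along the harshness ramp, so this
  # check needs a crossed grid where each varies independently
  crossed <- tidyr::expand_grid(reaction_time_s = c(120, 360, 600),
                                temperature_C = c(50, 125, 200)) |>
    dplyr::mutate(harshness_rank = dplyr::row_number())
  pval <- function(var, seed) {
    syn <- generate_library(synthetic_config(seed = seed,
                                             response_noise_sd = 1),
                            grid = crossed)
    d <- label_outcomes(syn$dataset)
    d <- d[d$label != "missing", ]
    suppressWarnings(
      chisq.test(table(d[[var]], d$label == "successful"))$p.value)
  }
  temp_p <- vapply(1:8, function(s) pval("temperature_C", s), 0)
  time_p <- vapply(1:8, function(s) pval("reaction_time_s", s), 0)
  # temperature association is overwhelming in every campaign
  expect_true(all(temp_p < 1e-10))
  # a zero-slope covariate yields uniform p-values: most runs non-significant
  expect_gte(mean(time_p > 0.01), 0.75)
})

test_that("class balance is near even across seeds, as configured", {
  rates <- vapply(1:8, function(sd) {
    d <- label_outcomes(generate_library(synthetic_config(seed = sd))$dataset)
    mean(d$label[d$label != "missing"] == "successful")
  }, 0)
  expect_gt(mean(rates), 0.3)
  expect_lt(mean(rates), 0.7)
})

test_that("every pool pair condenses to a distinct amide product", {
  acids <- smiles_pool("acid")
  amines <- smiles_pool("amine")
  expect_length(acids, 12)
  expect_length(amines, 12)
  products <- character()
  for (a in acids) for (b in amines) {
    products <- c(products, amide_product_smiles(a, b))
  }
  expect_length(products, 144)
  expect_length(unique(products), 144)
})

test_that("property tables carry signal only when rho > 0", {
  syn <- generate_library(synthetic_config(seed = 5))
  rg <- syn$reagents[syn$reagents$role != "coupling_agent", ]
  eff <- c(syn$truth$acid_effects, syn$truth$amine_effects)
  flat <- generate_property_table(rg, eff, rho = 0, seed = 4)
  sharp <- generate_property_table(rg, eff, rho = 1, seed = 4)
  expect_equal(dim(flat), c(10, 1 + 6 + 4))
  z <- (eff[flat$reagent_id] - mean(eff)) / sd(eff)
  expect_equal(unname(cor(sharp$prop_1, z)), 1, tolerance = 1e-8)
  expect_lt(abs(cor(flat$prop_1, z)), 0.9)
  expect_error(generate_property_table(rg[0, ]),
               class = "amidescreen_invalid_reagent")
})
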