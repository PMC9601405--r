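# Synthetic screening campaigns with the statistical structure the analysis
# assumes: a logistic latent success surface that is temperature-dominant,
# coupling-agent-dependent and pair-specific, with sporadic instrument
# dropouts. A deliberately simple surrogate for the screening response - not
# a chemistry model.

#' A packaged pool of screening reagent SMILES
#'
#' Twelve mono-functional carboxylic acids and twelve mono-functional
#' primary/secondary amines chosen so that every acid-amine pair condenses to
#' a unique amide without ambiguity.
#'
#' @param role `"acid"` or `"amine"`.
#' @return A character vector of SMILES.
#' @export
smiles_pool <- function(role = c("acid", "amine")) {
  role <- match.arg(role)
  if (role == "acid") {
    c("CC(=O)O", "CCC(=O)O", "CCCC(=O)O", "CC(C)C(=O)O", "CC(C)(C)C(=O)O",
      "OC(=O)c1ccccc1", "Cc1ccc(cc1)C(=O)O", "Clc1ccc(cc1)C(=O)O",
      "COc1ccc(cc1)C(=O)O", "OC(=O)C1CC1", "OC(=O)c1ccco1",
      "OC(=O)Cc1ccccc1")
  } else {
    c("CN", "CCN", "CCCN", "CC(C)N", "CCCCN", "NCc1ccccc1", "Nc1ccccc1",
      "NC1CCCCC1", "CNC", "C1CCNC1", "C1CCNCC1", "O1CCNCC1")
  }
}

#' Configure a synthetic screening campaign
#'
#' Encodes the study conditions the generator emulates: a 5 x 5 library
#' screened with 4 coupling agents whose effectiveness differs (log-odds
#' ordered PyCIU > TCFH > HATU > T3P), a strongly temperature-dependent and
#' time-independent latent response, reagent- and pair-specific difficulty,
#' roughly balanced success/failure classes at the 10\% area threshold, and a
#' dropout rate sized so a 900-reaction campaign keeps about 836 usable
#' records.
#'
#' @param n_acids,n_amines Library dimensions (each <= 12, the SMILES pool
#'   size).
#' @param agent_effects Named log-odds offset per coupling agent.
#' @param temperature_slope Log-odds per standard deviation of temperature
#'   across the grid; large and positive by default (harsher is better).
#' @param time_slope Log-odds per standard deviation of reaction time;
#'   default 0 (time does not matter once temperature is accounted for).
#' @param acid_sd,amine_sd,pair_sd Standard deviations (log-odds) of the
#'   per-acid, per-amine and per-pair random difficulty effects.
#' @param response_noise_sd Gaussian noise on the percentage response scale.
#' @param dropout_rate Probability that a record is lost to instrument
#'   failure; default 64/900.
#' @param threshold_pct Success threshold used for labelling; default 10.
#' @param intercept Baseline log-odds; defaults to `qlogis(threshold_pct/100)`
#'   so the latent response clears the threshold about half the time and the
#'   two outcome classes are roughly balanced.
#' @param seed Master seed. Reagent effects are keyed to reagent ids, so two
#'   campaigns generated from one config share the effects of the reagents
#'   they have in common.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_acids = 5, n_amines = 5,
                             agent_effects = c(HATU = -0.5, PyCIU = 1.0,
                                               TCFH = 0.7, T3P = -1.2),
                             temperature_slope = 1.5, time_slope = 0,
                             acid_sd = 0.8, amine_sd = 0.8, pair_sd = 0.8,
                             response_noise_sd = 4, dropout_rate = 64 / 900,
                             threshold_pct = 10,
                             intercept = stats::qlogis(threshold_pct / 100),
                             seed = 1) {
  stopifnot(n_acids >= 1, n_amines >= 1,
            dropout_rate >= 0, dropout_rate <= 1,
            acid_sd >= 0, amine_sd >= 0, pair_sd >= 0, response_noise_sd >= 0)
  structure(list(n_acids = n_acids, n_amines = n_amines,
                 agent_effects = agent_effects,
                 temperature_slope = temperature_slope, time_slope = time_slope,
                 acid_sd = acid_sd, amine_sd = amine_sd, pair_sd = pair_sd,
                 response_noise_sd = response_noise_sd,
                 dropout_rate = dropout_rate, threshold_pct = threshold_pct,
                 intercept = intercept, seed = as.integer(seed)),
            class = "synthetic_config")
}

string_seed <- function(seed, kind, id) {
  derive_seed(seed, match(kind, c("acid", "amine", "pair")),
              sum(utf8ToInt(id) * seq_along(utf8ToInt(id))))
}

id_effect <- function(config, kind, id) {
  sd <- switch(kind, acid = config$acid_sd, amine = config$amine_sd,
               pair = config$pair_sd)
  if (sd == 0) return(0)
  withr::with_seed(string_seed(config$seed, kind, id), rnorm(1, 0, sd))
}

condition_scaling <- function(grid) {
  zs <- function(x) {
    s <- sd(x)
    list(mean = mean(x), sd = if (is.na(s) || s == 0) 1 else s)
  }
  list(temperature = zs(grid$temperature_C), time = zs(grid$reaction_time_s))
}

#' Latent success probability of one experiment
#'
#' The generator's ground truth: a logistic model
#' `p = plogis(b0 + b_agent + b_T z(T) + b_t z(t) + u_acid + v_amine +
#' w_pair)`, with temperature and time standardised over the grid. Reagent
#' and pair effects are deterministic functions of the config seed and the
#' reagent id.
#'
#' @param config A [synthetic_config()].
#' @param acid_id,amine_id,agent_id Identifiers; `agent_id` must name an
#'   entry of `config$agent_effects`.
#' @param condition One-row tibble with `temperature_C` and
#'   `reaction_time_s`.
#' @param scaling Standardisation constants from the grid (means/sds); pass
#'   the same object for every experiment of a design.
#' @return A probability.
#' @export
ground_truth_probability <- function(config, acid_id, amine_id, agent_id,
                                     condition,
                                     scaling = condition_scaling(condition)) {
  if (!agent_id %in% names(config$agent_effects)) {
    abort(sprintf("Unknown agent '%s'.", agent_id),
          class = "amidescreen_invalid_reagent")
  }
  beta_a <- config$agent_effects[[agent_id]]
  zT <- (condition$temperature_C - scaling$temperature$mean) / scaling$temperature$sd
  zt <- (condition$reaction_time_s - scaling$time$mean) / scaling$time$sd
  plogis(config$intercept + beta_a +
           config$temperature_slope * zT + config$time_slope * zt +
           id_effect(config, "acid", acid_id) +
           id_effect(config, "amine", amine_id) +
           id_effect(config, "pair", paste(acid_id, amine_id, sep = ".")))
}

#' Generate a synthetic screening campaign
#'
#' Enumerates the full factorial design, draws the latent success
#' probabilities, adds Gaussian noise on the percentage scale (clipped to
#' \[0, 100\]) and knocks out records at the instrument-failure rate. The
#' returned ground truth carries every realized effect and per-record
#' probability for recovery tests.
#'
#' @param config A [synthetic_config()].
#' @param grid Condition grid; default the 9-point soft-to-harsh preset.
#' @param campaign_id Campaign label stamped on every record.
#' @param acid_ids,amine_ids Reagent ids; default `A1..An` / `B1..Bn`.
#'   Ids ending in a number pick the matching entry of [smiles_pool()], so
#'   e.g. `B6..B10` get fresh structures not used by `B1..B5`.
#' @return A list: `dataset` (record tibble ready for [label_outcomes()]),
#'   `truth` (per-record latent probabilities plus realized effect tables)
#'   and `reagents` (reagent table with SMILES).
#' @examples
#' syn <- generate_library(synthetic_config(seed = 42))
#' nrow(syn$dataset)  # 900
#' @export
generate_library <- function(config, grid = build_condition_grid(9),
                             campaign_id = "campaign_1",
                             acid_ids = paste0("A", seq_len(config$n_acids)),
                             amine_ids = paste0("B", seq_len(config$n_amines))) {
  stopifnot(inherits(config, "synthetic_config"))
  pool_index <- function(ids, pool) {
    num <- suppressWarnings(as.integer(sub("^\\D*", "", ids)))
    num[is.na(num)] <- seq_along(ids)[is.na(num)]
    if (any(num > length(pool))) {
      abort("Reagent id exceeds the packaged SMILES pool.",
            class = "amidescreen_invalid_reagent")
    }
    pool[num]
  }
  acids <- bind_rows(purrr::map2(acid_ids,
                                 pool_index(acid_ids, smiles_pool("acid")),
                                 ~reagent_spec(.x, "acid", smiles = .y,
                                               stock_concentration = 0.13)))
  amines <- bind_rows(purrr::map2(amine_ids,
                                  pool_index(amine_ids, smiles_pool("amine")),
                                  ~reagent_spec(.x, "amine", smiles = .y,
                                                stock_concentration = 0.10)))
  agents <- bind_rows(purrr::map(names(config$agent_effects),
                                 ~reagent_spec(.x, "coupling_agent",
                                               stock_concentration = 0.15)))
  plans <- enumerate_experiments(acids, amines, agents, grid)
  scaling <- condition_scaling(grid)
  p <- vapply(seq_len(nrow(plans)), function(i) {
    ground_truth_probability(config, plans$acid_id[i], plans$amine_id[i],
                             plans$agent_id[i], plans[i, ], scaling)
  }, 0)
  withr::with_seed(derive_seed(config$seed, 101, nrow(plans)), {
    response <- pmin(pmax(100 * p + rnorm(nrow(plans), 0, config$response_noise_sd),
                          0), 100)
    failed <- runif(nrow(plans)) < config$dropout_rate
  })
  dataset <- plans |>
    mutate(campaign_id = campaign_id, .before = 1) |>
    mutate(response_area_pct = ifelse(failed, NA_real_, response),
           product_area = ifelse(failed, NA_real_, 10 * response),
           is_area = ifelse(failed, NA_real_, 100),
           status = ifelse(failed, "instrument_failure", "ok"))
  truth <- list(
    per_record = plans |> mutate(p = p),
    acid_effects = setNames(vapply(acid_ids,
                                   function(a) id_effect(config, "acid", a), 0),
                            acid_ids),
    amine_effects = setNames(vapply(amine_ids,
                                    function(a) id_effect(config, "amine", a), 0),
                             amine_ids),
    agent_effects = config$agent_effects,
    scaling = scaling)
  list(dataset = dataset, truth = truth,
       reagents = bind_rows(acids, amines, agents))
}

#' Generate a reagent property table
#'
#' Continuous stand-in descriptors plus pKa1-pKa4 columns per reagent, with a
#' configurable correlation `rho` between the first descriptor / pKa1 and the
#' reagent's supplied latent effect. At `rho = 0` the properties carry no
#' signal; at high `rho` property-bearing feature sets can genuinely
#' outperform.
#'
#' @param reagents Reagent table (acids and amines).
#' @param effects Named numeric vector of latent effects per reagent id (e.g.
#'   from a generated library's truth); defaults to zeros.
#' @param n_properties Number of continuous descriptors; default 6.
#' @param rho Correlation in \[0, 1\] between the signal-bearing columns and
#'   the latent effect.
#' @param seed Integer seed.
#' @return A wide tibble: `reagent_id`, `prop_1..n`, `pka1..pka4`.
#' @export
generate_property_table <- function(reagents, effects = NULL, n_properties = 6,
                                    rho = 0, seed = 1) {
  if (nrow(reagents) == 0) abort("`reagents` is empty.",
                                 class = "amidescreen_invalid_reagent")
  stopifnot(rho >= 0, rho <= 1)
  ids <- reagents$id
  eff <- setNames(rep(0, length(ids)), ids)
  if (!is.null(effects)) eff[names(effects)[names(effects) %in% ids]] <-
    effects[names(effects) %in% ids]
  z <- if (sd(eff) > 0) (eff - mean(eff)) / sd(eff) else eff * 0
  withr::with_seed(derive_seed(seed, 77, length(ids)), {
    props <- matrix(rnorm(length(ids) * n_properties), length(ids),
                    dimnames = list(NULL, paste0("prop_", seq_len(n_properties))))
    props[, 1] <- rho * z + sqrt(1 - rho^2) * props[, 1]
    pka <- matrix(rnorm(length(ids) * 4, mean = rep(c(4.5, 7, 9.5, 11),
                                                    each = length(ids))),
                  length(ids), dimnames = list(NULL, paste0("pka", 1:4)))
    pka[, 1] <- 4.5 + 2 * (rho * z + sqrt(1 - rho^2) * rnorm(length(ids)))
  })
  dplyr::bind_cols(tibble(reagent_id = ids), as_tibble(props), as_tibble(pka))
}
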