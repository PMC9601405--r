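#' Reaction-condition points and soft-to-harsh screening grids
#'
#' High-throughput screens in a stopped-flow reactor explore reaction time and
#' temperature jointly. Because screening outcomes are dominated by temperature
#' and only weakly affected by time, the two-dimensional space is collapsed to a
#' single "harshness" ramp: an ordered sequence of (time, temperature) points
#' running from soft (short, cool) to harsh (long, hot). [condition_point()]
#' builds a single point; [build_condition_grid()] builds the ramp.
#'
#' @param reaction_time_s Reaction time in seconds (> 0). For a stopped-flow
#'   reactor this is transit time plus stationary hold time, see
#'   [reaction_time_components()].
#' @param temperature_C Reactor temperature in degrees Celsius (> 0).
#' @param harshness_rank Integer rank (>= 1) of the point within its grid;
#'   rank 1 is the softest condition.
#' @return A one-row tibble with columns `harshness_rank`, `reaction_time_s`
#'   and `temperature_C`.
#' @examples
#' condition_point(120, 50, 1)
#' @export
condition_point <- function(reaction_time_s, temperature_C, harshness_rank = 1L) {
  if (!is.numeric(reaction_time_s) || reaction_time_s <= 0) {
    abort("`reaction_time_s` must be a positive number.", class = "amidescreen_invalid_condition")
  }
  if (!is.numeric(temperature_C) || temperature_C <= 0) {
    abort("`temperature_C` must be a positive number.", class = "amidescreen_invalid_condition")
  }
  if (harshness_rank < 1) {
    abort("`harshness_rank` must be >= 1.", class = "amidescreen_invalid_condition")
  }
  tibble(
    harshness_rank = as.integer(harshness_rank),
    reaction_time_s = as.numeric(reaction_time_s),
    temperature_C = as.numeric(temperature_C)
  )
}

#' Build a soft-to-harsh condition grid
#'
#' Interpolates `n_points` reaction conditions between three named anchors:
#' soft, mid and harsh. Reaction times are linear from soft to harsh;
#' temperatures are piecewise-linear *through* the mid anchor (soft to mid over
#' the first half of the ranking, mid to harsh over the second), because a
#' single linear ramp between the soft and harsh anchors would miss the named
#' mid condition. The default anchors are the screening campaign's
#' (120 s, 50 degC) / (360 s, 120 degC) / (600 s, 200 degC); the 9-point
#' default grid is the standard screening preset.
#'
#' @param n_points Number of grid points (>= 1). With odd `n_points >= 3` all
#'   three anchors appear exactly in the grid; with even `n_points` the mid
#'   anchor is snapped to the nearest rank and a warning is raised.
#' @param soft,mid,harsh One-row condition tibbles as returned by
#'   [condition_point()] (the `harshness_rank` column is ignored). Must be
#'   component-wise non-decreasing from soft to harsh.
#' @return A `condition_grid` tibble with `n_points` rows, ordered by
#'   `harshness_rank`, both coordinates non-decreasing along the ranking.
#' @examples
#' build_condition_grid(9)
#' build_condition_grid(1)
#' @export
build_condition_grid <- function(n_points = 9,
                                 soft = condition_point(120, 50),
                                 mid = condition_point(360, 120),
                                 harsh = condition_point(600, 200)) {
  if (n_points < 1) abort("`n_points` must be >= 1.", class = "amidescreen_invalid_grid")
  a <- c(soft$reaction_time_s, soft$temperature_C)
  b <- c(mid$reaction_time_s, mid$temperature_C)
  d <- c(harsh$reaction_time_s, harsh$temperature_C)
  if (any(b < a) || any(d < b)) {
    abort("Anchors must be component-wise non-decreasing soft <= mid <= harsh.",
          class = "amidescreen_invalid_anchor")
  }
  if (n_points == 1) {
    out <- tibble(harshness_rank = 1L,
                  reaction_time_s = a[1], temperature_C = a[2])
    class(out) <- c("condition_grid", class(out))
    return(out)
  }
  rank <- seq_len(n_points)
  frac <- (rank - 1) / (n_points - 1)
  times <- a[1] + frac * (d[1] - a[1])
  # temperature ramp passes through the mid anchor at the middle rank
  mid_rank <- (n_points + 1) / 2
  if (n_points %% 2 == 0 && n_points >= 3) {
    mid_rank <- round(mid_rank)
    warn("Even `n_points`: mid anchor snapped to the nearest rank.",
         class = "amidescreen_mid_snapped")
  }
  temps <- ifelse(
    rank <= mid_rank,
    a[2] + (rank - 1) / max(mid_rank - 1, 1) * (b[2] - a[2]),
    b[2] + (rank - mid_rank) / max(n_points - mid_rank, 1) * (d[2] - b[2])
  )
  out <- tibble(harshness_rank = rank,
                reaction_time_s = times, temperature_C = temps)
  class(out) <- c("condition_grid", class(out))
  out
}

#' Declare a screening reagent
#'
#' @param id Short label, e.g. "A1" (acid), "B4" (amine), "CA2" (coupling
#'   agent). Must be unique within a reagent table.
#' @param role One of `"acid"`, `"amine"`, `"coupling_agent"`.
#' @param smiles Optional SMILES string; coupling agents used purely as
#'   categorical levels may omit it.
#' @param stock_concentration Optional stock concentration in mol/L (> 0).
#'   Typical screening stocks: acid 0.13 M, amine 0.10 M, coupling agent
#'   0.15 M, activating base 0.35 M, toluene internal standard 0.10 M.
#' @param base_partner,base_concentration Optional activating base premixed
#'   with the reagent and its concentration in mol/L.
#' @return A one-row tibble; bind rows to form a reagent table.
#' @examples
#' reagent_spec("A1", "acid", smiles = "CC(=O)O", stock_concentration = 0.13)
#' @export
reagent_spec <- function(id, role, smiles = NA_character_,
                         stock_concentration = NA_real_,
                         base_partner = NA_character_,
                         base_concentration = NA_real_) {
  role <- match.arg(role, c("acid", "amine", "coupling_agent"))
  if (!is.na(stock_concentration) && stock_concentration <= 0) {
    abort("`stock_concentration` must be > 0 when given.",
          class = "amidescreen_invalid_reagent")
  }
  tibble(id = as.character(id), role = role, smiles = as.character(smiles),
         stock_concentration = as.numeric(stock_concentration),
         base_partner = as.character(base_partner),
         base_concentration = as.numeric(base_concentration))
}

check_reagent_table <- function(reagents, expected_role, arg) {
  if (nrow(reagents) == 0) {
    abort(sprintf("`%s` must contain at least one reagent.", arg),
          class = "amidescreen_invalid_reagent")
  }
  if (anyDuplicated(reagents$id)) {
    abort(sprintf("Duplicate reagent ids in `%s`: %s.", arg,
                  paste(unique(reagents$id[duplicated(reagents$id)]), collapse = ", ")),
          class = "amidescreen_duplicate_id")
  }
  if (!all(reagents$role == expected_role)) {
    abort(sprintf("All reagents in `%s` must have role '%s'.", arg, expected_role),
          class = "amidescreen_role_mismatch")
  }
  invisible(reagents)
}

#' Enumerate a full factorial screening campaign
#'
#' Crosses every acid with every amine, coupling agent and grid condition, one
#' row per planned reaction. The target product of a plan is identified by its
#' (acid, amine) pair. A 5 x 5 x 4 library over a 9-point grid yields the
#' 900-reaction campaign; a 6 x 5 x 4 library over 2 conditions yields the
#' 240-reaction validation campaign.
#'
#' @param acids,amines,coupling_agents Reagent tables built from
#'   [reagent_spec()] rows, with matching roles.
#' @param grid A [build_condition_grid()] tibble.
#' @return A tibble with one row per planned experiment: `acid_id`, `amine_id`,
#'   `agent_id`, `product_id` (`"<acid>.<amine>"`), `harshness_rank`,
#'   `reaction_time_s`, `temperature_C`.
#' @examples
#' acids <- dplyr::bind_rows(lapply(paste0("A", 1:5), reagent_spec, role = "acid"))
#' amines <- dplyr::bind_rows(lapply(paste0("B", 1:5), reagent_spec, role = "amine"))
#' agents <- dplyr::bind_rows(lapply(paste0("CA", 1:4), reagent_spec, role = "coupling_agent"))
#' nrow(enumerate_experiments(acids, amines, agents, build_condition_grid(9)))
#' @export
enumerate_experiments <- function(acids, amines, coupling_agents, grid) {
  check_reagent_table(acids, "acid", "acids")
  check_reagent_table(amines, "amine", "amines")
  check_reagent_table(coupling_agents, "coupling_agent", "coupling_agents")
  if (nrow(grid) == 0) abort("`grid` must contain at least one condition.",
                             class = "amidescreen_invalid_grid")
  plans <- tidyr::expand_grid(
    acid_id = acids$id, amine_id = amines$id, agent_id = coupling_agents$id,
    harshness_rank = grid$harshness_rank
  )
  plans |>
    left_join(grid, by = "harshness_rank") |>
    mutate(product_id = paste(.data$acid_id, .data$amine_id, sep = "."),
           .after = "agent_id")
}

#' Describe a stopped-flow reactor setup
#'
#' Captures the volumes and flows needed for reaction-time and reagent-usage
#' accounting. Defaults describe a 1000 uL coil fed by three HPLC pumps at
#' 0.5 mL/min each (total 1.5 mL/min), a 500 uL reagent slug carried with a
#' two-fold safety margin against axial dispersion, and a 10 mL steady-state
#' requirement for the fully continuous comparator.
#'
#' @param reactor_volume_uL Reactor coil volume, uL.
#' @param per_pump_flow_uL_min Flow rate per pump, uL/min.
#' @param n_pumps Number of pumps feeding the mixer (>= 1).
#' @param slug_volume_uL Premixed reagent slug volume, uL.
#' @param safety_multiplier Slug oversize factor (>= 1); default 2.
#' @param steady_state_volume_mL Reagent volume a continuous-flow run would
#'   consume to reach steady state before sampling, mL.
#' @return A `flow_setup` list.
#' @examples
#' flow_setup()
#' @export
flow_setup <- function(reactor_volume_uL = 1000, per_pump_flow_uL_min = 500,
                       n_pumps = 3, slug_volume_uL = 500,
                       safety_multiplier = 2, steady_state_volume_mL = 10) {
  vals <- c(reactor_volume_uL, per_pump_flow_uL_min, slug_volume_uL,
            steady_state_volume_mL)
  if (any(vals <= 0)) abort("All volumes and flows must be > 0.",
                            class = "amidescreen_invalid_setup")
  if (n_pumps < 1) abort("`n_pumps` must be >= 1.", class = "amidescreen_invalid_setup")
  if (safety_multiplier < 1) abort("`safety_multiplier` must be >= 1.",
                                   class = "amidescreen_invalid_setup")
  structure(list(reactor_volume_uL = reactor_volume_uL,
                 per_pump_flow_uL_min = per_pump_flow_uL_min,
                 n_pumps = n_pumps, slug_volume_uL = slug_volume_uL,
                 safety_multiplier = safety_multiplier,
                 steady_state_volume_mL = steady_state_volume_mL),
            class = "flow_setup")
}

#' Decompose a stopped-flow reaction time
#'
#' In a stopped-flow reactor the reaction time is the residence time while
#' flowing (one reactor volume at total flow) plus the stationary hold with the
#' pumps stopped. The hold is set freely by the controller, so reaction time is
#' decoupled from the flow-rate capacity of the pumps.
#'
#' @param setup A [flow_setup()].
#' @param stationary_time_s Stationary hold time in seconds (>= 0).
#' @return A one-row tibble with `transit_s`, `stationary_s` and
#'   `reaction_time_s` (their sum).
#' @examples
#' reaction_time_components(flow_setup(), stationary_time_s = 600)
#' @export
reaction_time_components <- function(setup, stationary_time_s = 0) {
  stopifnot(inherits(setup, "flow_setup"))
  if (any(stationary_time_s < 0)) abort("`stationary_time_s` must be >= 0.",
                                        class = "amidescreen_invalid_time")
  total_flow <- setup$n_pumps * setup$per_pump_flow_uL_min
  if (total_flow <= 0) abort("Total flow must be > 0.", class = "amidescreen_zero_flow")
  transit_s <- setup$reactor_volume_uL / total_flow * 60
  tibble(transit_s = transit_s, stationary_s = as.numeric(stationary_time_s),
         reaction_time_s = transit_s + stationary_time_s)
}

#' Compare reagent usage: stopped-flow vs continuous flow
#'
#' A stopped-flow run consumes one oversized reagent slug; a continuous-flow
#' run must pump reagents until steady state. With the default setup (0.5 mL
#' slug, two-fold safety margin, 10 mL steady-state volume) the stopped-flow
#' reactor uses 1 mL against 10 mL, a 90\% reduction.
#'
#' @param setup A [flow_setup()].
#' @return A one-row tibble with `stopped_flow_mL`, `continuous_mL` and
#'   `reduction_pct` = 100 (1 - stopped/continuous). A non-positive reduction
#'   (stopped-flow using at least as much) is reported with a warning, not an
#'   error.
#' @examples
#' reagent_usage_comparison(flow_setup())
#' @export
reagent_usage_comparison <- function(setup) {
  stopifnot(inherits(setup, "flow_setup"))
  stopped <- setup$slug_volume_uL * setup$safety_multiplier / 1000
  continuous <- setup$steady_state_volume_mL
  reduction <- 100 * (1 - stopped / continuous)
  if (reduction <= 0) {
    warn("Stopped-flow usage is not below the continuous comparator.",
         class = "amidescreen_no_reduction")
  }
  tibble(stopped_flow_mL = stopped, continuous_mL = continuous,
         reduction_pct = reduction)
}
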