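#' Label screening outcomes from relative UV peak areas
#'
#' A screening reaction is called successful when the target product's UV peak
#' area at 254 nm reaches a threshold share of the total chromatogram area
#' (default 10\%, an experimental proxy for recovering ~2.5 mg of product).
#' Records whose analysis failed (`status == "instrument_failure"`) are
#' labelled `missing`, never counted as failures.
#'
#' @param dataset A tibble of experiment records with at least
#'   `response_area_pct` (percent, `NA` when analysis failed) and `status`
#'   (`"ok"` or `"instrument_failure"`).
#' @param threshold_pct Success threshold in percent, in (0, 100).
#' @param inclusive If `TRUE` (default) a response exactly at the threshold is
#'   successful (response >= threshold); if `FALSE` the comparison is strict.
#' @return The dataset with a `label` factor column
#'   (`successful`/`failed`/`missing`). Idempotent: relabelling a labelled
#'   dataset simply recomputes the column.
#' @examples
#' d <- tibble::tibble(response_area_pct = c(10, 9.99, NA),
#'                     status = c("ok", "ok", "instrument_failure"))
#' label_outcomes(d)$label
#' @export
label_outcomes <- function(dataset, threshold_pct = 10, inclusive = TRUE) {
  if (threshold_pct <= 0 || threshold_pct >= 100) {
    abort("`threshold_pct` must lie in (0, 100).", class = "amidescreen_invalid_threshold")
  }
  check_record_columns(dataset, c("response_area_pct", "status"))
  ok <- dataset$status == "ok"
  hit <- if (inclusive) dataset$response_area_pct >= threshold_pct
         else dataset$response_area_pct > threshold_pct
  lab <- ifelse(!ok, "missing", ifelse(hit, "successful", "failed"))
  dataset$label <- factor(lab, levels = .label_levels)
  dataset
}

check_record_columns <- function(dataset, cols) {
  miss <- setdiff(cols, names(dataset))
  if (length(miss)) {
    abort(paste0("Dataset is missing column(s): ", paste(miss, collapse = ", "), "."),
          class = "amidescreen_bad_schema")
  }
  invisible(dataset)
}

check_labelled <- function(dataset) {
  if (!"label" %in% names(dataset)) {
    abort("Dataset has no `label` column; run `label_outcomes()` first.",
          class = "amidescreen_not_labelled")
  }
  invisible(dataset)
}

#' Library success-rate tables
#'
#' Summarises how many of the designed amide products were obtained under
#' different screening regimes. A product counts as successful in a scope when
#' at least one of its experiments in that scope is labelled successful;
#' missing records never count as successes and never shrink the denominator,
#' which is always the number of distinct designed products.
#'
#' @param dataset A labelled dataset (see [label_outcomes()]) with `acid_id`,
#'   `amine_id`, `agent_id`, `product_id` and `harshness_rank` columns.
#' @param mode Scope of the table:
#'   * `"single_condition"` - one row per (agent, condition): products
#'     successful in that exact bucket. These are the entries a single fixed
#'     protocol would have achieved.
#'   * `"per_agent_sequence"` - one row per agent: products successful under
#'     at least one grid condition for that agent (a physical-conditions
#'     screen with a fixed coupling agent).
#'   * `"full_screen"` - one row: products successful anywhere in the design.
#' @return A `success_rate_table` tibble with columns `scope`, `agent_id`,
#'   (`harshness_rank` for single-condition rows), `SRxn` (successful
#'   products), `denominator` (designed products) and `LS_pct`
#'   (100 SRxn / denominator).
#' @examples
#' syn <- generate_library(synthetic_config(seed = 1))
#' success_rate_table(label_outcomes(syn$dataset), mode = "full_screen")
#' @export
success_rate_table <- function(dataset,
                               mode = c("single_condition", "per_agent_sequence",
                                        "full_screen")) {
  mode <- match.arg(mode)
  check_labelled(dataset)
  check_record_columns(dataset, c("agent_id", "product_id", "harshness_rank"))
  denom <- dplyr::n_distinct(dataset$product_id)
  succ <- dataset |> filter(.data$label == "successful")
  out <- switch(mode,
    single_condition = {
      buckets <- distinct(dataset, .data$agent_id, .data$harshness_rank)
      counts <- succ |>
        group_by(.data$agent_id, .data$harshness_rank) |>
        summarise(SRxn = dplyr::n_distinct(.data$product_id), .groups = "drop")
      buckets |>
        left_join(counts, by = c("agent_id", "harshness_rank")) |>
        mutate(SRxn = dplyr::coalesce(.data$SRxn, 0L), scope = "single_condition")
    },
    per_agent_sequence = {
      agents <- distinct(dataset, .data$agent_id)
      counts <- succ |>
        group_by(.data$agent_id) |>
        summarise(SRxn = dplyr::n_distinct(.data$product_id), .groups = "drop")
      agents |>
        left_join(counts, by = "agent_id") |>
        mutate(SRxn = dplyr::coalesce(.data$SRxn, 0L), scope = "per_agent_sequence")
    },
    full_screen = tibble(scope = "full_screen", agent_id = "all",
                         SRxn = dplyr::n_distinct(succ$product_id))
  )
  out <- out |>
    mutate(denominator = denom, LS_pct = 100 * .data$SRxn / denom) |>
    select(all_of(c("scope", "agent_id",
                    intersect("harshness_rank", names(out)),
                    "SRxn", "denominator", "LS_pct")))
  class(out) <- c("success_rate_table", class(out))
  out
}

#' Screening heatmap matrix
#'
#' Arranges relative response areas as the screening heatmap: one row per
#' (acid, condition rank), one column per (amine, coupling agent). Cells of
#' records lost to instrument failure are `NA` - masked, never zero. The
#' 5 x 5 x 4 x 9 campaign yields a 45 x 20 matrix.
#'
#' @param dataset A labelled dataset.
#' @return A numeric matrix with dimnames `"<acid>|r<rank>"` and
#'   `"<amine>|<agent>"`, and attribute `n_missing` (count of masked cells).
#' @seealso [plot_screen_heatmap()]
#' @export
heatmap_matrix <- function(dataset) {
  check_labelled(dataset)
  check_record_columns(dataset, c("acid_id", "amine_id", "agent_id",
                                  "harshness_rank", "response_area_pct"))
  if (nrow(dataset) == 0) {
    m <- matrix(numeric(), 0, 0)
    attr(m, "n_missing") <- 0L
    return(m)
  }
  d <- dataset |>
    mutate(row_key = paste0(.data$acid_id, "|r", .data$harshness_rank),
           col_key = paste0(.data$amine_id, "|", .data$agent_id))
  rows <- d |> distinct(.data$acid_id, .data$harshness_rank, .data$row_key) |>
    arrange(.data$acid_id, .data$harshness_rank)
  cols <- d |> distinct(.data$amine_id, .data$agent_id, .data$col_key) |>
    arrange(.data$amine_id, .data$agent_id)
  m <- matrix(NA_real_, nrow(rows), nrow(cols),
              dimnames = list(rows$row_key, cols$col_key))
  m[cbind(match(d$row_key, rows$row_key), match(d$col_key, cols$col_key))] <-
    ifelse(d$status == "ok", d$response_area_pct, NA_real_)
  attr(m, "n_missing") <- sum(d$status != "ok")
  m
}

#' Plot a screening heatmap
#'
#' @param dataset A labelled dataset.
#' @return A ggplot: tiles coloured by relative response area, instrument
#'   failures drawn as crossed empty cells.
#' @export
plot_screen_heatmap <- function(dataset) {
  check_labelled(dataset)
  d <- dataset |>
    mutate(row_key = paste0(.data$acid_id, "|r", .data$harshness_rank),
           col_key = paste0(.data$amine_id, "|", .data$agent_id),
           value = ifelse(.data$status == "ok", .data$response_area_pct, NA_real_))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col_key, y = .data$row_key)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$value), colour = "grey80") +
    ggplot2::geom_point(data = d[is.na(d$value), , drop = FALSE],
                        shape = 4, size = 1, colour = "grey40") +
    ggplot2::scale_fill_viridis_c(name = "Area (%)", na.value = "white",
                                  limits = c(0, 100)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "amine | coupling agent", y = "acid | condition rank") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Condition-search minimisation objective
#'
#' The fast condition search minimises the ratio of the internal-standard peak
#' area to the product peak area: as the product peak grows the objective
#' shrinks. A non-positive product area returns `Inf` (worst case).
#'
#' @param product_area,is_area Peak areas in arbitrary (identical) units;
#'   `is_area` must be > 0. Vectorised.
#' @return `is_area / product_area`, with `Inf` where `product_area <= 0`.
#' @examples
#' optimisation_objective(product_area = 0.5, is_area = 2) # 4
#' @export
optimisation_objective <- function(product_area, is_area) {
  if (any(is_area <= 0, na.rm = TRUE)) {
    abort("`is_area` must be > 0.", class = "amidescreen_invalid_area")
  }
  out <- ifelse(product_area <= 0, Inf, is_area / product_area)
  if (any(is.infinite(out))) {
    warn("Non-positive product area: objective set to Inf.",
         class = "amidescreen_degenerate_objective")
  }
  out
}

# exact CSV schema for screening datasets
.screen_schema <- c("campaign_id", "acid_id", "amine_id", "agent_id",
                    "reaction_time_s", "temperature_C", "response_area_pct",
                    "is_area", "product_area", "status")

#' Read / write screening datasets as CSV
#'
#' The on-disk schema is the exact column set `campaign_id, acid_id, amine_id,
#' agent_id, reaction_time_s, temperature_C, response_area_pct, is_area,
#' product_area, status`. On read, records are validated: `status` must be
#' `ok` or `instrument_failure`; `response_area_pct` must be in \[0, 100\] and
#' present exactly when `status == "ok"`. `product_id` and `harshness_rank`
#' (rank of the condition within the campaign, by ascending time then
#' temperature) are reconstructed. Writing then reading reproduces the
#' records.
#'
#' @param path File path.
#' @param dataset For [write_screen_csv()], a dataset tibble containing at
#'   least the schema columns.
#' @return [read_screen_csv()] returns a dataset tibble ready for
#'   [label_outcomes()].
#' @export
read_screen_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         campaign_id = "c", acid_id = "c", amine_id = "c",
                         agent_id = "c", reaction_time_s = "d",
                         temperature_C = "d", response_area_pct = "d",
                         is_area = "d", product_area = "d", status = "c"))
  miss <- setdiff(.screen_schema, names(d))
  if (length(miss)) {
    abort(paste0("Screening CSV is missing column(s): ",
                 paste(miss, collapse = ", "), "."),
          class = "amidescreen_bad_schema")
  }
  bad_status <- which(!d$status %in% c("ok", "instrument_failure"))
  if (length(bad_status)) {
    abort(sprintf("Invalid `status` at row %d: %s.", bad_status[1],
                  d$status[bad_status[1]]), class = "amidescreen_bad_schema")
  }
  bad_rng <- which(d$status == "ok" &
                     (is.na(d$response_area_pct) |
                        d$response_area_pct < 0 | d$response_area_pct > 100))
  if (length(bad_rng)) {
    abort(sprintf("`response_area_pct` invalid or absent for an ok record at row %d.",
                  bad_rng[1]), class = "amidescreen_bad_schema")
  }
  bad_na <- which(d$status == "instrument_failure" & !is.na(d$response_area_pct))
  if (length(bad_na)) {
    abort(sprintf("`response_area_pct` must be blank for instrument failures (row %d).",
                  bad_na[1]), class = "amidescreen_bad_schema")
  }
  conds <- d |> distinct(.data$reaction_time_s, .data$temperature_C) |>
    arrange(.data$reaction_time_s, .data$temperature_C) |>
    mutate(harshness_rank = row_number())
  d |>
    left_join(conds, by = c("reaction_time_s", "temperature_C")) |>
    mutate(product_id = paste(.data$acid_id, .data$amine_id, sep = "."),
           .after = "agent_id")
}

#' @rdname read_screen_csv
#' @export
write_screen_csv <- function(dataset, path) {
  check_record_columns(dataset, .screen_schema)
  readr::write_csv(dataset[, .screen_schema], path)
  invisible(path)
}
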