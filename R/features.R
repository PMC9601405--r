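# model features: reaction/product fingerprints, condition one-hots,
# property and pKa blocks, assembled per a named feature-set spec.

.fp_cache <- new.env(parent = emptyenv())

cached_fp <- function(smiles, radius, n_bits, variant) {
  key <- paste(smiles, radius, n_bits, variant, sep = "\r")
  hit <- .fp_cache[[key]]
  if (is.null(hit)) {
    hit <- circular_count_fp(smiles, radius = radius, n_bits = n_bits,
                             variant = variant)
    .fp_cache[[key]] <- hit
  }
  hit
}

#' Condition vocabularies of a campaign
#'
#' The coupling-agent, temperature and time levels present in a dataset, used
#' to fix the width of the condition one-hot encoding. For a campaign with 4
#' agents and 5 distinct temperatures and times the encoding is 14 bits wide.
#'
#' @param dataset A dataset with `agent_id`, `temperature_C`,
#'   `reaction_time_s` columns.
#' @return A list with sorted character vectors `agents`, `temperatures`,
#'   `times`.
#' @export
condition_vocabulary <- function(dataset) {
  check_record_columns(dataset, c("agent_id", "temperature_C", "reaction_time_s"))
  list(agents = sort(unique(as.character(dataset$agent_id))),
       temperatures = sort(unique(as.character(dataset$temperature_C))),
       times = sort(unique(as.character(dataset$reaction_time_s))))
}

#' One-hot encode reaction conditions
#'
#' Three concatenated one-hot blocks - coupling agent, temperature, reaction
#' time - each with one bit per vocabulary level, so every encoded row has
#' exactly three active bits. Temperature and time are treated as categorical
#' levels, not scaled numerics. Values outside the vocabulary raise an error
#' rather than silently extending it.
#'
#' @param dataset A dataset with `agent_id`, `temperature_C`,
#'   `reaction_time_s` columns.
#' @param vocab A [condition_vocabulary()]; defaults to the dataset's own.
#' @return A binary matrix, one row per record, with named columns
#'   `agent_*`, `temp_*`, `time_*`.
#' @examples
#' syn <- generate_library(synthetic_config(seed = 1))
#' ncol(encode_conditions(syn$dataset))  # 4 + 9 + 9 on the default grid
#' @export
encode_conditions <- function(dataset, vocab = condition_vocabulary(dataset)) {
  check_record_columns(dataset, c("agent_id", "temperature_C", "reaction_time_s"))
  one_hot <- function(values, levels, prefix) {
    idx <- match(as.character(values), levels)
    if (anyNA(idx)) {
      abort(sprintf("Value '%s' not in the %s vocabulary.",
                    as.character(values)[which(is.na(idx))[1]], prefix),
            class = "amidescreen_out_of_vocabulary")
    }
    m <- matrix(0L, length(values), length(levels),
                dimnames = list(NULL, paste0(prefix, "_", levels)))
    m[cbind(seq_along(values), idx)] <- 1L
    m
  }
  cbind(one_hot(dataset$agent_id, vocab$agents, "agent"),
        one_hot(dataset$temperature_C, vocab$temperatures, "temp"),
        one_hot(dataset$reaction_time_s, vocab$times, "time"))
}

#' Define a feature set
#'
#' @param name Short identifier.
#' @param blocks Non-empty subset of `"reaction_fp"`, `"product_fp"`,
#'   `"conditions"`, `"properties"` (the property block carries the pKa
#'   columns when supplied).
#' @param fp_variant Fingerprint variant, see [circular_count_fp()].
#' @param fp_n_bits Folded fingerprint length per block.
#' @param fp_radius Circular-environment radius.
#' @return A `feature_set_spec` list.
#' @export
feature_set_spec <- function(name, blocks,
                             fp_variant = c("circular", "circular_path"),
                             fp_n_bits = 2048, fp_radius = 3) {
  fp_variant <- match.arg(fp_variant)
  allowed <- c("reaction_fp", "product_fp", "conditions", "properties")
  blocks <- unique(blocks)
  if (length(blocks) == 0 || !all(blocks %in% allowed)) {
    abort(paste0("`blocks` must be a non-empty subset of: ",
                 paste(allowed, collapse = ", "), "."),
          class = "amidescreen_invalid_spec")
  }
  structure(list(name = name, blocks = blocks, fp_variant = fp_variant,
                 fp_n_bits = fp_n_bits, fp_radius = fp_radius),
            class = "feature_set_spec")
}

#' The default 12-entry feature-set registry
#'
#' Crosses three fingerprint choices (reaction fingerprint, product
#' fingerprint, both) with the optional condition and property blocks:
#' 3 x 2 x 2 = 12 named feature sets. The registry is a plain named list and
#' can be replaced or extended freely.
#'
#' @param fp_variant,fp_n_bits,fp_radius Passed to every [feature_set_spec()].
#' @return A named list of 12 `feature_set_spec`s.
#' @examples
#' names(feature_set_registry())
#' @export
feature_set_registry <- function(fp_variant = "circular", fp_n_bits = 2048,
                                 fp_radius = 3) {
  fp_choices <- list(rfp = "reaction_fp", pfp = "product_fp",
                     rfp_pfp = c("reaction_fp", "product_fp"))
  specs <- list()
  for (fp_name in names(fp_choices)) {
    for (with_cond in c(FALSE, TRUE)) {
      for (with_props in c(FALSE, TRUE)) {
        blocks <- c(fp_choices[[fp_name]],
                    if (with_cond) "conditions",
                    if (with_props) "properties")
        nm <- paste(c(fp_name, if (with_cond) "cond", if (with_props) "props"),
                    collapse = "_")
        specs[[nm]] <- feature_set_spec(nm, blocks, fp_variant = fp_variant,
                                        fp_n_bits = fp_n_bits,
                                        fp_radius = fp_radius)
      }
    }
  }
  specs
}

#' Fit / apply a column standardizer
#'
#' Continuous feature blocks are standardized with statistics fitted on
#' training rows only; the fitted standardizer is then applied unchanged to
#' held-out rows. Zero-variance columns get scale 1.
#'
#' @param X Numeric matrix with column names.
#' @param cols Columns to standardize.
#' @return `fit_standardizer()` returns a `standardizer`; `apply_standardizer()`
#'   returns the transformed matrix.
#' @keywords internal
#' @export
fit_standardizer <- function(X, cols = colnames(X)) {
  cols <- intersect(cols, colnames(X))
  ctr <- colMeans(X[, cols, drop = FALSE])
  scl <- apply(X[, cols, drop = FALSE], 2, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  structure(list(cols = cols, center = ctr, scale = scl), class = "standardizer")
}

#' @rdname fit_standardizer
#' @param s A fitted `standardizer`.
#' @export
apply_standardizer <- function(X, s) {
  if (is.null(s) || length(s$cols) == 0) return(X)
  X[, s$cols] <- sweep(sweep(X[, s$cols, drop = FALSE], 2, s$center), 2,
                       s$scale, "/")
  X
}

#' Read reagent property and pKa tables
#'
#' Properties arrive in long format (`reagent_id, property_name, value`) and
#' are pivoted wide; pKa tables are wide (`reagent_id, pka1..pka4`). Missing
#' pKa values are median-imputed at assembly time with a companion indicator
#' column.
#'
#' @param path CSV path.
#' @return A wide tibble keyed by `reagent_id`.
#' @export
read_property_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  check_record_columns(d, c("reagent_id", "property_name", "value"))
  tidyr::pivot_wider(d, id_cols = "reagent_id",
                     names_from = "property_name", values_from = "value")
}

#' @rdname read_property_csv
#' @export
read_pka_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  check_record_columns(d, c("reagent_id", "pka1"))
  d
}

# median-impute numeric columns; add <col>_missing indicators where needed
impute_with_indicators <- function(tbl) {
  num_cols <- names(tbl)[vapply(tbl, is.numeric, TRUE)]
  for (cl in num_cols) {
    nas <- is.na(tbl[[cl]])
    if (any(nas)) {
      med <- median(tbl[[cl]], na.rm = TRUE)
      if (!is.finite(med)) med <- 0
      tbl[[paste0(cl, "_missing")]] <- as.numeric(nas)
      tbl[[cl]][nas] <- med
    }
  }
  tbl
}

reagent_property_block <- function(dataset, properties, prefix, id_col) {
  idx <- match(dataset[[id_col]], properties$reagent_id)
  if (anyNA(idx)) {
    abort(sprintf("No properties for reagent '%s'.",
                  dataset[[id_col]][which(is.na(idx))[1]]),
          class = "amidescreen_missing_block")
  }
  vals <- properties[idx, setdiff(names(properties), "reagent_id"), drop = FALSE]
  m <- as.matrix(vals)
  colnames(m) <- paste0(prefix, "_", colnames(m))
  m
}

#' Assemble a model feature matrix and label vector
#'
#' Builds one feature row per non-missing record of a labelled dataset by
#' concatenating the blocks named in the feature-set spec, in declared order:
#' reaction fingerprint, product fingerprint, condition one-hot, reagent
#' properties (acid block then amine block, pKa columns included, median
#' imputation with indicator columns). The reaction fingerprint subtracts the
#' acid and amine fingerprints from the product fingerprint; the coupling
#' agent enters only through the condition one-hot. Continuous property
#' columns are standardized with statistics fitted on these rows (or with a
#' supplied, previously fitted standardizer for held-out data).
#'
#' @param dataset A labelled dataset. Rows with `label == "missing"` are
#'   dropped.
#' @param spec A [feature_set_spec()].
#' @param reagents Reagent table with SMILES for every acid and amine
#'   (required when the spec includes a fingerprint block).
#' @param properties Wide property tibble keyed by `reagent_id` (required when
#'   the spec includes the property block).
#' @param vocab Condition vocabulary; pass the full campaign's vocabulary when
#'   assembling subsets so widths agree across splits.
#' @param standardizer Optional previously fitted standardizer.
#' @return A list: `X` (numeric matrix), `y` (0/1 integer vector, successful
#'   = 1), `row_keys` (tibble of identifying columns, same order), and
#'   `standardizer`.
#' @export
assemble_features <- function(dataset, spec, reagents = NULL,
                              properties = NULL,
                              vocab = condition_vocabulary(dataset),
                              standardizer = NULL) {
  stopifnot(inherits(spec, "feature_set_spec"))
  check_labelled(dataset)
  d <- dataset |> filter(.data$label != "missing")
  if (nrow(d) == 0) abort("No non-missing records to featurize.",
                          class = "amidescreen_empty_features")
  blocks <- list()

  needs_fp <- any(c("reaction_fp", "product_fp") %in% spec$blocks)
  if (needs_fp) {
    if (is.null(reagents) || !"smiles" %in% names(reagents)) {
      abort("Fingerprint blocks need a `reagents` table with SMILES.",
            class = "amidescreen_missing_block")
    }
    smiles_of <- setNames(reagents$smiles, reagents$id)
    pairs <- distinct(d, .data$acid_id, .data$amine_id)
    need <- unique(c(pairs$acid_id, pairs$amine_id))
    if (anyNA(smiles_of[need])) {
      abort(sprintf("Missing SMILES for reagent '%s'.",
                    need[which(is.na(smiles_of[need]))[1]]),
            class = "amidescreen_missing_block")
    }
    fp <- function(s) cached_fp(s, spec$fp_radius, spec$fp_n_bits, spec$fp_variant)
    pair_rows <- purrr::pmap(pairs, function(acid_id, amine_id) {
      prod_smiles <- amide_product_smiles(smiles_of[[acid_id]],
                                          smiles_of[[amine_id]])
      pfp <- fp(prod_smiles)
      list(product = as.integer(pfp),
           reaction = as.integer(reaction_fingerprint(
             pfp, list(fp(smiles_of[[acid_id]]), fp(smiles_of[[amine_id]])))))
    })
    key <- paste(pairs$acid_id, pairs$amine_id)
    row_idx <- match(paste(d$acid_id, d$amine_id), key)
    if ("reaction_fp" %in% spec$blocks) {
      m <- do.call(rbind, lapply(pair_rows, `[[`, "reaction"))[row_idx, , drop = FALSE]
      colnames(m) <- paste0("rfp_", seq_len(ncol(m)))
      blocks$reaction_fp <- m
    }
    if ("product_fp" %in% spec$blocks) {
      m <- do.call(rbind, lapply(pair_rows, `[[`, "product"))[row_idx, , drop = FALSE]
      colnames(m) <- paste0("pfp_", seq_len(ncol(m)))
      blocks$product_fp <- m
    }
  }
  if ("conditions" %in% spec$blocks) {
    blocks$conditions <- encode_conditions(d, vocab)
  }
  prop_cols <- character()
  if ("properties" %in% spec$blocks) {
    if (is.null(properties)) {
      abort("The property block needs a `properties` table.",
            class = "amidescreen_missing_block")
    }
    props <- impute_with_indicators(properties)
    pm <- cbind(reagent_property_block(d, props, "acid", "acid_id"),
                reagent_property_block(d, props, "amine", "amine_id"))
    if (anyNA(pm)) abort("NaN left in the property block after imputation.",
                         class = "amidescreen_data_error")
    prop_cols <- colnames(pm)
    blocks$properties <- pm
  }
  X <- do.call(cbind, blocks[intersect(
    c("reaction_fp", "product_fp", "conditions", "properties"), names(blocks))])
  storage.mode(X) <- "double"
  if (length(prop_cols)) {
    # indicator columns are binary flags, left unscaled
    cont <- prop_cols[!grepl("_missing$", prop_cols)]
    if (is.null(standardizer)) standardizer <- fit_standardizer(X, cont)
    X <- apply_standardizer(X, standardizer)
  }
  y <- as.integer(d$label == "successful")
  list(X = X, y = y,
       row_keys = d[, intersect(c("campaign_id", "acid_id", "amine_id",
                                  "agent_id", "harshness_rank"), names(d))],
       standardizer = standardizer)
}
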