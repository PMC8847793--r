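#' Item-level measure means
#'
#' Aggregates viewing-time records to the item (target word) level: the mean
#' SFD, GD and TVT over participants, computed only over non-excluded
#' (non-missing) observations, joined with the per-word predictor table and
#' restricted to target words. A word with no observation for a measure has
#' `NA` for that measure's mean and is dropped from that measure's
#' correlation.
#'
#' @param records Viewing-time records ([compute_viewing_times()]).
#' @param predictors Predictor table ([assemble_predictors()]).
#' @return A tibble with one row per target word: `sentence_id`, `word_pos`,
#'   `mean_sfd`, `mean_gd`, `mean_tvt`, `n_obs` and all predictor columns.
#' @export
item_summaries <- function(records, predictors) {
  check_columns(records, c("sentence_id", "word_pos", "sfd", "gd", "tvt"), "records")
  items <- records |>
    group_by(.data$sentence_id, .data$word_pos) |>
    summarise(
      mean_sfd = if (all(is.na(.data$sfd))) NA_real_ else mean(.data$sfd, na.rm = TRUE),
      mean_gd = if (all(is.na(.data$gd))) NA_real_ else mean(.data$gd, na.rm = TRUE),
      mean_tvt = if (all(is.na(.data$tvt))) NA_real_ else mean(.data$tvt, na.rm = TRUE),
      n_obs = dplyr::n(),
      .groups = "drop"
    )
  predictors |>
    filter(.data$is_target) |>
    dplyr::inner_join(items, by = c("sentence_id", "word_pos"))
}

#' Item-level correlations of predictors with measure means
#'
#' Pearson correlations among the chosen predictor columns and the item
#' means of SFD, GD and TVT, using pairwise-complete observations. With
#' `transformed = TRUE` (default) the logit/log10 predictor columns are
#' used; with `FALSE` the raw probability columns (`*_raw`). Zero-variance
#' columns give `NA` correlations with a warning rather than an error.
#'
#' @param items Item table from [item_summaries()].
#' @param sources Predictor sources to include.
#' @param transformed Use transformed (`TRUE`) or raw (`FALSE`) predictor
#'   scales.
#' @param covariates Additional covariate columns (default length and
#'   frequency class when present).
#' @return A correlation matrix (predictors and measures in both
#'   dimensions).
#' @export
item_correlations <- function(items,
                              sources = c("ccp", "ngram", "topic", "rnn"),
                              transformed = TRUE,
                              covariates = intersect(
                                c("length", "freq"), names(items)
                              )) {
  if (nrow(items) < 3) {
    stop_lexpred("need at least 3 items", "lexpred_validation_error")
  }
  pred_cols <- if (transformed) sources else paste0(sources, "_raw")
  cols <- c(covariates, pred_cols, c("mean_sfd", "mean_gd", "mean_tvt"))
  cols <- intersect(cols, names(items))
  m <- as.matrix(items[cols])
  zero_var <- apply(m, 2, function(x) sd(x, na.rm = TRUE) == 0 || all(is.na(x)))
  if (any(zero_var)) {
    warn(sprintf(
      "zero-variance column(s), correlations undefined: %s",
      paste(cols[zero_var], collapse = ", ")
    ))
  }
  suppressWarnings(cor(m, use = "pairwise.complete.obs"))
}
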