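#' Logit transform of cloze completion probability
#'
#' `CCP = 0.5 * log(ccp / (1 - ccp))` on the natural log, after clamping the
#' empirical proportion into `[1/(2K), 1 - 1/(2K)]`, where `K` is the number
#' of complete cloze protocols (83 in the reference norms): proportions of
#' exactly 0 and 1 are replaced by `1/(2K)` and `1 - 1/(2K)`, and clamping
#' extends the same replacement to any value beyond those bounds for
#' numerical safety (identical behaviour on exact 0/1 inputs).
#'
#' @param ccp Numeric vector of completion proportions in `[0, 1]`.
#' @param K Number of complete protocols (>= 1). Default 83.
#' @return Transformed predictability values.
#' @examples
#' logit_ccp(c(0, 0.5, 1), K = 83)
#' @export
logit_ccp <- function(ccp, K = 83) {
  if (K < 1) stop_lexpred("K must be >= 1", "lexpred_validation_error")
  if (any(ccp < 0 | ccp > 1, na.rm = TRUE)) {
    stop_lexpred("ccp must lie in [0, 1]", "lexpred_validation_error")
  }
  eps <- 1 / (2 * K)
  p <- pmin(pmax(ccp, eps), 1 - eps)
  0.5 * log(p / (1 - p))
}

#' Log10 transform of language-model probabilities
#'
#' @param p Numeric vector of strictly positive probabilities (language-model
#'   probabilities are strictly positive by construction; `NA` is passed
#'   through for out-of-vocabulary words).
#' @return `log10(p)`.
#' @export
transform_lm <- function(p) {
  if (any(p <= 0, na.rm = TRUE)) {
    stop_lexpred("probabilities must be > 0", "lexpred_domain_error")
  }
  log10(p)
}

#' Word probabilities for a stimulus set
#'
#' Generic incremental-probability contract shared by the three language
#' models: one probability per stimulus word given its within-sentence
#' history, `NA` where the word is outside the model's training vocabulary.
#'
#' @param model A trained `ngram_model`, `topic_model` or `rnn_model`.
#' @param stimuli A stimulus tibble.
#' @param ... Passed to the model-specific scorer.
#' @return A tibble `sentence_id`, `word_pos`, `prob`.
#' @export
word_probabilities <- function(model, stimuli, ...) {
  UseMethod("word_probabilities")
}

# internal: run a per-sentence scorer across the stimulus set
score_stimuli <- function(stimuli, scorer) {
  check_columns(stimuli, c("sentence_id", "word_pos", "word"), "stimuli")
  stimuli |>
    arrange(.data$sentence_id, .data$word_pos) |>
    group_by(.data$sentence_id) |>
    reframe(word_pos = .data$word_pos, prob = scorer(.data$word))
}

#' @rdname word_probabilities
#' @export
word_probabilities.ngram_model <- function(model, stimuli, ...) {
  score_stimuli(stimuli, function(tokens) {
    known <- tokens %in% model$vocab
    probs <- rep(NA_real_, length(tokens))
    for (i in which(known)) {
      probs[i] <- ngram_prob(model, tokens[i], tokens[seq_len(i - 1)])
    }
    probs
  })
}

#' @rdname word_probabilities
#' @export
word_probabilities.topic_model <- function(model, stimuli, ...) {
  score_stimuli(stimuli, function(tokens) {
    sentence_topic_probs(model, tokens, ...)$prob
  })
}

#' @rdname word_probabilities
#' @export
word_probabilities.rnn_model <- function(model, stimuli, ...) {
  score_stimuli(stimuli, function(tokens) {
    known <- tokens %in% model$vocab
    probs <- rep(NA_real_, length(tokens))
    for (i in which(known)) {
      ok_prefix <- tokens[seq_len(i - 1)]
      ok_prefix <- ok_prefix[ok_prefix %in% model$vocab_in]
      d <- rnn_next_distribution(model, ok_prefix, ...)
      probs[i] <- d[[tokens[i]]]
    }
    probs
  })
}

#' Assemble the per-target-word predictor table
#'
#' Joins cloze norms and language-model probabilities onto the stimulus set,
#' applies the predictor transforms (logit with factor 0.5 and `1/(2K)`
#' replacement for cloze; log10 for model probabilities), aligns last- and
#' next-word predictability by position shift within each sentence, adds
#' word length and Leipzig-style frequency class (also shifted), and flags
#' exclusions: the first and the last word of every sentence, and words
#' absent from the training vocabulary (out-of-vocabulary, OOV), which are
#' invalid as targets for all predictability sources but still serve as
#' context for their neighbours. The number of remaining target words is
#' reported as attribute `n_targets` and satisfies
#' `total words - 2 * sentences - OOV non-boundary words`.
#'
#' @param stimuli A stimulus tibble.
#' @param cloze A cloze tibble (with `ccp`), e.g. from
#'   [generate_cloze_norms()] or [read_cloze()].
#' @param probabilities Named list of word-probability tibbles (from
#'   [word_probabilities()]); names become predictor column names, typically
#'   `ngram`, `topic`, `rnn`.
#' @param vocabulary Optional training-corpus vocabulary
#'   ([build_vocabulary()]) used for frequency classes and the
#'   `in_training_vocab` flag; if omitted, OOV status is inferred from
#'   missing model probabilities.
#' @param K Number of cloze protocols for the logit transform. Default 83.
#' @return A predictor tibble with one row per stimulus word: raw (`*_raw`)
#'   and transformed predictor columns for `ccp` and each model source,
#'   their `_last`/`_next` shifts, `length`/`freq` covariates with shifts,
#'   and flags `is_first`, `is_last`, `oov`, `is_target`.
#' @export
assemble_predictors <- function(stimuli, cloze, probabilities,
                                vocabulary = NULL, K = 83) {
  check_columns(stimuli, c("sentence_id", "word_pos", "word"), "stimuli")
  if (!all(c("is_first", "is_last") %in% names(stimuli))) {
    stimuli <- finalize_stimuli(stimuli)
  }
  check_columns(cloze, c("sentence_id", "word_pos", "ccp"), "cloze norms")
  stopifnot(is.list(probabilities), !is.null(names(probabilities)))

  out <- stimuli |>
    select(
      "sentence_id", "word_pos", "word", "word_length", "is_first", "is_last"
    ) |>
    rename(length = "word_length")

  cl <- cloze[c("sentence_id", "word_pos", "ccp")]
  out <- dplyr::left_join(out, cl, by = c("sentence_id", "word_pos"))
  if (anyNA(out$ccp)) {
    bad <- out |> filter(is.na(.data$ccp))
    stop_lexpred(
      sprintf(
        "cloze norms do not cover stimulus word(s): %s",
        paste(head(paste0(bad$sentence_id, ":", bad$word_pos), 5), collapse = ", ")
      ),
      "lexpred_join_error"
    )
  }
  out <- out |>
    rename(ccp_raw = "ccp") |>
    mutate(ccp = logit_ccp(.data$ccp_raw, K = K))

  for (src in names(probabilities)) {
    pr <- probabilities[[src]]
    check_columns(pr, c("sentence_id", "word_pos", "prob"), paste0(src, " probabilities"))
    pr <- setNames(
      pr[c("sentence_id", "word_pos", "prob")],
      c("sentence_id", "word_pos", paste0(src, "_raw"))
    )
    out <- dplyr::left_join(out, pr, by = c("sentence_id", "word_pos"))
    out[[src]] <- transform_lm(out[[paste0(src, "_raw")]])
  }

  if (!is.null(vocabulary)) {
    out$in_training_vocab <- out$word %in% vocabulary$token
    suppressWarnings(out$freq <- frequency_class(out$word, vocabulary))
  } else {
    raw_cols <- paste0(names(probabilities), "_raw")
    out$in_training_vocab <-
      rowSums(is.na(as.matrix(out[raw_cols]))) == 0
    out$freq <- NA_integer_
  }

  shift_cols <- c("ccp", names(probabilities), "length", "freq")
  out <- out |>
    arrange(.data$sentence_id, .data$word_pos) |>
    group_by(.data$sentence_id) |>
    mutate(across(
      dplyr::all_of(shift_cols),
      list(last = ~ dplyr::lag(.x), "next" = ~ dplyr::lead(.x)),
      .names = "{.col}_{.fn}"
    )) |>
    ungroup() |>
    mutate(
      oov = !.data$in_training_vocab,
      is_target = !.data$is_first & !.data$is_last & !.data$oov
    )
  attr(out, "n_targets") <- sum(out$is_target)
  out
}
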