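#' Construct a corpus tibble
#'
#' A corpus is a tibble with one row per sentence: `sentence_id`, `doc_id`
#' (grouping of sentences into documents for topic-model training) and
#' `tokens` (a list column of character vectors). Empty sentences are
#' rejected.
#'
#' @param tokens A list of character vectors, one per sentence.
#' @param doc_id Optional integer vector of document ids (default: one
#'   document per sentence).
#' @return A corpus tibble.
#' @export
new_corpus <- function(tokens, doc_id = NULL) {
  stopifnot(is.list(tokens))
  if (any(lengths(tokens) == 0)) {
    stop_lexpred("corpus contains an empty sentence", "lexpred_validation_error")
  }
  if (is.null(doc_id)) doc_id <- seq_along(tokens)
  stopifnot(length(doc_id) == length(tokens))
  tibble(
    sentence_id = seq_along(tokens),
    doc_id = as.integer(doc_id),
    tokens = tokens
  )
}

#' Write / read a corpus as plain text
#'
#' One sentence per line, space-tokenized. Documents are separated by blank
#' lines; with one sentence per document (the default produced by
#' [generate_corpus()] with `sentences_per_doc = 1`) no blank lines are
#' written. A `# seed:` comment header records the generator seed when the
#' corpus carries one.
#'
#' @param corpus A corpus tibble.
#' @param path File path.
#' @return `write_corpus()` returns `path` invisibly; `read_corpus()` returns
#'   a corpus tibble.
#' @export
write_corpus <- function(corpus, path) {
  check_columns(corpus, c("sentence_id", "doc_id", "tokens"), "corpus")
  lines <- character(0)
  cfg <- attr(corpus, "config")
  if (!is.null(cfg$seed)) lines <- c(lines, paste0("# seed: ", cfg$seed))
  docs <- split(corpus$tokens, corpus$doc_id)
  body <- lapply(docs, function(d) vapply(d, paste, "", collapse = " "))
  if (length(body) == length(corpus$tokens)) {
    lines <- c(lines, unlist(body, use.names = FALSE))
  } else {
    # blank line between documents
    lines <- c(lines, head(unlist(lapply(body, c, ""), use.names = FALSE), -1))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_corpus
#' @param casefold Passed to [tokenize()].
#' @export
read_corpus <- function(path, casefold = TRUE) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^#", lines)]
  doc <- cumsum(!nzchar(lines)) + 1L
  keep <- nzchar(lines)
  toks <- tokenize_lines(lines[keep], casefold = casefold)
  new_corpus(toks, doc_id = match(doc[keep], unique(doc[keep])))
}

#' Stimulus set from a corpus
#'
#' Builds the per-word stimulus table (one row per word) from tokenized
#' sentences: sentence id, 1-based word position, word form, word length in
#' letters, and first/last-word flags (computed, never stored in inputs).
#'
#' @param corpus A corpus tibble.
#' @return A stimulus tibble with columns `sentence_id`, `word_pos`, `word`,
#'   `word_length`, `is_first`, `is_last`.
#' @export
as_stimuli <- function(corpus) {
  check_columns(corpus, c("sentence_id", "tokens"), "corpus")
  out <- tibble(
    sentence_id = rep(corpus$sentence_id, lengths(corpus$tokens)),
    word = unlist(corpus$tokens, use.names = FALSE)
  ) |>
    group_by(.data$sentence_id) |>
    mutate(word_pos = dplyr::row_number()) |>
    ungroup()
  finalize_stimuli(out)
}

# internal: add derived columns + validate contiguity of word positions
finalize_stimuli <- function(df) {
  check_columns(df, c("sentence_id", "word_pos", "word"), "stimuli")
  bad <- df |>
    group_by(.data$sentence_id) |>
    summarise(ok = all(sort(.data$word_pos) == seq_len(dplyr::n()))) |>
    filter(!.data$ok)
  if (nrow(bad) > 0) {
    stop_lexpred(
      sprintf(
        "word positions not contiguous from 1 in sentence(s): %s",
        paste(head(bad$sentence_id, 5), collapse = ", ")
      ),
      "lexpred_validation_error"
    )
  }
  df |>
    arrange(.data$sentence_id, .data$word_pos) |>
    group_by(.data$sentence_id) |>
    mutate(
      word_length = nchar(.data$word),
      is_first = .data$word_pos == 1L,
      is_last = .data$word_pos == max(.data$word_pos)
    ) |>
    ungroup()
}

# internal: shared TSV reader with typed validation and line numbers
read_lexpred_tsv <- function(path, col_types, what) {
  out <- suppressWarnings(readr::read_tsv(
    path,
    col_types = col_types, comment = "#",
    progress = FALSE, show_col_types = FALSE
  ))
  check_columns(out, names(col_types$cols), what)
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    stop_lexpred(
      sprintf(
        "malformed %s file '%s': e.g. line %d, column '%s' (%s); %d problem row(s) in all",
        what, path, probs$row[1], names(col_types$cols)[probs$col[1]],
        probs$expected[1], nrow(probs)
      ),
      "lexpred_format_error"
    )
  }
  out
}

# internal: shared TSV writer with a seed comment header
write_lexpred_tsv <- function(df, path, seed = attr(df, "seed")) {
  if (!is.null(seed)) {
    writeLines(paste0("# seed: ", seed), path, useBytes = TRUE)
    readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_tsv(df, path)
  }
  invisible(path)
}

#' Read and write stimulus, cloze and fixation tables
#'
#' Tab-separated with a header row and UTF-8 encoding; `#`-prefixed comment
#' lines (used to record seeds) are skipped. Malformed rows are reported with
#' line numbers, and a missing required column raises a format error naming
#' the column.
#'
#' Columns: stimuli `sentence_id, word_pos, word`; cloze `sentence_id,
#' word_pos, completions_total, target_count`; fixations `participant, trial,
#' sentence_id, word_pos, fix_index, duration_ms, landing_letter`.
#'
#' @param path File path.
#' @return A validated tibble of the respective kind.
#' @export
read_stimuli <- function(path) {
  ct <- readr::cols(
    sentence_id = readr::col_integer(),
    word_pos = readr::col_integer(),
    word = readr::col_character()
  )
  finalize_stimuli(read_lexpred_tsv(path, ct, "stimuli"))
}

#' @rdname read_stimuli
#' @export
read_cloze <- function(path) {
  ct <- readr::cols(
    sentence_id = readr::col_integer(),
    word_pos = readr::col_integer(),
    completions_total = readr::col_integer(),
    target_count = readr::col_integer()
  )
  out <- read_lexpred_tsv(path, ct, "cloze norms")
  mutate(out, ccp = .data$target_count / .data$completions_total)
}

#' @rdname read_stimuli
#' @export
read_fixations <- function(path) {
  ct <- readr::cols(
    participant = readr::col_integer(),
    trial = readr::col_integer(),
    sentence_id = readr::col_integer(),
    word_pos = readr::col_integer(),
    fix_index = readr::col_integer(),
    duration_ms = readr::col_double(),
    landing_letter = readr::col_integer()
  )
  read_lexpred_tsv(path, ct, "fixation report")
}

#' @rdname read_stimuli
#' @param df Table to write.
#' @export
write_stimuli <- function(df, path) {
  check_columns(df, c("sentence_id", "word_pos", "word"), "stimuli")
  write_lexpred_tsv(df[c("sentence_id", "word_pos", "word")], path,
    seed = attr(df, "seed")
  )
}

#' @rdname read_stimuli
#' @export
write_cloze <- function(df, path) {
  check_columns(
    df, c("sentence_id", "word_pos", "completions_total", "target_count"),
    "cloze norms"
  )
  write_lexpred_tsv(
    df[c("sentence_id", "word_pos", "completions_total", "target_count")],
    path,
    seed = attr(df, "seed")
  )
}

#' @rdname read_stimuli
#' @export
write_fixations <- function(df, path) {
  cols <- c(
    "participant", "trial", "sentence_id", "word_pos", "fix_index",
    "duration_ms", "landing_letter"
  )
  check_columns(df, cols, "fixation report")
  write_lexpred_tsv(df[cols], path, seed = attr(df, "seed"))
}
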