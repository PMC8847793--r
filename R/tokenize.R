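#' Tokenize a line of text
#'
#' Splits on whitespace, strips punctuation from word edges, and optionally
#' casefolds. Casefolding is usually wanted for English material; for German,
#' where capitalised nouns are lexically distinctive, `casefold = FALSE` is the
#' more faithful choice. The policy is configurable throughout the package.
#'
#' @param line A single character string.
#' @param casefold Lowercase the tokens? Default `TRUE`.
#' @return A character vector of tokens; an empty line yields `character(0)`.
#' @examples
#' tokenize("The cat sat.")
#' @export
tokenize <- function(line, casefold = TRUE) {
  stopifnot(is.character(line), length(line) == 1)
  toks <- strsplit(trimws(line), "\\s+")[[1]]
  toks <- gsub("^[^[:alnum:]]+|[^[:alnum:]]+$", "", toks)
  toks <- toks[nzchar(toks)]
  if (casefold) toks <- tolower(toks)
  toks
}

#' Tokenize many lines at once
#'
#' @param lines Character vector of lines.
#' @inheritParams tokenize
#' @return A list of token vectors, one per line.
#' @export
tokenize_lines <- function(lines, casefold = TRUE) {
  lapply(lines, tokenize, casefold = casefold)
}

#' Build a vocabulary from a corpus
#'
#' Tokens are assigned dense integer ids `0..V-1` in decreasing order of
#' frequency (ties broken alphabetically). Sentence-begin, sentence-end and
#' unknown markers are carried as attributes rather than vocabulary rows; the
#' language models add them to their event spaces as needed.
#'
#' @param corpus A corpus tibble as returned by [generate_corpus()] or
#'   [read_corpus()].
#' @return A tibble with columns `token`, `id`, `count`, carrying attributes
#'   `bos`, `eos`, `unk`.
#' @export
build_vocabulary <- function(corpus) {
  check_columns(corpus, "tokens", "corpus")
  counts <- table(unlist(corpus$tokens))
  if (length(counts) == 0) {
    stop_lexpred("corpus contains no tokens", "lexpred_validation_error")
  }
  tb <- tibble(token = names(counts), count = as.integer(counts)) |>
    arrange(desc(.data$count), .data$token) |>
    mutate(id = dplyr::row_number() - 1L) |>
    select("token", "id", "count")
  attr(tb, "bos") <- "<s>"
  attr(tb, "eos") <- "</s>"
  attr(tb, "unk") <- "<unk>"
  tb
}

#' Leipzig-style word frequency classes
#'
#' The frequency class of a word relates its corpus count to the count of the
#' most frequent word: the most common word is `2^class` times more frequent
#' than the word whose class is given. The reference word itself has class 0,
#' and classes are rounded to the nearest integer and clipped at 0.
#'
#' @param tokens Character vector of words to classify.
#' @param vocabulary A vocabulary tibble from [build_vocabulary()], or any
#'   data frame with `token` and `count` columns.
#' @return Integer vector of classes; tokens absent from the vocabulary give
#'   `NA` with a warning.
#' @examples
#' v <- tibble::tibble(token = c("the", "cat"), count = c(1024L, 256L))
#' frequency_class(c("the", "cat"), v)
#' @export
frequency_class <- function(tokens, vocabulary) {
  check_columns(vocabulary, c("token", "count"), "vocabulary")
  ref <- max(vocabulary$count)
  cnt <- vocabulary$count[match(tokens, vocabulary$token)]
  if (anyNA(cnt)) {
    warn(sprintf(
      "%d token(s) not in vocabulary; frequency class set to NA",
      sum(is.na(cnt))
    ))
  }
  cls <- as.integer(pmax(0, round(log2(ref / cnt))))
  cls
}

#' Frequency classes for a whole vocabulary
#'
#' @inheritParams frequency_class
#' @return A tibble `token`, `freq_class` with attribute `reference_token`,
#'   the most frequent word (class 0).
#' @export
frequency_class_table <- function(vocabulary) {
  check_columns(vocabulary, c("token", "count"), "vocabulary")
  ref_tok <- vocabulary$token[which.max(vocabulary$count)]
  out <- tibble(
    token = vocabulary$token,
    freq_class = frequency_class(vocabulary$token, vocabulary)
  )
  attr(out, "reference_token") <- ref_tok
  out
}
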