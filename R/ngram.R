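#' Train an interpolated Kneser-Ney n-gram language model
#'
#' Sentences are padded with `n - 1` begin tokens and one end token; the end
#' token is part of the event space so that every conditional distribution
#' normalizes exactly. Smoothing is interpolated Kneser-Ney with one discount
#' per order: the top order uses raw counts, lower orders use continuation
#' counts (the number of distinct left-extensions), and the recursion bottoms
#' out at the continuation-unigram distribution interpolated with the uniform
#' distribution over the event vocabulary.
#'
#' Discounts default to the count-of-counts estimate `D_k = n1 / (n1 + 2 n2)`
#' at each order (n1, n2 = number of grams seen once / twice at that order's
#' count table). Degenerate tables (no singletons, or no doubletons, which
#' would give D outside `[0, 1)`) fall back to `D = 0.5`, and all discounts
#' are clipped to `[0, 0.999]`.
#'
#' @param corpus A corpus tibble.
#' @param n Model order (default 3, i.e. trigram).
#' @param discounts Optional numeric vector of length `n` (or scalar) of
#'   discounts overriding the count-of-counts estimate; useful to approach the
#'   maximum-likelihood estimate as discounts tend to 0.
#' @return An object of class `ngram_model`.
#' @export
train_ngram <- function(corpus, n = 3, discounts = NULL) {
  check_columns(corpus, "tokens", "corpus")
  n <- as.integer(n)
  if (n < 1) stop_lexpred("order n must be >= 1", "lexpred_config_error")
  total_tokens <- sum(lengths(corpus$tokens))
  if (nrow(corpus) == 0 || total_tokens < n) {
    stop_lexpred(
      "training corpus is empty or smaller than the model order",
      "lexpred_training_error"
    )
  }
  bos <- "<s>"
  eos <- "</s>"
  vocab <- sort(unique(unlist(corpus$tokens, use.names = FALSE)))

  # raw counts at the top order
  top <- new.env(parent = emptyenv())
  for (toks in corpus$tokens) {
    padded <- c(rep(bos, n - 1), toks, eos)
    L <- length(padded)
    for (i in seq_len(L - n + 1)) {
      key <- paste(padded[i:(i + n - 1)], collapse = " ")
      top[[key]] <- (top[[key]] %||% 0) + 1
    }
  }
  build_ngram_model(top, n, vocab, total_tokens, discounts)
}

# internal: derive all lower-order continuation tables, context aggregates
# and discounts from the top-order raw count table
build_ngram_model <- function(top, n, vocab, total_tokens, discounts = NULL) {
  bos <- "<s>"
  eos <- "</s>"
  event_vocab <- c(vocab, eos)
  # per-order tables: counts (raw at order n, continuation counts below),
  # context totals and context type counts
  counts <- vector("list", n)
  ctx_total <- vector("list", n)
  ctx_types <- vector("list", n)
  counts[[n]] <- top
  for (k in seq(n, 1)) {
    if (k < n) {
      # continuation counts: number of distinct left-extensions at order k+1
      cnt <- new.env(parent = emptyenv())
      for (key in ls(counts[[k + 1]])) {
        toks <- strsplit(key, " ", fixed = TRUE)[[1]]
        suffix <- paste(toks[-1], collapse = " ")
        if (toks[length(toks)] == bos) next # grams ending in <s> are padding only
        cnt[[suffix]] <- (cnt[[suffix]] %||% 0) + 1
      }
      counts[[k]] <- cnt
    }
    tot <- new.env(parent = emptyenv())
    typ <- new.env(parent = emptyenv())
    for (key in ls(counts[[k]])) {
      toks <- strsplit(key, " ", fixed = TRUE)[[1]]
      if (toks[length(toks)] == bos) next
      h <- ctx_key(paste(toks[-length(toks)], collapse = " "))
      tot[[h]] <- (tot[[h]] %||% 0) + counts[[k]][[key]]
      typ[[h]] <- (typ[[h]] %||% 0) + 1
    }
    ctx_total[[k]] <- tot
    ctx_types[[k]] <- typ
  }

  # one discount per order from that order's count-of-counts
  D <- numeric(n)
  for (k in seq_len(n)) {
    vals <- unlist(mget(ls(counts[[k]]), envir = counts[[k]]), use.names = FALSE)
    n1 <- sum(vals == 1)
    n2 <- sum(vals == 2)
    D[k] <- if (n1 > 0 && n2 > 0) n1 / (n1 + 2 * n2) else 0.5
  }
  D <- pmin(pmax(D, 0), 0.999)
  if (!is.null(discounts)) {
    D <- rep_len(discounts, n)
    if (any(D < 0 | D >= 1)) {
      stop_lexpred("discounts must lie in [0, 1)", "lexpred_config_error")
    }
  }

  structure(
    list(
      n = n, vocab = vocab, event_vocab = event_vocab,
      bos = bos, eos = eos,
      counts = counts, ctx_total = ctx_total, ctx_types = ctx_types,
      D = D, total_tokens = total_tokens
    ),
    class = "ngram_model"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# internal: environments cannot hold the empty string as a key, so the empty
# (unigram) context is stored under a sentinel
ctx_key <- function(h) if (nzchar(h)) h else "\x01"

# internal: vectorized count lookup in an environment
env_lookup <- function(env, keys) {
  vapply(
    mget(keys, envir = env, ifnotfound = list(0)),
    identity, numeric(1),
    USE.NAMES = FALSE
  )
}

# internal: interpolated KN recursion at order k for words w given history h
kn_level <- function(model, k, w, h) {
  if (k == 0) {
    return(rep(1 / length(model$event_vocab), length(w)))
  }
  h_use <- if (k > 1) tail(h, k - 1) else character(0)
  key_h <- paste(h_use, collapse = " ")
  lower <- kn_level(model, k - 1, w, h_use)
  tot <- model$ctx_total[[k]][[ctx_key(key_h)]] %||% 0
  if (tot == 0) {
    return(lower)
  }
  keys <- if (nzchar(key_h)) paste(key_h, w) else w
  cnt <- env_lookup(model$counts[[k]], keys)
  types <- model$ctx_types[[k]][[ctx_key(key_h)]] %||% 0
  D <- model$D[k]
  pmax(cnt - D, 0) / tot + D * types / tot * lower
}

#' Kneser-Ney conditional word probability
#'
#' Interpolated Kneser-Ney probability of `word` given up to `n - 1`
#' preceding tokens. Histories shorter than `n - 1` are left-padded with the
#' begin token; unseen histories back off to the lower-order distribution.
#' The probability is strictly positive and, summed over the event vocabulary
#' (words plus the end token), equals 1 for every history.
#'
#' @param model An `ngram_model`.
#' @param word Character vector of target words (all sharing `history`).
#'   Words outside the training vocabulary raise an unknown-token error;
#'   out-of-vocabulary targets are excluded upstream of any analysis.
#' @param history Character vector of preceding tokens (may be empty).
#' @return Numeric vector of probabilities.
#' @export
ngram_prob <- function(model, word, history = character(0)) {
  stopifnot(inherits(model, "ngram_model"))
  unknown <- setdiff(word, model$event_vocab)
  if (length(unknown) > 0) {
    stop_lexpred(
      sprintf(
        "unknown token(s): %s (out-of-vocabulary targets are excluded upstream)",
        paste(head(unknown, 5), collapse = ", ")
      ),
      "lexpred_unknown_token_error"
    )
  }
  h <- as.character(history)
  if (length(h) < model$n - 1) {
    h <- c(rep(model$bos, model$n - 1 - length(h)), h)
  }
  h <- tail(h, model$n - 1)
  kn_level(model, model$n, word, h)
}

#' Per-word conditional probabilities for a sentence
#'
#' One probability per word position, with the history truncated or padded
#' with begin tokens at the sentence start. Scoring is stateless: the result
#' does not depend on any other sentence scored before or after.
#'
#' @param model An `ngram_model`.
#' @param tokens Tokenized sentence (character vector).
#' @return A tibble `word_pos`, `word`, `prob`.
#' @export
sentence_ngram_probs <- function(model, tokens) {
  stopifnot(inherits(model, "ngram_model"))
  probs <- vapply(seq_along(tokens), function(i) {
    ngram_prob(model, tokens[i], history = tokens[seq_len(i - 1)])
  }, numeric(1))
  tibble(word_pos = seq_along(tokens), word = tokens, prob = probs)
}

#' @export
print.ngram_model <- function(x, ...) {
  cat(sprintf(
    "Interpolated Kneser-Ney %d-gram model: %d word types, %d tokens\n",
    x$n, length(x$vocab), x$total_tokens
  ))
  cat(sprintf(
    "discounts: %s\n",
    paste(sprintf("D%d = %.3f", seq_len(x$n), x$D), collapse = ", ")
  ))
  invisible(x)
}
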