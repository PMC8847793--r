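# Independent brute-force implementation of interpolated Kneser-Ney,
# written directly from the recursion with plain named vectors and table(),
# used as the oracle for the package's count-table implementation.

oracle_kn_tables <- function(corpus_tokens, n) {
  bos <- "<s>"
  eos <- "</s>"
  top_grams <- unlist(lapply(corpus_tokens, function(toks) {
    padded <- c(rep(bos, n - 1), toks, eos)
    L <- length(padded)
    vapply(seq_len(L - n + 1), function(i) {
      paste(padded[i:(i + n - 1)], collapse = " ")
    }, "")
  }))
  tabs <- vector("list", n)
  tabs[[n]] <- c(table(top_grams))
  if (n > 1) {
    for (k in seq(n - 1, 1)) {
      keys <- names(tabs[[k + 1]])
      split_keys <- strsplit(keys, " ", fixed = TRUE)
      last_tok <- vapply(split_keys, function(t) t[length(t)], "")
      suffixes <- vapply(split_keys, function(t) paste(t[-1], collapse = " "), "")
      # continuation count: distinct left-extensions, ignoring padding grams
      tabs[[k]] <- c(table(suffixes[last_tok != bos]))
    }
  }
  tabs
}

oracle_kn_discounts <- function(tabs) {
  vapply(tabs, function(tb) {
    n1 <- sum(tb == 1)
    n2 <- sum(tb == 2)
    d <- if (n1 > 0 && n2 > 0) n1 / (n1 + 2 * n2) else 0.5
    min(max(d, 0), 0.999)
  }, numeric(1))
}

# p(w | h) by the interpolated KN recursion; h is the full (length n-1,
# bos-padded) history, vocab the event vocabulary including the end token
oracle_kn_prob <- function(tabs, D, vocab, w, h) {
  rec <- function(k, hist) {
    if (k == 0) {
      return(1 / length(vocab))
    }
    tb <- tabs[[k]]
    hist_k <- if (k > 1) tail(hist, k - 1) else character(0)
    lower <- rec(k - 1, hist_k)
    prefix <- paste(hist_k, collapse = " ")
    keys <- names(tb)
    in_ctx <- if (k == 1) {
      !grepl(" ", keys, fixed = TRUE)
    } else {
      startsWith(keys, paste0(prefix, " ")) &
        lengths(strsplit(keys, " ", fixed = TRUE)) == k
    }
    # drop grams whose predicted word is the begin token
    last_tok <- vapply(
      strsplit(keys, " ", fixed = TRUE),
      function(t) t[length(t)], ""
    )
    in_ctx <- in_ctx & last_tok != "<s>"
    total <- sum(tb[in_ctx])
    if (total == 0) {
      return(lower)
    }
    types <- sum(in_ctx)
    key_w <- if (k == 1) w else paste(prefix, w)
    cnt <- if (key_w %in% keys) tb[[key_w]] else 0
    max(cnt - D[k], 0) / total + D[k] * types / total * lower
  }
  n <- length(tabs)
  h <- c(rep("<s>", max(0, n - 1 - length(h))), h)
  rec(n, tail(h, n - 1))
}

# full KN distribution over the event vocabulary from the oracle
oracle_kn_dist <- function(corpus_tokens, n, h, discounts = NULL) {
  tabs <- oracle_kn_tables(corpus_tokens, n)
  D <- if (is.null(discounts)) {
    oracle_kn_discounts(tabs)
  } else {
    rep_len(discounts, n)
  }
  vocab <- c(sort(unique(unlist(corpus_tokens))), "</s>")
  setNames(
    vapply(vocab, function(w) oracle_kn_prob(tabs, D, vocab, w, h), numeric(1)),
    vocab
  )
}
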