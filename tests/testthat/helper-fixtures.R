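# Shared fixtures, all generated in code.

toy_corpus <- function() {
  new_corpus(list(
    c("the", "cat", "sat"),
    c("the", "cat", "ran"),
    c("the", "dog", "sat")
  ))
}

# standard planted two-topic corpus used by the LDA recovery checks
planted_corpus <- function(seed = 11, n_sentences = 500, markov = 0) {
  generate_corpus(corpus_config(
    vocab_size = 40, n_topics = 2, n_sentences = n_sentences,
    markov_strength = markov, seed = seed
  ))
}

# stimulus set with an exact sentence/word budget, as in the reference
# eye-movement corpora; `oov_words` words (placed at word position 3 of the
# first sentences) are excluded from the accompanying vocabulary
shaped_stimuli <- function(n_sentences, n_words, oov_words = 0) {
  base <- n_words %/% n_sentences
  lens <- rep(base, n_sentences)
  extra <- n_words - base * n_sentences
  if (extra > 0) lens[seq_len(extra)] <- lens[seq_len(extra)] + 1L
  stopifnot(sum(lens) == n_words)
  vocab_tokens <- sprintf("tok%02d", 1:30)
  words <- rep_len(vocab_tokens, n_words)
  stim <- tibble::tibble(
    sentence_id = rep(seq_len(n_sentences), lens),
    word = words
  ) |>
    dplyr::group_by(sentence_id) |>
    dplyr::mutate(word_pos = dplyr::row_number()) |>
    dplyr::ungroup()
  if (oov_words > 0) {
    for (i in seq_len(oov_words)) {
      stim$word[stim$sentence_id == i & stim$word_pos == 3] <-
        sprintf("oovword%d", i)
    }
  }
  stim <- lexpred:::finalize_stimuli(stim)
  vocab <- tibble::tibble(
    token = vocab_tokens,
    id = seq_along(vocab_tokens) - 1L,
    count = rev(seq_along(vocab_tokens)) * 10L
  )
  list(stimuli = stim, vocabulary = vocab)
}

# uniform pseudo-probabilities for each stimulus word, NA for words outside
# the vocabulary (as the models would return)
fake_probabilities <- function(stimuli, vocabulary, seed = 1) {
  set.seed(seed)
  pr <- tibble::tibble(
    sentence_id = stimuli$sentence_id,
    word_pos = stimuli$word_pos,
    prob = runif(nrow(stimuli), 1e-6, 0.5)
  )
  pr$prob[!stimuli$word %in% vocabulary$token] <- NA_real_
  list(ngram = pr, topic = pr, rnn = pr)
}

# gamma-family event data with log-mean linear in planted predictors
gamma_events <- function(n, slopes = c(x1 = -0.3), intercept = log(250),
                         shape = 25, seed = 1, x_gen = NULL) {
  set.seed(seed)
  xs <- list()
  for (nm in names(slopes)) {
    xs[[nm]] <- if (is.null(x_gen)) runif(n) else x_gen[[nm]](n)
  }
  d <- tibble::as_tibble(xs)
  lp <- intercept
  for (nm in names(slopes)) lp <- lp + slopes[[nm]] * d[[nm]]
  d$y <- rgamma(n, shape = shape, rate = shape / exp(lp))
  d
}
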