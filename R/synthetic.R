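#' Configuration for the synthetic training corpus
#'
#' The generator plants known structure so every downstream stage is testable
#' without external data: sentences are drawn from a blend of topic-conditioned
#' unigram distributions (disjoint topic vocabularies, Zipf-shaped within a
#' topic) and a first-order transition table, emulating the topical and
#' sequential statistics of a subtitle-style training corpus.
#'
#' @param vocab_size Number of word types (>= 2).
#' @param n_topics Number of planted topics; the vocabulary is split into
#'   disjoint per-topic blocks.
#' @param n_sentences Number of sentences to generate.
#' @param sentence_length_range Integer `(min, max)` sentence length in words.
#' @param markov_strength Weight in `[0, 1]` mixing first-order transition
#'   structure (each word has a designated within-topic successor) with
#'   topic-conditioned unigram draws. 0 = pure unigram, 1 = deterministic
#'   chain.
#' @param sentences_per_doc Sentences grouped into one document (topic-model
#'   training unit). Default 1.
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   corpora.
#' @return A `corpus_config` list.
#' @export
corpus_config <- function(vocab_size = 50, n_topics = 2, n_sentences = 500,
                          sentence_length_range = c(5, 11),
                          markov_strength = 0.5, sentences_per_doc = 1,
                          seed = 1) {
  if (vocab_size < 2) {
    stop_lexpred("vocab_size must be >= 2", "lexpred_config_error")
  }
  if (n_topics < 1 || n_topics > vocab_size) {
    stop_lexpred("n_topics must be in [1, vocab_size]", "lexpred_config_error")
  }
  if (length(sentence_length_range) != 2 ||
    sentence_length_range[1] > sentence_length_range[2] ||
    sentence_length_range[1] < 1) {
    stop_lexpred(
      "sentence_length_range must be (min, max) with 1 <= min <= max",
      "lexpred_config_error"
    )
  }
  if (markov_strength < 0 || markov_strength > 1) {
    stop_lexpred("markov_strength must be in [0, 1]", "lexpred_config_error")
  }
  structure(
    list(
      vocab_size = as.integer(vocab_size), n_topics = as.integer(n_topics),
      n_sentences = as.integer(n_sentences),
      sentence_length_range = as.integer(sentence_length_range),
      markov_strength = markov_strength,
      sentences_per_doc = as.integer(sentences_per_doc),
      seed = as.integer(seed)
    ),
    class = "corpus_config"
  )
}

#' Generate a topic-structured Markov corpus
#'
#' Each sentence draws a topic, then words from a
#' `markov_strength : (1 - markov_strength)` blend of a deterministic
#' within-topic successor chain and the topic's Zipf-shaped unigram
#' distribution. The planted topic labels, per-topic vocabularies and the
#' successor map are attached as attributes (`sentence_topic`, `topic_vocab`,
#' `successor`, `unigram`) so recovery can be scored downstream.
#'
#' @param config A [corpus_config()].
#' @return A corpus tibble (see [new_corpus()]) with planted-structure
#'   attributes.
#' @export
generate_corpus <- function(config) {
  if (!inherits(config, "corpus_config")) {
    stop_lexpred("config must be a corpus_config object", "lexpred_config_error")
  }
  set.seed(config$seed)
  V <- config$vocab_size
  # unique pseudo-words with word lengths varying over 3..8 letters so the
  # length covariate behaves like real text downstream
  words <- vapply(seq_len(V), function(i) {
    paste0("x", i, strrep("a", (i * 7) %% 6))
  }, "")
  # disjoint topic blocks of near-equal size
  block <- sort(rep_len(seq_len(config$n_topics), V))
  topic_vocab <- split(words, block)
  # Zipf-shaped unigram distribution within each topic block
  unigram <- lapply(topic_vocab, function(ws) {
    p <- 1 / seq_along(ws)
    setNames(p / sum(p), ws)
  })
  # deterministic successor: next word within the same block, cyclically
  successor <- setNames(
    unlist(lapply(topic_vocab, function(ws) ws[c(seq_along(ws)[-1], 1)]),
      use.names = FALSE
    ),
    unlist(topic_vocab, use.names = FALSE)
  )
  lens <- sample(
    seq(config$sentence_length_range[1], config$sentence_length_range[2]),
    config$n_sentences,
    replace = TRUE
  )
  topics <- sample.int(config$n_topics, config$n_sentences, replace = TRUE)
  sentences <- vector("list", config$n_sentences)
  for (s in seq_len(config$n_sentences)) {
    uni <- unigram[[topics[s]]]
    toks <- character(lens[s])
    toks[1] <- sample(names(uni), 1, prob = uni)
    if (lens[s] > 1) {
      use_chain <- runif(lens[s] - 1) < config$markov_strength
      draws <- sample(names(uni), lens[s] - 1, replace = TRUE, prob = uni)
      for (i in seq_len(lens[s] - 1)) {
        toks[i + 1] <- if (use_chain[i]) successor[[toks[i]]] else draws[i]
      }
    }
    sentences[[s]] <- toks
  }
  doc_id <- ((seq_len(config$n_sentences) - 1) %/% config$sentences_per_doc) + 1L
  out <- new_corpus(sentences, doc_id = doc_id)
  attr(out, "config") <- config
  attr(out, "sentence_topic") <- topics
  attr(out, "topic_vocab") <- topic_vocab
  attr(out, "successor") <- successor
  attr(out, "unigram") <- unigram
  out
}

#' Generate multinomial cloze completion norms
#'
#' Emulates a cloze norming study with `K` complete protocols: for each
#' stimulus word, the number of participants completing the frame with the
#' target word is drawn from the completion multinomial, of which only the
#' target-vs-other margin matters downstream, so counts are Binomial(K,
#' target probability). The empirical `ccp` is `target_count / K`.
#'
#' @param stimuli A stimulus tibble ([as_stimuli()]).
#' @param target_prob Either a numeric vector (one probability per stimulus
#'   row, in stimulus order) or a tibble with `sentence_id`, `word_pos`,
#'   `target_prob`.
#' @param K Number of complete protocols (reference studies used 83).
#' @param seed Integer seed.
#' @return A cloze tibble `sentence_id`, `word_pos`, `completions_total`,
#'   `target_count`, `ccp` with a `seed` attribute.
#' @export
generate_cloze_norms <- function(stimuli, target_prob, K = 83, seed = 1) {
  check_columns(stimuli, c("sentence_id", "word_pos"), "stimuli")
  if (K < 1) stop_lexpred("K must be >= 1", "lexpred_config_error")
  if (is.data.frame(target_prob)) {
    check_columns(
      target_prob, c("sentence_id", "word_pos", "target_prob"),
      "target_prob"
    )
    p <- dplyr::left_join(
      stimuli[c("sentence_id", "word_pos")], target_prob,
      by = c("sentence_id", "word_pos")
    )$target_prob
  } else {
    p <- target_prob
  }
  if (length(p) != nrow(stimuli) || anyNA(p)) {
    stop_lexpred(
      "target_prob must supply one probability per stimulus word",
      "lexpred_validation_error"
    )
  }
  if (any(p < 0 | p > 1)) {
    stop_lexpred(
      "completion distribution not normalized: target probabilities must lie in [0, 1]",
      "lexpred_validation_error"
    )
  }
  set.seed(seed)
  cnt <- rbinom(length(p), size = K, prob = p)
  out <- tibble(
    sentence_id = stimuli$sentence_id,
    word_pos = stimuli$word_pos,
    completions_total = as.integer(K),
    target_count = as.integer(cnt),
    ccp = cnt / K
  )
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Fixation-generation effect specification
#'
#' Durations are gamma with fixed shape and mean `exp(intercept +
#' sum(slope * predictor))`, matching the gamma/log-link family used in the
#' analysis stage so recovery tests are well-posed. Refixations (a second
#' first-pass fixation) and regressions (a later revisit) are independent
#' Bernoulli events per word.
#'
#' @param intercept Log-mean duration in log-ms (default `log(250)`).
#' @param slopes Named numeric vector of coefficients on transformed-predictor
#'   columns of the predictor table (may be empty).
#' @param gamma_shape Gamma shape parameter (> 0); larger = less noise.
#' @param refixation_prob,regression_prob Probabilities in `[0, 1]`.
#' @param seed Integer seed.
#' @return A `fixation_effects` list.
#' @export
fixation_effects <- function(intercept = log(250), slopes = c(),
                             gamma_shape = 25, refixation_prob = 0.1,
                             regression_prob = 0.1, seed = 1) {
  if (gamma_shape <= 0) {
    stop_lexpred("gamma_shape must be > 0", "lexpred_config_error")
  }
  for (p in c(refixation_prob, regression_prob)) {
    if (p < 0 || p > 1) {
      stop_lexpred("probabilities must be in [0, 1]", "lexpred_config_error")
    }
  }
  if (length(slopes) > 0 && is.null(names(slopes))) {
    stop_lexpred("slopes must be a named vector", "lexpred_config_error")
  }
  structure(
    list(
      intercept = intercept, slopes = slopes, gamma_shape = gamma_shape,
      refixation_prob = refixation_prob, regression_prob = regression_prob,
      seed = as.integer(seed)
    ),
    class = "fixation_effects"
  )
}

#' Generate synthetic fixation events
#'
#' Each of `n_trials` participants reads every sentence left to right. Every
#' word receives one first-pass fixation (two with probability
#' `refixation_prob`); with probability `regression_prob` a non-final word is
#' revisited after the sentence has been read. Every fixation duration is
#' gamma-distributed with the word's model-implied mean; landing letters are
#' uniform over the word's letters. Predictor values that are `NA` (e.g. OOV
#' words) contribute their column mean to the linear predictor.
#'
#' @param stimuli A stimulus tibble.
#' @param predictors A per-word predictor table covering all stimulus words
#'   (e.g. from [assemble_predictors()]); must contain every column named in
#'   `effects$slopes`.
#' @param effects A [fixation_effects()] specification.
#' @param n_trials Number of simulated participants.
#' @return A fixation tibble `participant`, `trial`, `sentence_id`,
#'   `word_pos`, `fix_index`, `duration_ms`, `landing_letter` with a `seed`
#'   attribute.
#' @export
generate_fixations <- function(stimuli, predictors, effects, n_trials = 20) {
  stopifnot(inherits(effects, "fixation_effects"))
  check_columns(stimuli, c("sentence_id", "word_pos", "word_length"), "stimuli")
  check_columns(predictors, c("sentence_id", "word_pos"), "predictors")
  missing <- setdiff(names(effects$slopes), names(predictors))
  if (length(missing) > 0) {
    stop_lexpred(
      sprintf(
        "slope predictor(s) not in predictor table: %s",
        paste(missing, collapse = ", ")
      ),
      "lexpred_config_error"
    )
  }
  dat <- dplyr::left_join(
    stimuli[c("sentence_id", "word_pos", "word_length")],
    predictors,
    by = c("sentence_id", "word_pos")
  )
  if (anyNA(dat$word_length)) {
    stop_lexpred(
      "predictors must cover all stimulus words",
      "lexpred_validation_error"
    )
  }
  lp <- rep(effects$intercept, nrow(dat))
  for (nm in names(effects$slopes)) {
    x <- dat[[nm]]
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    lp <- lp + effects$slopes[[nm]] * x
  }
  mu <- exp(lp)

  set.seed(effects$seed)
  shape <- effects$gamma_shape
  draw <- function(m) rgamma(length(m), shape = shape, rate = shape / m)

  sent_rows <- split(seq_len(nrow(dat)), dat$sentence_id)
  out <- vector("list", n_trials * length(sent_rows))
  k <- 0
  for (p in seq_len(n_trials)) {
    for (rows in sent_rows) {
      nw <- length(rows)
      refix <- runif(nw) < effects$refixation_prob
      regress <- runif(nw) < effects$regression_prob
      regress[nw] <- FALSE # a revisit of the final word would merge into first pass
      word_seq <- rep(seq_len(nw), times = 1L + refix)
      word_seq <- c(word_seq, which(regress))
      ridx <- rows[word_seq]
      k <- k + 1
      out[[k]] <- tibble(
        participant = p,
        trial = dat$sentence_id[rows[1]],
        sentence_id = dat$sentence_id[rows[1]],
        word_pos = dat$word_pos[ridx],
        fix_index = seq_along(ridx),
        duration_ms = draw(mu[ridx]),
        landing_letter = vapply(
          dat$word_length[ridx],
          function(wl) sample.int(wl, 1), 1L
        )
      )
    }
  }
  res <- list_rbind(out)
  res$participant <- as.integer(res$participant)
  res$trial <- as.integer(res$trial)
  attr(res, "seed") <- effects$seed
  res
}
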