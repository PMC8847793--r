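test_that("corpus generation is deterministic and validates its config", {
  cfg <- corpus_config(vocab_size = 20, n_topics = 2, n_sentences = 30, seed = 5)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_identical(a$tokens, b$tokens)
  expect_identical(attr(a, "sentence_topic"), attr(b, "sentence_topic"))
  expect_equal(nrow(a), 30)
  expect_true(all(lengths(a$tokens) >= 5 & lengths(a$tokens) <= 11))

  expect_error(corpus_config(vocab_size = 1), class = "lexpred_config_error")
  expect_error(
    corpus_config(markov_strength = 1.2),
    class = "lexpred_config_error"
  )
  expect_error(
    corpus_config(sentence_length_range = c(9, 3)),
    class = "lexpred_config_error"
  )
})

test_that("single-topic unigram draws match the generating distribution", {
  cfg <- corpus_config(
    vocab_size = 2, n_topics = 1, n_sentences = 400,
    sentence_length_range = c(5, 5), markov_strength = 0, seed = 3
  )
  co <- generate_corpus(cfg)
  gen <- attr(co, "unigram")[[1]]
  toks <- unlist(co$tokens)
  n <- length(toks)
  for (w in names(gen)) {
    phat <- mean(toks == w)
    se <- sqrt(gen[[w]] * (1 - gen[[w]]) / n)
    expect_lt(abs(phat - gen[[w]]), 3 * se)
  }
})

test_that("two disjoint planted topics are separable by word counts", {
  co <- planted_corpus(seed = 21, n_sentences = 200)
  tv <- attr(co, "topic_vocab")
  topics <- attr(co, "sentence_topic")
  # classify each sentence by which planted vocabulary its words come from
  guess <- vapply(co$tokens, function(t) {
    ifelse(sum(t %in% tv[[1]]) >= sum(t %in% tv[[2]]), 1L, 2L)
  }, 1L)
  expect_equal(guess, topics) # disjoint vocabularies: perfectly separable
})

test_that("cloze norms follow the completion multinomial", {
  stim <- as_stimuli(new_corpus(list(c("aa", "bb", "cc"))))
  # degenerate probabilities
  cz1 <- generate_cloze_norms(stim, c(1, 1, 1), K = 83, seed = 2)
  expect_equal(cz1$ccp, c(1, 1, 1))
  cz0 <- generate_cloze_norms(stim, c(0, 0, 0), K = 83, seed = 2)
  expect_equal(cz0$ccp, c(0, 0, 0))
  # binomial concentration: p = 0.5, K = 10000
  stim1 <- stim[1, ]
  cz <- generate_cloze_norms(stim1, 0.5, K = 10000, seed = 7)
  expect_true(cz$ccp >= 0.48 && cz$ccp <= 0.52)
  # validation
  expect_error(
    generate_cloze_norms(stim, c(0.5, 1.2, 0.1), K = 83),
    class = "lexpred_validation_error"
  )
  expect_error(
    generate_cloze_norms(stim, c(0.5, 0.5), K = 83),
    class = "lexpred_validation_error"
  )
})

test_that("null-effect fixations have the planted mean duration", {
  co <- planted_corpus(seed = 31, n_sentences = 25)
  stim <- as_stimuli(co)
  preds <- stim[c("sentence_id", "word_pos")]
  eff <- fixation_effects(
    intercept = log(250), gamma_shape = 400,
    refixation_prob = 0, regression_prob = 0, seed = 9
  )
  fx <- generate_fixations(stim, preds, eff, n_trials = 30)
  expect_true(abs(mean(fx$duration_ms) - 250) < 2)
  # every word exactly once per trial, in order
  expect_equal(nrow(fx), 30 * nrow(stim))
})

test_that("fixations reference existing words and respect the seed", {
  co <- planted_corpus(seed = 32, n_sentences = 10)
  stim <- as_stimuli(co)
  preds <- stim[c("sentence_id", "word_pos")]
  eff <- fixation_effects(refixation_prob = 0.3, regression_prob = 0.2, seed = 4)
  fx1 <- generate_fixations(stim, preds, eff, n_trials = 5)
  fx2 <- generate_fixations(stim, preds, eff, n_trials = 5)
  expect_identical(fx1, fx2)
  key_fix <- paste(fx1$sentence_id, fx1$word_pos)
  key_stim <- paste(stim$sentence_id, stim$word_pos)
  expect_true(all(key_fix %in% key_stim))
  expect_true(all(
    fx1$landing_letter >= 1 &
      fx1$landing_letter <= stim$word_length[match(key_fix, key_stim)]
  ))
  expect_error(
    generate_fixations(
      stim, preds,
      fixation_effects(slopes = c(nosuch = 1)), 2
    ),
    class = "lexpred_config_error"
  )
})

test_that("gamma shape is recovered from null-slope durations", {
  co <- planted_corpus(seed = 33, n_sentences = 60)
  stim <- as_stimuli(co)
  preds <- stim[c("sentence_id", "word_pos")]
  eff <- fixation_effects(
    gamma_shape = 25, refixation_prob = 0, regression_prob = 0, seed = 12
  )
  fx <- generate_fixations(stim, preds, eff, n_trials = 25)
  expect_gt(nrow(fx), 10000)
  # method-of-moments estimate of the gamma shape
  shape_hat <- mean(fx$duration_ms)^2 / var(fx$duration_ms)
  expect_lt(abs(shape_hat - 25) / 25, 0.1)
})
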