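test_that("counts reproduce the maximum-likelihood estimate as discounts vanish", {
  # count(the cat) = 2, count(the) = 3 -> unsmoothed p(cat | the) = 2/3
  m <- train_ngram(toy_corpus(), n = 2, discounts = 1e-9)
  expect_equal(ngram_prob(m, "cat", "the"), 2 / 3, tolerance = 1e-6)
  expect_equal(ngram_prob(m, "dog", "the"), 1 / 3, tolerance = 1e-6)
})

test_that("every conditional distribution normalizes exactly", {
  co <- generate_corpus(corpus_config(
    vocab_size = 15, n_topics = 2, n_sentences = 20,
    markov_strength = 0.5, seed = 13
  ))
  m <- train_ngram(co, n = 3)
  # all observed trigram histories
  hists <- unique(lapply(
    ls(m$counts[[3]]),
    function(k) head(strsplit(k, " ", fixed = TRUE)[[1]], 2)
  ))
  for (h in hists[1:min(40, length(hists))]) {
    expect_equal(sum(ngram_prob(m, m$event_vocab, h)), 1, tolerance = 1e-8)
  }
  # unseen and empty histories normalize too
  expect_equal(sum(ngram_prob(m, m$event_vocab, c("zz", "qq"))), 1,
    tolerance = 1e-8
  )
  expect_equal(sum(ngram_prob(m, m$event_vocab, character(0))), 1,
    tolerance = 1e-8
  )
})

test_that("probabilities match the brute-force recursion oracle", {
  for (corp in list(
    toy_corpus(),
    generate_corpus(corpus_config(
      vocab_size = 12, n_topics = 2, n_sentences = 30,
      markov_strength = 0.6, seed = 17
    ))
  )) {
    m <- train_ngram(corp, n = 3)
    hists <- list(
      c("<s>", "<s>"),
      corp$tokens[[1]][1:2],
      c("nosuch", corp$tokens[[2]][1]),
      c("nosuch1", "nosuch2")
    )
    for (h in hists) {
      mine <- ngram_prob(m, m$event_vocab, h)
      oracle <- oracle_kn_dist(corp$tokens, 3, h)
      expect_equal(setNames(mine, m$event_vocab), oracle, tolerance = 1e-10)
    }
  }
})

test_that("a deterministic corpus yields near-certain continuations", {
  rep100 <- new_corpus(rep(list(c("aa", "bb", "cc")), 100))
  m <- train_ngram(rep100, n = 3)
  expect_gt(ngram_prob(m, "cc", c("aa", "bb")), 0.9)
  expect_gt(ngram_prob(m, "bb", c("<s>", "aa")), 0.9)
})

test_that("the one-word-type vocabulary degenerates to word vs end token", {
  m <- train_ngram(new_corpus(rep(list(c("aa", "aa", "aa")), 5)), n = 3)
  p <- ngram_prob(m, m$event_vocab, c("aa", "aa"))
  expect_equal(sum(p), 1, tolerance = 1e-10)
  expect_gt(p[1], 0.5) # the single word dominates its distribution
  expect_true(all(p > 0))
})

test_that("adding counts for a continuation never decreases its probability", {
  base <- toy_corpus()
  more <- new_corpus(c(base$tokens, list(c("the", "cat", "sat"))))
  m1 <- train_ngram(base, n = 3, discounts = 0.4)
  m2 <- train_ngram(more, n = 3, discounts = 0.4)
  expect_gte(
    ngram_prob(m2, "sat", c("the", "cat")),
    ngram_prob(m1, "sat", c("the", "cat"))
  )
})

test_that("unseen histories equal the backed-off lower-order distribution", {
  co <- planted_corpus(seed = 23, n_sentences = 40, markov = 0.5)
  m <- train_ngram(co, n = 3)
  w <- m$event_vocab
  v <- co$tokens[[1]][2]
  # unseen bigram history (unknown first token) backs off to p(w | v)
  p_backoff <- ngram_prob(m, w, c("neverseen", v))
  p_level2 <- lexpred:::kn_level(m, 2, w, v)
  expect_equal(p_backoff, p_level2, tolerance = 1e-12)
})

test_that("sentence scoring is stateless and handles boundaries", {
  co <- toy_corpus()
  m <- train_ngram(co, n = 3)
  s1 <- sentence_ngram_probs(m, c("the"))
  expect_equal(nrow(s1), 1)
  expect_equal(s1$prob, ngram_prob(m, "the", character(0)))
  sp_before <- sentence_ngram_probs(m, c("the", "cat", "sat"))
  invisible(sentence_ngram_probs(m, c("the", "dog", "sat")))
  sp_after <- sentence_ngram_probs(m, c("the", "cat", "sat"))
  expect_identical(sp_before, sp_after)
})

test_that("unknown targets and empty corpora raise the contracted errors", {
  m <- train_ngram(toy_corpus(), n = 3)
  expect_error(ngram_prob(m, "zebra"), class = "lexpred_unknown_token_error")
  expect_error(
    train_ngram(new_corpus(list("a")[0]), n = 3),
    class = "lexpred_training_error"
  )
  expect_error(
    train_ngram(new_corpus(list(c("a", "b"))), n = 5),
    class = "lexpred_training_error"
  )
})

test_that("n-gram models round-trip through the text serialization", {
  dir <- withr::local_tempdir()
  m <- train_ngram(toy_corpus(), n = 3)
  p <- file.path(dir, "model.ngram")
  write_ngram_model(m, p)
  m2 <- read_ngram_model(p)
  h <- c("the", "cat")
  expect_equal(
    ngram_prob(m2, m2$event_vocab, h),
    ngram_prob(m, m$event_vocab, h),
    tolerance = 1e-12
  )
  expect_equal(m2$D, m$D)
})
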