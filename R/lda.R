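#' Topic model hyperparameters
#'
#' Defaults mirror common practice for subtitle-scale corpora (200 topics,
#' document-topic prior 0.25, topic-word prior 0.001); desk-scale fixtures
#' use far fewer topics. Inference on new documents resamples token-topic
#' assignments with the trained topic-word distribution frozen, averaging
#' `infer_samples` theta samples taken every `infer_thin` sweeps after
#' `infer_burnin` burn-in sweeps.
#'
#' @param n_topics Number of topics `N` (>= 1).
#' @param alpha Document-topic Dirichlet prior (> 0).
#' @param beta Topic-word Dirichlet prior (> 0).
#' @param train_iterations Gibbs sweeps over the training corpus.
#' @param infer_burnin,infer_samples,infer_thin Inference schedule.
#' @param seed Integer seed.
#' @return A `topic_params` list.
#' @export
topic_params <- function(n_topics = 200, alpha = 0.25, beta = 0.001,
                         train_iterations = 200, infer_burnin = 50,
                         infer_samples = 5, infer_thin = 2, seed = 1) {
  if (n_topics < 1) stop_lexpred("n_topics must be >= 1", "lexpred_config_error")
  if (alpha <= 0 || beta <= 0) {
    stop_lexpred("alpha and beta must be > 0", "lexpred_config_error")
  }
  if (infer_samples < 1) {
    stop_lexpred("infer_samples must be >= 1", "lexpred_config_error")
  }
  structure(
    list(
      n_topics = as.integer(n_topics), alpha = alpha, beta = beta,
      train_iterations = as.integer(train_iterations),
      infer_burnin = as.integer(infer_burnin),
      infer_samples = as.integer(infer_samples),
      infer_thin = as.integer(infer_thin),
      seed = as.integer(seed)
    ),
    class = "topic_params"
  )
}

#' Train a latent Dirichlet allocation topic model
#'
#' Collapsed Gibbs sampling over token-topic assignments, with documents
#' given by the corpus `doc_id` grouping. The topic-word matrix is estimated
#' as `phi[z, w] = (count(z, w) + beta) / (count(z) + V beta)`, so every
#' entry is strictly positive and every row sums to one. Deterministic given
#' `params$seed`.
#'
#' @param corpus A corpus tibble with a `doc_id` column.
#' @param params A [topic_params()] object.
#' @return An object of class `topic_model` with elements `phi` (N x V),
#'   `vocab`, `doc_topics` (document-topic proportions) and `params`.
#' @export
train_lda <- function(corpus, params = topic_params()) {
  stopifnot(inherits(params, "topic_params"))
  check_columns(corpus, c("doc_id", "tokens"), "corpus")
  if (nrow(corpus) == 0) {
    stop_lexpred("need at least one document", "lexpred_training_error")
  }
  vocab <- sort(unique(unlist(corpus$tokens, use.names = FALSE)))
  V <- length(vocab)
  docs_tokens <- lapply(
    split(corpus$tokens, corpus$doc_id),
    function(d) unlist(d, use.names = FALSE)
  )
  docs <- lapply(docs_tokens, function(toks) match(toks, vocab) - 1L)
  total_tokens <- sum(lengths(docs))
  if (params$n_topics > total_tokens) {
    warn("more topics than tokens; most topics will stay empty")
  }
  set.seed(params$seed)
  fit <- lda_gibbs_train(
    docs, V, params$n_topics, params$alpha, params$beta,
    params$train_iterations
  )
  phi <- (fit$nwt + params$beta) /
    (matrix(fit$nt, nrow = params$n_topics, ncol = V) + V * params$beta)
  colnames(phi) <- vocab
  ndt <- fit$ndt
  theta_train <- (ndt + params$alpha) /
    (rowSums(ndt) + params$n_topics * params$alpha)
  structure(
    list(
      phi = phi, vocab = vocab, doc_topics = theta_train,
      doc_ids = names(docs), params = params
    ),
    class = "topic_model"
  )
}

#' Infer the topic mixture of a new document
#'
#' Gibbs sampling over the new document's token-topic assignments with the
#' trained topic-word distribution frozen; theta is the average over
#' post-burn-in samples of `(count(z) + alpha) / (length + N alpha)` and sums
#' to one. Tokens outside the model vocabulary are dropped; a document with
#' no known token raises an inference error.
#'
#' @param model A `topic_model`.
#' @param tokens Character vector, the document (e.g. a sentence prefix).
#' @param seed Integer seed (defaults to the training seed, so repeated
#'   calls are reproducible).
#' @return Numeric topic-mixture vector of length `n_topics`.
#' @export
infer_theta <- function(model, tokens, seed = model$params$seed) {
  stopifnot(inherits(model, "topic_model"))
  ids <- match(tokens, model$vocab) - 1L
  ids <- ids[!is.na(ids)]
  if (length(ids) == 0) {
    stop_lexpred(
      "no document token occurs in the model vocabulary",
      "lexpred_inference_error"
    )
  }
  p <- model$params
  set.seed(seed)
  as.numeric(lda_infer_theta(
    ids, model$phi, p$alpha, p$infer_burnin, p$infer_samples, p$infer_thin
  ))
}

#' Incremental topic-model word probability
#'
#' The probability of the word at `position` is computed by treating the
#' sentence history *including the current word* as a new document, inferring
#' its topic mixture theta, and mixing the topic-word distributions:
#' `p(w | d) = sum_z phi[z, w] * theta[z]`. Including the current word in the
#' inferred prefix document is deliberate (it is how the incremental
#' retrieval probability is defined here) and introduces a mild circularity
#' that is documented rather than corrected.
#'
#' @param model A `topic_model`.
#' @param tokens Tokenized sentence.
#' @param position 1-based word position to score.
#' @inheritParams infer_theta
#' @return Probability of the word at `position` given its sentence history.
#' @export
topic_word_prob <- function(model, tokens, position,
                            seed = model$params$seed) {
  stopifnot(inherits(model, "topic_model"))
  if (position < 1 || position > length(tokens)) {
    stop_lexpred("position out of range", "lexpred_validation_error")
  }
  w <- tokens[position]
  if (!w %in% model$vocab) {
    stop_lexpred(
      sprintf("unknown token '%s' (excluded upstream)", w),
      "lexpred_unknown_token_error"
    )
  }
  theta <- infer_theta(model, tokens[seq_len(position)], seed = seed)
  sum(model$phi[, w] * theta)
}

#' Per-word incremental topic probabilities for a sentence
#'
#' @param model A `topic_model`.
#' @param tokens Tokenized sentence.
#' @inheritParams infer_theta
#' @return A tibble `word_pos`, `word`, `prob` (`NA` for words outside the
#'   model vocabulary).
#' @export
sentence_topic_probs <- function(model, tokens, seed = model$params$seed) {
  probs <- vapply(seq_along(tokens), function(i) {
    if (!tokens[i] %in% model$vocab) {
      return(NA_real_)
    }
    topic_word_prob(model, tokens, i, seed = seed)
  }, numeric(1))
  tibble(word_pos = seq_along(tokens), word = tokens, prob = probs)
}

#' Align trained topics with planted topic vocabularies
#'
#' For generator fixtures with known disjoint topic vocabularies, each
#' planted topic is matched to the trained topic putting the most probability
#' mass on its vocabulary; the returned alignment reports that mass (1.0 =
#' perfect recovery).
#'
#' @param model A `topic_model`.
#' @param topic_vocab A list of character vectors, one per planted topic
#'   (e.g. `attr(corpus, "topic_vocab")`).
#' @return A tibble `planted_topic`, `trained_topic`, `mass`.
#' @export
align_topics <- function(model, topic_vocab) {
  mass <- vapply(topic_vocab, function(ws) {
    ws <- intersect(ws, model$vocab)
    rowSums(model$phi[, ws, drop = FALSE])
  }, numeric(nrow(model$phi)))
  # mass: trained x planted
  mass <- matrix(mass, nrow = nrow(model$phi))
  best <- apply(mass, 2, which.max)
  tibble(
    planted_topic = seq_along(topic_vocab),
    trained_topic = as.integer(best),
    mass = mass[cbind(best, seq_along(topic_vocab))]
  )
}

#' @export
print.topic_model <- function(x, ...) {
  cat(sprintf(
    "LDA topic model: %d topics, %d word types (alpha = %g, beta = %g)\n",
    nrow(x$phi), length(x$vocab), x$params$alpha, x$params$beta
  ))
  invisible(x)
}
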