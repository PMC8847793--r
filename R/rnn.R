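#' Elman network configuration
#'
#' A simple recurrent network language model: one-hot word input, sigmoid
#' hidden layer whose state is copied back as context for the next word, and
#' a full softmax output over the vocabulary plus the sentence-end token.
#' The reference setting for large corpora is 400 hidden units with a
#' retrieval temperature of 0.6; desk-scale fixtures use 16-64 units.
#' Training is plain per-token cross-entropy gradient descent with the
#' copy-back recurrence (`bptt_steps = 1`, i.e. gradients do not flow through
#' the copied context); output weights start at zero so the untrained model
#' is exactly uniform, input and recurrent weights start uniform in
#' `[-init_scale, init_scale]`.
#'
#' @param hidden_size Number of hidden units (>= 1). Default 400.
#' @param temperature Retrieval softmax temperature (> 0); logits are divided
#'   by it at scoring time, 1 reproduces the training softmax. Default 0.6.
#' @param epochs Passes over the training corpus.
#' @param learning_rate Gradient step size (> 0).
#' @param bptt_steps Recurrence depth for gradient flow; 1 is the pure Elman
#'   copy-back scheme (the only scheme implemented; larger values are
#'   reserved).
#' @param hidden_init Constant initial hidden state at each sentence start
#'   (0.5 = mid-sigmoid neutral state).
#' @param init_scale Half-width of the uniform weight initialisation.
#' @param seed Integer seed.
#' @return An `rnn_config` list.
#' @export
rnn_config <- function(hidden_size = 400, temperature = 0.6, epochs = 5,
                       learning_rate = 0.1, bptt_steps = 1,
                       hidden_init = 0.5, init_scale = 0.1, seed = 1) {
  if (hidden_size < 1) {
    stop_lexpred("hidden_size must be >= 1", "lexpred_config_error")
  }
  if (temperature <= 0) {
    stop_lexpred("temperature must be > 0", "lexpred_config_error")
  }
  if (learning_rate <= 0) {
    stop_lexpred("learning_rate must be > 0", "lexpred_config_error")
  }
  structure(
    list(
      hidden_size = as.integer(hidden_size), temperature = temperature,
      epochs = as.integer(epochs), learning_rate = learning_rate,
      bptt_steps = as.integer(bptt_steps), hidden_init = hidden_init,
      init_scale = init_scale, seed = as.integer(seed)
    ),
    class = "rnn_config"
  )
}

#' Train a simple recurrent network language model
#'
#' For each sentence the hidden state is reset to the constant init vector,
#' the begin token is presented, and the model is trained to predict each
#' word (and finally the end token) from the sigmoid hidden state
#' `h_t = sigmoid(W_in x_t + W_rec h_{t-1})` through a full softmax.
#' Per-token cross-entropy gradients update the output, input and recurrent
#' weights; the recurrence is copy-back only. Training diverging to a
#' non-finite loss raises a training error reporting the epoch.
#'
#' @param corpus A corpus tibble.
#' @param config An [rnn_config()].
#' @return An object of class `rnn_model` with the weight matrices, the
#'   vocabulary, per-epoch mean cross-entropies (`epoch_loss`, nats/token;
#'   element 1 is the pre-training loss) and the config.
#' @export
train_rnn <- function(corpus, config = rnn_config()) {
  stopifnot(inherits(config, "rnn_config"))
  check_columns(corpus, "tokens", "corpus")
  if (nrow(corpus) == 0 || sum(lengths(corpus$tokens)) == 0) {
    stop_lexpred("training corpus is empty", "lexpred_training_error")
  }
  bos <- "<s>"
  eos <- "</s>"
  vocab <- sort(unique(unlist(corpus$tokens, use.names = FALSE)))
  vocab_in <- c(bos, vocab) # input units
  vocab_out <- c(vocab, eos) # event space
  H <- config$hidden_size
  set.seed(config$seed)
  W_in <- matrix(
    runif(H * length(vocab_in), -config$init_scale, config$init_scale),
    nrow = H
  )
  W_rec <- matrix(
    runif(H * H, -config$init_scale, config$init_scale),
    nrow = H
  )
  W_out <- matrix(0, nrow = length(vocab_out), ncol = H)

  sents_in <- lapply(corpus$tokens, function(t) match(c(bos, t), vocab_in))
  sents_out <- lapply(corpus$tokens, function(t) match(c(t, eos), vocab_out))
  lr <- config$learning_rate
  h0 <- rep(config$hidden_init, H)
  n_tokens <- sum(lengths(sents_out))

  epoch_ce <- function() {
    tot <- 0
    for (s in seq_along(sents_in)) {
      h <- h0
      xin <- sents_in[[s]]
      tgt <- sents_out[[s]]
      for (i in seq_along(xin)) {
        h <- stats::plogis(W_in[, xin[i]] + W_rec %*% h)
        z <- W_out %*% h
        z <- z - max(z)
        tot <- tot - (z[tgt[i]] - log(sum(exp(z))))
      }
    }
    tot / n_tokens
  }

  losses <- numeric(config$epochs + 1)
  losses[1] <- epoch_ce()
  for (ep in seq_len(config$epochs)) {
    for (s in seq_along(sents_in)) {
      h_prev <- h0
      xin <- sents_in[[s]]
      tgt <- sents_out[[s]]
      for (i in seq_along(xin)) {
        h <- as.numeric(stats::plogis(W_in[, xin[i]] + W_rec %*% h_prev))
        z <- W_out %*% h
        z <- z - max(z)
        p <- exp(z)
        p <- p / sum(p)
        dz <- p
        dz[tgt[i]] <- dz[tgt[i]] - 1
        dh <- as.numeric(crossprod(W_out, dz)) * h * (1 - h)
        W_out <- W_out - lr * tcrossprod(as.numeric(dz), h)
        W_in[, xin[i]] <- W_in[, xin[i]] - lr * dh
        W_rec <- W_rec - lr * tcrossprod(dh, h_prev)
        h_prev <- h # copy-back context
      }
    }
    losses[ep + 1] <- epoch_ce()
    if (!is.finite(losses[ep + 1])) {
      stop_lexpred(
        sprintf("training diverged (non-finite loss at epoch %d)", ep),
        "lexpred_training_error"
      )
    }
  }

  structure(
    list(
      W_in = W_in, W_rec = W_rec, W_out = W_out,
      vocab = vocab, vocab_in = vocab_in, vocab_out = vocab_out,
      bos = bos, eos = eos, epoch_loss = losses, config = config
    ),
    class = "rnn_model"
  )
}

#' Next-word distribution of the recurrent network
#'
#' Runs the recurrence over the prefix (after a hidden-state reset and the
#' begin token) and returns the full softmax distribution over the event
#' vocabulary, with logits divided by `temperature`. The vector is strictly
#' positive and sums to one.
#'
#' @param model An `rnn_model`.
#' @param prefix Character vector of preceding tokens (may be empty: the
#'   first-word distribution comes from the reset state).
#' @param temperature Softmax temperature; defaults to the training config's.
#' @return Named probability vector over the event vocabulary (words plus
#'   the end token).
#' @export
rnn_next_distribution <- function(model, prefix = character(0),
                                  temperature = model$config$temperature) {
  stopifnot(inherits(model, "rnn_model"))
  if (temperature <= 0) {
    stop_lexpred("temperature must be > 0", "lexpred_config_error")
  }
  ids <- match(c(model$bos, prefix), model$vocab_in)
  if (anyNA(ids)) {
    bad <- prefix[is.na(match(prefix, model$vocab_in))]
    stop_lexpred(
      sprintf("unknown prefix token(s): %s", paste(head(bad, 5), collapse = ", ")),
      "lexpred_unknown_token_error"
    )
  }
  h <- rep(model$config$hidden_init, model$config$hidden_size)
  for (i in ids) {
    h <- stats::plogis(model$W_in[, i] + model$W_rec %*% h)
  }
  z <- as.numeric(model$W_out %*% h) / temperature
  z <- z - max(z)
  p <- exp(z)
  p <- p / sum(p)
  setNames(p, model$vocab_out)
}

#' Per-word RNN probabilities for a sentence
#'
#' The probability of word `i` is read from the next-word distribution after
#' the prefix `w_1 .. w_{i-1}`; the hidden state is reset before each
#' sentence, so scoring is independent of previously scored sentences.
#'
#' @param model An `rnn_model`.
#' @param tokens Tokenized sentence (all words must be in the vocabulary).
#' @inheritParams rnn_next_distribution
#' @return A tibble `word_pos`, `word`, `prob`.
#' @export
sentence_rnn_probs <- function(model, tokens,
                               temperature = model$config$temperature) {
  probs <- vapply(seq_along(tokens), function(i) {
    d <- rnn_next_distribution(model, tokens[seq_len(i - 1)],
      temperature = temperature
    )
    if (!tokens[i] %in% names(d)) {
      stop_lexpred(
        sprintf("unknown token '%s'", tokens[i]),
        "lexpred_unknown_token_error"
      )
    }
    d[[tokens[i]]]
  }, numeric(1))
  tibble(word_pos = seq_along(tokens), word = tokens, prob = probs)
}

#' @export
print.rnn_model <- function(x, ...) {
  cat(sprintf(
    "Elman RNN language model: %d hidden units, %d word types, temperature %g\n",
    x$config$hidden_size, length(x$vocab), x$config$temperature
  ))
  cat(sprintf(
    "mean cross-entropy: %.3f -> %.3f nats/token over %d epoch(s)\n",
    x$epoch_loss[1], tail(x$epoch_loss, 1), x$config$epochs
  ))
  invisible(x)
}
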