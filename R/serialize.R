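#' Write and read trained language models as plain text
#'
#' Each model round-trips through a documented, sorted text format:
#' \describe{
#'   \item{n-gram}{`# ngram`/`# order`/`# discounts`/`# vocab` header lines
#'     followed by tab-separated `gram<TAB>count` rows of the top-order raw
#'     counts; all lower-order continuation tables are derived on read.}
#'   \item{topic model}{header with the hyperparameters, the vocabulary
#'     line, then one tab-separated row of topic-word probabilities per
#'     topic.}
#'   \item{RNN}{header with the config, the vocabulary line, then the
#'     input, recurrent and output weight matrices row by row.}
#' }
#'
#' @param model A trained model object.
#' @param path File path.
#' @return The writers return `path` invisibly; the readers return the
#'   reconstructed model.
#' @export
write_ngram_model <- function(model, path) {
  stopifnot(inherits(model, "ngram_model"))
  top <- model$counts[[model$n]]
  keys <- sort(ls(top))
  lines <- c(
    "# ngram",
    paste0("# order: ", model$n),
    paste0("# discounts: ", paste(format(model$D, digits = 17), collapse = " ")),
    paste0("# total_tokens: ", model$total_tokens),
    paste0("# vocab: ", paste(model$vocab, collapse = " ")),
    paste0(keys, "\t", vapply(keys, function(k) top[[k]], numeric(1)))
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# internal: pull "key: value" out of a header line
header_value <- function(lines, key) {
  ln <- grep(paste0("^# ", key, ": "), lines, value = TRUE)
  if (length(ln) != 1) {
    stop_lexpred(
      sprintf("model file is missing header '%s'", key), "lexpred_format_error"
    )
  }
  sub(paste0("^# ", key, ": "), "", ln)
}

#' @rdname write_ngram_model
#' @export
read_ngram_model <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0 || lines[1] != "# ngram") {
    stop_lexpred("not an n-gram model file", "lexpred_format_error")
  }
  n <- as.integer(header_value(lines, "order"))
  D <- as.numeric(strsplit(header_value(lines, "discounts"), " ")[[1]])
  total_tokens <- as.integer(header_value(lines, "total_tokens"))
  vocab <- strsplit(header_value(lines, "vocab"), " ")[[1]]
  body <- lines[!grepl("^#", lines)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  top <- new.env(parent = emptyenv())
  for (p in parts) top[[p[1]]] <- as.numeric(p[2])
  build_ngram_model(top, n, vocab, total_tokens, discounts = D)
}

#' @rdname write_ngram_model
#' @export
write_topic_model <- function(model, path) {
  stopifnot(inherits(model, "topic_model"))
  p <- model$params
  lines <- c(
    "# lda",
    sprintf(
      "# params: %d %.17g %.17g %d %d %d %d %d",
      p$n_topics, p$alpha, p$beta, p$train_iterations, p$infer_burnin,
      p$infer_samples, p$infer_thin, p$seed
    ),
    paste0("# vocab: ", paste(model$vocab, collapse = " ")),
    apply(model$phi, 1, function(r) paste(format(r, digits = 17), collapse = "\t"))
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_ngram_model
#' @export
read_topic_model <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0 || lines[1] != "# lda") {
    stop_lexpred("not a topic model file", "lexpred_format_error")
  }
  pv <- as.numeric(strsplit(header_value(lines, "params"), " ")[[1]])
  params <- topic_params(
    n_topics = pv[1], alpha = pv[2], beta = pv[3], train_iterations = pv[4],
    infer_burnin = pv[5], infer_samples = pv[6], infer_thin = pv[7],
    seed = pv[8]
  )
  vocab <- strsplit(header_value(lines, "vocab"), " ")[[1]]
  body <- lines[!grepl("^#", lines)]
  phi <- do.call(rbind, lapply(
    strsplit(body, "\t", fixed = TRUE), as.numeric
  ))
  colnames(phi) <- vocab
  structure(
    list(
      phi = phi, vocab = vocab, doc_topics = NULL, doc_ids = NULL,
      params = params
    ),
    class = "topic_model"
  )
}

#' @rdname write_ngram_model
#' @export
write_rnn_model <- function(model, path) {
  stopifnot(inherits(model, "rnn_model"))
  cfg <- model$config
  mat_lines <- function(m) {
    apply(m, 1, function(r) paste(format(r, digits = 17), collapse = "\t"))
  }
  lines <- c(
    "# rnn",
    sprintf(
      "# config: %d %.17g %d %.17g %d %.17g %.17g %d",
      cfg$hidden_size, cfg$temperature, cfg$epochs, cfg$learning_rate,
      cfg$bptt_steps, cfg$hidden_init, cfg$init_scale, cfg$seed
    ),
    paste0("# vocab: ", paste(model$vocab, collapse = " ")),
    paste0("# epoch_loss: ", paste(format(model$epoch_loss, digits = 17), collapse = " ")),
    "# W_in", mat_lines(model$W_in),
    "# W_rec", mat_lines(model$W_rec),
    "# W_out", mat_lines(model$W_out)
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_ngram_model
#' @export
read_rnn_model <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0 || lines[1] != "# rnn") {
    stop_lexpred("not an RNN model file", "lexpred_format_error")
  }
  cv <- as.numeric(strsplit(header_value(lines, "config"), " ")[[1]])
  cfg <- rnn_config(
    hidden_size = cv[1], temperature = cv[2], epochs = cv[3],
    learning_rate = cv[4], bptt_steps = cv[5], hidden_init = cv[6],
    init_scale = cv[7], seed = cv[8]
  )
  vocab <- strsplit(header_value(lines, "vocab"), " ")[[1]]
  losses <- as.numeric(strsplit(header_value(lines, "epoch_loss"), " ")[[1]])
  marks <- which(lines %in% c("# W_in", "# W_rec", "# W_out"))
  stopifnot(length(marks) == 3)
  read_mat <- function(from, to) {
    do.call(rbind, lapply(
      strsplit(lines[seq(from, to)], "\t", fixed = TRUE), as.numeric
    ))
  }
  W_in <- read_mat(marks[1] + 1, marks[2] - 1)
  W_rec <- read_mat(marks[2] + 1, marks[3] - 1)
  W_out <- read_mat(marks[3] + 1, length(lines))
  structure(
    list(
      W_in = W_in, W_rec = W_rec, W_out = W_out,
      vocab = vocab, vocab_in = c("<s>", vocab),
      vocab_out = c(vocab, "</s>"),
      bos = "<s>", eos = "</s>", epoch_loss = losses, config = cfg
    ),
    class = "rnn_model"
  )
}
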