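#' Fixation-record-level analysis table
#'
#' Joins viewing-time records with the per-word predictor table, keeping
#' target words only (first/last words of each sentence and OOV words carry
#' no analysis weight). The result is the event-level table the GAM ladder
#' consumes.
#'
#' @param records Viewing-time records ([compute_viewing_times()]).
#' @param predictors Predictor table ([assemble_predictors()]).
#' @return A tibble with one row per participant x trial x target word.
#' @export
gam_data <- function(records, predictors) {
  check_columns(records, c("sentence_id", "word_pos", "sfd", "gd", "tvt"), "records")
  check_columns(predictors, c("sentence_id", "word_pos", "is_target"), "predictors")
  records |>
    dplyr::inner_join(
      filter(predictors, .data$is_target),
      by = c("sentence_id", "word_pos")
    )
}

#' Pipeline configuration
#'
#' Bundles the generator, model and analysis settings for [run_pipeline()].
#' All stage seeds are derived deterministically from `seed`.
#'
#' @param corpus A [corpus_config()] for the synthetic training corpus.
#' @param n_stimulus_sentences Stimulus sentences drawn as a fresh sample
#'   from the same generator.
#' @param cloze_K Number of cloze protocols.
#' @param topic A [topic_params()].
#' @param rnn An [rnn_config()].
#' @param effects A [fixation_effects()] or `NULL` to use slopes on the
#'   log10 n-gram probability only.
#' @param n_trials Simulated participants.
#' @param policy A [cutoff_policy()].
#' @param measures Measures to run ladders for.
#' @param sources Ladder sources.
#' @param gam_k Basis dimension.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(corpus = corpus_config(
                              vocab_size = 60, n_topics = 3,
                              n_sentences = 400, seed = 101
                            ),
                            n_stimulus_sentences = 40,
                            cloze_K = 83,
                            topic = topic_params(
                              n_topics = 3, train_iterations = 150
                            ),
                            rnn = rnn_config(hidden_size = 24, epochs = 3),
                            effects = NULL,
                            n_trials = 12,
                            policy = cutoff_policy(),
                            measures = "gd",
                            sources = list("ccp", "ngram"),
                            gam_k = 5,
                            seed = 1) {
  structure(
    list(
      corpus = corpus, n_stimulus_sentences = n_stimulus_sentences,
      cloze_K = cloze_K, topic = topic, rnn = rnn, effects = effects,
      n_trials = n_trials, policy = policy, measures = measures,
      sources = sources, gam_k = gam_k, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Run the full synthetic-to-ladder pipeline
#'
#' Executes the demonstration workflow end to end: generate a training
#' corpus and stimulus sentences, train the three language models, norm the
#' stimuli with synthetic cloze protocols, score every stimulus word,
#' assemble the predictor table, simulate fixation events whose log-mean
#' durations follow planted predictor effects, extract and filter viewing
#' times, and run the item-level correlations and the GAM ladder(s). A
#' manifest records the seed and row count of every stage; any stage error
#' halts with the stage name. Reruns with the same config are identical.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory; when given, the corpus, stimulus,
#'   cloze, fixation and predictor tables are written there as plain
#'   text/TSV.
#' @return A list: `corpus`, `stimuli`, `models`, `cloze`, `predictors`,
#'   `records`, `items`, `correlations`, `ladders`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- config$seed + 1:6
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_lexpred(
        sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
        "lexpred_pipeline_error"
      )
    })
  }

  corpus <- stage("corpus", generate_corpus(config$corpus))
  vocab <- stage("corpus", build_vocabulary(corpus))

  stim_cfg <- config$corpus
  stim_cfg$n_sentences <- config$n_stimulus_sentences
  stim_cfg$seed <- seeds[1]
  stimuli <- stage("stimuli", as_stimuli(generate_corpus(stim_cfg)))

  models <- stage("models", list(
    ngram = train_ngram(corpus, n = 3),
    topic = train_lda(corpus, config$topic),
    rnn = train_rnn(corpus, config$rnn)
  ))

  probs <- stage("scoring", lapply(models, word_probabilities, stimuli = stimuli))

  # cloze target probabilities loosely track n-gram predictability, as human
  # norms track corpus statistics
  pr <- probs$ngram$prob
  pr[is.na(pr)] <- min(pr, na.rm = TRUE)
  target_prob <- pmin(1, pr^0.5)
  cloze <- stage(
    "cloze",
    generate_cloze_norms(stimuli, target_prob, K = config$cloze_K, seed = seeds[2])
  )

  predictors <- stage("predictors", assemble_predictors(
    stimuli, cloze, probs,
    vocabulary = vocab, K = config$cloze_K
  ))

  effects <- config$effects %||% fixation_effects(
    intercept = log(250), slopes = c(ngram = -0.02),
    gamma_shape = 25, refixation_prob = 0.1, regression_prob = 0.08,
    seed = seeds[3]
  )
  fixations <- stage(
    "fixations",
    generate_fixations(stimuli, predictors, effects, n_trials = config$n_trials)
  )

  records <- stage(
    "viewing-times",
    compute_viewing_times(fixations, stimuli, policy = config$policy)
  )

  items <- stage("items", item_summaries(records, predictors))
  correlations <- stage(
    "correlations",
    item_correlations(items, sources = c("ccp", "ngram", "topic", "rnn"))
  )

  dat <- gam_data(records, predictors)
  ladders <- stage("gam-ladder", {
    out <- list()
    for (m in config$measures) {
      for (src in config$sources) {
        out[[paste(m, paste(src, collapse = "+"), sep = ":")]] <-
          run_ladder(dat, m, src, k = config$gam_k)
      }
    }
    out
  })

  manifest <- tibble(
    stage = c(
      "corpus", "stimuli", "cloze", "predictors", "targets", "fixations",
      "records", "items"
    ),
    rows = c(
      nrow(corpus), nrow(stimuli), nrow(cloze), nrow(predictors),
      sum(predictors$is_target), nrow(fixations), nrow(records), nrow(items)
    ),
    seed = c(
      config$corpus$seed, seeds[1], seeds[2], NA, NA, effects$seed, NA, NA
    )
  )

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_corpus(corpus, file.path(output_dir, "corpus.txt"))
    write_stimuli(stimuli, file.path(output_dir, "stimuli.tsv"))
    write_cloze(cloze, file.path(output_dir, "cloze.tsv"))
    write_fixations(fixations, file.path(output_dir, "fixations.tsv"))
    readr::write_tsv(predictors, file.path(output_dir, "predictors.tsv"))
    readr::write_tsv(manifest, file.path(output_dir, "manifest.tsv"))
  }

  list(
    corpus = corpus, stimuli = stimuli, models = models, cloze = cloze,
    predictors = predictors, fixations = fixations, records = records,
    items = items, correlations = correlations, ladders = ladders,
    manifest = manifest
  )
}
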