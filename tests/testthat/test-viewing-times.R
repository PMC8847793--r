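fx_row <- function(participant, trial, sent, word, idx, dur, land = 1) {
  tibble::tibble(
    participant = participant, trial = trial, sentence_id = sent,
    word_pos = word, fix_index = idx, duration_ms = dur,
    landing_letter = land
  )
}

test_that("the definitional viewing-time cases hold", {
  # single fixation, no revisit
  fx <- fx_row(1, 1, 1, 1, 1, 250)
  r <- compute_viewing_times(fx)
  expect_equal(c(r$sfd, r$gd, r$tvt), c(250, 250, 250))

  # refixated first pass plus a later revisit
  fx <- dplyr::bind_rows(
    fx_row(1, 1, 1, 2, 1, 200),
    fx_row(1, 1, 1, 2, 2, 150),
    fx_row(1, 1, 1, 3, 3, 300),
    fx_row(1, 1, 1, 2, 4, 100)
  )
  r <- compute_viewing_times(fx) |> dplyr::filter(word_pos == 2)
  expect_true(is.na(r$sfd))
  expect_equal(r$gd, 350)
  expect_equal(r$tvt, 450)

  # 5 -> 3 -> 5: the second visit to 5 counts toward TVT only
  fx <- dplyr::bind_rows(
    fx_row(1, 1, 1, 5, 1, 220),
    fx_row(1, 1, 1, 3, 2, 180),
    fx_row(1, 1, 1, 5, 3, 120)
  )
  r <- compute_viewing_times(fx) |> dplyr::filter(word_pos == 5)
  expect_equal(r$sfd, 220)
  expect_equal(r$gd, 220)
  expect_equal(r$tvt, 340)
})

test_that("measure availability nests and TVT is additive", {
  co <- planted_corpus(seed = 61, n_sentences = 20)
  stim <- as_stimuli(co)
  eff <- fixation_effects(refixation_prob = 0.3, regression_prob = 0.25, seed = 3)
  fx <- generate_fixations(stim, stim[c("sentence_id", "word_pos")], eff, 10)
  r <- compute_viewing_times(fx, stim)
  expect_true(all(!is.na(r$gd)))
  expect_true(all(!is.na(r$tvt)))
  expect_true(all(is.na(r$sfd) | r$sfd == r$gd))
  expect_true(all(r$gd <= r$tvt + 1e-9))
  # additivity: revisit durations are exactly TVT - GD
  revisit <- fx |>
    dplyr::group_by(participant, trial) |>
    dplyr::mutate(visit = cumsum(c(TRUE, diff(word_pos) != 0))) |>
    dplyr::group_by(participant, trial, word_pos) |>
    dplyr::summarise(
      rv = sum(duration_ms[visit != min(visit)]),
      .groups = "drop"
    )
  j <- dplyr::inner_join(r, revisit, by = c("participant", "trial", "word_pos"))
  expect_equal(j$tvt - j$gd, j$rv, tolerance = 1e-9)
  # relative landing position lies in (0, 1]
  expect_true(all(r$rel_landing > 0 & r$rel_landing <= 1))
})

test_that("without refixations or regressions SFD covers every fixated word", {
  co <- planted_corpus(seed = 62, n_sentences = 15)
  stim <- as_stimuli(co)
  eff <- fixation_effects(refixation_prob = 0, regression_prob = 0, seed = 4)
  fx <- generate_fixations(stim, stim[c("sentence_id", "word_pos")], eff, 5)
  r <- compute_viewing_times(fx, stim)
  expect_true(all(!is.na(r$sfd)))
  expect_equal(r$sfd, r$gd)
  expect_equal(r$sfd, r$tvt)
})

test_that("cutoff boundaries behave as inclusive exclusions", {
  fx <- dplyr::bind_rows(
    fx_row(1, 1, 1, 1, 1, 60), # below the 70 ms floor: dropped pre-aggregation
    fx_row(1, 1, 1, 2, 2, 800), # SFD of exactly 800: excluded
    fx_row(1, 2, 1, 2, 1, 799), # retained
    fx_row(1, 3, 1, 3, 1, 600),
    fx_row(1, 3, 1, 4, 2, 599),
    fx_row(1, 3, 1, 3, 3, 600), # TVT 1200 < 1600 retained; GD 600
    fx_row(1, 4, 1, 5, 1, 700),
    fx_row(1, 4, 1, 5, 2, 500), # GD 1200 exactly: excluded
    fx_row(1, 5, 1, 6, 1, 700),
    fx_row(1, 5, 1, 6, 2, 499) # GD 1199: retained
  )
  r <- compute_viewing_times(fx, policy = cutoff_policy())
  excl <- attr(r, "exclusions")
  expect_equal(excl$n[excl$rule == "fixation < floor"], 1L)
  # word 1 only had the sub-floor fixation: no record at all
  expect_false(any(r$word_pos == 1))
  expect_true(is.na(r$sfd[r$trial == 1 & r$word_pos == 2]))
  expect_equal(r$sfd[r$trial == 2 & r$word_pos == 2], 799)
  expect_true(is.na(r$gd[r$trial == 4 & r$word_pos == 5]))
  expect_equal(r$gd[r$trial == 5 & r$word_pos == 6], 1199)
  # TVT boundary
  fx2 <- dplyr::bind_rows(
    fx_row(1, 1, 1, 2, 1, 900),
    fx_row(1, 1, 1, 3, 2, 100),
    fx_row(1, 1, 1, 2, 3, 700) # TVT 1600 exactly: excluded; GD 900 kept
  )
  r2 <- compute_viewing_times(fx2, policy = cutoff_policy())
  expect_true(is.na(r2$tvt[r2$word_pos == 2]))
  expect_equal(r2$gd[r2$word_pos == 2], 900)
})

test_that("ordering and reference errors are raised", {
  bad <- dplyr::bind_rows(fx_row(1, 1, 1, 1, 2, 250), fx_row(1, 1, 1, 2, 1, 250))
  expect_error(compute_viewing_times(bad), class = "lexpred_ordering_error")
  stim <- as_stimuli(new_corpus(list(c("aa", "bb"))))
  off <- fx_row(1, 1, 1, 9, 1, 250)
  expect_error(
    compute_viewing_times(off, stim),
    class = "lexpred_reference_error"
  )
  expect_error(
    compute_viewing_times(fx_row(1, 1, 1, 1, 1, -5)),
    class = "lexpred_validation_error"
  )
})
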