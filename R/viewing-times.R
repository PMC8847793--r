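#' Duration cutoff policy
#'
#' The floor is applied to individual fixations before any aggregation:
#' fixations shorter than `floor` ms are dropped. The ceilings are applied to
#' the aggregated measures, as inclusive exclusions: a measure value greater
#' than or equal to its ceiling is removed from that measure's analysis set
#' (set to `NA`), so an SFD of exactly 800 ms is excluded while a GD of
#' 1199 ms is retained.
#'
#' @param floor Minimum individual fixation duration in ms (default 70).
#' @param sfd_max,gd_max,tvt_max Measure ceilings in ms (defaults 800, 1200,
#'   1600).
#' @return A `cutoff_policy` list.
#' @export
cutoff_policy <- function(floor = 70, sfd_max = 800, gd_max = 1200,
                          tvt_max = 1600) {
  if (any(c(sfd_max, gd_max, tvt_max) <= floor)) {
    stop_lexpred("floor must be below all ceilings", "lexpred_config_error")
  }
  structure(
    list(floor = floor, sfd_max = sfd_max, gd_max = gd_max, tvt_max = tvt_max),
    class = "cutoff_policy"
  )
}

#' Word viewing times from fixation events
#'
#' Computes, per participant x trial x word: the first pass (the maximal run
#' of consecutive fixations on the word starting at its first fixation,
#' before any fixation on a different word), single-fixation duration (SFD,
#' defined only when the first pass has exactly one fixation, in which case
#' SFD = GD), gaze duration (GD, sum of first-pass durations), total viewing
#' time (TVT, sum of all durations on the word in the trial, so
#' GD <= TVT), and the relative landing position (first-fixation landing
#' letter divided by word length, in `(0, 1]`). Skipped words yield no row.
#'
#' If a `policy` is supplied, fixations below the floor are dropped before
#' aggregation and the measure ceilings are applied afterwards via
#' [apply_cutoffs()]; the exclusion report is attached as attribute
#' `exclusions`.
#'
#' @param fixations A fixation tibble (`participant`, `trial`, `sentence_id`,
#'   `word_pos`, `fix_index`, `duration_ms`, `landing_letter`), sorted by
#'   fixation order within trial.
#' @param stimuli Optional stimulus tibble used to validate word references
#'   and compute relative landing position from word length.
#' @param policy Optional [cutoff_policy()].
#' @return A viewing-time tibble `participant`, `trial`, `sentence_id`,
#'   `word_pos`, `sfd`, `gd`, `tvt`, `rel_landing`.
#' @export
compute_viewing_times <- function(fixations, stimuli = NULL, policy = NULL) {
  check_columns(
    fixations,
    c("participant", "trial", "sentence_id", "word_pos", "fix_index", "duration_ms"),
    "fixation report"
  )
  if (any(fixations$duration_ms <= 0)) {
    stop_lexpred("fixation durations must be > 0", "lexpred_validation_error")
  }
  ord_ok <- fixations |>
    group_by(.data$participant, .data$trial) |>
    summarise(ok = !is.unsorted(.data$fix_index, strictly = TRUE), .groups = "drop")
  if (!all(ord_ok$ok)) {
    stop_lexpred(
      "fixations must be sorted by fix_index within participant x trial",
      "lexpred_ordering_error"
    )
  }
  if (!is.null(stimuli)) {
    key_fix <- paste(fixations$sentence_id, fixations$word_pos)
    key_stim <- paste(stimuli$sentence_id, stimuli$word_pos)
    if (!all(key_fix %in% key_stim)) {
      stop_lexpred(
        "fixation references a (sentence, word) pair absent from the stimuli",
        "lexpred_reference_error"
      )
    }
  }

  n_floor <- 0L
  if (!is.null(policy)) {
    keep <- fixations$duration_ms >= policy$floor
    n_floor <- sum(!keep)
    fixations <- fixations[keep, ]
  }

  has_landing <- "landing_letter" %in% names(fixations)
  records <- fixations |>
    group_by(.data$participant, .data$trial) |>
    mutate(visit = cumsum(c(TRUE, diff(.data$word_pos) != 0))) |>
    group_by(.data$participant, .data$trial, .data$sentence_id, .data$word_pos) |>
    mutate(first_pass = .data$visit == min(.data$visit)) |>
    summarise(
      sfd = if (sum(.data$first_pass) == 1) {
        .data$duration_ms[.data$first_pass][1]
      } else {
        NA_real_
      },
      gd = sum(.data$duration_ms[.data$first_pass]),
      tvt = sum(.data$duration_ms),
      landing_letter = if (has_landing) {
        .data$landing_letter[.data$first_pass][1]
      } else {
        NA_integer_
      },
      .groups = "drop"
    )

  if (!is.null(stimuli) && "word_length" %in% names(stimuli)) {
    records <- records |>
      dplyr::left_join(
        stimuli[c("sentence_id", "word_pos", "word_length")],
        by = c("sentence_id", "word_pos")
      ) |>
      mutate(rel_landing = .data$landing_letter / .data$word_length) |>
      select(-"word_length")
  } else {
    records$rel_landing <- NA_real_
  }
  records <- select(records, -"landing_letter")

  if (!is.null(policy)) {
    records <- apply_cutoffs(records, policy)
    excl <- attr(records, "exclusions")
    excl$n[excl$rule == "fixation < floor"] <- n_floor
    attr(records, "exclusions") <- excl
  }
  records
}

#' Apply measure-level duration ceilings
#'
#' Sets measure values at or above the measure-specific ceiling to `NA`
#' ("800 ms or greater" style inclusive exclusion) and attaches an exclusion
#' report counting removals per rule as attribute `exclusions`. The
#' fixation-level floor belongs to [compute_viewing_times()], which removes
#' short fixations before aggregation; its count is carried in the report
#' when the full pipeline is used.
#'
#' @param records A viewing-time tibble from [compute_viewing_times()].
#' @param policy A [cutoff_policy()].
#' @return The records with censored measures and an `exclusions` attribute
#'   (tibble `rule`, `n`).
#' @export
apply_cutoffs <- function(records, policy = cutoff_policy()) {
  stopifnot(inherits(policy, "cutoff_policy"))
  check_columns(records, c("sfd", "gd", "tvt"), "viewing-time records")
  n_sfd <- sum(records$sfd >= policy$sfd_max, na.rm = TRUE)
  n_gd <- sum(records$gd >= policy$gd_max, na.rm = TRUE)
  n_tvt <- sum(records$tvt >= policy$tvt_max, na.rm = TRUE)
  records <- records |>
    mutate(
      sfd = ifelse(.data$sfd >= policy$sfd_max, NA_real_, .data$sfd),
      gd = ifelse(.data$gd >= policy$gd_max, NA_real_, .data$gd),
      tvt = ifelse(.data$tvt >= policy$tvt_max, NA_real_, .data$tvt)
    )
  attr(records, "exclusions") <- tibble(
    rule = c(
      "fixation < floor", "sfd >= ceiling", "gd >= ceiling", "tvt >= ceiling"
    ),
    n = c(0L, n_sfd, n_gd, n_tvt)
  )
  records
}
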