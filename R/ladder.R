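#' Baseline GAM terms for viewing-time analysis
#'
#' The baseline model contains the single-word covariates of the present,
#' last and next word — length and frequency class — plus the relative
#' landing position, seven smooths in all.
#'
#' @return Character vector of baseline term names.
#' @export
baseline_terms <- function() {
  c(
    "rel_landing", "length", "length_last", "length_next",
    "freq", "freq_last", "freq_next"
  )
}

#' Run the GAM comparison ladder for one predictability source
#'
#' Fits the baseline GAM, then successively adds the predictability of the
#' present word, the last word and the next word for the given source(s),
#' comparing each fit against the previous one: GCV, change in adjusted
#' R-squared (percentage points), deviance difference with effective-df
#' difference, and the chi-square test at `alpha`. With several sources
#' (e.g. `c("ngram", "topic", "rnn")`) each step adds that role's term for
#' all sources at once, giving the combined-language-model ladder.
#'
#' @param data Fixation-record-level analysis table ([gam_data()]).
#' @param response Measure column: `"sfd"`, `"gd"` or `"tvt"`.
#' @param sources Predictability source name(s): columns `source`,
#'   `source_last`, `source_next` must exist (e.g. `"ccp"`, `"ngram"`,
#'   `"topic"`, `"rnn"`).
#' @param roles Which roles to add, in order. Default present, last, next.
#' @param baseline Baseline term names; default [baseline_terms()].
#' @param k Basis dimension per smooth.
#' @param alpha Decision level for the chi-square tests.
#' @return An object of class `reading_ladder`: a tibble with one row per
#'   step (`step`, `terms_added`, `gcv`, `adj_r_squared`, `delta_r2`,
#'   `deviance_diff`, `df_diff`, `statistic`, `p.value`, `significant`) with
#'   the fits in attribute `fits`.
#' @export
run_ladder <- function(data, response, sources,
                       roles = c("present", "last", "next"),
                       baseline = baseline_terms(), k = 10, alpha = 0.05) {
  role_cols <- function(role) {
    if (role == "present") sources else paste0(sources, "_", role)
  }
  needed <- c(response, baseline, unlist(lapply(roles, role_cols)))
  check_columns(data, needed, "analysis data")

  terms <- baseline
  fits <- list(baseline = fit_reading_gam(data, response, terms, k = k))
  g0 <- glance(fits$baseline)
  steps <- list(tibble(
    step = "baseline", terms_added = list(baseline),
    gcv = g0$gcv, adj_r_squared = g0$adj_r_squared,
    delta_r2 = NA_real_, deviance_diff = NA_real_, df_diff = NA_real_,
    statistic = NA_real_, p.value = NA_real_, significant = NA
  ))
  # drop rows missing any ladder column once, so every fit shares its rows
  data <- data[complete.cases(data[needed]), , drop = FALSE]
  fits$baseline <- fit_reading_gam(data, response, terms, k = k)
  g0 <- glance(fits$baseline)
  steps[[1]]$gcv <- g0$gcv
  steps[[1]]$adj_r_squared <- g0$adj_r_squared

  prev <- fits$baseline
  for (role in roles) {
    add <- role_cols(role)
    terms <- c(terms, add)
    label <- paste0("+ ", role)
    fit <- fit_reading_gam(data, response, terms, k = k)
    cmp <- compare_gams(prev, fit, alpha = alpha)
    steps[[length(steps) + 1]] <- tibble(
      step = label, terms_added = list(add),
      gcv = cmp$gcv, adj_r_squared = glance(fit)$adj_r_squared,
      delta_r2 = cmp$delta_r2, deviance_diff = cmp$deviance_diff,
      df_diff = cmp$df_diff, statistic = cmp$statistic,
      p.value = cmp$p.value, significant = cmp$significant
    )
    fits[[label]] <- fit
    prev <- fit
  }
  out <- list_rbind(steps)
  attr(out, "fits") <- fits
  attr(out, "response") <- response
  attr(out, "sources") <- sources
  class(out) <- c("reading_ladder", class(out))
  out
}

#' @export
print.reading_ladder <- function(x, ...) {
  cat(sprintf(
    "GAM ladder for %s (%s)\n",
    attr(x, "response"), paste(attr(x, "sources"), collapse = " + ")
  ))
  df <- as.data.frame(x[c(
    "step", "gcv", "delta_r2", "deviance_diff", "df_diff", "p.value"
  )])
  df$sig <- ifelse(!is.na(x$significant) & x$significant, "*", "")
  print(df, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Full model with every predictability source
#'
#' Fits a single GAM containing the baseline covariates plus present-, last-
#' and next-word predictability of every source, the design used to report
#' per-term F and effective degrees of freedom when all predictors compete
#' for variance.
#'
#' @inheritParams run_ladder
#' @return A `reading_gam`; use [tidy()] for the per-term F/edf table.
#' @export
fit_full_model <- function(data, response,
                           sources = c("ccp", "ngram", "topic", "rnn"),
                           baseline = baseline_terms(), k = 10) {
  terms <- c(
    baseline,
    sources, paste0(sources, "_last"), paste0(sources, "_next")
  )
  fit_reading_gam(data, response, terms, k = k)
}

#' Ladder step effects as a plot
#'
#' @param object A `reading_ladder`.
#' @param ... Unused.
#' @return A ggplot bar chart of the adjusted-R-squared increments per step.
#' @export
autoplot.reading_ladder <- function(object, ...) {
  df <- as_tibble(object[-1, c("step", "delta_r2", "significant")])
  df$step <- factor(df$step, levels = df$step)
  ggplot(df, aes(x = .data$step, y = .data$delta_r2, fill = .data$significant)) +
    geom_col() +
    labs(
      x = NULL, y = "adj. R-squared change (percentage points)",
      title = sprintf(
        "%s ladder: %s", attr(object, "response"),
        paste(attr(object, "sources"), collapse = " + ")
      )
    ) +
    theme_minimal()
}
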