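test_that("item correlations satisfy the basic identities", {
  set.seed(71)
  items <- tibble::tibble(
    length = rpois(60, 5) + 1,
    ccp = rnorm(60), ngram = rnorm(60),
    topic = rnorm(60), rnn = rnorm(60),
    mean_sfd = rnorm(60, 250, 20),
    mean_gd = rnorm(60, 300, 30),
    mean_tvt = rnorm(60, 350, 40)
  )
  items$topic <- items$ngram # two identical columns
  cm <- item_correlations(items, covariates = "length")
  expect_equal(diag(cm), rep(1, nrow(cm)), ignore_attr = TRUE)
  expect_equal(cm["ngram", "topic"], 1)
  expect_equal(cm, t(cm))
  # zero-variance column flagged, not fatal
  items$rnn <- 1
  expect_warning(
    cm2 <- item_correlations(items, covariates = "length"),
    "zero-variance"
  )
  expect_true(is.na(cm2["rnn", "mean_gd"]))
  expect_error(
    item_correlations(items[1:2, ]),
    class = "lexpred_validation_error"
  )
})

test_that("transformed predictors correlate more strongly under log-scale effects", {
  # item-level means with log-mean durations linear in log10 probability
  set.seed(72)
  n <- 400
  raw <- 10^runif(n, -8, -0.5)
  lg <- log10(raw)
  mean_gd <- exp(log(300) - 0.02 * lg + rnorm(n, 0, 0.05))
  items <- tibble::tibble(
    ngram_raw = raw, ngram = lg,
    ccp_raw = raw, ccp = lg,
    mean_sfd = mean_gd, mean_gd = mean_gd, mean_tvt = mean_gd
  )
  ct <- item_correlations(items, sources = "ngram", covariates = character(0))
  cr <- item_correlations(items,
    sources = "ngram", transformed = FALSE,
    covariates = character(0)
  )
  expect_gt(abs(ct["ngram", "mean_gd"]), abs(cr["ngram_raw", "mean_gd"]))
})

test_that("an intercept-only gamma GAM explains nothing", {
  d <- gamma_events(500, slopes = c(x1 = 0), seed = 73)
  f <- fit_reading_gam(d, "y", character(0))
  expect_lt(abs(glance(f)$adj_r_squared), 0.01)
})

test_that("a planted log-link slope is recovered within 20 percent", {
  set.seed(74)
  n <- 5000
  x <- rnorm(n, -4, 1.5)
  d <- tibble::tibble(x = x, y = rgamma(n, 25, 25 / exp(log(250) - 0.05 * x)))
  f <- fit_reading_gam(d, "y", "x")
  cv <- export_smooths(f, "x", n = 100)
  qs <- quantile(d$x, c(0.1, 0.9))
  central <- cv[cv$x >= qs[1] & cv$x <= qs[2], ]
  slope <- coef(lm(effect ~ x, data = central))[[2]]
  expect_lt(abs(slope - (-0.05)) / 0.05, 0.2)
  # monotone decreasing over the central 80%
  expect_true(all(diff(central$effect) < 0))
})

test_that("null smooth terms shrink and stay non-significant", {
  set.seed(75)
  hits <- replicate(100, {
    d <- gamma_events(300,
      slopes = c(x1 = -0.3, x2 = 0),
      seed = sample.int(1e6, 1)
    )
    f <- fit_reading_gam(d, "y", c("x1", "x2"))
    td <- tidy(f)
    c(edf = td$edf[td$term == "x2"], sig = td$p.value[td$term == "x2"] < 0.05)
  })
  expect_gte(mean(hits["sig", ] == 0), 0.9) # non-significant in >= 90%
  expect_lt(median(hits["edf", ]), 1.5) # penalized toward a line or out
})

test_that("identical specifications compare as a perfect tie", {
  d <- gamma_events(300, seed = 76)
  r <- fit_reading_gam(d, "y", "x1")
  e <- fit_reading_gam(d, "y", "x1")
  cmp <- compare_gams(r, e)
  expect_equal(cmp$delta_r2, 0)
  expect_equal(cmp$deviance_diff, 0)
  expect_equal(cmp$p.value, 1)
})

test_that("comparison guards reject mismatched fits", {
  d1 <- gamma_events(300, seed = 77)
  d2 <- gamma_events(300, seed = 78)
  r <- fit_reading_gam(d1, "y", "x1")
  e <- fit_reading_gam(d2, "y", "x1")
  expect_error(compare_gams(r, e), class = "lexpred_comparison_error")
  d1$x2 <- runif(300)
  a <- fit_reading_gam(d1, "y", "x1")
  b <- fit_reading_gam(d1, "y", "x2")
  expect_error(compare_gams(a, b), class = "lexpred_comparison_error")
})

test_that("adding terms never increases the deviance", {
  d <- gamma_events(600, slopes = c(x1 = -0.2, x2 = 0), seed = 79)
  r <- fit_reading_gam(d, "y", "x1")
  e <- fit_reading_gam(d, "y", c("x1", "x2"))
  expect_gte(compare_gams(r, e)$deviance_diff, -1e-6)
})

test_that("exported smooth curves meet their contracts", {
  set.seed(80)
  n <- 2000
  d <- tibble::tibble(
    x1 = runif(n, -2, 2), x2 = runif(n, 0, 1)
  )
  d$y <- rgamma(n, 25, 25 / exp(log(250) - 0.1 * d$x1)) # x2 has no effect
  f <- fit_reading_gam(d, "y", c("x1", "x2"))
  c1 <- export_smooths(f, "x1")
  # grid covers the observed range exactly
  expect_equal(range(c1$x), range(d$x1))
  # linear truth: central deviation from the best-fit line under 2 SE
  qs <- quantile(d$x1, c(0.1, 0.9))
  cc <- c1[c1$x >= qs[1] & c1$x <= qs[2], ]
  resid <- stats::residuals(lm(effect ~ x, data = cc))
  expect_true(all(abs(resid) < 2 * cc$se))
  # constant truth: curve within 2 SE of zero everywhere
  c2 <- export_smooths(f, "x2")
  expect_true(all(abs(c2$effect) <= 2 * pmax(c2$se, 1e-8) + 1e-8))
  expect_error(export_smooths(f, "zz"), class = "lexpred_reference_error")
})

test_that("the ladder runs on a small fixture and reports every step", {
  set.seed(81)
  n <- 120
  d <- tibble::tibble(
    rel_landing = runif(n, 0.1, 1),
    length = sample(2:9, n, TRUE),
    length_last = sample(2:9, n, TRUE),
    length_next = sample(2:9, n, TRUE),
    freq = sample(0:5, n, TRUE),
    freq_last = sample(0:5, n, TRUE),
    freq_next = sample(0:5, n, TRUE),
    ngram = rnorm(n, -4, 1.5),
    ngram_last = rnorm(n, -4, 1.5),
    ngram_next = rnorm(n, -4, 1.5)
  )
  d$gd <- rgamma(n, 25, 25 / exp(log(300) - 0.05 * d$ngram))
  lad <- run_ladder(d, "gd", "ngram", k = 5)
  expect_equal(lad$step, c("baseline", "+ present", "+ last", "+ next"))
  expect_true(all(is.finite(lad$gcv)))
  expect_true(all(is.finite(lad$deviance_diff[-1])))
  expect_true(all(is.finite(lad$df_diff[-1])))
  expect_true(all(!is.na(lad$p.value[-1])))
})

test_that("the ladder attributes effects to the role that carries them", {
  set.seed(82)
  n <- 1500
  d <- tibble::tibble(
    rel_landing = runif(n, 0.1, 1),
    length = sample(2:9, n, TRUE),
    length_last = sample(2:9, n, TRUE),
    length_next = sample(2:9, n, TRUE),
    freq = sample(0:5, n, TRUE),
    freq_last = sample(0:5, n, TRUE),
    freq_next = sample(0:5, n, TRUE),
    ngram = rnorm(n, -4, 1.5),
    ngram_last = rnorm(n, -4, 1.5),
    ngram_next = rnorm(n, -4, 1.5)
  )
  # present-word effect only
  d$gd <- rgamma(n, 25, 25 / exp(log(300) - 0.08 * d$ngram))
  lad <- run_ladder(d, "gd", "ngram", k = 5)
  expect_true(lad$significant[lad$step == "+ present"])
  expect_false(lad$significant[lad$step == "+ last"])
  expect_false(lad$significant[lad$step == "+ next"])
})
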