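test_that("quantile_def2 follows the EDF-inversion-with-averaging rule", {
  expect_equal(quantile_def2(c(1, 2, 3, 4), 0.5), 2.5)
  expect_equal(quantile_def2(c(1, 2, 3, 4), 0.3), 2)
  expect_equal(quantile_def2(rep(7, 10), 0.123), 7)
  expect_equal(quantile_def2(c(5, 1), 0.1), 1)     # n*p < 1
  expect_equal(quantile_def2(c(1, 2, 3, 4), 0.999), 4)
  expect_error(quantile_def2(1:4, 0), "\\(0, 1\\)")
  expect_error(quantile_def2(numeric(0), 0.5), "non-empty")
  # agrees with the standard type-2 sample quantile
  set.seed(9)
  x <- rnorm(137)
  for (p in c(0.025, 0.1, 0.5, 0.9, 0.975)) {
    expect_equal(quantile_def2(x, p),
                 unname(stats::quantile(x, p, type = 2)))
  }
})

test_that("bootstrap is deterministic given a seed and degenerate on constant classes", {
  s <- toy_sample()
  b1 <- roc_bootstrap(s, "aurc", B = 50, seed = 42)
  b2 <- roc_bootstrap(s, "aurc", B = 50, seed = 42)
  expect_identical(b1$replications, b2$replications)
  b3 <- roc_bootstrap(s, "aurc", B = 50, seed = 43)
  expect_false(identical(b1$replications$value, b3$replications$value))

  deg <- score_sample(rep(5, 8), rep(1, 9))
  for (spec in list(stat_spec("aurc"), stat_spec("eer"),
                    stat_spec("tar_at_far", far = 0.3),
                    stat_spec("rates_at_threshold", threshold = 3))) {
    b <- roc_bootstrap(deg, spec = spec, B = 20, seed = 1)
    sm <- summarize_bootstrap(b)
    expect_equal(sm$std_error, rep(0, nrow(sm)))
    expect_equal(sm$ci_quantile_lower, sm$estimate)
    expect_equal(sm$ci_normal_upper, sm$estimate)
  }
})

test_that("replications match statistics recomputed on reconstructed resamples", {
  # the multinomial resampling path must agree with evaluating the plain
  # statistic on an equivalent rebuilt sample
  s <- toy_sample()
  b <- roc_bootstrap(s, "aurc", B = 5, seed = 11)
  d <- score_distribution(s)
  set.seed(11)
  gmat <- stats::rmultinom(5, attr(d, "n_genuine"), d$count_genuine)
  imat <- stats::rmultinom(5, attr(d, "n_impostor"), d$count_impostor)
  manual <- vapply(1:5, function(j) {
    aurc(score_sample(rep(d$score, gmat[, j]), rep(d$score, imat[, j])))
  }, numeric(1))
  expect_equal(b$replications$value, manual)
})

test_that("summaries carry both CI styles with quantile endpoints from the replication set", {
  s <- simulate_scores(preset_low_accuracy(n_genuine = 80, n_impostor = 120),
                       seed = 2)
  b <- roc_bootstrap(s, "eer", B = 199, seed = 3)
  sm <- summarize_bootstrap(b, alpha = 0.05)
  v <- sort(b$replications$value)
  # endpoints are members, or midpoints of adjacent members, of the set
  is_member_or_midpoint <- function(q) {
    any(abs(v - q) < 1e-12) ||
      any(abs((v[-length(v)] + v[-1]) / 2 - q) < 1e-12)
  }
  expect_true(is_member_or_midpoint(sm$ci_quantile_lower))
  expect_true(is_member_or_midpoint(sm$ci_quantile_upper))
  expect_lte(sm$ci_quantile_lower, sm$ci_quantile_upper)
  expect_equal(sm$std_error, sd(b$replications$value))
  expect_equal(sm$ci_normal_lower, sm$estimate - qnorm(0.975) * sm$std_error)
  expect_error(summarize_bootstrap(b, alpha = 1.2), "\\(0, 1\\)")
})

test_that("rates_at_threshold bootstraps two paired components", {
  s <- simulate_scores(preset_low_accuracy(n_genuine = 60, n_impostor = 90),
                       seed = 8)
  b <- roc_bootstrap(s, "rates_at_threshold", threshold = 1.5, B = 30, seed = 4)
  expect_setequal(unique(b$replications$statistic), c("tar", "far"))
  expect_equal(nrow(b$replications), 60)
  sm <- summarize_bootstrap(b)
  expect_equal(sm$statistic, c("tar", "far"))
  g <- glance(b)
  expect_equal(g$B, 30)
  expect_equal(g$statistic, "rates_at_threshold")
})

test_that("bootstrap SE of TAR at FAR shrinks as class separation grows", {
  hi <- simulate_scores(preset_high_accuracy(), seed = 21)
  lo <- simulate_scores(preset_low_accuracy(), seed = 21)
  se_hi <- summarize_bootstrap(
    roc_bootstrap(hi, "tar_at_far", far = 0.05, B = 400, seed = 6))$std_error
  se_lo <- summarize_bootstrap(
    roc_bootstrap(lo, "tar_at_far", far = 0.05, B = 400, seed = 6))$std_error
  expect_lt(se_hi, se_lo)
})

test_that("stat_spec validates its parameters", {
  expect_error(stat_spec("tar_at_far"), "`far` must be supplied")
  expect_error(stat_spec("tar_at_far", far = 1.2), "\\(0, 1\\)")
  expect_error(stat_spec("weighted_cost"), "`threshold`")
  expect_error(stat_spec("weighted_cost", threshold = 1, w1 = -2),
               "non-negative")
  expect_error(roc_bootstrap(toy_sample(), "aurc", B = 1), "at least 2")
})
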