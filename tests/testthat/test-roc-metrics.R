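test_that("roc_curve runs from the origin to (1,1) through counted vertices", {
  cur <- roc_curve(toy_sample())
  expect_equal(cur$far[1], 0)
  expect_equal(cur$tar[1], 0)
  expect_equal(cur$far[nrow(cur)], 1)
  expect_equal(cur$tar[nrow(cur)], 1)
  expect_true(all(diff(cur$far) >= 0) && all(diff(cur$tar) >= 0))
  # hand-derived vertices (C_I, C_G) at scores 3 and 2
  expect_true(any(abs(cur$far - 1 / 6) < 1e-12 & abs(cur$tar - 1 / 2) < 1e-12))
  expect_true(any(abs(cur$far - 1 / 2) < 1e-12 & abs(cur$tar - 3 / 4) < 1e-12))
})

test_that("identical classes put the curve on the diagonal; a single shared value degenerates to two points", {
  cur <- roc_curve(score_sample(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(cur$far, cur$tar)
  cur1 <- roc_curve(score_sample(c(7, 7), c(7)))
  expect_equal(cur1$far, c(0, 1))
  expect_equal(cur1$tar, c(0, 1))
})

test_that("tar_at_far reproduces the tie-division example and vertex collapse", {
  s <- toy_sample()
  r <- tar_at_far(s, 0.25)
  expect_equal(r$threshold, 2)
  expect_equal(r$tar, 0.5625)
  # at an achievable FAR vertex with impostor mass, TAR equals C_G exactly
  v <- tar_at_far(s, 1 / 6)
  expect_equal(v$tar, 0.5)
  expect_equal(v$threshold, 3)
  expect_error(tar_at_far(s, 0), "strictly inside")
  expect_error(tar_at_far(s, 1), "strictly inside")
})

test_that("tar_at_far is non-decreasing in f and matches all vertices", {
  set.seed(17)
  for (rep in 1:10) {
    s <- random_small_sample()
    d <- score_distribution(s)
    fs <- seq(0.02, 0.98, by = 0.02)
    tars <- tar_at_far(d, fs)$tar
    expect_true(all(diff(tars) >= -1e-12))
    vert_idx <- which(d$p_impostor > 0 & d$c_impostor < 1)
    if (length(vert_idx) > 0) {
      expect_equal(tar_at_far(d, d$c_impostor[vert_idx])$tar,
                   d$c_genuine[vert_idx])
    }
  }
})

test_that("rates_at_threshold uses the support ceiling and handles the extremes", {
  s <- toy_sample()
  r <- rates_at_threshold(s, 1.5)
  expect_equal(r$score, 2)
  expect_equal(r$tar, 0.75)
  expect_equal(r$far, 0.5)
  ext <- rates_at_threshold(s, c(3, 3.5, 0, -10))
  expect_equal(ext$tar, c(0.5, 0, 1, 1))   # at s_max: P_G(s_max)
  expect_equal(ext$far, c(1 / 6, 0, 1, 1)) # at s_max: P_I(s_max)
})

test_that("eer matches the exhaustive-scan example and the separating gap", {
  r <- eer(score_sample(c(3, 2, 2, 1), c(2, 1, 1, 0)))
  expect_equal(r$eer, 0.5)
  expect_equal(r$min_absdiff, 0.5)
  expect_equal(c(r$s_lower, r$s_upper), c(1, 2))
  expect_equal(r$threshold, 1)
  expect_equal(r$systematic_error, 0.5)

  # separating gap: the unused score 2 separates the classes perfectly
  gap <- eer(score_sample(c(3, 3), c(1, 1)))
  expect_equal(gap$eer, 0)
  expect_equal(gap$min_absdiff, 0)
  expect_equal(gap$systematic_error, 0)
  expect_equal(c(gap$s_lower, gap$s_upper), c(2, 2))
  expect_equal(gap$threshold, 2)
})

test_that("eer lies between the attainable error-rate extremes and its range is contiguous", {
  set.seed(23)
  for (rep in 1:15) {
    s <- random_small_sample()
    d <- score_distribution(s)
    r <- eer(d)
    er1 <- 1 - c(d$c_genuine[-1], 0)
    er2 <- d$c_impostor
    expect_gte(r$eer + 1e-12, min(er1))
    expect_lte(r$eer - 1e-12, max(er2))
    expect_true(r$s_lower <= r$threshold && r$threshold <= r$s_upper)
    # the minimizing set is contiguous in the support
    absdiff <- abs(er1 - er2)
    idx <- which(absdiff <= min(absdiff) + 1e-15)
    expect_equal(idx, seq(min(idx), max(idx)))
  }
})

test_that("aurc equals exhaustive pair counting and the trapezoidal curve area", {
  s <- toy_sample()
  expect_equal(aurc(s), 17 / 24)
  expect_equal(aurc(score_sample(1:5, 1:5)), 0.5)
  expect_equal(aurc(score_sample(6:8, 1:5)), 1)
  set.seed(31)
  for (rep in 1:10) {
    s <- random_small_sample()
    expect_equal(aurc(s), oracle_aurc(genuine_scores(s), impostor_scores(s)))
    expect_equal(aurc(s), roc_curve_area(roc_curve(s)), tolerance = 1e-12)
  }
})

test_that("weighted_cost reduces to its components and sums the toy rates", {
  s <- toy_sample()
  expect_equal(weighted_cost(s, 1.5, w1 = 1, w2 = 0), 0.25)
  expect_equal(weighted_cost(s, 1.5, w1 = 0, w2 = 1), 0.5)
  expect_equal(weighted_cost(s, 1.5, w1 = 1, w2 = 1), 0.75)
  expect_error(weighted_cost(s, 1.5, w1 = -1), "non-negative")
})

test_that("fnmr_transform reflects the estimate and swaps CI bounds, keeping the SE", {
  b <- roc_bootstrap(toy_sample(), "tar_at_far", far = 0.25, B = 100, seed = 5)
  sm <- summarize_bootstrap(b)
  fn <- fnmr_transform(sm)
  expect_equal(fn$estimate, 1 - sm$estimate)
  expect_equal(fn$std_error, sm$std_error)
  expect_equal(fn$ci_quantile_lower, 1 - sm$ci_quantile_upper)
  expect_equal(fn$ci_normal_upper, 1 - sm$ci_normal_lower)
  expect_equal(fn$statistic, "fnmr_tar")
})
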