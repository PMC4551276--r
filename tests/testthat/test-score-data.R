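test_that("score samples validate sizes and finiteness", {
  s <- toy_sample()
  expect_equal(n_genuine(s), 4)
  expect_equal(n_impostor(s), 6)
  expect_error(score_sample(numeric(0), 1), "genuine set empty")
  expect_error(score_sample(1, numeric(0)), "impostor set empty")
  expect_error(score_sample(c(1, NaN), 1), "non-finite genuine score at position 2")
  expect_error(score_sample(1, c(2, Inf)), "non-finite impostor score at position 2")
})

test_that("labelled score files parse with row-accurate errors", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("genuine,3", "genuine,3", "genuine,2", "genuine,1",
               "impostor,3", "impostor,2", "impostor,2", "impostor,1",
               "impostor,1", "impostor,0"), tf)
  s <- read_scores(scores = tf)
  expect_equal(n_genuine(s), 4)
  expect_equal(n_impostor(s), 6)
  expect_equal(genuine_scores(s), c(3, 3, 2, 1))

  writeLines(c("genuine,1", "impostor,abc"), tf)
  expect_error(read_scores(scores = tf), "non-numeric score 'abc' at row 2")

  writeLines(c("genuine,1", "genuine,2"), tf)
  expect_error(read_scores(scores = tf), "impostor set empty")

  writeLines(c("genuine,1", "intruder,2"), tf)
  expect_error(read_scores(scores = tf), "unknown label 'intruder' at row 2")
})

test_that("one-per-line files parse and preserve order", {
  gf <- withr::local_tempfile()
  impf <- withr::local_tempfile()
  writeLines(c("3", "1", "2"), gf)
  writeLines(c("0.5", "0.1"), impf)
  s <- read_scores(genuine = gf, impostor = impf)
  expect_equal(genuine_scores(s), c(3, 1, 2))
  expect_equal(impostor_scores(s), c(0.5, 0.1))
  writeLines(c("3", "x"), gf)
  expect_error(read_scores(genuine = gf, impostor = impf),
               "non-numeric score 'x' at row 2")
})

test_that("write_scores round-trips through read_scores", {
  s <- toy_sample()
  tf <- withr::local_tempfile(fileext = ".csv")
  write_scores(s, tf)
  s2 <- read_scores(scores = tf)
  expect_equal(genuine_scores(s2), genuine_scores(s))
  expect_equal(impostor_scores(s2), impostor_scores(s))
})

test_that("paired samples enforce matching class sizes and keep order", {
  a <- toy_sample()
  b <- score_sample(c(1, 2, 3, 4), c(0, 1, 2, 3, 4, 5))
  p <- paired_score_sample(a, b)
  expect_equal(genuine_scores(p$sample_b), c(1, 2, 3, 4))
  expect_error(paired_score_sample(a, score_sample(1:5, 1:6)),
               "genuine score counts differ: A has 4, B has 5")
  expect_error(paired_score_sample(a, score_sample(1:4, 1:5)),
               "impostor score counts differ: A has 6, B has 5")
  ident <- paired_score_sample(a, a)
  expect_identical(genuine_scores(ident$sample_a),
                   genuine_scores(ident$sample_b))
})

test_that("distinct-values discretization matches hand counts", {
  d <- score_distribution(toy_sample())
  expect_equal(d$score, c(0, 1, 2, 3))
  expect_equal(d$p_genuine, c(0, 0.25, 0.25, 0.5))
  expect_equal(d$c_genuine, c(1, 1, 0.75, 0.5))
  expect_equal(d$c_impostor, c(1, 5 / 6, 0.5, 1 / 6))
})

test_that("distribution invariants hold on random samples", {
  set.seed(41)
  for (rep in 1:25) {
    s <- random_small_sample()
    d <- score_distribution(s)
    expect_equal(sum(d$p_genuine), 1, tolerance = 1e-12)
    expect_equal(sum(d$p_impostor), 1, tolerance = 1e-12)
    expect_equal(d$c_genuine[1], 1)
    expect_equal(d$c_impostor[1], 1)
    expect_true(all(diff(d$c_genuine) <= 1e-15))
    expect_true(all(diff(d$c_impostor) <= 1e-15))
    expect_true(all(diff(d$score) > 0))
    # P(s) = C(s) - C(next(s)), C beyond the maximum being 0
    expect_equal(d$p_genuine, d$c_genuine - c(d$c_genuine[-1], 0))
    # raw multisets are recoverable from P * N
    expect_equal(rep(d$score, round(d$p_genuine * attr(d, "n_genuine"))),
                 sort(genuine_scores(s)))
    expect_equal(rep(d$score, round(d$p_impostor * attr(d, "n_impostor"))),
                 sort(impostor_scores(s)))
  }
})

test_that("discretization is order-invariant and decimal mode merges values", {
  s1 <- score_sample(c(3, 1, 2, 3), c(0, 3, 2, 1, 2, 1))
  s2 <- score_sample(c(1, 3, 3, 2), c(3, 2, 1, 0, 1, 2))
  expect_equal(tibble::as_tibble(score_distribution(s1)),
               tibble::as_tibble(score_distribution(s2)))

  s <- score_sample(c(0.514, 0.51), c(0.2, 0.3))
  d <- score_distribution(s, method = "decimal", digits = 2)
  # complete 0.01 grid from 0.20 to 0.51; 0.514 and 0.51 share a point
  expect_equal(nrow(d), 32)
  expect_equal(diff(d$score), rep(0.01, 31))
  expect_equal(d$p_genuine[d$score == 0.51], 1)
  expect_error(score_distribution(s, method = "decimal", digits = -1),
               "non-negative")
})

test_that("a point-mass genuine class gives P = C = 1 at its value", {
  d <- score_distribution(score_sample(c(5, 5, 5), c(1, 2)))
  expect_equal(d$p_genuine[d$score == 5], 1)
  expect_equal(d$c_genuine[d$score == 5], 1)
})
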