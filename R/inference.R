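#' One-algorithm Z-test against a hypothesized value
#'
#' Tests \eqn{H_0: T = \mu_0} against \eqn{H_a: T \ne \mu_0} for a
#' probability measure T (TAR, EER, AURC, ...) whose bootstrap distribution
#' is taken to be normal: \eqn{Z = (\hat T - \mu_0) / SE(\hat T)}, with the
#' two-tailed p-value \eqn{2(1 - \Phi(|Z|))}. When the difference is
#' significant, its sign together with the metric's orientation (larger- or
#' smaller-is-better, supplied by the caller, never inferred) says whether
#' the algorithm beats the criterion.
#'
#' @param estimate Point estimate \eqn{\hat T} (typically from
#'   [summarize_bootstrap()]).
#' @param mu0 Hypothesized value \eqn{\mu_0}.
#' @param se Standard error of the estimate (positive).
#' @param better `"larger"` if larger values of the metric are better
#'   (TAR, AURC), `"smaller"` if smaller are (EER, FNMR, cost).
#' @return An object of class `roc_test`; see [tidy.roc_test()].
#' @examples
#' one_algorithm_test(0.993255, mu0 = 0.9885, se = 0.000325)
#' @export
one_algorithm_test <- function(estimate, mu0, se,
                               better = c("larger", "smaller")) {
  better <- match.arg(better)
  if (se <= 0) stop("`se` must be positive", call. = FALSE)
  z <- (estimate - mu0) / se
  p <- 2 * stats::pnorm(-abs(z))
  direction <- if (estimate == mu0) {
    "estimate equals the hypothesized value"
  } else {
    favorable <- xor(estimate > mu0, better == "smaller")
    paste0("estimate is ", if (estimate > mu0) "above" else "below",
           " the hypothesized value (",
           if (favorable) "favorable" else "unfavorable",
           " for a ", better, "-is-better metric)")
  }
  structure(list(test = "one_algorithm", z = z, p_value = p,
                 estimates = c(estimate = estimate), ses = c(se = se),
                 mu0 = mu0, r = NA_real_, better = better,
                 direction = direction),
            class = "roc_test")
}

#' Two-algorithm Z-test with correlation adjustment
#'
#' Tests \eqn{H_0: T_1 = T_2} for the same statistic measured on two
#' algorithms, accounting for the correlation r between the two estimators
#' (from shared underlying comparisons; see [synchronized_correlation()]):
#' \deqn{Z = (\hat T_1 - \hat T_2) /
#'   \sqrt{SE_1^2 + SE_2^2 - 2 r\, SE_1 SE_2}.}
#' Ignoring a positive correlation inflates the denominator and can hide a
#' real difference. With `r = 0` this reduces to the unpaired two-sample Z.
#'
#' @param estimate1,estimate2 Point estimates of the two algorithms.
#' @param se1,se2 Their standard errors (positive).
#' @param r Correlation coefficient between the two estimators, in
#'   \[-1, 1\] (default 0).
#' @param better Metric orientation, as in [one_algorithm_test()].
#' @return An object of class `roc_test`.
#' @examples
#' two_algorithm_test(0.012409, 0.013634, 0.000378, 0.000338, r = 0.398198)
#' @export
two_algorithm_test <- function(estimate1, estimate2, se1, se2, r = 0,
                               better = c("larger", "smaller")) {
  better <- match.arg(better)
  if (se1 <= 0 || se2 <= 0) stop("standard errors must be positive", call. = FALSE)
  if (abs(r) > 1) stop("`r` must lie in [-1, 1]", call. = FALSE)
  diff <- estimate1 - estimate2
  radicand <- se1^2 + se2^2 - 2 * r * se1 * se2
  if (diff == 0) {
    z <- 0
  } else if (radicand <= 0) {
    stop("degenerate test: the correlation-adjusted variance ",
         "se1^2 + se2^2 - 2*r*se1*se2 is not positive (r = ", r,
         " with nearly equal SEs leaves no residual variance)",
         call. = FALSE)
  } else {
    z <- diff / sqrt(radicand)
  }
  p <- 2 * stats::pnorm(-abs(z))
  direction <- if (diff == 0) {
    "the two estimates are equal"
  } else {
    winner <- if (xor(diff > 0, better == "smaller")) 1L else 2L
    paste0("algorithm ", winner, " has the ", better,
           " estimate, the favorable side for a ", better,
           "-is-better metric")
  }
  structure(list(test = "two_algorithm", z = z, p_value = p,
                 estimates = c(estimate1 = estimate1, estimate2 = estimate2),
                 ses = c(se1 = se1, se2 = se2), mu0 = NA_real_, r = r,
                 better = better, direction = direction),
            class = "roc_test")
}

#' @export
print.roc_test <- function(x, ...) {
  cat("<roc_test> ", x$test, ": Z = ", signif(x$z, 6),
      ", two-tailed p = ", format.pval(x$p_value, digits = 4), "\n",
      "  ", x$direction, "\n", sep = "")
  invisible(x)
}

#' Tidy a Z-test result
#'
#' @param x A `roc_test` from [one_algorithm_test()] or
#'   [two_algorithm_test()].
#' @param ... Unused.
#' @return A one-row tibble with the estimates, SEs, hypothesized value or
#'   correlation, the Z statistic, the two-tailed p-value, significance
#'   flags at the 5% and 1% levels, and the verdict text.
#' @export
tidy.roc_test <- function(x, ...) {
  tibble::tibble(
    test = x$test,
    estimate1 = unname(x$estimates[1]),
    estimate2 = if (x$test == "two_algorithm") unname(x$estimates[2]) else NA_real_,
    mu0 = x$mu0,
    se1 = unname(x$ses[1]),
    se2 = if (x$test == "two_algorithm") unname(x$ses[2]) else NA_real_,
    r = x$r,
    z = x$z,
    p_value = x$p_value,
    significant_05 = x$p_value < 0.05,
    significant_01 = x$p_value < 0.01,
    direction = x$direction
  )
}

#' @export
glance.roc_test <- function(x, ...) {
  tibble::tibble(test = x$test, z = x$z, p_value = x$p_value)
}

#' Correlation between two algorithms' statistics via synchronized resampling
#'
#' Estimates the correlation coefficient r entering
#' [two_algorithm_test()]. Per Monte Carlo iteration, one with-replacement
#' index vector is drawn for the genuine class and one for the impostor
#' class, and the *same* indices are applied to both algorithms' score
#' lists — if a score of algorithm A is selected, the co-varying score of
#' algorithm B (same ordinal position, same underlying comparison) is
#' selected too, preserving any cross-algorithm correlation. The statistic
#' is evaluated for each algorithm in each of the `M` iterations, and the
#' Pearson correlation of the two replication sequences is computed. The
#' average over `runs` independent runs reduces Monte Carlo fluctuation.
#'
#' @param paired A [paired_score_sample()].
#' @param statistic,far,threshold,w1,w2,spec Statistic selection as in
#'   [roc_bootstrap()]; must be a single-component statistic
#'   (`"tar_at_far"`, `"eer"`, `"aurc"` or `"weighted_cost"`).
#' @param M Resampling iterations per run (default 2000).
#' @param runs Number of independent runs averaged (default 10).
#' @param seed Optional integer master seed; per-run substream seeds are
#'   derived from it.
#' @return An object of class `roc_correlation`: list with `r_mean` (the
#'   average over runs with defined correlation), `per_run` (tibble `run`,
#'   `r`; `NA` when a replication sequence was constant), `M`, `runs`,
#'   `seed`, `spec`.
#' @examples
#' p <- simulate_paired_algorithms(preset_high_accuracy(n_genuine = 100,
#'                                                      n_impostor = 200),
#'                                 latent_rho = 0.8, seed = 4)
#' synchronized_correlation(p, "aurc", M = 100, runs = 2, seed = 5)
#' @export
synchronized_correlation <- function(paired, statistic = "eer", far = NULL,
                                     threshold = NULL, w1 = 1, w2 = 1,
                                     M = 2000, runs = 10, seed = NULL,
                                     spec = NULL) {
  if (!inherits(paired, "paired_score_sample")) {
    stop("`paired` must be a paired_score_sample", call. = FALSE)
  }
  if (M < 2) stop("`M` must be at least 2", call. = FALSE)
  if (runs < 1) stop("`runs` must be at least 1", call. = FALSE)
  if (is.null(spec)) {
    spec <- stat_spec(statistic, far = far, threshold = threshold,
                      w1 = w1, w2 = w2)
  }
  if (spec$statistic == "rates_at_threshold") {
    stop("synchronized correlation needs a single-component statistic; ",
         "use tar_at_far, eer, aurc or weighted_cost", call. = FALSE)
  }
  alg <- purrr::map(list(paired$sample_a, paired$sample_b), function(s) {
    g <- genuine_scores(s)
    i <- impostor_scores(s)
    support <- sort(unique(c(g, i)))
    list(support = support, gidx = match(g, support),
         iidx = match(i, support), k = length(support))
  })
  ng <- n_genuine(paired$sample_a)
  ni <- n_impostor(paired$sample_a)
  if (!is.null(seed)) set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max, runs)
  per_run <- vapply(seq_len(runs), function(run) {
    set.seed(run_seeds[run])
    reps <- vapply(seq_len(M), function(i) {
      kg <- sample.int(ng, ng, replace = TRUE)
      ki <- sample.int(ni, ni, replace = TRUE)
      vapply(alg, function(a) {
        gc <- tabulate(a$gidx[kg], nbins = a$k)
        ic <- tabulate(a$iidx[ki], nbins = a$k)
        unname(eval_stat_counts(spec, a$support, gc, ic, ng, ni))
      }, numeric(1))
    }, numeric(2))
    if (stats::sd(reps[1, ]) == 0 || stats::sd(reps[2, ]) == 0) {
      warning("replication sequence constant in run ", run,
              "; correlation undefined for that run", call. = FALSE)
      NA_real_
    } else {
      stats::cor(reps[1, ], reps[2, ])
    }
  }, numeric(1))
  structure(
    list(r_mean = mean(per_run, na.rm = TRUE),
         per_run = tibble::tibble(run = seq_len(runs), r = per_run),
         M = M, runs = runs, seed = seed, spec = spec),
    class = "roc_correlation")
}

#' @export
print.roc_correlation <- function(x, ...) {
  cat("<roc_correlation> ", x$spec$statistic, ": r_mean = ",
      signif(x$r_mean, 6), " over ", x$runs, " runs of M = ", x$M,
      " synchronized resamplings\n", sep = "")
  invisible(x)
}

#' @export
tidy.roc_correlation <- function(x, ...) x$per_run

#' @export
glance.roc_correlation <- function(x, ...) {
  tibble::tibble(r_mean = x$r_mean, M = x$M, runs = x$runs,
                 statistic = x$spec$statistic)
}
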