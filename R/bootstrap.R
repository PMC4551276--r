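#' Specify a statistic of interest
#'
#' Bundles the name of an operational ROC statistic with its parameters so
#' resampling routines can evaluate it repeatedly. Supported kinds:
#' `"tar_at_far"` (needs `far`), `"rates_at_threshold"` (needs `threshold`;
#' two components, `tar` and `far`), `"eer"`, `"aurc"`, and
#' `"weighted_cost"` (needs `threshold`; weights `w1`, `w2`).
#'
#' @param statistic One of the kinds above.
#' @param far Specified false accept rate in (0, 1), for `"tar_at_far"`.
#' @param threshold Threshold score, for `"rates_at_threshold"` and
#'   `"weighted_cost"`.
#' @param w1,w2 Non-negative weights for `"weighted_cost"`.
#' @return A list of class `stat_spec`.
#' @examples
#' stat_spec("tar_at_far", far = 0.001)
#' @export
stat_spec <- function(statistic = c("tar_at_far", "rates_at_threshold",
                                    "eer", "aurc", "weighted_cost"),
                      far = NULL, threshold = NULL, w1 = 1, w2 = 1) {
  statistic <- match.arg(statistic)
  if (statistic == "tar_at_far") {
    if (is.null(far) || far <= 0 || far >= 1) {
      stop("`far` must be supplied in (0, 1) for tar_at_far", call. = FALSE)
    }
  }
  if (statistic %in% c("rates_at_threshold", "weighted_cost") &&
      is.null(threshold)) {
    stop("`threshold` must be supplied for ", statistic, call. = FALSE)
  }
  if (w1 < 0 || w2 < 0) stop("weights must be non-negative", call. = FALSE)
  structure(list(statistic = statistic, far = far, threshold = threshold,
                 w1 = w1, w2 = w2),
            class = "stat_spec")
}

#' @export
print.stat_spec <- function(x, ...) {
  extra <- switch(x$statistic,
    tar_at_far = paste0("(far = ", x$far, ")"),
    rates_at_threshold = paste0("(threshold = ", x$threshold, ")"),
    weighted_cost = paste0("(threshold = ", x$threshold,
                           ", w1 = ", x$w1, ", w2 = ", x$w2, ")"),
    "")
  cat("<stat_spec>", x$statistic, extra, "\n")
  invisible(x)
}

stat_components <- function(spec) {
  switch(spec$statistic,
    tar_at_far = "tar",
    rates_at_threshold = c("tar", "far"),
    eer = "eer",
    aurc = "aurc",
    weighted_cost = "cost")
}

# evaluate a statistic from support counts (single sample); named numeric
eval_stat_counts <- function(spec, support, gc, ic, ng, ni) {
  d <- list(support = support, gc = gc, ic = ic, ng = ng, ni = ni)
  switch(spec$statistic,
    tar_at_far = c(tar = unname(tar_at_far_one(d, spec$far)[2])),
    rates_at_threshold = {
      r <- rates_counts(d, spec$threshold)
      c(tar = r[1], far = r[2])
    },
    eer = c(eer = unname(eer_one(d)["eer"])),
    aurc = c(aurc = aurc_counts(gc, ic, ng, ni)),
    weighted_cost = {
      r <- rates_counts(d, spec$threshold)
      c(cost = spec$w1 * (1 - r[1]) + spec$w2 * r[2])
    })
}

rates_counts <- function(d, threshold) {
  k <- length(d$support)
  idx <- findInterval(threshold, d$support, left.open = TRUE) + 1L
  if (idx > k) return(c(0, 0))
  c(cum_top(d$gc)[idx] / d$ng, cum_top(d$ic)[idx] / d$ni)
}

# column-wise top-down cumulative of a K x B count matrix
col_cum_top <- function(m) {
  k <- nrow(m)
  if (k == 1L) return(m)
  r <- apply(m[k:1, , drop = FALSE], 2, cumsum)
  r[k:1, , drop = FALSE]
}

# B bootstrap replications of a statistic, as a components x B matrix.
# Resampling N scores with replacement is realized as a multinomial draw
# over the support counts (the same distribution, evaluated in O(K)).
# Draw order per call: genuine block first, then impostor block.
boot_replications <- function(spec, d, B) {
  gmat <- stats::rmultinom(B, d$ng, d$gc)
  imat <- stats::rmultinom(B, d$ni, d$ic)
  k <- length(d$support)
  cols <- seq_len(B)
  out <- switch(spec$statistic,
    tar_at_far = {
      cgm <- col_cum_top(gmat) / d$ng
      cim <- col_cum_top(imat) / d$ni
      f <- spec$far
      tidx <- colSums(cim >= f)
      ci_t <- cim[cbind(tidx, cols)]
      ci_n <- ifelse(tidx < k, cim[cbind(pmin(tidx + 1L, k), cols)], 0)
      cg_t <- cgm[cbind(tidx, cols)]
      cg_n <- ifelse(tidx < k, cgm[cbind(pmin(tidx + 1L, k), cols)], 0)
      rbind(tar = cg_n + (cg_t - cg_n) * (f - ci_n) / (ci_t - ci_n))
    },
    rates_at_threshold = ,
    weighted_cost = {
      idx <- findInterval(spec$threshold, d$support, left.open = TRUE) + 1L
      if (idx > k) {
        tar <- numeric(B); far <- numeric(B)
      } else {
        tar <- col_cum_top(gmat)[idx, ] / d$ng
        far <- col_cum_top(imat)[idx, ] / d$ni
      }
      if (spec$statistic == "rates_at_threshold") {
        rbind(tar = tar, far = far)
      } else {
        rbind(cost = spec$w1 * (1 - tar) + spec$w2 * far)
      }
    },
    eer = {
      cgm <- col_cum_top(gmat) / d$ng
      cim <- col_cum_top(imat) / d$ni
      vals <- vapply(cols, function(j) {
        er1 <- 1 - c(cgm[-1, j], 0)
        er2 <- cim[, j]
        absdiff <- abs(er1 - er2)
        m <- min(absdiff)
        idx <- which(absdiff <= m + 1e-15)
        mean((er1[idx] + er2[idx]) / 2)
      }, numeric(1))
      rbind(eer = vals)
    },
    aurc = {
      below <- apply(imat, 2, cumsum) - imat
      rbind(aurc = colSums(gmat * (below + 0.5 * imat)) / (d$ng * d$ni))
    })
  out
}

#' Nonparametric two-sample bootstrap of an ROC statistic
#'
#' In each of `B` iterations, \eqn{N_G} genuine scores and \eqn{N_I}
#' impostor scores are drawn independently with replacement from the
#' original score sets, the discrete distributions are rebuilt, and the
#' statistic of interest is evaluated, yielding `B` bootstrap replications
#' per statistic component. Resampling operates on the discretized support
#' (a multinomial draw over the observed counts), which is equivalent in
#' distribution to resampling the raw scores. Given the same `seed` and `B`
#' the replication sequence is reproduced exactly.
#'
#' @param x A `score_sample`, labelled data frame, or `score_distribution`.
#' @param statistic Statistic kind (see [stat_spec()]); ignored when `spec`
#'   is given.
#' @param far,threshold,w1,w2 Statistic parameters, passed to [stat_spec()].
#' @param B Number of bootstrap replications (default 2000, the replication
#'   count at which the coefficient of variation of the bootstrap SE falls
#'   below the 0.02 tolerance; see [bootstrap_variability()]).
#' @param seed Optional integer seed for reproducibility.
#' @param spec A ready-made [stat_spec()] (overrides `statistic` and the
#'   parameter arguments).
#' @param ... Passed to [as_score_distribution()].
#' @return An object of class `roc_boot`: a list with `replications` (a
#'   long tibble with columns `replicate`, `statistic`, `value`),
#'   `point_estimate` (named vector evaluated on the original sample),
#'   `spec`, `B`, `seed`, `n_genuine`, `n_impostor`. Summarize with
#'   [summarize_bootstrap()] / [tidy()].
#' @examples
#' s <- simulate_scores(preset_high_accuracy(), seed = 7)
#' b <- roc_bootstrap(s, "tar_at_far", far = 0.01, B = 200, seed = 1)
#' tidy(b)
#' @export
roc_bootstrap <- function(x, statistic = "tar_at_far", far = NULL,
                          threshold = NULL, w1 = 1, w2 = 1,
                          B = 2000, seed = NULL, spec = NULL, ...) {
  if (is.null(spec)) {
    spec <- stat_spec(statistic, far = far, threshold = threshold,
                      w1 = w1, w2 = w2)
  }
  if (B < 2) stop("`B` must be at least 2", call. = FALSE)
  dist <- as_score_distribution(x, ...)
  d <- dist_env(dist)
  point <- eval_stat_counts(spec, d$support, d$gc, d$ic, d$ng, d$ni)
  if (!is.null(seed)) set.seed(seed)
  mat <- boot_replications(spec, d, B)
  comp <- stat_components(spec)
  reps <- tibble::tibble(
    replicate = rep(seq_len(B), each = length(comp)),
    statistic = rep(comp, B),
    value = as.vector(mat)
  )
  structure(
    list(replications = reps, point_estimate = point, spec = spec,
         B = B, seed = seed, n_genuine = d$ng, n_impostor = d$ni),
    class = "roc_boot")
}

#' @export
print.roc_boot <- function(x, ...) {
  cat("<roc_boot> ", x$spec$statistic, ": B = ", x$B,
      ", N_G = ", x$n_genuine, ", N_I = ", x$n_impostor, "\n", sep = "")
  print(summarize_bootstrap(x))
  invisible(x)
}

#' Sample quantile by inverting the EDF with averaging at discontinuities
#'
#' The quantile definition used for the bootstrap percentile intervals
#' (Hyndman-Fan definition 2). With sorted values \eqn{x_{(1)} \le \dots \le
#' x_{(n)}}: when \eqn{np} is an integer \eqn{j \ge 1} the quantile is the
#' average \eqn{(x_{(j)} + x_{(j+1)})/2} (with \eqn{x_{(n+1)} := x_{(n)}});
#' otherwise it is \eqn{x_{(\lceil np \rceil)}}, and \eqn{x_{(1)}} when
#' \eqn{np < 1}.
#'
#' @param values Non-empty numeric vector.
#' @param p Probability strictly inside (0, 1).
#' @return The sample quantile.
#' @examples
#' quantile_def2(c(1, 2, 3, 4), 0.5)  # 2.5
#' quantile_def2(c(1, 2, 3, 4), 0.3)  # 2
#' @export
quantile_def2 <- function(values, p) {
  if (length(values) == 0) stop("`values` must be non-empty", call. = FALSE)
  if (p <= 0 || p >= 1) stop("`p` must lie in (0, 1)", call. = FALSE)
  x <- sort(values)
  n <- length(x)
  np <- n * p
  j <- round(np)
  if (abs(np - j) < 1e-9 && j >= 1) {
    (x[j] + x[min(j + 1, n)]) / 2
  } else if (np < 1) {
    x[1]
  } else {
    x[ceiling(np)]
  }
}

#' Normal-approximation confidence interval from an estimate and its SE
#'
#' @param estimate Point estimate.
#' @param se Standard error (non-negative).
#' @param alpha Significance level (default 0.05 for a 95% interval).
#' @return A tibble with columns `lower` and `upper`:
#'   `estimate` \eqn{\pm z_{1-\alpha/2}} `se`.
#' @examples
#' normal_ci(0.993255, 0.000325)
#' @export
normal_ci <- function(estimate, se, alpha = 0.05) {
  z <- stats::qnorm(1 - alpha / 2)
  tibble::tibble(lower = estimate - z * se, upper = estimate + z * se)
}

#' Summarize a bootstrap distribution: SE and two confidence intervals
#'
#' The standard error is the sample standard deviation (divisor B - 1) of
#' the replications. Two interval styles are reported: the percentile
#' interval from [quantile_def2()] at \eqn{\alpha/2} and \eqn{1-\alpha/2},
#' and the normal-approximation interval centred on the original-sample
#' point estimate. Close agreement between the two indicates approximate
#' normality of the bootstrap distribution.
#'
#' @param boot A `roc_boot` object.
#' @param alpha Significance level (default 0.05).
#' @return A tibble with one row per statistic component: `statistic`,
#'   `estimate`, `std_error`, `ci_quantile_lower`, `ci_quantile_upper`,
#'   `ci_normal_lower`, `ci_normal_upper`, `alpha`, `B`, `seed`.
#' @export
summarize_bootstrap <- function(boot, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)", call. = FALSE)
  comp <- stat_components(boot$spec)
  rows <- purrr::map(comp, function(cmp) {
    v <- boot$replications$value[boot$replications$statistic == cmp]
    est <- unname(boot$point_estimate[cmp])
    se <- stats::sd(v)
    nci <- normal_ci(est, se, alpha)
    tibble::tibble(
      statistic = cmp, estimate = est, std_error = se,
      ci_quantile_lower = quantile_def2(v, alpha / 2),
      ci_quantile_upper = quantile_def2(v, 1 - alpha / 2),
      ci_normal_lower = nci$lower, ci_normal_upper = nci$upper,
      alpha = alpha, B = boot$B, seed = boot$seed %||% NA_integer_
    )
  })
  dplyr::bind_rows(rows)
}

#' @rdname summarize_bootstrap
#' @param x A `roc_boot` object.
#' @param ... Unused.
#' @export
tidy.roc_boot <- function(x, alpha = 0.05, ...) {
  summarize_bootstrap(x, alpha = alpha)
}

#' @export
glance.roc_boot <- function(x, ...) {
  tibble::tibble(statistic = x$spec$statistic, B = x$B,
                 seed = x$seed %||% NA_integer_,
                 n_genuine = x$n_genuine, n_impostor = x$n_impostor)
}
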