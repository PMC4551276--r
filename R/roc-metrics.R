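#' Empirical ROC curve of a score sample
#'
#' The ROC curve of a discrete score distribution is the polyline through
#' the points \eqn{(C_I(s), C_G(s))} as the threshold s moves from the
#' highest support value down to the lowest, extended to the origin. Under
#' the trapezoidal rule a segment is horizontal where only impostor mass
#' sits at s, vertical where only genuine mass does, and inclined where
#' both classes have mass (a tie at s).
#'
#' @param x A `score_sample`, labelled data frame, or `score_distribution`.
#' @param ... Passed to [as_score_distribution()].
#' @return A tibble of class `roc_curve` with columns `score` (the
#'   threshold; `NA` for the origin), `far` and `tar`, ordered from the
#'   origin to (1, 1).
#' @examples
#' s <- score_sample(c(3, 3, 2, 1), c(3, 2, 2, 1, 1, 0))
#' roc_curve(s)
#' @export
roc_curve <- function(x, ...) {
  dist <- as_score_distribution(x, ...)
  k <- nrow(dist)
  out <- tibble::tibble(
    score = c(NA_real_, dist$score[k:1]),
    far = c(0, dist$c_impostor[k:1]),
    tar = c(0, dist$c_genuine[k:1])
  )
  class(out) <- c("roc_curve", class(out))
  out
}

#' Trapezoidal area under an ROC curve polyline
#'
#' @param curve A `roc_curve` tibble (or any data frame with `far`/`tar`
#'   columns ordered along the curve).
#' @return The trapezoidal area, a number in \[0, 1\].
#' @export
roc_curve_area <- function(curve) {
  sum(diff(curve$far) * (utils::head(curve$tar, -1) + utils::tail(curve$tar, -1)) / 2)
}

#' True accept rate at a specified false accept rate
#'
#' Scenario 1 of operational ROC analysis. For a specified FAR
#' \eqn{f \in (0,1)} the threshold t is the support value with
#' \eqn{C_I(next(t)) < f \le C_I(t)}; the impostor mass \eqn{P_I(t)} at t is
#' then necessarily positive. Genuine scores tied at t are divided
#' proportionally (the trapezoidal rule), giving
#' \deqn{TAR(f) = C_G(next(t)) + P_G(t) (f - C_I(next(t))) / P_I(t),}
#' i.e. linear interpolation along the inclined ROC segment at t.
#'
#' @param x A `score_sample`, labelled data frame, or `score_distribution`.
#' @param far Numeric vector of FAR values, each strictly inside (0, 1).
#' @param ... Passed to [as_score_distribution()].
#' @return A tibble with one row per requested FAR: columns `far`,
#'   `threshold` (the support value t) and `tar`.
#' @examples
#' s <- score_sample(c(3, 3, 2, 1), c(3, 2, 2, 1, 1, 0))
#' tar_at_far(s, 0.25)
#' @export
tar_at_far <- function(x, far, ...) {
  dist <- as_score_distribution(x, ...)
  if (any(far <= 0 | far >= 1)) {
    stop("`far` must lie strictly inside (0, 1): the threshold condition ",
         "C_I(next(t)) < f <= C_I(t) has no solution otherwise", call. = FALSE)
  }
  res <- vapply(far, function(f) tar_at_far_one(dist_env(dist), f),
                numeric(2))
  tibble::tibble(far = far, threshold = res[1, ], tar = res[2, ])
}

# core evaluator on the vector view; returns c(threshold, tar)
tar_at_far_one <- function(d, f) {
  ci <- cum_top(d$ic) / d$ni
  cg <- cum_top(d$gc) / d$ng
  k <- length(ci)
  t_idx <- sum(ci >= f)  # C_I non-increasing: last support value with C_I >= f
  ci_next <- if (t_idx < k) ci[t_idx + 1] else 0
  cg_next <- if (t_idx < k) cg[t_idx + 1] else 0
  p_i <- ci[t_idx] - ci_next
  p_g <- cg[t_idx] - cg_next
  tar <- cg_next + p_g * (f - ci_next) / p_i
  c(d$support[t_idx], tar)
}

#' True and false accept rates at a given threshold
#'
#' Scenario 2. An arbitrary real threshold `t` is mapped to the smallest
#' support value \eqn{s \ge t} (the ceiling onto the discrete score grid);
#' the rates are the top-down cumulatives there: `tar` \eqn{= C_G(s)},
#' `far` \eqn{= C_I(s)}. A threshold above the highest score accepts
#' nothing (rates 0); one at or below the lowest accepts everything
#' (rates 1).
#'
#' @param x A `score_sample`, labelled data frame, or `score_distribution`.
#' @param threshold Numeric vector of thresholds.
#' @param ... Passed to [as_score_distribution()].
#' @return A tibble with one row per threshold: columns `threshold`
#'   (as given), `score` (the support ceiling, `NA` above the maximum),
#'   `tar` and `far`.
#' @examples
#' s <- score_sample(c(3, 3, 2, 1), c(3, 2, 2, 1, 1, 0))
#' rates_at_threshold(s, 1.5)
#' @export
rates_at_threshold <- function(x, threshold, ...) {
  dist <- as_score_distribution(x, ...)
  d <- dist_env(dist)
  cg <- cum_top(d$gc) / d$ng
  ci <- cum_top(d$ic) / d$ni
  k <- length(d$support)
  # smallest support index with support >= t; k+1 when t exceeds the maximum
  idx <- findInterval(threshold, d$support, left.open = TRUE) + 1L
  above <- idx > k
  s <- ifelse(above, NA_real_, d$support[pmin(idx, k)])
  tibble::tibble(
    threshold = threshold,
    score = s,
    tar = ifelse(above, 0, cg[pmin(idx, k)]),
    far = ifelse(above, 0, ci[pmin(idx, k)])
  )
}

#' Equal error rate of a discrete score distribution
#'
#' Scenario 3. At each support value s the type I error (false rejection)
#' is \eqn{ER_I(s) = 1 - C_G(next(s))} and the type II error (false
#' acceptance) is \eqn{ER_{II}(s) = C_I(s)}, with \eqn{C_G} beyond the
#' maximum score taken as 0. As s decreases, \eqn{ER_I} decreases and
#' \eqn{ER_{II}} increases, so \eqn{|ER_I - ER_{II}|} attains its minimum on
#' a contiguous score range \eqn{[s_1, s_2]}. Because the distributions are
#' discrete the minimum is rarely exactly zero; the EER is estimated as the
#' midpoint of the two error rates over that range, and half the residual
#' gap relative to the EER is reported as the discreteness-induced
#' systematic error.
#'
#' The reported operating `threshold` is the largest support value not
#' exceeding the midpoint of \eqn{(s_1 + s_2)/2} (the floor of the midpoint
#' generalized to non-integer supports).
#'
#' @param x A `score_sample`, labelled data frame, or `score_distribution`.
#' @param ... Passed to [as_score_distribution()].
#' @return A one-row tibble with columns `eer`, `s_lower`, `s_upper`,
#'   `threshold`, `min_absdiff` and `systematic_error` (0 when `eer` is 0).
#' @examples
#' s <- score_sample(c(3, 2, 2, 1), c(2, 1, 1, 0))
#' eer(s)
#' @export
eer <- function(x, ...) {
  dist <- as_score_distribution(x, ...)
  res <- eer_one(dist_env(dist))
  tibble::as_tibble(as.list(res))
}

eer_one <- function(d) {
  cg <- cum_top(d$gc) / d$ng
  ci <- cum_top(d$ic) / d$ni
  k <- length(cg)
  er1 <- 1 - c(cg[-1], 0)   # 1 - C_G(next(s))
  er2 <- ci                 # C_I(s)
  absdiff <- abs(er1 - er2)
  m <- min(absdiff)
  idx <- which(absdiff <= m + 1e-15)
  i1 <- min(idx); i2 <- max(idx)
  eer_val <- mean((er1[i1:i2] + er2[i1:i2]) / 2)
  mid <- (d$support[i1] + d$support[i2]) / 2
  thr <- max(d$support[d$support <= mid])
  sys_err <- if (eer_val > 0) (m / 2) / eer_val else 0
  c(eer = eer_val, s_lower = d$support[i1], s_upper = d$support[i2],
    threshold = thr, min_absdiff = m, systematic_error = sys_err)
}

#' Area under the ROC curve (Mann-Whitney statistic)
#'
#' Under the trapezoidal rule the area under the empirical ROC curve equals
#' the Mann-Whitney statistic of the two score sets: the proportion of
#' genuine-impostor pairs where the genuine score wins, ties counting one
#' half. Computed via midranks, without materializing the
#' \eqn{N_G \times N_I} pairs.
#'
#' @param x A `score_sample` or labelled data frame.
#' @return A number in \[0, 1\].
#' @examples
#' aurc(score_sample(c(3, 3, 2, 1), c(3, 2, 2, 1, 1, 0)))
#' @export
aurc <- function(x) {
  x <- as_score_sample(x)
  g <- genuine_scores(x)
  i <- impostor_scores(x)
  r <- rank(c(g, i))
  ng <- length(g)
  (sum(r[seq_len(ng)]) - ng * (ng + 1) / 2) / (ng * length(i))
}

# AURC from support counts (same quantity; used by the resampling loops)
aurc_counts <- function(gc, ic, ng, ni) {
  below <- cumsum(ic) - ic
  sum(gc * (below + 0.5 * ic)) / (ng * ni)
}

#' Weighted cost of the two error types at a threshold
#'
#' The scalar operating cost \eqn{w_1 (1 - TAR(t)) + w_2 FAR(t)} combining
#' the type I (false rejection) and type II (false acceptance) error
#' probabilities at threshold `t`, with user-chosen non-negative weights.
#'
#' @param x A `score_sample`, labelled data frame, or `score_distribution`.
#' @param threshold Numeric vector of thresholds.
#' @param w1 Non-negative weight on the type I error `1 - tar`.
#' @param w2 Non-negative weight on the type II error `far`.
#' @param ... Passed to [as_score_distribution()].
#' @return Numeric vector of costs, one per threshold.
#' @export
weighted_cost <- function(x, threshold, w1 = 1, w2 = 1, ...) {
  if (w1 < 0 || w2 < 0) stop("weights must be non-negative", call. = FALSE)
  r <- rates_at_threshold(x, threshold, ...)
  w1 * (1 - r$tar) + w2 * r$far
}

#' Transform TAR uncertainty results to the FNMR scale
#'
#' The false non-match rate is FNMR = 1 - TAR. Standard errors (and Z
#' statistics, correlations, p-values) are unchanged by this reflection,
#' but confidence-interval bounds swap: the FNMR lower bound is one minus
#' the TAR upper bound and vice versa.
#'
#' @param summary A bootstrap summary tibble as returned by
#'   [summarize_bootstrap()] (columns `estimate`, `std_error` and the four
#'   CI bound columns).
#' @return The summary on the FNMR scale, with `statistic` prefixed
#'   `"fnmr_"`.
#' @export
fnmr_transform <- function(summary) {
  out <- summary
  out$statistic <- paste0("fnmr_", summary$statistic)
  out$estimate <- 1 - summary$estimate
  out$ci_quantile_lower <- 1 - summary$ci_quantile_upper
  out$ci_quantile_upper <- 1 - summary$ci_quantile_lower
  out$ci_normal_lower <- 1 - summary$ci_normal_upper
  out$ci_normal_upper <- 1 - summary$ci_normal_lower
  out
}
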