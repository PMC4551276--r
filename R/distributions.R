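#' Discretize a score sample into aligned empirical distributions
#'
#' Builds the shared discrete support of a score sample together with the
#' per-class empirical probabilities and top-down cumulative probabilities.
#' The cumulative of class i at score s is \eqn{C_i(s) = \sum_{\tau \ge s}
#' P_i(\tau)}, cumulated from the highest support value down, so that
#' \eqn{C_G} is the true accept rate and \eqn{C_I} the false accept rate at
#' threshold s.
#'
#' Two discretization modes are offered. `"distinct"` (default) keeps the
#' observed score values as they are; `"decimal"` first rounds every score
#' to `digits` decimal places, rescaling real-valued scores onto a regular
#' grid. In either mode, when the (possibly rounded) scores sit on a
#' regular decimal grid — integers, or multiples of `10^-d` for some
#' `d <= 6`, detected automatically — the support is
#' the *complete* grid from the lowest to the highest observed score,
#' including unused values (with zero mass in both classes). Operating
#' points between occupied scores are part of the score scale, and the EER
#' scan in particular must see them: a separating gap between the classes
#' contains thresholds where both error rates vanish. Scores not on a
#' recognizable grid fall back to the union of distinct observed values.
#'
#' @param x A `score_sample` or labelled data frame (see [as_score_sample()]).
#' @param method `"distinct"` or `"decimal"`.
#' @param digits Number of decimal digits kept in `"decimal"` mode
#'   (non-negative integer).
#' @return A tibble of class `score_distribution` with one row per support
#'   value (strictly increasing `score`) and columns `count_genuine`,
#'   `count_impostor`, `p_genuine`, `p_impostor`, `c_genuine`, `c_impostor`.
#'   Sample sizes are kept in attributes `n_genuine` / `n_impostor`.
#' @examples
#' s <- score_sample(c(3, 3, 2, 1), c(3, 2, 2, 1, 1, 0))
#' score_distribution(s)
#' @export
score_distribution <- function(x, method = c("distinct", "decimal"),
                               digits = NULL) {
  x <- as_score_sample(x)
  method <- match.arg(method)
  g <- genuine_scores(x)
  i <- impostor_scores(x)
  scale <- 1
  if (method == "decimal") {
    if (is.null(digits) || digits < 0 || digits != round(digits)) {
      stop("`digits` must be a non-negative integer in decimal mode",
           call. = FALSE)
    }
    scale <- 10^digits
  }
  on_grid <- method == "decimal"
  if (method == "distinct") {
    # auto-detect a decimal grid: smallest d with all scores multiples of 10^-d
    for (d in 0:6) {
      v <- c(g, i) * 10^d
      if (max(abs(v - round(v))) < 1e-9) {
        scale <- 10^d
        on_grid <- TRUE
        break
      }
    }
  }
  gs <- g * scale
  is_ <- i * scale
  if (on_grid) {
    gs <- round(gs)
    is_ <- round(is_)
    lo <- min(gs, is_)
    hi <- max(gs, is_)
    support_scaled <- if (hi - lo < 1e6) {
      seq(lo, hi)                    # complete grid incl. unused scores
    } else {
      sort(unique(c(gs, is_)))       # range too wide to enumerate
    }
    support <- support_scaled / scale
    gi <- match(gs, support_scaled)
    ii <- match(is_, support_scaled)
  } else {
    support <- sort(unique(c(g, i)))
    gi <- match(g, support)
    ii <- match(i, support)
  }
  k <- length(support)
  cg_counts <- tabulate(gi, nbins = k)
  ci_counts <- tabulate(ii, nbins = k)
  # cumulatives from counts, in the same arithmetic order as the
  # resampling internals, so vertex values are bit-identical across paths
  out <- tibble::tibble(
    score = support,
    count_genuine = cg_counts,
    count_impostor = ci_counts,
    p_genuine = cg_counts / length(g),
    p_impostor = ci_counts / length(i),
    c_genuine = cum_top(cg_counts) / length(g),
    c_impostor = cum_top(ci_counts) / length(i)
  )
  attr(out, "n_genuine") <- length(g)
  attr(out, "n_impostor") <- length(i)
  attr(out, "method") <- method
  attr(out, "digits") <- digits
  attr(out, "sample_label") <- attr(x, "sample_label")
  class(out) <- c("score_distribution", class(out))
  out
}

#' Coerce to a score distribution
#'
#' Passes `score_distribution` objects through and discretizes score samples
#' (or labelled data frames) with the default distinct-values mode.
#'
#' @param x A `score_distribution`, `score_sample`, or labelled data frame.
#' @param ... Passed to [score_distribution()] when discretization is needed.
#' @return A `score_distribution`.
#' @export
as_score_distribution <- function(x, ...) {
  if (inherits(x, "score_distribution")) x else score_distribution(x, ...)
}

# top-down cumulative: C(s) = sum over support values >= s
cum_top <- function(p) rev(cumsum(rev(p)))

#' @export
print.score_distribution <- function(x, ...) {
  cat("<score_distribution> ", attr(x, "sample_label"), ": ",
      nrow(x), " support values in [", min(x$score), ", ", max(x$score),
      "], N_G = ", attr(x, "n_genuine"),
      ", N_I = ", attr(x, "n_impostor"), "\n", sep = "")
  NextMethod()
}

# Lightweight internal view used by the resampling loops: plain vectors,
# no tibble overhead.
dist_env <- function(dist) {
  list(
    support = dist$score,
    gc = dist$count_genuine,
    ic = dist$count_impostor,
    ng = attr(dist, "n_genuine"),
    ni = attr(dist, "n_impostor")
  )
}
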