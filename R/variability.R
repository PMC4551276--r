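#' Coefficient of variation
#'
#' Standard deviation divided by mean (sample variance with divisor
#' n - 1). Used to express bootstrap variability on a scale that accounts
#' for the magnitude of the quantity.
#'
#' @param values Numeric vector with non-zero mean.
#' @return `sd(values) / mean(values)`.
#' @examples
#' coefficient_of_variation(c(1, 3))  # sqrt(2)/2
#' @export
coefficient_of_variation <- function(values) {
  m <- mean(values)
  if (m == 0) {
    stop("coefficient of variation undefined: mean of values is zero",
         call. = FALSE)
  }
  stats::sd(values) / m
}

cv_or_na <- function(values) {
  m <- mean(values)
  if (m == 0) NA_real_ else stats::sd(values) / m
}

#' Monte Carlo study of bootstrap variability
#'
#' Runs the two-sample bootstrap `L` independent times for each replication
#' count in `B`, collects the `L` estimated standard errors and lower/upper
#' percentile-CI bounds, and reports their coefficients of variation
#' (`cv_se`, `cv_lb`, `cv_ub`). The CV of the SE as a function of `B` is
#' the calibration curve used to pick the number of bootstrap replications:
#' it decreases with `B`, and the smallest `B` at which it falls below a
#' chosen tolerance (0.02 being a customary value) is sufficient.
#'
#' The study seed derives one substream seed per (B, run) cell, so every
#' cell is independently reproducible.
#'
#' @param x A `score_sample`, labelled data frame, or `score_distribution`.
#' @param statistic,far,threshold,w1,w2,spec Statistic selection as in
#'   [roc_bootstrap()].
#' @param B Integer vector of bootstrap replication counts to study.
#' @param L Number of Monte Carlo repetitions per replication count
#'   (at least 2).
#' @param alpha Significance level of the percentile interval whose bounds
#'   are tracked.
#' @param seed Optional integer master seed.
#' @param transform `"none"`, or `"fnmr"` to track the bounds on the
#'   false non-match-rate scale (1 - value, bounds swapped; the SE and its
#'   CV are unchanged by the reflection). Only meaningful for TAR-type
#'   statistics.
#' @param ... Passed to [as_score_distribution()].
#' @return A tibble of class `roc_variability` with one row per
#'   (B, statistic component): columns `B`, `statistic`, `cv_se`, `cv_lb`,
#'   `cv_ub`. A CV whose underlying set has mean zero (degenerate samples)
#'   is reported as `NA`. The raw per-run sets are kept in the `"sets"`
#'   attribute (a tibble with columns `B`, `run`, `statistic`, `se`, `lb`,
#'   `ub`); `L`, `alpha`, `seed` and the spec are stored as attributes.
#' @examples
#' s <- simulate_scores(preset_high_accuracy(n_genuine = 100,
#'                                           n_impostor = 200), seed = 3)
#' bootstrap_variability(s, "aurc", B = c(50, 100), L = 5, seed = 9)
#' @export
bootstrap_variability <- function(x, statistic = "tar_at_far", far = NULL,
                                  threshold = NULL, w1 = 1, w2 = 1,
                                  B = c(200, 500, 1000, 2000), L = 100,
                                  alpha = 0.05, seed = NULL, spec = NULL,
                                  transform = c("none", "fnmr"), ...) {
  transform <- match.arg(transform)
  if (L < 2) stop("`L` must be at least 2", call. = FALSE)
  if (any(B < 2)) stop("each `B` must be at least 2", call. = FALSE)
  if (is.null(spec)) {
    spec <- stat_spec(statistic, far = far, threshold = threshold,
                      w1 = w1, w2 = w2)
  }
  dist <- as_score_distribution(x, ...)
  d <- dist_env(dist)
  comp <- stat_components(spec)
  if (!is.null(seed)) set.seed(seed)
  cell_seeds <- matrix(sample.int(.Machine$integer.max, length(B) * L),
                       nrow = L)
  sets <- purrr::map(seq_along(B), function(bi) {
    b <- B[bi]
    runs <- purrr::map(seq_len(L), function(i) {
      set.seed(cell_seeds[i, bi])
      mat <- boot_replications(spec, d, b)
      purrr::map(seq_along(comp), function(ci) {
        v <- mat[ci, ]
        se <- stats::sd(v)
        lb <- quantile_def2(v, alpha / 2)
        ub <- quantile_def2(v, 1 - alpha / 2)
        if (transform == "fnmr") {
          tmp <- lb
          lb <- 1 - ub
          ub <- 1 - tmp
        }
        tibble::tibble(B = b, run = i, statistic = comp[ci],
                       se = se, lb = lb, ub = ub)
      }) |> dplyr::bind_rows()
    })
    dplyr::bind_rows(runs)
  }) |> dplyr::bind_rows()
  out <- sets |>
    dplyr::group_by(.data$B, .data$statistic) |>
    dplyr::summarise(cv_se = cv_or_na(.data$se),
                     cv_lb = cv_or_na(.data$lb),
                     cv_ub = cv_or_na(.data$ub),
                     .groups = "drop") |>
    dplyr::arrange(.data$B)
  attr(out, "sets") <- sets
  attr(out, "L") <- L
  attr(out, "alpha") <- alpha
  attr(out, "seed") <- seed
  attr(out, "spec") <- spec
  attr(out, "transform") <- transform
  class(out) <- c("roc_variability", class(out))
  out
}

#' @export
print.roc_variability <- function(x, ...) {
  cat("<roc_variability> ", attr(x, "spec")$statistic,
      ": L = ", attr(x, "L"), " runs per B, alpha = ", attr(x, "alpha"),
      if (attr(x, "transform") == "fnmr") ", FNMR scale" else "",
      "\n", sep = "")
  NextMethod()
}

#' @export
glance.roc_variability <- function(x, ...) {
  tibble::tibble(statistic = attr(x, "spec")$statistic,
                 L = attr(x, "L"), alpha = attr(x, "alpha"),
                 transform = attr(x, "transform"),
                 n_B = length(unique(x$B)))
}
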