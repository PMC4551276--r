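# Independent brute-force oracles, implemented from first principles and
# kept free of the package's internal code paths.

# TAR at FAR by linear interpolation along the empirical ROC polyline,
# walked in curve order. Vertices are direct counts: (FAR, TAR)(s) =
# (mean(i >= s), mean(g >= s)) for s from the highest score down, plus the
# origin. The segment containing f runs from the last vertex with FAR < f
# to the following vertex; at a vertical run of duplicated FAR this leaves
# from the top of the run, while an exact vertex hit lands on the bottom —
# the trapezoidal-rule geometry of proportional tie division.
oracle_tar_at_far <- function(g, i, f) {
  support <- sort(unique(c(g, i)), decreasing = TRUE)
  far <- c(0, vapply(support, function(s) mean(i >= s), numeric(1)))
  tar <- c(0, vapply(support, function(s) mean(g >= s), numeric(1)))
  j <- max(which(far < f))
  k <- j + 1
  tar[j] + (tar[k] - tar[j]) * (f - far[j]) / (far[k] - far[j])
}

# AURC by exhaustive enumeration of all genuine-impostor pairs.
oracle_aurc <- function(g, i) {
  cmp <- outer(g, i, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# EER by exhaustive direct-count evaluation of both error rates at every
# value of the given support (the support definition is a shared input;
# the error rates and the scan are computed independently).
oracle_eer <- function(g, i, support = sort(unique(c(g, i)))) {
  k <- length(support)
  er1 <- vapply(seq_len(k), function(j) {
    if (j == k) 1 - 0 else mean(g < support[j + 1])
  }, numeric(1))
  er2 <- vapply(support, function(s) mean(i >= s), numeric(1))
  absdiff <- abs(er1 - er2)
  m <- min(absdiff)
  idx <- which(absdiff <= m + 1e-15)
  list(eer = mean((er1[idx] + er2[idx]) / 2),
       min_absdiff = m,
       s_lower = support[min(idx)], s_upper = support[max(idx)])
}

# Analytic SE of the Mann-Whitney AUC: unbiased two-sample U-statistic
# variance from the per-observation placement values.
oracle_mw_se <- function(g, i) {
  v10 <- vapply(g, function(x) mean((x > i) + 0.5 * (x == i)), numeric(1))
  v01 <- vapply(i, function(x) mean((g > x) + 0.5 * (g == x)), numeric(1))
  sqrt(stats::var(v10) / length(g) + stats::var(v01) / length(i))
}

# Small random discrete sample with deliberate ties.
random_small_sample <- function() {
  ng <- sample(2:50, 1)
  ni <- sample(2:50, 1)
  score_sample(sample(0:12, ng, replace = TRUE) + sample(c(0, 0.5), ng, replace = TRUE),
               sample(0:10, ni, replace = TRUE))
}

toy_sample <- function() score_sample(c(3, 3, 2, 1), c(3, 2, 2, 1, 1, 0))
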