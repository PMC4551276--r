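#' Parameters for synthetic score-sample generation
#'
#' Describes a pair of unimodal (Gaussian) score distributions with the
#' structural features the operational ROC methods must handle: a
#' configurable separation between the genuine and impostor classes,
#' discretization-induced ties (rounding to `decimals` digits), and an
#' optional point mass ("spike") at the top of the genuine class — real
#' matchers often pile a stand-alone peak of genuine scores at the maximum
#' score.
#'
#' @param n_genuine,n_impostor Class sizes (at least 1).
#' @param genuine_location,genuine_scale Mean and SD of the genuine class.
#' @param impostor_location,impostor_scale Mean and SD of the impostor
#'   class.
#' @param decimals Decimal digits the generated scores are rounded to
#'   (discretization; non-negative integer).
#' @param spike_mass Probability with which a genuine score is replaced by
#'   the spike value `genuine_location + 5 * genuine_scale` (the effective
#'   maximum of the genuine support); in \[0, 1).
#' @param label Optional sample identifier.
#' @return A list of class `sim_params`.
#' @seealso [preset_high_accuracy()], [preset_low_accuracy()]
#' @export
sim_params <- function(n_genuine = 500, n_impostor = 1000,
                       genuine_location = 5, genuine_scale = 1,
                       impostor_location = 0, impostor_scale = 1,
                       decimals = 2, spike_mass = 0, label = NULL) {
  if (n_genuine < 1 || n_impostor < 1) {
    stop("class sizes must be at least 1", call. = FALSE)
  }
  if (genuine_scale <= 0 || impostor_scale <= 0) {
    stop("scales must be positive", call. = FALSE)
  }
  if (decimals < 0 || decimals != round(decimals)) {
    stop("`decimals` must be a non-negative integer", call. = FALSE)
  }
  if (spike_mass < 0 || spike_mass >= 1) {
    stop("`spike_mass` must lie in [0, 1)", call. = FALSE)
  }
  structure(list(n_genuine = n_genuine, n_impostor = n_impostor,
                 genuine_location = genuine_location,
                 genuine_scale = genuine_scale,
                 impostor_location = impostor_location,
                 impostor_scale = impostor_scale,
                 decimals = decimals, spike_mass = spike_mass,
                 label = label %||% "synthetic"),
            class = "sim_params")
}

#' Named simulation presets mirroring high- and low-accuracy matchers
#'
#' The two presets differ only in class separation. The high-accuracy
#' preset places the genuine class five impostor SDs above the impostor
#' class (population EER near 0.006, TAR at low FAR near 0.99); the
#' low-accuracy preset uses three SDs (population EER near 0.07). These
#' mimic the qualitative contrast between a high- and a low-accuracy
#' matching algorithm.
#'
#' @param ... Overrides passed to [sim_params()] (e.g. `n_genuine`,
#'   `spike_mass`).
#' @return A `sim_params` object.
#' @export
preset_high_accuracy <- function(...) {
  do.call(sim_params, utils::modifyList(
    list(genuine_location = 5, label = "high-accuracy"), list(...)))
}

#' @rdname preset_high_accuracy
#' @export
preset_low_accuracy <- function(...) {
  do.call(sim_params, utils::modifyList(
    list(genuine_location = 3, label = "low-accuracy"), list(...)))
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params> ", x$label, ": genuine N(", x$genuine_location, ", ",
      x$genuine_scale, "^2) x ", x$n_genuine, ", impostor N(",
      x$impostor_location, ", ", x$impostor_scale, "^2) x ", x$n_impostor,
      ", ", x$decimals, " decimals",
      if (x$spike_mass > 0) paste0(", spike mass ", x$spike_mass) else "",
      "\n", sep = "")
  invisible(x)
}

#' Simulate a score sample
#'
#' Draws the two classes from the Gaussian distributions described by
#' `params`, applies the genuine-class spike replacement with probability
#' `spike_mass`, and rounds to `decimals` digits. Deterministic given
#' `seed`. Draw order: genuine scores, spike indicators, impostor scores.
#'
#' @param params A [sim_params()] object.
#' @param seed Optional integer seed.
#' @return A `score_sample`.
#' @examples
#' s <- simulate_scores(preset_high_accuracy(), seed = 1)
#' eer(s)
#' @export
simulate_scores <- function(params, seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(seed)) set.seed(seed)
  g <- stats::rnorm(params$n_genuine, params$genuine_location,
                    params$genuine_scale)
  if (params$spike_mass > 0) {
    spike <- params$genuine_location + 5 * params$genuine_scale
    g[stats::runif(params$n_genuine) < params$spike_mass] <- spike
  }
  i <- stats::rnorm(params$n_impostor, params$impostor_location,
                    params$impostor_scale)
  score_sample(round(g, params$decimals), round(i, params$decimals),
               label = params$label)
}

#' Simulate ordinally paired score samples for two algorithms
#'
#' Emulates two matching algorithms scoring the same comparisons: per
#' class, standard-normal pairs with correlation `latent_rho` (a Gaussian
#' copula on a shared latent variable) are drawn and mapped through each
#' algorithm's location/scale/rounding, so the j-th score of A and the j-th
#' score of B co-vary. `latent_rho = 1` with identical parameters yields
#' identical samples; `latent_rho = 0` yields independent ones. Spike
#' replacement, when requested, uses one shared indicator per genuine pair
#' so the spikes co-occur.
#'
#' @param params_a,params_b [sim_params()] for the two algorithms; class
#'   sizes must match (B defaults to A's parameters).
#' @param latent_rho Latent correlation in \[0, 1\].
#' @param seed Optional integer seed.
#' @return A `paired_score_sample`.
#' @examples
#' p <- simulate_paired_algorithms(preset_low_accuracy(), latent_rho = 0.6,
#'                                 seed = 2)
#' @export
simulate_paired_algorithms <- function(params_a, params_b = params_a,
                                       latent_rho, seed = NULL) {
  stopifnot(inherits(params_a, "sim_params"), inherits(params_b, "sim_params"))
  if (params_a$n_genuine != params_b$n_genuine ||
      params_a$n_impostor != params_b$n_impostor) {
    stop("class sizes must match across the two algorithms", call. = FALSE)
  }
  if (latent_rho < 0 || latent_rho > 1) {
    stop("`latent_rho` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  pair_z <- function(n) {
    z <- stats::rnorm(n)
    e <- stats::rnorm(n)
    list(a = z, b = latent_rho * z + sqrt(1 - latent_rho^2) * e)
  }
  zg <- pair_z(params_a$n_genuine)
  u <- stats::runif(params_a$n_genuine)
  zi <- pair_z(params_a$n_impostor)
  build <- function(p, zgen, zimp) {
    g <- p$genuine_location + p$genuine_scale * zgen
    if (p$spike_mass > 0) {
      g[u < p$spike_mass] <- p$genuine_location + 5 * p$genuine_scale
    }
    i <- p$impostor_location + p$impostor_scale * zimp
    score_sample(round(g, p$decimals), round(i, p$decimals), label = p$label)
  }
  paired_score_sample(build(params_a, zg$a, zi$a),
                      build(params_b, zg$b, zi$b))
}
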