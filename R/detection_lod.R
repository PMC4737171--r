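#' Poisson-Bernoulli detection model for a bulk reaction
#'
#' Templates load into a reaction as Poisson with mean `copies`, and each
#' loaded template independently amplifies with probability `efficiency`
#' (the digital efficiency). The reaction is detected when at least one
#' template amplifies, so the number of amplifying templates is Poisson
#' with thinned mean `copies * efficiency`.
#'
#' @param efficiency Per-molecule amplification probability in (0, 1\].
#' @param volume_ul Reaction volume in microliters (bookkeeping only; the
#'   model works in copies per reaction).
#' @return An object of class `detection_model`.
#' @export
detection_model <- function(efficiency, volume_ul = 10) {
  if (length(efficiency) != 1L || !is.finite(efficiency) ||
      efficiency <= 0 || efficiency > 1) {
    stop("'efficiency' must be in (0, 1]", call. = FALSE)
  }
  if (length(volume_ul) != 1L || !is.finite(volume_ul) || volume_ul <= 0) {
    stop("'volume_ul' must be positive", call. = FALSE)
  }
  structure(
    list(efficiency = efficiency, volume_ul = volume_ul),
    class = "detection_model"
  )
}

#' Probability of detecting a reaction at a given mean template load
#'
#' \eqn{P(\mathrm{detect}) = 1 - e^{-c E}} for mean load \eqn{c} copies per
#' reaction and digital efficiency \eqn{E}: the probability that at least
#' one Poisson-loaded template amplifies.
#'
#' @param copies_mean Mean template copies per reaction (>= 0); vectorized.
#' @param model A [detection_model()].
#' @return Detection probability in \[0, 1).
#' @examples
#' detection_probability(1.2, detection_model(0.48))  # ~0.44
#' @export
detection_probability <- function(copies_mean, model) {
  stopifnot(inherits(model, "detection_model"))
  if (!all(is.finite(copies_mean)) || any(copies_mean < 0)) {
    stop("'copies_mean' must be non-negative", call. = FALSE)
  }
  -expm1(-copies_mean * model$efficiency)
}

#' Limit of detection at a given confidence
#'
#' The mean template load detected with probability `confidence` under the
#' Poisson-Bernoulli model: solving \eqn{1 - e^{-c E} = } confidence gives
#' \eqn{c = \ln(1/(1-\mathrm{confidence}))/E}, i.e. \eqn{\ln(20)/E \approx
#' 3/E} copies per reaction at the conventional 95%.
#'
#' @param model A [detection_model()].
#' @param confidence Detection probability defining the LOD (default 0.95).
#' @return LOD in copies per reaction.
#' @examples
#' lod95(detection_model(1))    # ~3 copies
#' lod95(detection_model(0.5))  # ~6 copies
#' @export
lod95 <- function(model, confidence = 0.95) {
  stopifnot(inherits(model, "detection_model"))
  if (length(confidence) != 1L || !is.finite(confidence) ||
      confidence <= 0 || confidence >= 1) {
    stop("'confidence' must be in (0, 1)", call. = FALSE)
  }
  log(1 / (1 - confidence)) / model$efficiency
}

#' Dilution-series detection results
#'
#' @param concentrations Mean copies per reaction at each level (>= 3
#'   distinct positive values for LOD fitting).
#' @param n_reactions Reactions tested per level.
#' @param n_positive Reactions detected per level.
#' @param condition_label Optional label.
#' @return An object of class `dilution_series`.
#' @export
dilution_series <- function(concentrations, n_reactions, n_positive,
                            condition_label = "") {
  if (length(concentrations) != length(n_reactions) ||
      length(concentrations) != length(n_positive)) {
    stop("all three vectors must have equal length", call. = FALSE)
  }
  if (!all(is.finite(concentrations)) || any(concentrations < 0)) {
    stop("'concentrations' must be non-negative", call. = FALSE)
  }
  if (any(n_positive < 0) || any(n_positive > n_reactions)) {
    stop("'n_positive' must lie in [0, n_reactions]", call. = FALSE)
  }
  structure(
    list(
      concentrations = as.numeric(concentrations),
      n_reactions = as.integer(n_reactions),
      n_positive = as.integer(n_positive),
      condition_label = as.character(condition_label)
    ),
    class = "dilution_series"
  )
}

#' Estimate digital efficiency and LOD from a dilution series
#'
#' Fits the one-parameter Poisson-Bernoulli model to binomial detection
#' counts by maximum likelihood: at level \eqn{c_i},
#' \eqn{k_i \sim \mathrm{Bin}(n_i, 1 - e^{-c_i E})}. The likelihood is
#' unimodal in \eqn{\ln E}, so a bounded one-dimensional search
#' ([stats::optimize()] on \eqn{\ln E}, tolerance 1e-8) suffices; ties
#' break toward smaller \eqn{E}. The LOD follows from the closed form
#' \eqn{\ln(1/(1-\mathrm{confidence}))/\hat E}.
#'
#' An all-negative or all-positive series leaves \eqn{E} unidentified (the
#' likelihood is monotone) and raises an error naming the problem.
#'
#' @param series A [dilution_series()] with >= 3 distinct concentrations.
#' @param confidence LOD confidence level (default 0.95).
#' @return A list of class `lod_fit`: `efficiency_hat`, `lod_copies`,
#'   `confidence`, `log_lik`, `condition_label`.
#' @export
estimate_lod_from_series <- function(series, confidence = 0.95) {
  stopifnot(inherits(series, "dilution_series"))
  pos_levels <- series$concentrations > 0
  if (length(unique(series$concentrations[pos_levels])) < 3L) {
    stop("need at least 3 distinct positive concentrations", call. = FALSE)
  }
  if (sum(series$n_positive) == 0L) {
    stop("all reactions negative: efficiency not identifiable ",
         "(likelihood decreases without bound in E)", call. = FALSE)
  }
  if (all(series$n_positive == series$n_reactions)) {
    stop("all reactions positive: efficiency not identifiable ",
         "(likelihood increases without bound in E)", call. = FALSE)
  }
  c_i <- series$concentrations
  n_i <- series$n_reactions
  k_i <- series$n_positive
  nll <- function(log_e) {
    p <- -expm1(-c_i * exp(log_e))
    # guard exact 0/1 probabilities at extreme E
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(stats::dbinom(k_i, n_i, p, log = TRUE))
  }
  opt <- stats::optimize(nll, interval = c(log(1e-6), log(1)), tol = 1e-8)
  structure(
    list(
      efficiency_hat = exp(opt$minimum),
      lod_copies = log(1 / (1 - confidence)) / exp(opt$minimum),
      confidence = confidence,
      log_lik = -opt$objective,
      condition_label = series$condition_label
    ),
    class = "lod_fit"
  )
}

#' @export
print.lod_fit <- function(x, ...) {
  lbl <- if (nzchar(x$condition_label)) paste0(" [", x$condition_label, "]") else ""
  cat(sprintf(
    "LOD fit%s: efficiency %.3f, LOD%.0f = %.3g copies/reaction\n",
    lbl, x$efficiency_hat, 100 * x$confidence, x$lod_copies
  ))
  invisible(x)
}

#' Effective-concentration factor of the digital format
#'
#' When a fraction `positive_fraction` of wells holds template, all
#' template molecules are concentrated into that fraction of the device
#' volume, so each occupied well experiences a concentration
#' `1 / positive_fraction` times the bulk concentration. At ~20% occupancy
#' the digital format therefore runs at ~5x the bulk concentration, which
#' is why digital reactions read out faster than bulk reactions of the
#' same loaded solution.
#'
#' @param positive_fraction Fraction of occupied wells, in (0, 1\].
#' @return The concentration ratio (>= 1).
#' @examples
#' effective_concentration_factor(0.20)  # 5
#' @export
effective_concentration_factor <- function(positive_fraction) {
  if (!all(is.finite(positive_fraction)) || any(positive_fraction <= 0) ||
      any(positive_fraction > 1)) {
    stop("'positive_fraction' must be in (0, 1]", call. = FALSE)
  }
  1 / positive_fraction
}
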