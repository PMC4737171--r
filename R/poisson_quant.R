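#' Standard deviation of ln(lambda) for a digital device
#'
#' Uncertainty of the most-probable-number concentration estimate on the
#' natural-log scale, for a device with `n` wells of volume `nu`:
#'
#' \deqn{\sigma = \frac{1}{\lambda \nu \sqrt{n / (e^{\nu\lambda} - 1)}}}
#'
#' The formula follows from binomial sampling of positive wells propagated
#' through the MPN estimator by the delta method; it is minimal near
#' occupancy \eqn{\nu\lambda \approx 1.6} and scales as \eqn{1/\sqrt{n}}.
#'
#' @param lambda_ Template concentration in molecules/ml (positive).
#' @param device A [device_spec()].
#' @return The standard deviation of \eqn{\ln\hat\lambda} (dimensionless).
#' @examples
#' sigma_ln_lambda(5e4, slipchip())  # 0.075
#' @export
sigma_ln_lambda <- function(lambda_, device) {
  stopifnot(inherits(device, "device_spec"))
  if (!all(is.finite(lambda_)) || any(lambda_ <= 0)) {
    stop("'lambda_' must be positive", call. = FALSE)
  }
  nu <- device$well_volume_ml
  n <- device$n_wells
  1 / (lambda_ * nu * sqrt(n / (exp(nu * lambda_) - 1)))
}

#' Expected fraction of positive wells under Poisson loading
#'
#' Probability that a well of volume \eqn{\nu} receives at least one
#' template at concentration \eqn{\lambda}: \eqn{1 - e^{-\lambda\nu}}.
#'
#' @inheritParams sigma_ln_lambda
#' @return Expected positive fraction in \[0, 1).
#' @export
expected_positive_fraction <- function(lambda_, device) {
  stopifnot(inherits(device, "device_spec"))
  if (!all(is.finite(lambda_)) || any(lambda_ < 0)) {
    stop("'lambda_' must be non-negative", call. = FALSE)
  }
  -expm1(-lambda_ * device$well_volume_ml)
}

#' Estimate template concentration from a positive-well count
#'
#' Most-probable-number (MPN) estimator for a single-volume digital device:
#' \eqn{\hat\lambda = -\ln(1 - k/n)/\nu} molecules/ml, with a lognormal
#' confidence interval \eqn{\exp(\ln\hat\lambda \pm z_{1-\alpha/2}\,\sigma)}
#' using the plug-in \eqn{\sigma} from [sigma_ln_lambda()].
#'
#' Boundary handling: `k = 0` returns \eqn{\hat\lambda = 0} with `ci_low = 0`
#' and a one-sided upper \eqn{(1-\alpha)} bound \eqn{-\ln(\alpha)/(n\nu)}
#' from the exact binomial zero-count bound. `k = n` means every well is
#' positive and the estimator diverges; this raises a saturation error.
#'
#' @param count A [digital_count()].
#' @param device A [device_spec()]; `count$n_total` must equal
#'   `device$n_wells`.
#' @param alpha Two-sided significance level for the CI (default 0.05).
#' @return An object of class `concentration_estimate` with elements
#'   `lambda_hat`, `sigma_ln_lambda`, `ci_low`, `ci_high`, `alpha`,
#'   `k_positive`, `n_total`, `condition_label`.
#' @examples
#' estimate_lambda(digital_count(178, 1280), slipchip())
#' @export
estimate_lambda <- function(count, device, alpha = 0.05) {
  stopifnot(inherits(count, "digital_count"), inherits(device, "device_spec"))
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("'alpha' must be in (0, 1)", call. = FALSE)
  }
  if (count$n_total != device$n_wells) {
    stop(sprintf(
      "count has %d wells but device has %d", count$n_total, device$n_wells
    ), call. = FALSE)
  }
  k <- count$k_positive
  n <- count$n_total
  nu <- device$well_volume_ml
  if (k == n) {
    stop(
      "all wells positive: concentration is not estimable (device saturated)",
      call. = FALSE
    )
  }
  if (k == 0L) {
    est <- list(
      lambda_hat = 0,
      sigma_ln_lambda = NA_real_,
      ci_low = 0,
      ci_high = -log(alpha) / (n * nu),
      alpha = alpha,
      k_positive = k, n_total = n,
      condition_label = count$condition_label
    )
    return(structure(est, class = "concentration_estimate"))
  }
  lambda_hat <- -log1p(-k / n) / nu
  sig <- sigma_ln_lambda(lambda_hat, device)
  z <- stats::qnorm(1 - alpha / 2)
  structure(
    list(
      lambda_hat = lambda_hat,
      sigma_ln_lambda = sig,
      ci_low = exp(log(lambda_hat) - z * sig),
      ci_high = exp(log(lambda_hat) + z * sig),
      alpha = alpha,
      k_positive = k, n_total = n,
      condition_label = count$condition_label
    ),
    class = "concentration_estimate"
  )
}

#' @export
print.concentration_estimate <- function(x, ...) {
  lbl <- if (nzchar(x$condition_label)) paste0(" [", x$condition_label, "]") else ""
  cat(sprintf(
    "Concentration estimate%s: %.4g molecules/ml (%d/%d wells)\n",
    lbl, x$lambda_hat, x$k_positive, x$n_total
  ))
  cat(sprintf(
    "  %.0f%% CI [%.4g, %.4g], sigma(ln lambda) = %s\n",
    100 * (1 - x$alpha), x$ci_low, x$ci_high,
    if (is.na(x$sigma_ln_lambda)) "NA (zero count)"
    else sprintf("%.4g", x$sigma_ln_lambda)
  ))
  invisible(x)
}

#' Digital efficiency of an amplification condition
#'
#' The fraction of loaded template molecules that amplified to a detectable
#' signal: the MPN concentration estimate divided by the concentration
#' actually loaded. Values above 1 can arise through estimation noise and
#' are not clipped.
#'
#' @param observed A `concentration_estimate` from [estimate_lambda()].
#' @param loaded_lambda Loaded template concentration in molecules/ml
#'   (positive).
#' @return Efficiency as a fraction (0 = nothing amplified, 1 = everything).
#' @export
digital_efficiency <- function(observed, loaded_lambda) {
  stopifnot(inherits(observed, "concentration_estimate"))
  if (length(loaded_lambda) != 1L || !is.finite(loaded_lambda) ||
      loaded_lambda <= 0) {
    stop("'loaded_lambda' must be positive", call. = FALSE)
  }
  observed$lambda_hat / loaded_lambda
}

#' Per-condition efficiency summary
#'
#' Bundles replicate-level (per-device) efficiencies into a condition-level
#' estimate: the mean efficiency, its standard error over replicates, and
#' the replicate count.
#'
#' @param condition_label Condition name.
#' @param efficiencies Numeric vector of per-device efficiencies (>= 1 value).
#' @return An object of class `efficiency_estimate` with elements
#'   `condition_label`, `efficiency`, `se`, `n_replicates`, `normalized`.
#' @export
efficiency_estimate <- function(condition_label, efficiencies) {
  if (!is.numeric(efficiencies) || length(efficiencies) < 1L ||
      !all(is.finite(efficiencies)) || any(efficiencies < 0)) {
    stop("'efficiencies' must be non-negative finite values", call. = FALSE)
  }
  m <- length(efficiencies)
  structure(
    list(
      condition_label = as.character(condition_label),
      efficiency = mean(efficiencies),
      se = if (m > 1L) stats::sd(efficiencies) / sqrt(m) else 0,
      n_replicates = m,
      replicate_values = as.numeric(efficiencies),
      normalized = FALSE
    ),
    class = "efficiency_estimate"
  )
}

#' Normalize condition efficiencies to a reference condition
#'
#' Divides every condition's mean efficiency (and, by the same factor, its
#' standard error and replicate values) by the reference condition's mean,
#' so the reference becomes exactly 1. The reference mean is treated as a
#' fixed scale constant; its own sampling error is not propagated into the
#' other conditions, and the output records this in the `normalized` flag.
#'
#' @param estimates List of [efficiency_estimate()] objects.
#' @param reference_label Label of the reference condition; must be present
#'   and have positive mean efficiency.
#' @return List of `efficiency_estimate` objects on the normalized scale.
#' @export
normalize_efficiencies <- function(estimates, reference_label) {
  stopifnot(is.list(estimates), length(estimates) >= 1L)
  labs <- vapply(estimates, function(e) e$condition_label, character(1))
  idx <- match(reference_label, labs)
  if (is.na(idx)) {
    stop(sprintf("reference condition '%s' not found", reference_label),
         call. = FALSE)
  }
  ref <- estimates[[idx]]$efficiency
  if (!is.finite(ref) || ref <= 0) {
    stop("reference condition has non-positive mean efficiency", call. = FALSE)
  }
  lapply(estimates, function(e) {
    e$efficiency <- e$efficiency / ref
    e$se <- e$se / ref
    e$replicate_values <- e$replicate_values / ref
    e$normalized <- TRUE
    e
  })
}

#' @export
print.efficiency_estimate <- function(x, ...) {
  cat(sprintf(
    "%s: efficiency %.3f +/- %.3f SE (n = %d%s)\n",
    x$condition_label, x$efficiency, x$se, x$n_replicates,
    if (x$normalized) ", normalized" else ""
  ))
  invisible(x)
}

#' Two-sample comparison of replicate values between conditions
#'
#' Welch's unequal-variance two-sided t-test on replicate-level values
#' (efficiencies or times to positive). When both groups have zero variance
#' the t statistic is undefined; the comparison then degenerates to an exact
#' statement (p = 0 if the means differ, p = 1 otherwise) and a warning is
#' emitted.
#'
#' @param a,b Numeric vectors of replicate values, each of length >= 2.
#' @return A list of class `condition_comparison`: `mean_difference`
#'   (mean(a) - mean(b)), `se` (Welch standard error, `NA` in the degenerate
#'   case), `p_value`, `df`, `method`.
#' @examples
#' compare_conditions(c(1.02, 0.98, 1.01), c(0.61, 0.58, 0.64))
#' @export
compare_conditions <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) < 2L || length(b) < 2L) {
    stop("both groups need at least 2 replicate values", call. = FALSE)
  }
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    stop("replicate values must be finite", call. = FALSE)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    warning("both groups have zero variance; exact degenerate comparison")
    return(structure(
      list(
        mean_difference = mean(a) - mean(b),
        se = NA_real_,
        p_value = if (mean(a) == mean(b)) 1 else 0,
        df = NA_real_,
        method = "degenerate (zero variance)"
      ),
      class = "condition_comparison"
    ))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  structure(
    list(
      mean_difference = unname(tt$estimate[1] - tt$estimate[2]),
      se = unname(tt$stderr),
      p_value = tt$p.value,
      df = unname(tt$parameter),
      method = "Welch two-sample t-test"
    ),
    class = "condition_comparison"
  )
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf(
    "%s: difference %.4g +/- %s SE, p = %.3g\n",
    x$method, x$mean_difference,
    if (is.na(x$se)) "NA" else sprintf("%.4g", x$se), x$p_value
  ))
  invisible(x)
}
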