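#' Sample-size constant from significance level and power
#'
#' The normal-approximation sample-size constant
#' \eqn{C = (z_{1-\alpha/2} + z_{\mathrm{power}})^2}. At \eqn{\alpha = 0.05}
#' and 95% power it is 12.99, conventionally quoted as 13.0.
#'
#' @param alpha Two-sided significance level in (0, 1).
#' @param power Statistical power in (0, 1).
#' @return The constant (dimensionless).
#' @examples
#' c_constant(0.05, 0.95)  # 12.99
#' @export
c_constant <- function(alpha = 0.05, power = 0.95) {
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0 || alpha >= 1 ||
      length(power) != 1L || !is.finite(power) || power <= 0 || power >= 1) {
    stop("'alpha' and 'power' must be in (0, 1)", call. = FALSE)
  }
  (stats::qnorm(1 - alpha / 2) + stats::qnorm(power))^2
}

#' Power-analysis settings
#'
#' @param alpha Two-sided significance level (default 0.05).
#' @param power Statistical power (default 0.95).
#' @param c_constant Sample-size constant; by default (`NULL`) computed
#'   from `alpha` and `power` via [c_constant()] (12.99 at the defaults,
#'   the value conventionally rounded to 13.0). Supply 13.0 explicitly to
#'   reproduce back-of-envelope arithmetic that uses the rounded constant.
#' @return An object of class `power_spec`.
#' @export
power_spec <- function(alpha = 0.05, power = 0.95, c_constant = NULL) {
  if (is.null(c_constant)) {
    if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
      stop("'alpha' and 'power' must be in (0, 1)", call. = FALSE)
    }
    c_constant <- (stats::qnorm(1 - alpha / 2) + stats::qnorm(power))^2
  }
  if (length(c_constant) != 1L || !is.finite(c_constant) || c_constant <= 0) {
    stop("'c_constant' must be positive", call. = FALSE)
  }
  structure(
    list(alpha = alpha, power = power, c_constant = c_constant),
    class = "power_spec"
  )
}

#' Target difference on the ln-efficiency scale
#'
#' A relative efficiency difference of `relative_difference` (for example
#' 0.20 for "condition B amplifies 20% fewer templates than condition A",
#' i.e. \eqn{E_B = (1 - d) E_A}) corresponds to a target difference of
#' \eqn{TD = |\ln(1) - \ln(1-d)| = -\ln(1-d)} on the natural-log scale on
#' which the measurement error of digital concentration estimates is
#' (approximately) constant.
#'
#' @param relative_difference Relative difference in (0, 1).
#' @return Target difference (ln scale, positive).
#' @examples
#' target_difference(0.20)  # 0.223
#' @export
target_difference <- function(relative_difference) {
  if (length(relative_difference) != 1L || !is.finite(relative_difference) ||
      relative_difference <= 0 || relative_difference >= 1) {
    stop("'relative_difference' must be in (0, 1)", call. = FALSE)
  }
  -log1p(-relative_difference)
}

#' Standardized difference
#'
#' The target difference expressed in units of the per-replicate measurement
#' standard deviation: \eqn{SD = TD / \sigma}.
#'
#' @param td Target difference on the ln scale (positive).
#' @param sigma Standard deviation of one replicate's \eqn{\ln\hat\lambda}
#'   (positive), typically from [sigma_ln_lambda()].
#' @return The standardized difference (dimensionless).
#' @examples
#' standardized_difference(target_difference(0.20), 0.075)  # 2.98
#' @export
standardized_difference <- function(td, sigma) {
  if (length(td) != 1L || !is.finite(td) || td <= 0 ||
      length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    stop("'td' and 'sigma' must be positive", call. = FALSE)
  }
  td / sigma
}

#' Minimum number of replicates to resolve a standardized difference
#'
#' \eqn{N = (2 / SD^2)\, C} replicates per condition, where \eqn{C} is the
#' sample-size constant of the [power_spec()]. Both the raw value and its
#' ceiling are returned; planning uses the ceiling.
#'
#' @param sd Standardized difference (positive).
#' @param spec A [power_spec()]; defaults to alpha 0.05, power 0.95.
#' @return An object of class `power_result`: `target_difference` (`NA` if
#'   unknown at this level), `sigma` (`NA` likewise), `standardized_difference`,
#'   `n_raw`, `n_ceil`, `spec`.
#' @examples
#' replicates_required(2.98, power_spec(c_constant = 13.0))  # N = 2.93 -> 3
#' @export
replicates_required <- function(sd, spec = power_spec()) {
  if (length(sd) != 1L || !is.finite(sd) || sd <= 0) {
    stop("'sd' must be positive", call. = FALSE)
  }
  stopifnot(inherits(spec, "power_spec"))
  n_raw <- 2 / sd^2 * spec$c_constant
  structure(
    list(
      target_difference = NA_real_,
      sigma = NA_real_,
      standardized_difference = sd,
      n_raw = n_raw,
      n_ceil = as.integer(ceiling(n_raw)),
      spec = spec
    ),
    class = "power_result"
  )
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf(
    "Replicates required: N = %.3g (use %d) at SD = %.3g (alpha %.3g, power %.3g)\n",
    x$n_raw, x$n_ceil, x$standardized_difference, x$spec$alpha, x$spec$power
  ))
  invisible(x)
}

#' Replicates needed to resolve an efficiency difference on a given device
#'
#' Chains the uncertainty formula, the standardized difference and the
#' sample-size formula for a digital device at a reference concentration:
#' \eqn{\sigma} at `lambda_ref`, \eqn{TD = -\ln(1 - d)}, \eqn{SD = TD/\sigma},
#' \eqn{N = (2/SD^2) C}. \eqn{\sigma} is evaluated at the reference
#' concentration only; at occupancies \eqn{\nu\lambda \le 0.3} the
#' sensitivity of \eqn{N} to this choice is below 2%.
#'
#' @param relative_difference Relative efficiency difference in (0, 1).
#' @param device A [device_spec()].
#' @param lambda_ref Reference concentration, molecules/ml.
#' @param spec A [power_spec()].
#' @return A `power_result` with `target_difference` and `sigma` filled in.
#' @examples
#' plan_digital_experiment(0.20, slipchip(), 5e4)
#' @export
plan_digital_experiment <- function(relative_difference, device, lambda_ref,
                                    spec = power_spec()) {
  sig <- sigma_ln_lambda(lambda_ref, device)
  td <- target_difference(relative_difference)
  res <- replicates_required(standardized_difference(td, sig), spec)
  res$target_difference <- td
  res$sigma <- sig
  res
}

#' Replicates needed in a multi-molecule (well-plate) format
#'
#' Treats one trial of `wells_per_trial` bulk reactions as a digital
#' experiment with \eqn{n} = `wells_per_trial` partitions of volume
#' `well_volume_ml` loaded at `copies_per_well` templates per well
#' (\eqn{\lambda = } copies/\eqn{\nu}), then applies the same
#' \eqn{\sigma \to SD \to N} chain. Because \eqn{n} is small and the
#' occupancy is of order 1, \eqn{\sigma} per trial is large and many trials
#' are needed.
#'
#' @param relative_difference Relative efficiency difference in (0, 1).
#' @param wells_per_trial Number of reactions per trial (>= 1).
#' @param well_volume_ml Volume of one reaction in ml.
#' @param copies_per_well Mean template copies loaded per reaction (> 0).
#' @param spec A [power_spec()].
#' @return A list of class `multiwell_plan`: `sigma_per_trial`, `td`,
#'   `standardized_difference`, `trials_raw`, `trials_required`,
#'   `total_reactions`.
#' @examples
#' # 10 wells of 10 ul at ~1 copy/well, 20% difference: 90 trials, 900 reactions
#' plan_multiwell_experiment(0.20, 10, 0.01, 1, power_spec(c_constant = 13.0))
#' @export
plan_multiwell_experiment <- function(relative_difference, wells_per_trial,
                                      well_volume_ml, copies_per_well,
                                      spec = power_spec()) {
  if (length(wells_per_trial) != 1L || wells_per_trial < 1 ||
      wells_per_trial != round(wells_per_trial)) {
    stop("'wells_per_trial' must be a positive integer", call. = FALSE)
  }
  if (length(copies_per_well) != 1L || !is.finite(copies_per_well) ||
      copies_per_well <= 0) {
    stop("'copies_per_well' must be positive", call. = FALSE)
  }
  trial_device <- device_spec(wells_per_trial, well_volume_ml)
  lambda_ <- copies_per_well / well_volume_ml
  if (!is.finite(exp(well_volume_ml * lambda_))) {
    stop("occupancy too high: trial wells saturate", call. = FALSE)
  }
  sig <- sigma_ln_lambda(lambda_, trial_device)
  td <- target_difference(relative_difference)
  res <- replicates_required(standardized_difference(td, sig), spec)
  structure(
    list(
      sigma_per_trial = sig,
      td = td,
      standardized_difference = res$standardized_difference,
      trials_raw = res$n_raw,
      trials_required = res$n_ceil,
      total_reactions = res$n_ceil * as.integer(wells_per_trial)
    ),
    class = "multiwell_plan"
  )
}

#' @export
print.multiwell_plan <- function(x, ...) {
  cat(sprintf(
    "Multi-molecule plan: sigma/trial %.3g, SD %.3g -> %d trials (%.3g raw), %d reactions per condition\n",
    x$sigma_per_trial, x$standardized_difference, x$trials_required,
    x$trials_raw, x$total_reactions
  ))
  invisible(x)
}

#' Empirical power of the digital two-sample comparison
#'
#' Monte-Carlo check of the sample-size calculus: repeatedly simulates
#' `n_devices` digital devices per condition, one condition at `lambda_ref`
#' and the other at `lambda_ref * (1 - relative_difference)` (a relative
#' efficiency deficit thins Poisson loading by the same factor), estimates
#' \eqn{\ln\hat\lambda} per device and applies a two-sample comparison at
#' level `alpha`. Returns the fraction of replicate experiments detecting
#' the difference.
#'
#' Two comparison methods are available. `"z"` (default) is the
#' known-variance z-comparison the sample-size constant presumes:
#' \eqn{\sigma} is taken from the uncertainty formula at the reference
#' concentration, so the test statistic is
#' \eqn{(\bar{x}_1 - \bar{x}_2) / (\sigma\sqrt{2/m})}. `"welch"` estimates
#' the variance from the replicates (Welch t-test); with very few devices
#' per condition its power is far below the nominal value because the
#' variance is poorly estimated, which is exactly why the calculus uses the
#' known Poisson-statistics \eqn{\sigma}.
#'
#' Devices that saturate (all wells positive) make the MPN estimate
#' undefined; the affected replicate experiments are dropped from the power
#' denominator and their number is reported in the `n_saturated` attribute.
#'
#' @param relative_difference True relative efficiency difference in (0, 1).
#' @param n_devices Devices per condition (>= 2).
#' @param device A [device_spec()].
#' @param lambda_ref Reference concentration, molecules/ml.
#' @param reps Number of replicate experiments (>= 100).
#' @param seed Integer seed.
#' @param alpha Two-sided level (default 0.05).
#' @param method `"z"` (known-sigma comparison) or `"welch"`.
#' @return Empirical power in \[0, 1\], with attributes `n_saturated`,
#'   `reps`, `method`.
#' @examples
#' simulate_power(0.20, 3, slipchip(), 5e4, reps = 200, seed = 1)
#' @export
simulate_power <- function(relative_difference, n_devices, device, lambda_ref,
                           reps = 1000, seed = 1, alpha = 0.05,
                           method = c("z", "welch")) {
  method <- match.arg(method)
  stopifnot(inherits(device, "device_spec"))
  if (n_devices < 2) stop("'n_devices' must be >= 2", call. = FALSE)
  if (reps < 100) stop("'reps' must be >= 100", call. = FALSE)
  td <- target_difference(relative_difference)  # validates the difference
  n <- device$n_wells
  nu <- device$well_volume_ml
  p1 <- expected_positive_fraction(lambda_ref, device)
  p2 <- expected_positive_fraction(lambda_ref * (1 - relative_difference),
                                   device)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  k1 <- matrix(stats::rbinom(reps * n_devices, n, p1), nrow = reps)
  k2 <- matrix(stats::rbinom(reps * n_devices, n, p2), nrow = reps)
  saturated <- rowSums(k1 == n) + rowSums(k2 == n) > 0
  k1 <- k1[!saturated, , drop = FALSE]
  k2 <- k2[!saturated, , drop = FALSE]
  l1 <- log(-log1p(-k1 / n) / nu)
  l2 <- log(-log1p(-k2 / n) / nu)
  d <- rowMeans(l1) - rowMeans(l2)
  if (method == "z") {
    sig <- sigma_ln_lambda(lambda_ref, device)
    stat <- d / (sig * sqrt(2 / n_devices))
    detected <- abs(stat) > stats::qnorm(1 - alpha / 2)
  } else {
    v1 <- apply(l1, 1, stats::var)
    v2 <- apply(l2, 1, stats::var)
    se2 <- v1 / n_devices + v2 / n_devices
    dfw <- se2^2 / ((v1 / n_devices)^2 / (n_devices - 1) +
                      (v2 / n_devices)^2 / (n_devices - 1))
    detected <- abs(d / sqrt(se2)) > stats::qt(1 - alpha / 2, dfw)
  }
  structure(
    mean(detected),
    n_saturated = sum(saturated),
    reps = nrow(k1),
    method = method
  )
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
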