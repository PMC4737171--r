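test_that("MPN estimator matches closed forms", {
  dev <- slipchip()

  # no positives: zero estimate with an exact one-sided upper bound
  est0 <- estimate_lambda(digital_count(0, 1280), dev, alpha = 0.05)
  expect_identical(est0$lambda_hat, 0)
  expect_identical(est0$ci_low, 0)
  expect_equal(est0$ci_high, -log(0.05) / (1280 * 3e-6))

  # k chosen so 1 - k/n = exp(-0.15): lambda recovers ~5e4 molecules/ml
  est <- estimate_lambda(digital_count(178, 1280), dev)
  expect_equal(est$lambda_hat, -log(1 - 178 / 1280) / 3e-6)
  expect_equal(est$lambda_hat, 4.99e4, tolerance = 0.005)

  # half occupancy: lambda = ln(2)/nu
  est2 <- estimate_lambda(digital_count(640, 1280), dev)
  expect_equal(est2$lambda_hat, log(2) / 3e-6)

  # CI brackets the point estimate on the ln scale
  expect_lt(est$ci_low, est$lambda_hat)
  expect_gt(est$ci_high, est$lambda_hat)
  expect_equal(sqrt(est$ci_low * est$ci_high), est$lambda_hat,
               tolerance = 1e-10)
})

test_that("saturated and mismatched counts are rejected", {
  dev <- slipchip()
  expect_error(estimate_lambda(digital_count(1280, 1280), dev), "saturat")
  expect_error(estimate_lambda(digital_count(5, 96), dev), "96")
  expect_error(digital_count(10, 5), "exceed")
  expect_error(digital_count(-1, 5))
})

test_that("sigma of ln(lambda) follows the uncertainty formula", {
  # the running device example evaluates to 0.075
  expect_equal(round(sigma_ln_lambda(5e4, slipchip()), 3), 0.075)

  # hand evaluation at occupancy nu*lambda = 1 with 10 wells
  expect_equal(sigma_ln_lambda(100, device_spec(10, 0.01)),
               sqrt((exp(1) - 1) / 10), tolerance = 1e-12)

  # sigma scales as 1/sqrt(n): quadrupling wells halves sigma
  expect_equal(sigma_ln_lambda(5e4, device_spec(5120, 3e-6)),
               sigma_ln_lambda(5e4, slipchip()) / 2)

  expect_error(sigma_ln_lambda(0, slipchip()), "positive")
  expect_error(sigma_ln_lambda(-1, slipchip()), "positive")
})

test_that("sigma is decreasing in n with a unique interior minimum in lambda", {
  lam_grid <- 10^seq(3, 6.2, length.out = 120)
  sig <- sigma_ln_lambda(lam_grid, slipchip())
  # unique minimum: decreases to a valley then increases
  valley <- which.min(sig)
  expect_gt(valley, 1)
  expect_lt(valley, length(sig))
  expect_true(all(diff(sig[seq_len(valley)]) < 0))
  expect_true(all(diff(sig[valley:length(sig)]) > 0))
  # strictly decreasing in n at fixed lambda
  ns <- c(320, 640, 1280, 2560)
  sig_n <- vapply(ns, function(n) sigma_ln_lambda(5e4, device_spec(n, 3e-6)),
                  numeric(1))
  expect_true(all(diff(sig_n) < 0))
})

test_that("positive fraction and estimator are mutual inverses", {
  dev <- slipchip()
  expect_identical(expected_positive_fraction(0, dev), 0)
  expect_equal(expected_positive_fraction(log(2) / 3e-6, dev), 0.5)
  expect_equal(expected_positive_fraction(5e4, dev), 1 - exp(-0.15))
  expect_error(expected_positive_fraction(-1, dev), "non-negative")

  for (occ in c(0.05, 0.3, 1, 2, 2.9)) {
    lam <- occ / 3e-6
    k <- round(1280 * expected_positive_fraction(lam, dev))
    est <- estimate_lambda(digital_count(k, 1280), dev)
    # recovery to within the rounding granularity of one well
    expect_equal(est$lambda_hat, lam, tolerance = 0.01)
  }
})

test_that("digital efficiency is the ratio of estimated to loaded", {
  dev <- slipchip()
  est <- estimate_lambda(digital_count(178, 1280), dev)
  expect_equal(digital_efficiency(est, est$lambda_hat), 1.0)
  expect_equal(digital_efficiency(est, 2 * est$lambda_hat), 0.5)
  est0 <- estimate_lambda(digital_count(0, 1280), dev)
  expect_identical(digital_efficiency(est0, 5e4), 0)
  expect_error(digital_efficiency(est, 0), "positive")
})

test_that("normalization rescales to the reference condition", {
  ests <- list(efficiency_estimate("A", c(0.4, 0.4)),
               efficiency_estimate("B", c(0.4, 0.4)))
  norm <- normalize_efficiencies(ests, "A")
  expect_equal(vapply(norm, `[[`, numeric(1), "efficiency"), c(1, 1))

  ests2 <- list(efficiency_estimate("DOP", c(0.45, 0.50, 0.55)),
                efficiency_estimate("X", c(0.25, 0.30, 0.35)))
  norm2 <- normalize_efficiencies(ests2, "DOP")
  expect_equal(norm2[[1]]$efficiency, 1.0)
  expect_equal(norm2[[2]]$efficiency, 0.6)
  # SE rescaled by the same factor, reference treated as a constant
  expect_equal(norm2[[2]]$se, ests2[[2]]$se / 0.5)

  ests3 <- list(efficiency_estimate("DOP", 0.5),
                efficiency_estimate("BPP", 0.17))
  expect_equal(normalize_efficiencies(ests3, "DOP")[[2]]$efficiency, 0.34)

  expect_error(normalize_efficiencies(ests2, "missing"), "not found")
  expect_error(
    normalize_efficiencies(list(efficiency_estimate("Z", 0)), "Z"),
    "non-positive"
  )
})

test_that("condition comparison behaves at its boundaries", {
  same <- c(1.0, 1.1, 0.9)
  cmp <- compare_conditions(same, same)
  expect_equal(cmp$mean_difference, 0)
  expect_equal(cmp$p_value, 1)

  expect_warning(deg <- compare_conditions(c(1, 1, 1), c(0, 0, 0)),
                 "zero variance")
  expect_identical(deg$p_value, 0)
  expect_warning(deg2 <- compare_conditions(c(1, 1), c(1, 1)), "zero variance")
  expect_identical(deg2$p_value, 1)

  expect_error(compare_conditions(1, c(1, 2)), "at least 2")
})

test_that("the comparison reliably separates well-resolved groups", {
  set.seed(401)
  detected <- replicate(200, {
    a <- rnorm(8, 1.0, 0.05)
    b <- rnorm(8, 0.6, 0.05)
    compare_conditions(a, b)$p_value < 0.01
  })
  expect_gte(mean(detected), 0.99)
})

test_that("simulated devices validate the estimator and its uncertainty", {
  dev <- slipchip()
  set.seed(402)
  # consistency of the mean estimate across occupancies
  for (occ in c(0.05, 0.3, 1)) {
    lam <- occ / 3e-6
    k <- draw_counts(2000, dev, lam)
    lam_hat <- -log1p(-k / 1280) / 3e-6
    expect_equal(mean(lam_hat), lam, tolerance = 0.02)
  }
  # the ln-scale SD formula matches the empirical spread
  k <- draw_counts(2000, dev, 5e4)
  expect_equal(sd(log(-log1p(-k / 1280) / 3e-6)), 0.075, tolerance = 0.1)
})
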