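test_that("config invariants are enforced", {
  expect_error(simulation_config(lambda_true = -1), "positive")
  expect_error(simulation_config(efficiency = 1.5), "\\[0, 1\\]")
  expect_error(simulation_config(duration_min = 5, delay_offset_min = 10),
               "duration")
  expect_error(simulation_config(frame_interval_min = 20, duration_min = 60),
               "frame_interval")
})

test_that("fates are Bernoulli thinning of Poisson loading", {
  # zero efficiency: no positives regardless of loading
  cfg0 <- simulation_config(efficiency = 0, lambda_true = 5e5, seed = 1)
  expect_identical(simulate_device(cfg0, traces = FALSE)$counts$k_positive, 0L)

  # full efficiency: mean positive fraction ~ Poisson occupancy complement
  ks <- vapply(1:200, function(s) {
    cfg <- simulation_config(seed = s)
    simulate_device(cfg, traces = FALSE)$counts$k_positive
  }, integer(1))
  f <- mean(ks) / 1280
  se <- sd(ks / 1280) / sqrt(200)
  expect_lt(abs(f - (1 - exp(-0.15))), 3 * se + 1e-4)

  # half efficiency halves the exponent
  ks2 <- vapply(1:200, function(s) {
    cfg <- simulation_config(efficiency = 0.5, seed = 10000 + s)
    simulate_device(cfg, traces = FALSE)$counts$k_positive
  }, integer(1))
  f2 <- mean(ks2) / 1280
  se2 <- sd(ks2 / 1280) / sqrt(200)
  expect_lt(abs(f2 - (1 - exp(-0.075))), 3 * se2 + 1e-4)
})

test_that("per-well loading is Poisson and reproducible from the seed", {
  counts <- unlist(lapply(1:50, function(s) {
    simulate_device(simulation_config(seed = s), traces = FALSE)$template_counts
  }))
  # variance equals mean within 5% (64000 wells pooled)
  expect_lt(abs(var(counts) / mean(counts) - 1), 0.05)

  a <- simulate_device(simulation_config(seed = 42), traces = FALSE)
  b <- simulate_device(simulation_config(seed = 42), traces = FALSE)
  expect_identical(a$template_counts, b$template_counts)
  expect_identical(a$true_ttp_min, b$true_ttp_min)
})

test_that("simulated devices honour their internal consistency", {
  dev <- simulate_device(simulation_config(seed = 8, efficiency = 0.7),
                         traces = FALSE)
  expect_identical(dev$counts$k_positive, sum(dev$amplified))
  expect_true(all(is.na(dev$true_ttp_min[!dev$amplified])))
  expect_true(all(!is.na(dev$true_ttp_min[dev$amplified])))
  expect_true(all(dev$amplified <= (dev$template_counts > 0)))
  expect_true(all(dev$true_ttp_min[dev$amplified] >= 10))
})

test_that("estimator recovery works end to end at the formula's precision", {
  set.seed(601)
  seeds <- sample.int(1e6, 400)
  lam_hat <- vapply(seeds, function(s) {
    d <- simulate_device(simulation_config(seed = s), traces = FALSE)
    estimate_lambda(d$counts, slipchip())$lambda_hat
  }, numeric(1))
  sig <- sigma_ln_lambda(5e4, slipchip())
  covered <- abs(log(lam_hat) - log(5e4)) <= 1.96 * sig
  # ~95% of devices fall inside +/- 1.96 sigma
  expect_gt(mean(covered), 0.95 - 3 * sqrt(0.95 * 0.05 / 400))

  # efficiency recovery: thinned loading comes back as the Bernoulli rate
  set.seed(602)
  k <- draw_counts(2000, slipchip(), 5e4, efficiency = 0.6)
  eff <- (-log1p(-k / 1280) / 3e-6) / 5e4
  expect_lt(abs(mean(eff) - 0.6), 0.02)
})

test_that("device traces render positive wells as logistic curves", {
  cfg <- simulation_config(device = device_spec(24, 3e-6),
                           lambda_true = 3e5, noise_sd = 0.5, seed = 12)
  dev <- simulate_device(cfg, traces = TRUE)
  expect_length(dev$traces, 24)
  # fixed floor well above the noise ceiling: this test targets rendering,
  # not the background-derived floor heuristic
  calls <- lapply(dev$traces, call_well, signal_floor = 10 * cfg$noise_sd)
  called_pos <- vapply(calls, `[[`, logical(1), "positive")
  expect_identical(called_pos, dev$amplified)
  # called times match the simulated truth within a frame
  for (w in which(dev$amplified)) {
    expect_equal(calls[[w]]$time_to_positive_min, dev$true_ttp_min[w],
                 tolerance = 2 * cfg$frame_interval_min)
  }
})

test_that("bulk reactions show winner-takes-all concentration scaling", {
  # zero successful molecules: flat negative trace
  cfg_none <- simulation_config(lambda_true = 1, efficiency = 1, seed = 3)
  tr0 <- simulate_bulk_reaction(cfg_none, 1e-3)
  expect_identical(attr(tr0, "n_successful"), 0L)
  expect_true(is.na(plate_time_to_positive(tr0)))

  # the digital format reads out earlier than bulk at equal loading:
  # bulk concentration 5e4/ml is far below the single-molecule-in-a-well
  # concentration 1/nu = 3.3e8/ml, so the offset is large and positive
  dig_ttp <- vapply(1:30, function(s) {
    d <- simulate_device(simulation_config(seed = 700 + s), traces = FALSE)
    device_time_to_positive(calls_from_true_times(d))$time_min
  }, numeric(1))
  bulk_ttp <- vapply(1:30, function(s) {
    tr <- simulate_bulk_reaction(simulation_config(seed = 800 + s), 1e-2)
    attr(tr, "true_ttp_min")
  }, numeric(1))
  expect_gt(mean(bulk_ttp), mean(dig_ttp))

  # equal rate parameters, different efficiencies: winner-takes-all makes
  # the bulk time depend on efficiency only through ln(successful count),
  # so a 0.6 efficiency ratio shifts the bulk time by a fraction of a
  # minute while the efficiency estimates separate by the full factor
  bulk_hi <- vapply(1:30, function(s) attr(simulate_bulk_reaction(
    simulation_config(efficiency = 1.0, seed = 900 + s), 1e-2
  ), "true_ttp_min"), numeric(1))
  bulk_lo <- vapply(1:30, function(s) attr(simulate_bulk_reaction(
    simulation_config(efficiency = 0.6, seed = 950 + s), 1e-2
  ), "true_ttp_min"), numeric(1))
  shift <- mean(bulk_lo) - mean(bulk_hi)
  cfg <- simulation_config()
  expect_equal(shift, log(1 / 0.6) / cfg$steepness, tolerance = 0.5)
  expect_lt(abs(shift), 1)  # minor against the ~12 min reaction timescale
})

test_that("scenario bundles are complete, reproducible and truthful", {
  out <- file.path(tempdir(), "scen_test")
  on.exit(unlink(out, recursive = TRUE), add = TRUE)
  man <- generate_scenario("decoupled_fip", seed = 11, out_dir = out,
                           n_devices = 3, device = device_spec(256, 3e-6))
  expect_setequal(list.files(out),
                  c("counts.csv", "traces.csv", "dilution.csv",
                    "manifest.json"))
  cts <- read_counts(file.path(out, "counts.csv"))
  expect_identical(nrow(cts), 6L)
  expect_setequal(unique(cts$condition), c("A", "B"))
  dil <- read_dilution(file.path(out, "dilution.csv"))
  expect_true(all(dil$n_positive <= dil$n_reactions))
  expect_identical(man$efficiency$B, 0.6)

  # reproducibility: same seed, same files
  out2 <- file.path(tempdir(), "scen_test2")
  on.exit(unlink(out2, recursive = TRUE), add = TRUE)
  generate_scenario("decoupled_fip", seed = 11, out_dir = out2,
                    n_devices = 3, device = device_spec(256, 3e-6))
  expect_identical(readLines(file.path(out, "counts.csv")),
                   readLines(file.path(out2, "counts.csv")))
  expect_error(generate_scenario("nope", 1, tempdir()), "unknown scenario")
})

test_that("the enzyme-swap scenario is slower but more efficient", {
  out <- file.path(tempdir(), "scen_enzyme")
  on.exit(unlink(out, recursive = TRUE), add = TRUE)
  man <- generate_scenario("enzyme_swap", seed = 13, out_dir = out,
                           n_devices = 6)
  expect_gt(man$efficiency$RTx, man$efficiency$EM)
  expect_gt(man$delay_offset_min$RTx, man$delay_offset_min$EM)

  # efficiencies from the counts separate in the configured direction
  cts <- read_counts(file.path(out, "counts.csv"))
  conc <- quantify_counts(cts)
  eff <- split(conc$lambda_per_ml / 5e4, conc$condition)
  expect_gt(mean(eff$RTx), mean(eff$EM))
  expect_lt(compare_conditions(eff$RTx, eff$EM)$p_value, 0.05)

  # and the device-level times go the other way (slower yet better)
  ttp <- lapply(c(EM = 0, RTx = 500), function(offs) {
    vapply(1:6, function(d) {
      cfg <- simulation_config(
        efficiency = if (offs == 0) 0.45 else 0.9,
        delay_offset_min = if (offs == 0) 10 else 18,
        delay_scale_min = if (offs == 0) 2 else 2.5,
        seed = 13 + offs + d
      )
      dev <- simulate_device(cfg, traces = FALSE)
      device_time_to_positive(calls_from_true_times(dev))$time_min
    }, numeric(1))
  })
  expect_gt(mean(ttp$RTx), mean(ttp$EM))
})

test_that("null-scenario p-values are calibrated", {
  ps <- vapply(seq(100, 6000, by = 100), function(seed) {
    eff <- lapply(c(0, 500), function(offs) {
      vapply(1:4, function(d) {
        cfg <- simulation_config(efficiency = 0.8, seed = seed + offs + d)
        k <- simulate_device(cfg, traces = FALSE)$counts
        digital_efficiency(estimate_lambda(k, slipchip()), 5e4)
      }, numeric(1))
    })
    compare_conditions(eff[[1]], eff[[2]])$p_value
  }, numeric(1))
  # roughly uniform: the rejection rate at 0.05 is near nominal and the
  # distribution is not concentrated
  expect_lt(abs(mean(ps < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 60) + 0.02)
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})
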