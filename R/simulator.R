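#' Simulation configuration for single-molecule amplification
#'
#' The generative model behind the analysis: wells load templates as
#' Poisson(\eqn{\lambda\nu}); each template independently amplifies with
#' probability `efficiency` (its "fate"); each successful template starts
#' amplifying after a random delay (its "rate"), drawn from an offset gamma
#' distribution `delay_offset_min + Gamma(delay_shape, delay_scale_min)`;
#' a well turns positive at the minimum of its successful templates'
#' delays (the first winner); positive wells emit a logistic fluorescence
#' curve centred on that time, negative wells emit flat background, both
#' with additive Gaussian noise.
#'
#' Defaults mimic a 1280-well x 3 nl device loaded at
#' \eqn{5\times10^4} molecules/ml (occupancy \eqn{\nu\lambda = 0.15}) with
#' single-molecule start times around 10-25 min, as seen in isothermal
#' single-molecule amplification experiments.
#'
#' @param device A [device_spec()] (default [slipchip()]).
#' @param lambda_true True template concentration, molecules/ml.
#' @param efficiency Per-molecule amplification probability in (0, 1\].
#' @param delay_shape,delay_scale_min,delay_offset_min Offset-gamma delay
#'   model for single-molecule start times (shape, scale in minutes,
#'   offset in minutes).
#' @param amplitude Logistic curve amplitude, arbitrary units.
#' @param steepness Logistic steepness, 1/min; doubles as the exponential
#'   growth-rate surrogate for bulk reactions.
#' @param background_level Baseline intensity, arbitrary units.
#' @param noise_sd Additive Gaussian noise SD, arbitrary units.
#' @param frame_interval_min Imaging interval in minutes; must be less
#'   than a quarter of the duration.
#' @param duration_min Experiment duration in minutes; must be at least
#'   the delay offset.
#' @param seed Integer seed; all randomness in [simulate_device()] and
#'   [simulate_bulk_reaction()] flows from it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(device = slipchip(),
                              lambda_true = 5e4,
                              efficiency = 1,
                              delay_shape = 4,
                              delay_scale_min = 2,
                              delay_offset_min = 10,
                              amplitude = 100,
                              steepness = 1.5,
                              background_level = 50,
                              noise_sd = 1,
                              frame_interval_min = 0.5,
                              duration_min = 60,
                              seed = 1L) {
  stopifnot(inherits(device, "device_spec"))
  if (lambda_true <= 0) stop("'lambda_true' must be positive", call. = FALSE)
  if (efficiency < 0 || efficiency > 1) {
    stop("'efficiency' must be in [0, 1]", call. = FALSE)
  }
  if (delay_shape <= 0 || delay_scale_min <= 0 || delay_offset_min < 0) {
    stop("delay model parameters out of range", call. = FALSE)
  }
  if (amplitude <= 0 || steepness <= 0 || noise_sd < 0) {
    stop("curve model parameters out of range", call. = FALSE)
  }
  if (duration_min < delay_offset_min) {
    stop("'duration_min' must be >= 'delay_offset_min'", call. = FALSE)
  }
  if (frame_interval_min <= 0 || frame_interval_min >= duration_min / 4) {
    stop("'frame_interval_min' must be positive and < duration_min / 4",
         call. = FALSE)
  }
  structure(
    list(
      device = device, lambda_true = lambda_true, efficiency = efficiency,
      delay_shape = delay_shape, delay_scale_min = delay_scale_min,
      delay_offset_min = delay_offset_min,
      amplitude = amplitude, steepness = steepness,
      background_level = background_level, noise_sd = noise_sd,
      frame_interval_min = frame_interval_min, duration_min = duration_min,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

# Draw per-molecule start delays for 'total' successful molecules.
.draw_delays <- function(total, config) {
  config$delay_offset_min +
    stats::rgamma(total, shape = config$delay_shape,
                  scale = config$delay_scale_min)
}

# Logistic amplification curve with additive noise on a time grid.
.render_trace <- function(times, t_mid, config) {
  base <- config$background_level +
    stats::rnorm(length(times), sd = config$noise_sd)
  if (is.na(t_mid)) return(base)
  base + config$amplitude / (1 + exp(-config$steepness * (times - t_mid)))
}

#' Simulate one digital device
#'
#' Generates per-well template counts, per-molecule fates, per-well true
#' times to positive (the minimum successful-template delay), and
#' optionally per-well fluorescence traces, for one device under a
#' [simulation_config()]. Fully reproducible from `config$seed`.
#'
#' @param config A [simulation_config()].
#' @param traces Render per-well fluorescence traces? Default `TRUE`.
#'   Counts-only simulation (`FALSE`) is much faster and sufficient for
#'   estimator studies.
#' @return An object of class `simulated_device`: `template_counts`
#'   (integer per well), `amplified` (logical per well), `true_ttp_min`
#'   (numeric per well, `NA` for negative wells), `counts` (a
#'   [digital_count()]), `traces` (list of [well_trace()] or `NULL`),
#'   `times_min` (the frame grid, or `NULL`), `config`.
#' @examples
#' dev <- simulate_device(simulation_config(seed = 7), traces = FALSE)
#' dev$counts
#' @export
simulate_device <- function(config, traces = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  n <- config$device$n_wells
  nu <- config$device$well_volume_ml
  template_counts <- stats::rpois(n, config$lambda_true * nu)
  successes <- stats::rbinom(n, template_counts, config$efficiency)
  amplified <- successes > 0L
  true_ttp <- rep(NA_real_, n)
  pos <- which(amplified)
  if (length(pos)) {
    # one draw per successful molecule; a well fires at its first winner
    delays <- .draw_delays(sum(successes[pos]), config)
    owner <- rep.int(pos, successes[pos])
    o <- order(delays)
    keep <- !duplicated(owner[o])
    true_ttp[owner[o][keep]] <- delays[o][keep]
  }
  counts <- digital_count(sum(amplified), n, "")
  out <- list(
    template_counts = template_counts,
    amplified = amplified,
    true_ttp_min = true_ttp,
    counts = counts,
    traces = NULL,
    times_min = NULL,
    config = config
  )
  if (traces) {
    grid <- seq(0, config$duration_min, by = config$frame_interval_min)
    out$times_min <- grid
    out$traces <- lapply(seq_len(n), function(w) {
      well_trace(
        sprintf("w%04d", w), grid,
        .render_trace(grid, true_ttp[w], config)
      )
    })
  }
  structure(out, class = "simulated_device")
}

#' @export
print.simulated_device <- function(x, ...) {
  cat(sprintf(
    "Simulated device: %d/%d wells positive (efficiency %.2f, occupancy %.3f)\n",
    x$counts$k_positive, x$counts$n_total, x$config$efficiency,
    x$config$lambda_true * x$config$device$well_volume_ml
  ))
  invisible(x)
}

#' Well calls from a simulated device's true times
#'
#' Builds [call_well()]-style calls directly from the simulator's true
#' per-well times to positive, bypassing trace rendering. Useful for
#' device-level timing studies where rendering 1280 fluorescence curves
#' per device adds nothing.
#'
#' @param dev A [simulate_device()] result.
#' @return List of `well_call` objects.
#' @export
calls_from_true_times <- function(dev) {
  stopifnot(inherits(dev, "simulated_device"))
  lapply(seq_along(dev$amplified), function(w) {
    structure(
      list(
        well_id = sprintf("w%04d", w),
        positive = dev$amplified[w],
        time_to_positive_min = dev$true_ttp_min[w],
        threshold_value = NA_real_
      ),
      class = "well_call"
    )
  })
}

#' Simulate a bulk (multi-molecule) reaction
#'
#' Draws the number of templates in the reaction volume as
#' Poisson(\eqn{\lambda V}), thins by the digital efficiency, and models
#' winner-takes-all kinetics: the bulk time to threshold is the earliest
#' successful molecule's start delay plus a concentration offset
#' \eqn{\ln(c_{ref}/c)/r}, where \eqn{c} is the concentration of
#' successful templates in the reaction, \eqn{c_{ref} = 1/\nu} is the
#' single-molecule-in-a-well concentration of the digital device, and
#' \eqn{r} is the exponential growth-rate surrogate (the curve steepness).
#' Lower effective concentration means more doublings to reach threshold,
#' hence later crossing; a digital well at \eqn{c_{ref}} has zero offset.
#' A reaction with zero successful molecules yields a flat background
#' trace.
#'
#' @param config A [simulation_config()] (device well volume supplies
#'   \eqn{c_{ref}}).
#' @param volume_ml Bulk reaction volume in ml.
#' @return A [well_trace()] for the bulk reaction, with attributes
#'   `true_ttp_min` (`NA` if negative) and `n_successful`.
#' @export
simulate_bulk_reaction <- function(config, volume_ml) {
  stopifnot(inherits(config, "simulation_config"))
  if (length(volume_ml) != 1L || !is.finite(volume_ml) || volume_ml <= 0) {
    stop("'volume_ml' must be positive", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  m <- stats::rpois(1L, config$lambda_true * volume_ml)
  s <- stats::rbinom(1L, m, config$efficiency)
  grid <- seq(0, config$duration_min, by = config$frame_interval_min)
  if (s == 0L) {
    tr <- well_trace("bulk", grid, .render_trace(grid, NA_real_, config))
    attr(tr, "true_ttp_min") <- NA_real_
    attr(tr, "n_successful") <- 0L
    return(tr)
  }
  c_successful <- s / volume_ml
  c_ref <- 1 / config$device$well_volume_ml
  offset <- log(c_ref / c_successful) / config$steepness
  t_bulk <- min(.draw_delays(s, config)) + offset
  tr <- well_trace("bulk", grid, .render_trace(grid, t_bulk, config))
  attr(tr, "true_ttp_min") <- t_bulk
  attr(tr, "n_successful") <- s
  tr
}

#' Scenario presets for two-condition comparisons
#'
#' Packaged synthetic comparisons that reproduce the qualitative structure
#' of digital-versus-bulk primer and enzyme experiments:
#' \describe{
#'   \item{`decoupled_fip`}{Equal delay models, efficiencies 1.0 vs 0.6 -
#'     same speed, different digital efficiency (the headline decoupling).}
#'   \item{`loop_primer`}{Slower delay model in the second condition at
#'     equal efficiency - different speed, same efficiency.}
#'   \item{`enzyme_swap`}{Second condition slower but more efficient.}
#'   \item{`null`}{Both conditions identical.}
#' }
#'
#' Writes `counts.csv` (all devices), `traces.csv` (the first device of
#' each condition), `dilution.csv` (a 4-point detection series per
#' condition) and `manifest.json` (full ground truth) under `out_dir`.
#'
#' @param name One of `"decoupled_fip"`, `"loop_primer"`, `"enzyme_swap"`,
#'   `"null"`.
#' @param seed Integer seed.
#' @param out_dir Output directory (created if needed).
#' @param n_devices Devices per condition (default 8).
#' @param device A [device_spec()] (default [slipchip()]).
#' @return Invisibly, the manifest list (also written as JSON).
#' @export
generate_scenario <- function(name, seed, out_dir,
                              n_devices = 8, device = slipchip()) {
  scenarios <- list(
    decoupled_fip = list(
      conditions = c("A", "B"),
      efficiency = c(A = 1.0, B = 0.6),
      delay_offset_min = c(A = 10, B = 10),
      delay_scale_min = c(A = 2, B = 2)
    ),
    loop_primer = list(
      conditions = c("full", "noloop"),
      efficiency = c(full = 0.9, noloop = 0.9),
      delay_offset_min = c(full = 10, noloop = 16),
      delay_scale_min = c(full = 2, noloop = 2.5)
    ),
    enzyme_swap = list(
      conditions = c("EM", "RTx"),
      efficiency = c(EM = 0.45, RTx = 0.9),
      delay_offset_min = c(EM = 10, RTx = 18),
      delay_scale_min = c(EM = 2, RTx = 2.5)
    ),
    null = list(
      conditions = c("A", "B"),
      efficiency = c(A = 0.8, B = 0.8),
      delay_offset_min = c(A = 10, B = 10),
      delay_scale_min = c(A = 2, B = 2)
    )
  )
  if (!name %in% names(scenarios)) {
    stop(sprintf("unknown scenario '%s'; choose one of %s", name,
                 paste(names(scenarios), collapse = ", ")), call. = FALSE)
  }
  sc <- scenarios[[name]]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  lambda_true <- 5e4

  counts_rows <- list()
  traces_rows <- list()
  dilution_rows <- list()
  device_seeds <- list()
  for (ci in seq_along(sc$conditions)) {
    cond <- sc$conditions[ci]
    seeds <- seed + 1000L * ci + seq_len(n_devices)
    device_seeds[[cond]] <- seeds
    for (d in seq_len(n_devices)) {
      cfg <- simulation_config(
        device = device, lambda_true = lambda_true,
        efficiency = sc$efficiency[[cond]],
        delay_offset_min = sc$delay_offset_min[[cond]],
        delay_scale_min = sc$delay_scale_min[[cond]],
        seed = seeds[d]
      )
      want_traces <- d == 1L
      dev <- simulate_device(cfg, traces = want_traces)
      counts_rows[[length(counts_rows) + 1L]] <- data.frame(
        condition = cond,
        device_id = sprintf("%s_dev%02d", cond, d),
        k_positive = dev$counts$k_positive,
        n_total = dev$counts$n_total,
        well_volume_nl = device$well_volume_ml * 1e6
      )
      if (want_traces) {
        traces_rows[[length(traces_rows) + 1L]] <- do.call(rbind, lapply(
          dev$traces, function(tr) data.frame(
            condition = cond,
            device_id = sprintf("%s_dev%02d", cond, d),
            well_id = tr$well_id,
            time_min = tr$times_min,
            intensity = tr$intensities
          )
        ))
      }
    }
    # 4-point dilution series per condition, 96 reactions per level
    model_e <- sc$efficiency[[cond]]
    conc <- c(1, 3, 10, 30)
    set.seed(seed + 77L * ci)
    kpos <- stats::rbinom(length(conc), 96L, -expm1(-conc * model_e))
    dilution_rows[[length(dilution_rows) + 1L]] <- data.frame(
      condition = cond, copies_per_reaction = conc,
      n_reactions = 96L, n_positive = kpos
    )
  }

  utils::write.csv(do.call(rbind, counts_rows),
                   file.path(out_dir, "counts.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, traces_rows),
                   file.path(out_dir, "traces.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, dilution_rows),
                   file.path(out_dir, "dilution.csv"), row.names = FALSE)

  manifest <- list(
    scenario = name,
    seed = seed,
    lambda_true = lambda_true,
    n_devices = n_devices,
    device = list(n_wells = device$n_wells,
                  well_volume_ml = device$well_volume_ml),
    conditions = sc$conditions,
    efficiency = as.list(sc$efficiency),
    delay_offset_min = as.list(sc$delay_offset_min),
    delay_scale_min = as.list(sc$delay_scale_min),
    device_seeds = device_seeds
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
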