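# Build a noiseless logistic trace: amplitude A, midpoint t50, steepness k.
logistic_trace <- function(t50, amplitude = 100, steepness = 1.5,
                           background = 0, from = 0, to = 40, by = 0.25,
                           well_id = "w") {
  tm <- seq(from, to, by = by)
  well_trace(well_id, tm,
             background + amplitude / (1 + exp(-steepness * (tm - t50))))
}

# Well calls at given times (NA = negative well), for device-level rules.
calls_at <- function(times) {
  lapply(seq_along(times), function(i) structure(
    list(well_id = paste0("w", i), positive = !is.na(times[i]),
         time_to_positive_min = times[i], threshold_value = 1),
    class = "well_call"
  ))
}

# Vectorized digital-count draws: k positives for m devices at a given
# occupancy and per-molecule efficiency (binomial thinning of Poisson
# loading collapses to a binomial on wells).
draw_counts <- function(m, device, lambda_, efficiency = 1) {
  p <- -expm1(-lambda_ * device$well_volume_ml * efficiency)
  stats::rbinom(m, device$n_wells, p)
}
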