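#' Per-well real-time fluorescence trace
#'
#' @param well_id Well identifier.
#' @param times_min Strictly increasing sample times in minutes (>= 4).
#' @param intensities Fluorescence intensities (arbitrary units), same
#'   length as `times_min`.
#' @return An object of class `well_trace`.
#' @export
well_trace <- function(well_id, times_min, intensities) {
  if (length(times_min) < 4L) {
    stop("a trace needs at least 4 samples", call. = FALSE)
  }
  if (length(times_min) != length(intensities)) {
    stop("'times_min' and 'intensities' must have equal length", call. = FALSE)
  }
  if (!all(is.finite(times_min)) || any(diff(times_min) <= 0)) {
    stop("'times_min' must be finite and strictly increasing", call. = FALSE)
  }
  if (!all(is.finite(intensities))) {
    stop("'intensities' must be finite", call. = FALSE)
  }
  structure(
    list(
      well_id = as.character(well_id),
      times_min = as.numeric(times_min),
      intensities = as.numeric(intensities)
    ),
    class = "well_trace"
  )
}

#' Call a well positive or negative and extract its time to positive
#'
#' Deterministic analogue of the manual thresholding procedure used on
#' real-time digital amplification images: the background is the mean of
#' the first `background_frames` intensities; the trace is
#' background-corrected; the threshold is `threshold_fraction` (default
#' half) of the corrected maximum. A well is positive when its corrected
#' maximum exceeds a signal floor (by default 5 standard deviations of the
#' background frames, so a flat noisy trace is not called positive by the
#' fractional rule alone) and the corrected trace crosses the threshold
#' from below. The time to positive is the linearly interpolated time of
#' the first upward crossing; later re-crossings are ignored.
#'
#' The call is invariant under affine intensity transforms: an offset is
#' absorbed by the background correction and a gain cancels in the
#' fractional threshold and scales the noise-derived floor equally.
#'
#' @param trace A [well_trace()].
#' @param background_frames Number of leading frames averaged for
#'   background (default 3; must be < trace length).
#' @param threshold_fraction Fraction of the corrected maximum used as
#'   threshold, in (0, 1) (default 0.5).
#' @param signal_floor Minimum corrected maximum for a positive call, in
#'   corrected intensity units; `NULL` (default) uses 5 x the standard
#'   deviation of the background frames.
#' @return An object of class `well_call`: `well_id`, `positive`,
#'   `time_to_positive_min` (`NA` when negative), `threshold_value`.
#' @examples
#' tm <- seq(0, 40, by = 0.5)
#' tr <- well_trace("A1", tm, 100 / (1 + exp(-(tm - 20))))
#' call_well(tr)  # positive near t = 20 min
#' @export
call_well <- function(trace, background_frames = 3, threshold_fraction = 0.5,
                      signal_floor = NULL) {
  stopifnot(inherits(trace, "well_trace"))
  nt <- length(trace$times_min)
  if (background_frames < 1 || background_frames >= nt) {
    stop("'background_frames' must be >= 1 and < trace length", call. = FALSE)
  }
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    stop("'threshold_fraction' must be in (0, 1)", call. = FALSE)
  }
  bg_vals <- trace$intensities[seq_len(background_frames)]
  corrected <- trace$intensities - mean(bg_vals)
  if (is.null(signal_floor)) {
    signal_floor <- 5 * stats::sd(bg_vals)
    if (is.na(signal_floor)) signal_floor <- 0  # single background frame
  }
  peak <- max(corrected)
  threshold <- threshold_fraction * peak
  negative_call <- function() structure(
    list(
      well_id = trace$well_id, positive = FALSE,
      time_to_positive_min = NA_real_, threshold_value = threshold
    ),
    class = "well_call"
  )
  if (peak <= signal_floor || peak <= 0) return(negative_call())
  below <- corrected[-nt] < threshold
  above <- corrected[-1L] >= threshold
  cross <- which(below & above)
  if (length(cross) == 0L) return(negative_call())
  i <- cross[1L]
  t0 <- trace$times_min[i]; t1 <- trace$times_min[i + 1L]
  y0 <- corrected[i]; y1 <- corrected[i + 1L]
  structure(
    list(
      well_id = trace$well_id, positive = TRUE,
      time_to_positive_min = t0 + (threshold - y0) / (y1 - y0) * (t1 - t0),
      threshold_value = threshold
    ),
    class = "well_call"
  )
}

#' @export
print.well_call <- function(x, ...) {
  if (x$positive) {
    cat(sprintf("Well %s: positive at %.2f min (threshold %.3g)\n",
                x$well_id, x$time_to_positive_min, x$threshold_value))
  } else {
    cat(sprintf("Well %s: negative\n", x$well_id))
  }
  invisible(x)
}

#' Device-level time to positive from per-well calls
#'
#' The reported time to positive of a digital device is the time of the
#' earliest positive well that is promptly followed by further positive
#' wells: the earliest positive time \eqn{t^*} such that at least
#' `m_subsequent` other wells turn positive within
#' \eqn{[t^*, t^* + \mathrm{window}]} (wells positive at exactly \eqn{t^*}
#' count as simultaneous firsts). Single-molecule start times are
#' stochastic, so an isolated early well is not representative of the
#' condition; the subsequent-series requirement guards against it. If no
#' well satisfies the rule the earliest positive time is returned with
#' `fallback = TRUE` and a warning.
#'
#' @param calls List of [call_well()] results (at least one positive).
#' @param m_subsequent Required number of additional positive wells
#'   (default 2).
#' @param window_min Window length in minutes (default 3).
#' @return An object of class `device_ttp`: `time_min`,
#'   `n_supporting_wells` (the qualifying well plus followers in window),
#'   `rule_params`, `fallback`.
#' @export
device_time_to_positive <- function(calls, m_subsequent = 2, window_min = 3) {
  stopifnot(is.list(calls))
  times <- vapply(calls, function(cl) {
    stopifnot(inherits(cl, "well_call"))
    if (cl$positive) cl$time_to_positive_min else NA_real_
  }, numeric(1))
  times <- sort(times[!is.na(times)])
  if (length(times) == 0L) {
    stop("no positive wells: device time to positive undefined", call. = FALSE)
  }
  for (i in seq_along(times)) {
    t_star <- times[i]
    followers <- sum(times >= t_star & times <= t_star + window_min) - 1L
    if (followers >= m_subsequent) {
      return(structure(
        list(
          time_min = t_star,
          n_supporting_wells = followers + 1L,
          rule_params = list(m_subsequent = m_subsequent,
                             window_min = window_min),
          fallback = FALSE
        ),
        class = "device_ttp"
      ))
    }
  }
  warning("no well satisfied the subsequent-series rule; ",
          "falling back to the earliest positive time")
  structure(
    list(
      time_min = times[1L],
      n_supporting_wells = 1L,
      rule_params = list(m_subsequent = m_subsequent, window_min = window_min),
      fallback = TRUE
    ),
    class = "device_ttp"
  )
}

#' @export
print.device_ttp <- function(x, ...) {
  cat(sprintf(
    "Device time to positive: %.2f min (%d supporting wells%s)\n",
    x$time_min, x$n_supporting_wells,
    if (x$fallback) ", FALLBACK: series rule unmet" else ""
  ))
  invisible(x)
}

#' Time to threshold of a bulk (multi-molecule) reaction
#'
#' Applies the same background-correction, fractional-threshold and
#' interpolation computation as [call_well()] to a single bulk-reaction
#' trace. A trace that never exceeds the signal floor is a negative
#' reaction, not an error, and yields `NA`.
#'
#' @inheritParams call_well
#' @return The interpolated crossing time in minutes, or `NA_real_` for a
#'   negative reaction.
#' @export
plate_time_to_positive <- function(trace, background_frames = 3,
                                   threshold_fraction = 0.5,
                                   signal_floor = NULL) {
  cl <- call_well(trace, background_frames, threshold_fraction, signal_floor)
  if (cl$positive) cl$time_to_positive_min else NA_real_
}

#' Count positive wells
#'
#' @param calls List of [call_well()] results.
#' @param condition_label Optional label carried into the count.
#' @return A [digital_count()] with `k_positive` positives of
#'   `n_total = length(calls)` wells.
#' @export
count_positives <- function(calls, condition_label = "") {
  stopifnot(is.list(calls))
  pos <- vapply(calls, function(cl) {
    stopifnot(inherits(cl, "well_call"))
    cl$positive
  }, logical(1))
  digital_count(sum(pos), length(pos), condition_label)
}
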