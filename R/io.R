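# CSV interfaces. Counts are per device/condition; traces are long-format
# per well; dilution series are per condition/level. Volumes in files are
# nanoliters and converted to ml internally.

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' Read a digital count table
#'
#' Expects columns `condition`, `device_id`, `k_positive`, `n_total`,
#' `well_volume_nl`. Well volumes are converted from nl to ml into a
#' `well_volume_ml` column.
#'
#' @param path CSV file path.
#' @return A data.frame with the original columns plus `well_volume_ml`.
#' @export
read_counts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_columns(df, c("condition", "device_id", "k_positive", "n_total",
                         "well_volume_nl"), basename(path))
  df$well_volume_ml <- df$well_volume_nl * 1e-6
  df
}

#' Read long-format real-time traces
#'
#' Expects columns `device_id`, `well_id`, `time_min`, `intensity`
#' (optionally `condition`).
#'
#' @param path CSV file path.
#' @return A data.frame.
#' @export
read_traces <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_columns(df, c("device_id", "well_id", "time_min", "intensity"),
                   basename(path))
  df
}

#' Read a dilution-series table
#'
#' Expects columns `condition`, `copies_per_reaction`, `n_reactions`,
#' `n_positive`.
#'
#' @param path CSV file path.
#' @return A data.frame.
#' @export
read_dilution <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_columns(df, c("condition", "copies_per_reaction", "n_reactions",
                         "n_positive"), basename(path))
  df
}

#' Quantify every device in a count table
#'
#' Runs [estimate_lambda()] on each row of a count table read by
#' [read_counts()].
#'
#' @param counts Data.frame from [read_counts()].
#' @param alpha CI significance level.
#' @return A data.frame with columns `condition`, `device_id`,
#'   `lambda_per_ml`, `sigma_ln_lambda`, `ci_low`, `ci_high`.
#' @export
quantify_counts <- function(counts, alpha = 0.05) {
  .require_columns(counts, c("condition", "device_id", "k_positive",
                             "n_total", "well_volume_ml"), "counts table")
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    r <- counts[i, ]
    est <- estimate_lambda(
      digital_count(r$k_positive, r$n_total, r$condition),
      device_spec(r$n_total, r$well_volume_ml),
      alpha = alpha
    )
    data.frame(
      condition = r$condition, device_id = r$device_id,
      lambda_per_ml = est$lambda_hat,
      sigma_ln_lambda = est$sigma_ln_lambda,
      ci_low = est$ci_low, ci_high = est$ci_high
    )
  })
  do.call(rbind, rows)
}

#' Call every well in a long-format trace table
#'
#' Applies [call_well()] to each (device, well) trace in a table read by
#' [read_traces()].
#'
#' @param traces Data.frame from [read_traces()].
#' @param background_frames,threshold_fraction,signal_floor Passed to
#'   [call_well()].
#' @return A data.frame with columns `device_id`, `well_id`, `positive`,
#'   `time_to_positive_min`, `threshold_value` (plus `condition` if
#'   present in the input).
#' @export
call_traces <- function(traces, background_frames = 3,
                        threshold_fraction = 0.5, signal_floor = NULL) {
  .require_columns(traces, c("device_id", "well_id", "time_min", "intensity"),
                   "traces table")
  has_cond <- "condition" %in% names(traces)
  key <- paste(traces$device_id, traces$well_id, sep = "\r")
  pieces <- split(traces, key)
  rows <- lapply(pieces, function(p) {
    p <- p[order(p$time_min), ]
    cl <- call_well(well_trace(p$well_id[1], p$time_min, p$intensity),
                    background_frames, threshold_fraction, signal_floor)
    out <- data.frame(
      device_id = p$device_id[1], well_id = p$well_id[1],
      positive = cl$positive,
      time_to_positive_min = cl$time_to_positive_min,
      threshold_value = cl$threshold_value
    )
    if (has_cond) out$condition <- p$condition[1]
    out
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}
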