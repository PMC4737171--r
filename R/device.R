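#' Digital device geometry
#'
#' A digital device partitions a sample into `n_wells` wells of volume
#' `well_volume_ml` each. At sufficiently low template concentration every
#' well holds 0 or 1 template molecule, so the fraction of positive wells
#' carries the concentration information.
#'
#' @param n_wells Number of wells (positive integer).
#' @param well_volume_ml Volume of one well in ml (positive).
#' @return An object of class `device_spec` with elements `n_wells`,
#'   `well_volume_ml` and `total_volume_ml`.
#' @examples
#' device_spec(1280, 3e-6)   # a 1280-well, 3 nl device
#' @seealso [slipchip()] for the preset used throughout the examples.
#' @export
device_spec <- function(n_wells, well_volume_ml) {
  if (length(n_wells) != 1L || !is.finite(n_wells) || n_wells < 1 ||
      n_wells != round(n_wells)) {
    stop("'n_wells' must be a single positive integer", call. = FALSE)
  }
  if (length(well_volume_ml) != 1L || !is.finite(well_volume_ml) ||
      well_volume_ml <= 0) {
    stop("'well_volume_ml' must be a single positive number", call. = FALSE)
  }
  structure(
    list(
      n_wells = as.integer(n_wells),
      well_volume_ml = as.numeric(well_volume_ml),
      total_volume_ml = as.integer(n_wells) * as.numeric(well_volume_ml)
    ),
    class = "device_spec"
  )
}

#' @export
print.device_spec <- function(x, ...) {
  cat(sprintf(
    "Digital device: %d wells x %.3g nl (total %.3g ul)\n",
    x$n_wells, x$well_volume_ml * 1e6, x$total_volume_ml * 1e3
  ))
  invisible(x)
}

#' SlipChip device preset
#'
#' The microfluidic device geometry used as the running example: 1280 wells
#' of 3 nl each (3.84 ul total).
#'
#' @return A [device_spec()].
#' @export
slipchip <- function() device_spec(1280L, 3e-6)

#' Positive-well count for one device and condition
#'
#' @param k_positive Number of positive wells (non-negative integer).
#' @param n_total Total number of wells read (positive integer).
#' @param condition_label Optional condition name.
#' @return An object of class `digital_count`.
#' @examples
#' digital_count(178, 1280, "DOP")
#' @export
digital_count <- function(k_positive, n_total, condition_label = "") {
  if (length(k_positive) != 1L || !is.finite(k_positive) ||
      k_positive < 0 || k_positive != round(k_positive)) {
    stop("'k_positive' must be a single non-negative integer", call. = FALSE)
  }
  if (length(n_total) != 1L || !is.finite(n_total) || n_total < 1 ||
      n_total != round(n_total)) {
    stop("'n_total' must be a single positive integer", call. = FALSE)
  }
  if (k_positive > n_total) {
    stop("'k_positive' cannot exceed 'n_total'", call. = FALSE)
  }
  structure(
    list(
      k_positive = as.integer(k_positive),
      n_total = as.integer(n_total),
      condition_label = as.character(condition_label)
    ),
    class = "digital_count"
  )
}

#' @export
print.digital_count <- function(x, ...) {
  lbl <- if (nzchar(x$condition_label)) paste0(" [", x$condition_label, "]") else ""
  cat(sprintf(
    "Digital count%s: %d / %d wells positive (%.1f%%)\n",
    lbl, x$k_positive, x$n_total, 100 * x$k_positive / x$n_total
  ))
  invisible(x)
}
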