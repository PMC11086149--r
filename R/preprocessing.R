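# Exclusion and trimming rules applied before any overlap statistics:
# walking/standing exclusion for outdoor data, treadmill belt-ramp trimming
# for in-lab trials, and the tractability subsample used before depth
# computation.

#' Exclude walking and standing records
#'
#' Retains records with speed at or above 1.56 m/s AND cadence at or above
#' 100 strides/min; records *below* either threshold are excluded (the
#' comparisons are strict, so boundary values are retained). Order is
#' preserved. The operation is idempotent.
#'
#' @param records Tibble of gait records with `speed` and `cadence`.
#' @return A list with `records` (the retained rows) and `report` (a
#'   `filter_report` with input/excluded/output counts).
#' @export
exclude_walking <- function(records) {
  keep <- records$speed >= WALK_SPEED_MS & records$cadence >= WALK_CADENCE_SPM
  report <- filter_report(n_input = nrow(records),
                          n_excluded_walking = sum(!keep),
                          n_trimmed = 0L)
  list(records = records[keep, , drop = FALSE], report = report)
}

#' Trim treadmill trials of belt-ramp seconds
#'
#' Within each trial `[start, end)`, removes records with
#' `timestamp < start + 25` or `timestamp > end - 15`, the portions where
#' the belt speed is still changing and the device metrics lag the
#' runner's true gait. An empty boundary list leaves records unchanged.
#'
#' @param records Tibble of gait records.
#' @param trial_boundaries Tibble (or data frame) with `start` and `end`
#'   columns, one row per trial; non-overlapping, each at least 41 s long
#'   so that trimming leaves something.
#' @return The retained records, order preserved.
#' @export
trim_treadmill_trial <- function(records, trial_boundaries) {
  if (is.null(trial_boundaries) || nrow(trial_boundaries) == 0) {
    return(records)
  }
  b <- as.data.frame(trial_boundaries)[order(trial_boundaries$start), ]
  if (any(b$end - b$start < 41)) {
    stop("trial shorter than 41 s cannot survive trimming (25 s head + ",
         "15 s tail)", call. = FALSE)
  }
  if (nrow(b) > 1 && any(b$start[-1] < b$end[-nrow(b)])) {
    stop("trial boundaries overlap", call. = FALSE)
  }
  keep <- rep(FALSE, nrow(records))
  for (i in seq_len(nrow(b))) {
    in_trial <- records$timestamp >= b$start[i] & records$timestamp < b$end[i]
    keep <- keep | (in_trial &
                      records$timestamp >= b$start[i] + 25 &
                      records$timestamp <= b$end[i] - 15)
  }
  records[keep, , drop = FALSE]
}

#' Random subsample for depth-computation tractability
#'
#' Simple random sample without replacement of `round(fraction * n)` rows,
#' reproducible for a fixed seed. Original row order is preserved.
#'
#' @param records Tibble (or matrix) of records.
#' @param fraction Sampling fraction in (0, 1]; 1 is the identity.
#' @param seed Integer seed.
#' @return The subsampled records.
#' @export
thin_subsample <- function(records, fraction = 0.25, seed = 1) {
  if (fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]", call. = FALSE)
  }
  n <- nrow(records)
  if (fraction == 1) return(records)
  k <- round(fraction * n)
  idx <- with_seed(seed, sort(sample.int(n, k)))
  records[idx, , drop = FALSE]
}

#' Construct a filter report
#'
#' Bookkeeping for the exclusion rules: input count, records excluded as
#' walking/standing, records trimmed from treadmill ramps, and the implied
#' output count and excluded fraction.
#'
#' @param n_input,n_excluded_walking,n_trimmed Non-negative counts.
#' @return An object of class `filter_report`.
#' @export
filter_report <- function(n_input, n_excluded_walking = 0L, n_trimmed = 0L) {
  counts <- c(n_input, n_excluded_walking, n_trimmed)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  n_output <- n_input - n_excluded_walking - n_trimmed
  if (n_output < 0) stop("excluded more records than supplied", call. = FALSE)
  structure(
    list(n_input = as.integer(n_input),
         n_excluded_walking = as.integer(n_excluded_walking),
         n_trimmed = as.integer(n_trimmed),
         n_output = as.integer(n_output),
         excluded_fraction = if (n_input == 0) 0 else
           (n_excluded_walking + n_trimmed) / n_input),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(
    "Filter report: %d in, %d walking excluded, %d trimmed, %d out (%.1f%% excluded)\n",
    x$n_input, x$n_excluded_walking, x$n_trimmed, x$n_output,
    100 * x$excluded_fraction))
  invisible(x)
}

#' @export
format.filter_report <- function(x, ...) {
  sprintf("n_input=%d n_excluded_walking=%d n_trimmed=%d n_output=%d excluded_fraction=%.4f",
          x$n_input, x$n_excluded_walking, x$n_trimmed, x$n_output,
          x$excluded_fraction)
}
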