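# Heading, turn rate and grade from GNSS traces, and data-driven
# flat-and-straight classification.
#
# Traces are tibbles with columns `time` (s, epoch), `lat`, `lon` (decimal
# degrees) and `ele` (m). Derived columns added here: `heading` (compass
# degrees in [0, 360)), `turn_rate` (deg/s, left turn positive) and `grade`
# (%, incline positive).

# Local equirectangular projection of lat/lon displacements to metres.
# Step distances in running traces are a few metres, where the error of
# this approximation relative to great-circle formulas is below 1e-6
# relative (it is second order in angular displacement).
local_step_enu <- function(lat, lon) {
  n <- length(lat)
  de <- diff(lon) * pi / 180 * EARTH_RADIUS_M * cos(lat[-n] * pi / 180)
  dn <- diff(lat) * pi / 180 * EARTH_RADIUS_M
  list(de = de, dn = dn, dist = sqrt(de^2 + dn^2))
}

#' Compute per-point compass heading of a trace
#'
#' Heading at point i is the compass bearing (degrees clockwise from north,
#' in [0, 360)) from point i to point i+1 on a local equirectangular
#' projection. The final point inherits the previous heading; consecutive
#' duplicate positions carry the last defined heading forward.
#'
#' @param trace A tibble with `lat` and `lon` columns (>= 2 rows).
#' @return The trace with a `heading` column added.
#' @export
compute_heading <- function(trace) {
  if (nrow(trace) < 2) stop("need at least 2 trace points", call. = FALSE)
  step <- local_step_enu(trace$lat, trace$lon)
  h <- (atan2(step$de, step$dn) * 180 / pi) %% 360
  h[step$dist == 0] <- NA_real_
  h <- c(h, NA_real_)           # last point inherits below
  # carry forward over duplicates and onto the final point
  for (i in seq_along(h)) {
    if (is.na(h[i]) && i > 1) h[i] <- h[i - 1]
  }
  trace$heading <- h
  trace
}

#' Compute turn rate by central differences of heading
#'
#' Turn rate at point i is the angle-unwrapped heading change
#' `(heading[i-w] - heading[i+w])` divided by the elapsed time between those
#' samples, in degrees per second. Compass bearing increases clockwise, so
#' this sign convention makes a left turn positive (right-hand rule).
#' Heading differences are taken as minimal angles, so crossing the 0/360
#' wraparound behaves correctly. Points within `half_window` of either end
#' get `NA`.
#'
#' @param trace A trace; headings are computed first if absent.
#' @param half_window Half-width w of the central difference, in samples
#'   (default 1, i.e. +/- 1 s at 1 Hz).
#' @return The trace with a `turn_rate` column added.
#' @export
compute_turn_rate <- function(trace, half_window = 1) {
  w <- as.integer(half_window)
  if (w < 1) stop("half_window must be >= 1", call. = FALSE)
  if (!"heading" %in% names(trace)) trace <- compute_heading(trace)
  n <- nrow(trace)
  tr <- rep(NA_real_, n)
  if (n < 2 * w + 2) {
    warning("trace shorter than 2 * half_window + 2; turn rate undefined ",
            "everywhere", call. = FALSE)
  } else {
    # the last point's heading is inherited, not measured, so the central
    # difference stops at n - w - 1
    i <- (w + 1):(n - w - 1)
    dt <- trace$time[i + w] - trace$time[i - w]
    tr[i] <- angle_diff(trace$heading[i - w], trace$heading[i + w]) / dt
  }
  trace$turn_rate <- tr
  trace
}

#' Compute grade by central differences of elevation
#'
#' Grade at point i is 100 times the elevation change between samples i-w
#' and i+w divided by the horizontal path distance traversed between them
#' (sum of per-step horizontal distances). Positive grade is an incline.
#' The default +/- 2-sample window damps elevation jitter. Points where the
#' window has zero horizontal distance, or within `half_window` of either
#' end, get `NA`.
#'
#' @param trace A trace with `lat`, `lon`, `ele`.
#' @param half_window Half-width of the central difference, in samples
#'   (default 2).
#' @return The trace with a `grade` column added.
#' @export
compute_grade <- function(trace, half_window = 2) {
  w <- as.integer(half_window)
  if (w < 1) stop("half_window must be >= 1", call. = FALSE)
  if (!"ele" %in% names(trace) || all(is.na(trace$ele))) {
    stop("trace has no elevation data", call. = FALSE)
  }
  n <- nrow(trace)
  g <- rep(NA_real_, n)
  if (n >= 2 * w + 1) {
    step <- local_step_enu(trace$lat, trace$lon)
    cumdist <- c(0, cumsum(step$dist))
    i <- (w + 1):(n - w)
    run <- cumdist[i + w] - cumdist[i - w]
    rise <- trace$ele[i + w] - trace$ele[i - w]
    g[i] <- ifelse(run > 0, 100 * rise / run, NA_real_)
  }
  trace$grade <- g
  trace
}

#' Derive flat-and-straight thresholds from a calibration segment
#'
#' Given a trace restricted to ground known to be flat and straight (with
#' `turn_rate` and `grade` already computed), sets the turn-rate cutoff and
#' grade cutoff to the per-criterion upper order statistic of the absolute
#' values at level `1 - (1 - retention_target) / 2` — e.g. the 99.5th
#' percentile of each criterion when targeting 99% joint retention — so
#' that, by the union bound, applying both cutoffs retains at least
#' `retention_target` of the calibration points. The cutoffs are nonzero
#' only because of GNSS jitter: on noiseless data they collapse towards 0.
#'
#' @param calibration A trace (flat/straight points only) carrying
#'   `turn_rate` and `grade`; at least 100 usable points.
#' @param retention_target Joint fraction of calibration points the cutoffs
#'   must retain (default 0.99).
#' @return An object of class `segment_thresholds` with fields
#'   `turn_rate_cutoff` (deg/s), `grade_cutoff` (%), `retention_target`,
#'   `calibration_n`, and the achieved `calibration_retention`.
#' @export
derive_thresholds <- function(calibration, retention_target = 0.99) {
  if (!all(c("turn_rate", "grade") %in% names(calibration))) {
    stop("calibration trace must carry turn_rate and grade; run ",
         "compute_turn_rate() and compute_grade() first", call. = FALSE)
  }
  if (retention_target <= 0 || retention_target >= 1) {
    stop("retention_target must be in (0, 1)", call. = FALSE)
  }
  ok <- is.finite(calibration$turn_rate) & is.finite(calibration$grade)
  tr <- abs(calibration$turn_rate[ok])
  gr <- abs(calibration$grade[ok])
  n <- length(tr)
  if (n < 100) {
    stop("need at least 100 calibration points with defined turn rate and ",
         "grade (got ", n, "); quantiles would be unstable", call. = FALSE)
  }
  level <- 1 - (1 - retention_target) / 2
  # ceiling order statistic guarantees #{|x| <= cutoff} >= level * n exactly
  ord <- min(n, ceiling(level * n))
  turn_cut <- sort(tr)[ord]
  grade_cut <- sort(gr)[ord]
  retention <- mean(tr <= turn_cut & gr <= grade_cut)
  if (retention < retention_target) {
    stop("internal error: derived cutoffs retain ", format(retention),
         " < target ", retention_target, call. = FALSE)
  }
  structure(
    list(turn_rate_cutoff = turn_cut, grade_cutoff = grade_cut,
         retention_target = retention_target, calibration_n = n,
         calibration_retention = retention),
    class = "segment_thresholds"
  )
}

#' @export
print.segment_thresholds <- function(x, ...) {
  cat("Flat-and-straight segmentation thresholds\n")
  cat(sprintf("  |turn rate| <= %.3f deg/s, |grade| <= %.3f %%\n",
              x$turn_rate_cutoff, x$grade_cutoff))
  cat(sprintf("  calibration: n = %d, retained %.2f%% (target %.0f%%)\n",
              x$calibration_n, 100 * x$calibration_retention,
              100 * x$retention_target))
  invisible(x)
}

#' Classify trace points as flat-and-straight
#'
#' A point is flat-and-straight iff both |turn rate| and |grade| are at or
#' below their cutoffs (boundary values retained). Points whose central
#' differences are undefined (trace ends, duplicate positions) are
#' classified not-flat-straight.
#'
#' @param trace A trace with `turn_rate` and `grade` computed.
#' @param thresholds A `segment_thresholds` object from
#'   [derive_thresholds()], or a list with `turn_rate_cutoff` and
#'   `grade_cutoff`.
#' @return Logical vector, one entry per trace point.
#' @export
classify_flat_straight <- function(trace, thresholds) {
  if (!all(c("turn_rate", "grade") %in% names(trace))) {
    stop("trace must carry turn_rate and grade", call. = FALSE)
  }
  ok <- is.finite(trace$turn_rate) & is.finite(trace$grade)
  ok & abs(trace$turn_rate) <= thresholds$turn_rate_cutoff &
    abs(trace$grade) <= thresholds$grade_cutoff
}

#' Label trace points by latitude-longitude bounding boxes
#'
#' Assigns each point the label of the first box (in the order given) whose
#' latitude and longitude ranges contain it; points in no box get `NA`.
#' First-match-wins is the documented tie-break for overlapping boxes.
#'
#' @param trace A trace with `lat`, `lon`.
#' @param boxes A data frame with columns `label`, `lat_min`, `lat_max`,
#'   `lon_min`, `lon_max` (min strictly less than max on both axes).
#' @return The trace with a `box_label` column added.
#' @export
extract_by_bounding_box <- function(trace, boxes) {
  boxes <- as.data.frame(boxes)
  need <- c("label", "lat_min", "lat_max", "lon_min", "lon_max")
  if (!all(need %in% names(boxes))) {
    stop("boxes must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(boxes$lat_min >= boxes$lat_max) ||
      any(boxes$lon_min >= boxes$lon_max)) {
    stop("degenerate bounding box: min must be < max on both axes",
         call. = FALSE)
  }
  label <- rep(NA_character_, nrow(trace))
  for (b in rev(seq_len(nrow(boxes)))) {
    inside <- trace$lat >= boxes$lat_min[b] & trace$lat <= boxes$lat_max[b] &
      trace$lon >= boxes$lon_min[b] & trace$lon <= boxes$lon_max[b]
    label[inside] <- boxes$label[b]   # reversed loop => first match wins
  }
  trace$box_label <- label
  trace
}
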