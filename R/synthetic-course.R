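# Synthetic course geometry and GNSS traces.
#
# A course is an ordered list of segments (flat/straight runs, constant
# radius left/right turns, constant-grade inclines and declines). Traces
# sample the course at 1 Hz at given per-second speeds; the noiseless
# geometry is exact (turns are true circular arcs, ramps have constant
# grade), and GNSS jitter is added as white Gaussian noise per axis.

SEGMENT_KINDS <- c("flat_straight", "left_turn", "right_turn", "incline",
                   "decline")

#' Define a course as an ordered list of segments
#'
#' @param kind Character vector of segment kinds: `flat_straight`,
#'   `left_turn`, `right_turn`, `incline`, `decline`.
#' @param length Segment lengths in metres (horizontal, > 0).
#' @param radius Turn radius in metres (turns only, > 0).
#' @param grade Grade in percent for inclines/declines (sign is implied by
#'   the kind: inclines rise, declines fall); flat segments may carry a
#'   small residual grade, strictly smaller in magnitude than any
#'   incline/decline grade.
#' @return A tibble of class `course_spec`.
#' @export
course_spec <- function(kind, length, radius = NA_real_, grade = 0) {
  bad <- setdiff(kind, SEGMENT_KINDS)
  if (length(bad) > 0) {
    stop("unknown segment kind(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  seg <- tibble::tibble(kind = kind, length = length,
                        radius = rep_len(radius, base::length(kind)),
                        grade = rep_len(grade, base::length(kind)))
  if (any(seg$length <= 0)) stop("segment lengths must be > 0", call. = FALSE)
  turns <- seg$kind %in% c("left_turn", "right_turn")
  if (any(turns & (is.na(seg$radius) | seg$radius <= 0))) {
    stop("turn segments need a positive radius", call. = FALSE)
  }
  ramps <- seg$kind %in% c("incline", "decline")
  if (any(ramps & seg$grade <= 0)) {
    stop("incline/decline segments need a positive grade magnitude",
         call. = FALSE)
  }
  flat_g <- max(abs(seg$grade[seg$kind == "flat_straight"]), 0)
  if (any(ramps) && any(abs(seg$grade[ramps]) <= flat_g)) {
    stop("incline/decline grade magnitude must exceed the flat-segment ",
         "grade magnitude", call. = FALSE)
  }
  class(seg) <- c("course_spec", class(seg))
  seg
}

#' A measured out-and-back style course with all segment kinds
#'
#' Roughly 2.4 km: a long flat/straight calibration stretch, a left and a
#' right 180-degree turn of 15 m radius, and an out-and-back incline/decline
#' at 5.5% grade.
#'
#' @param flat_length Length of the first flat/straight segment in metres.
#' @param ramp_grade Grade of the incline/decline legs in percent.
#' @return A [course_spec()].
#' @export
default_course <- function(flat_length = 600, ramp_grade = 5.5) {
  course_spec(
    kind = c("flat_straight", "left_turn", "flat_straight", "right_turn",
             "incline", "decline", "flat_straight"),
    length = c(flat_length, 15 * pi, 400, 15 * pi, 250, 250, 400),
    radius = c(NA, 15, NA, 15, NA, NA, NA),
    grade = c(0, 0, 0, 0, ramp_grade, ramp_grade, 0)
  )
}

#' A single flat, straight segment (calibration course)
#'
#' @param length Length in metres.
#' @return A [course_spec()].
#' @export
flat_course <- function(length = 2000) {
  course_spec("flat_straight", length)
}

# Walk the exact course geometry: given per-second speeds, return the
# east/north/up coordinates (metres) and segment labels at each 1 Hz
# sample. The course loops if the run outlasts it.
walk_course <- function(course, speeds) {
  n <- length(speeds)
  x <- y <- z <- numeric(n + 1)
  seg_at <- integer(n + 1)
  si <- 1L; pos <- 0; phi <- 0  # compass radians, start heading north
  cx <- 0; cy <- 0; cz <- 0
  seg_at[1] <- si
  nseg <- nrow(course)
  for (t in seq_len(n)) {
    d <- speeds[t]
    while (d > 1e-12) {
      room <- course$length[si] - pos
      dd <- min(d, room)
      kind <- course$kind[si]
      if (kind %in% c("left_turn", "right_turn")) {
        r <- course$radius[si]
        dpsi <- dd / r
        if (kind == "left_turn") {
          # centre on the left (compass heading - 90 deg); motion is CCW in
          # east/north coordinates and compass heading decreases
          ccx <- cx + r * sin(phi - pi / 2)
          ccy <- cy + r * cos(phi - pi / 2)
          dx <- cx - ccx; dy <- cy - ccy
          cx <- ccx + dx * cos(dpsi) - dy * sin(dpsi)
          cy <- ccy + dx * sin(dpsi) + dy * cos(dpsi)
          phi <- phi - dpsi
        } else {
          ccx <- cx + r * sin(phi + pi / 2)
          ccy <- cy + r * cos(phi + pi / 2)
          dx <- cx - ccx; dy <- cy - ccy
          cx <- ccx + dx * cos(-dpsi) - dy * sin(-dpsi)
          cy <- ccy + dx * sin(-dpsi) + dy * cos(-dpsi)
          phi <- phi + dpsi
        }
      } else {
        cx <- cx + dd * sin(phi)
        cy <- cy + dd * cos(phi)
        g <- course$grade[si]
        if (kind == "decline") g <- -g
        cz <- cz + dd * g / 100
      }
      pos <- pos + dd
      d <- d - dd
      if (pos >= course$length[si] - 1e-9) {
        si <- if (si == nseg) 1L else si + 1L
        pos <- 0
      }
    }
    x[t + 1] <- cx; y[t + 1] <- cy; z[t + 1] <- cz
    seg_at[t + 1] <- si
  }
  list(x = x, y = y, z = z,
       segment = course$kind[seg_at], segment_id = seg_at)
}

# Convert east/north displacements (metres) to lat/lon by inverting the
# local equirectangular projection step by step, using the from-point
# latitude in the east scaling — the exact inverse of how headings and
# distances are later recovered from the trace.
enu_to_latlon <- function(x, y, origin) {
  n <- length(x)
  lat <- lon <- numeric(n)
  lat[1] <- origin[1]; lon[1] <- origin[2]
  dn <- diff(y); de <- diff(x)
  for (i in seq_len(n - 1)) {
    lat[i + 1] <- lat[i] + dn[i] / EARTH_RADIUS_M * 180 / pi
    lon[i + 1] <- lon[i] + de[i] /
      (EARTH_RADIUS_M * cos(lat[i] * pi / 180)) * 180 / pi
  }
  list(lat = lat, lon = lon)
}

#' Generate a GNSS trace along a course
#'
#' Samples the course at 1 Hz at the given per-second speeds. The noiseless
#' geometry is exact: turns are constant-radius circular arcs, inclines and
#' declines are constant-grade ramps. GNSS jitter is isotropic white
#' Gaussian on the horizontal position and independent Gaussian on
#' elevation. Every point carries its ground-truth segment label. The
#' course loops if the run is longer than the course.
#'
#' @param course A [course_spec()].
#' @param speeds Numeric vector of per-second speeds (m/s); one trace point
#'   is emitted per second plus the starting point.
#' @param jitter_sd Horizontal GNSS jitter standard deviation in metres per
#'   axis (default 0.1; >= 0).
#' @param ele_jitter_sd Elevation jitter standard deviation in metres
#'   (default 0.08).
#' @param seed Integer seed for the jitter draw.
#' @param origin Latitude/longitude of the starting point.
#' @param start_time Epoch seconds of the first sample.
#' @return A tibble with columns `time`, `lat`, `lon`, `ele`, `segment`,
#'   `segment_id`.
#' @export
generate_course_trace <- function(course, speeds, jitter_sd = 0.1,
                                  ele_jitter_sd = 0.08, seed = 1,
                                  origin = c(40.0, -86.0),
                                  start_time = 1.7e9) {
  if (jitter_sd < 0 || ele_jitter_sd < 0) {
    stop("jitter standard deviations must be >= 0", call. = FALSE)
  }
  path <- walk_course(course, speeds)
  n <- length(path$x)
  jit <- with_seed(seed, list(
    x = stats::rnorm(n, 0, jitter_sd),
    y = stats::rnorm(n, 0, jitter_sd),
    z = stats::rnorm(n, 0, ele_jitter_sd)
  ))
  ll <- enu_to_latlon(path$x + jit$x, path$y + jit$y, origin)
  tibble::tibble(
    time = start_time + seq_len(n) - 1,
    lat = ll$lat, lon = ll$lon,
    ele = path$z + jit$z + 200,   # arbitrary base elevation
    segment = path$segment, segment_id = path$segment_id
  )
}
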