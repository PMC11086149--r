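# Synthetic runs: in-lab treadmill speed-ladder sessions, measured-course
# runs and free-living real-world runs, with per-second gait records drawn
# from the subject's multivariate Gaussian conditioned on speed.

#' Specify a run protocol
#'
#' Three conditions are supported. `in_lab`: a treadmill session of
#' `n_trials` constant-speed trials spanning 30% slower to 25% faster than
#' the subject's preferred speed, presented slowest-two first, randomised
#' middle block, fastest-two last, with belt-speed ramps (and lagging
#' device metrics) contaminating the first 25 s and last 15 s of each
#' trial. `measured_course` and `real_world`: outdoor runs whose pace is an
#' AR(1) process around the preferred speed, carrying a 1 Hz GNSS trace;
#' real-world runs additionally contain walking bouts and receive the
#' distributional shift.
#'
#' @param condition One of `in_lab`, `measured_course`, `real_world`.
#' @param duration Run duration in seconds. Defaults: 2280 s (38 min)
#'   in-lab, 800 s measured course, 2400 s real-world.
#' @param n_trials Number of treadmill trials (in-lab only, default 12).
#' @param speed_range Trial-speed multipliers of preferred speed (default
#'   `c(0.70, 1.25)`, i.e. -30% to +25%).
#' @param walking_fraction Fraction of seconds spent walking/standing
#'   (default 0.06 for real-world runs, matching the exclusion rate the
#'   walking filter is expected to produce; 0 otherwise).
#' @param gnss_jitter_sd Horizontal GNSS jitter sd in metres (default 0.1).
#' @param ele_jitter_sd Elevation jitter sd in metres (default 0.08).
#' @param pace_phi AR(1) coefficient of the outdoor pace process
#'   (default 0.97).
#' @param pace_sd Stationary standard deviation of the outdoor pace
#'   process, m/s (default 0.4: free-living pace drifts with terrain,
#'   fatigue and workout type, spanning more than the second-to-second
#'   gait variation at a fixed pace).
#' @param metric_phi AR(1) coefficient of the within-run gait-metric
#'   residuals (default 0.3).
#' @return An object of class `run_spec`.
#' @export
run_spec <- function(condition = c("in_lab", "measured_course", "real_world"),
                     duration = NULL, n_trials = 12,
                     speed_range = c(0.70, 1.25),
                     walking_fraction = NULL,
                     gnss_jitter_sd = 0.1, ele_jitter_sd = 0.08,
                     pace_phi = 0.97, pace_sd = 0.4, metric_phi = 0.3) {
  condition <- match.arg(condition)
  if (is.null(duration)) {
    duration <- switch(condition, in_lab = 2280, measured_course = 800,
                       real_world = 2400)
  }
  if (is.null(walking_fraction)) {
    walking_fraction <- if (condition == "real_world") 0.06 else 0
  }
  structure(
    list(condition = condition, duration = as.integer(duration),
         n_trials = n_trials, speed_range = speed_range,
         walking_fraction = walking_fraction,
         gnss_jitter_sd = gnss_jitter_sd, ele_jitter_sd = ele_jitter_sd,
         pace_phi = pace_phi, pace_sd = pace_sd, metric_phi = metric_phi),
    class = "run_spec"
  )
}

# centred running mean with shrinking window at the edges
running_mean <- function(x, width) {
  half <- floor(width / 2)
  n <- length(x)
  out <- numeric(n)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# one-sided (trailing) running mean emulating device lag
trailing_mean <- function(x, width) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - width + 1, 1)
  (cs[seq_len(n) + 1] - cs[lo]) / (seq_len(n) - lo + 1)
}

# In-lab belt-speed series and trial boundaries for a subject.
in_lab_speed_series <- function(subject, spec) {
  k <- spec$n_trials
  targets <- subject$preferred_speed *
    seq(spec$speed_range[1], spec$speed_range[2], length.out = k)
  ord <- c(1, 2, sample(3:(k - 2)), k - 1, k)
  targets <- targets[ord]
  trial_dur <- spec$duration %/% k
  start0 <- 0
  boundaries <- tibble::tibble(
    trial = seq_len(k),
    start = start0 + (seq_len(k) - 1) * trial_dur,
    end = start0 + seq_len(k) * trial_dur,
    target_speed = targets
  )
  target_series <- rep(targets, each = trial_dur)
  # belt speed ramps gradually across trial changes (+/- 8 s), and the
  # device speed lags the belt by a trailing 8 s average
  belt <- running_mean(target_series, 17)
  device <- trailing_mean(belt, 8)
  list(speed = device, boundaries = boundaries)
}

# AR(1) pace process around preferred speed with stationary sd spec$pace_sd.
outdoor_speed_series <- function(subject, spec) {
  sigma <- spec$pace_sd
  n <- spec$duration
  phi <- spec$pace_phi
  s <- numeric(n)
  s[1] <- stats::rnorm(1, subject$preferred_speed, sigma)
  innov_sd <- sigma * sqrt(1 - phi^2)
  eps <- stats::rnorm(n - 1, 0, innov_sd)
  for (t in 2:n) {
    s[t] <- subject$preferred_speed + phi * (s[t - 1] - subject$preferred_speed) +
      eps[t - 1]
  }
  pmax(s, 0.5)
}

#' Generate one run for a subject
#'
#' Draws per-second gait records from the subject's multivariate Gaussian
#' conditioned on the speed series of the protocol: the treadmill speed
#' ladder for in-lab runs, an AR(1) pace process outdoors. The
#' distributional shift is applied only in the `real_world` condition.
#' Cadence is derived as `60 * speed / step_length` (strides/min). Walking
#' bouts (speed below the running threshold) are inserted at the requested
#' fraction. Rows where truncation produced a nonpositive metric are
#' redrawn and counted; a redraw rate above 1% triggers a warning.
#' Outdoor runs carry a 1 Hz GNSS trace along the supplied course; in-lab
#' runs carry none.
#'
#' @param subject A [subject_params()] object.
#' @param spec A [run_spec()].
#' @param shift A [shift_spec()]; applied only when the condition is
#'   `real_world`. Defaults to the zero shift.
#' @param course A [course_spec()]; required for conditions that carry a
#'   GNSS trace.
#' @param seed Integer seed; fixed seed reproduces the run bitwise.
#' @param start_time Epoch seconds of the first record.
#' @return A list with elements `records` (tibble of per-second gait
#'   records), `trace` (tibble or NULL), `trial_boundaries` (in-lab only),
#'   and `log` (redraw counts and seed).
#' @export
generate_run <- function(subject, spec, shift = shift_spec(), course = NULL,
                         seed = 1, start_time = 1.7e9) {
  stopifnot(inherits(subject, "subject_params"), inherits(spec, "run_spec"))
  needs_trace <- spec$condition != "in_lab"
  if (needs_trace && is.null(course)) {
    stop("a course is required for runs that carry a GNSS trace",
         call. = FALSE)
  }
  dist <- if (spec$condition == "real_world") {
    apply_shift(subject, shift)
  } else {
    list(mean = subject$mean_vector, covariance = subject$covariance)
  }
  mu <- dist$mean; sigma <- dist$covariance

  with_seed(seed, {
    boundaries <- NULL
    if (spec$condition == "in_lab") {
      lad <- in_lab_speed_series(subject, spec)
      speed <- lad$speed
      boundaries <- lad$boundaries
      boundaries$start <- boundaries$start + start_time
      boundaries$end <- boundaries$end + start_time
    } else {
      speed <- outdoor_speed_series(subject, spec)
    }
    n <- length(speed)

    walking <- rep(FALSE, n)
    n_walk <- round(spec$walking_fraction * n)
    while (sum(walking) < n_walk) {
      len <- min(stats::rgeom(1, 1 / 20) + 5, n_walk - sum(walking) + 5)
      at <- sample.int(n - len + 1, 1)
      walking[at:(at + len - 1)] <- TRUE
    }
    speed[walking] <- stats::runif(sum(walking), 0.9, 1.4)

    # conditional distribution of the other four metrics given speed
    beta <- sigma[2:5, 1] / sigma[1, 1]
    cond_cov <- sigma[2:5, 2:5] - tcrossprod(beta) * sigma[1, 1]
    cond_cov <- (cond_cov + t(cond_cov)) / 2
    ch <- chol(cond_cov + diag(1e-12, 4))
    phi <- spec$metric_phi
    innov <- matrix(stats::rnorm(n * 4), n, 4) %*% ch
    eta <- matrix(0, n, 4)
    eta[1, ] <- innov[1, ]
    if (n > 1) {
      scl <- sqrt(1 - phi^2)
      for (t in 2:n) eta[t, ] <- phi * eta[t - 1, ] + scl * innov[t, ]
    }
    cond_mean <- matrix(mu[2:5], n, 4, byrow = TRUE) +
      outer(speed - mu[1], beta)
    metrics <- cond_mean + eta

    # measurement noise on recorded speed
    rec_speed <- speed + stats::rnorm(n, 0, 0.02)

    # walking rows: plausible walking gait, guaranteed below thresholds
    if (any(walking)) {
      nw <- sum(walking)
      rec_speed[walking] <- speed[walking]
      metrics[walking, 1] <- stats::runif(nw, 0.60, 0.75)  # step length
      metrics[walking, 2] <- stats::runif(nw, 0.02, 0.04)  # vert osc
      metrics[walking, 3] <- stats::runif(nw, 0.55, 0.70)  # stance
      metrics[walking, 4] <- stats::runif(nw, 5, 8)        # stiffness
    }

    # truncation: redraw rows with nonpositive metrics
    n_redraw <- 0L
    bad <- which(rec_speed <= 0 | apply(metrics, 1, function(r) any(r <= 0)))
    for (i in bad) {
      for (try in 1:50) {
        cand <- cond_mean[i, ] + drop(stats::rnorm(4) %*% ch)
        if (all(cand > 0)) { metrics[i, ] <- cand; break }
      }
      rec_speed[i] <- max(rec_speed[i], 0.05)
      n_redraw <- n_redraw + 1L
    }
    redraw_rate <- n_redraw / n
    if (redraw_rate > 0.01) {
      warning(sprintf("%.1f%% of records hit the positivity truncation and ",
                      100 * redraw_rate), "were redrawn", call. = FALSE)
    }

    records <- tibble::tibble(
      timestamp = start_time + seq_len(n) - 1,
      speed = rec_speed,
      step_length = metrics[, 1],
      vertical_oscillation = metrics[, 2],
      stance_time = metrics[, 3],
      leg_stiffness = metrics[, 4],
      cadence = 60 * rec_speed / metrics[, 1]
    )

    trace <- NULL
    if (needs_trace) {
      trace <- generate_course_trace(
        course, speed, jitter_sd = spec$gnss_jitter_sd,
        ele_jitter_sd = spec$ele_jitter_sd,
        seed = derive_seed(seed, 7), start_time = start_time
      )
      trace <- trace[seq_len(n), ]   # one point per record second
    }

    list(records = records, trace = trace, trial_boundaries = boundaries,
         log = list(seed = seed, condition = spec$condition,
                    n_records = n, n_redrawn = n_redraw,
                    redraw_rate = redraw_rate))
  })
}
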