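# Internal helpers shared across modules.

#' Names of the five gait-pattern metrics
#'
#' The gait pattern is the joint, per-second observation of running speed,
#' step length, vertical oscillation, stance (ground contact) time, and leg
#' stiffness. Cadence (strides/min) is carried alongside but is derived from
#' speed and step length.
#'
#' @return Character vector of the five metric column names.
#' @export
gait_metrics <- function() {
  c("speed", "step_length", "vertical_oscillation", "stance_time",
    "leg_stiffness")
}

# Walking-exclusion thresholds: records slower than 1.56 m/s or below
# 100 strides/min are treated as standing/walking, not running.
WALK_SPEED_MS <- 1.56
WALK_CADENCE_SPM <- 100

# Mean Earth radius, metres.
EARTH_RADIUS_M <- 6371008.8

# Derive a stage-scoped substream seed from a master seed. Keeps results
# < 2^31 so they remain valid R integer seeds.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 1013 * k) %% 2147483647)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# Signed minimal angular difference a - b, wrapped to (-180, 180].
angle_diff <- function(a, b) {
  d <- (a - b + 180) %% 360 - 180
  # map -180 to +180 so the convention is symmetric under argument swap
  ifelse(d == -180, 180, d)
}

# Assert a symmetric positive-semidefinite matrix (up to numerical slack).
check_psd <- function(m, what = "covariance") {
  if (!isSymmetric(unname(m), tol = 1e-8)) {
    stop(what, " matrix must be symmetric", call. = FALSE)
  }
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop(what, " matrix is not positive semidefinite (smallest eigenvalue ",
         format(min(ev)), ")", call. = FALSE)
  }
  invisible(m)
}
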