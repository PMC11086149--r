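# Shared fixtures: small clouds, traces and runs built in code.

# n draws from a K-dim Gaussian with the package's default within-subject
# covariance (K = 5) or a 2-D slice of it.
gauss_cloud <- function(n, k = 5, seed = 1, mean = rep(0, k)) {
  sigma <- default_population()$within_cov[1:k, 1:k, drop = FALSE]
  set.seed(seed)
  m <- MASS::mvrnorm(n, mean, sigma)
  colnames(m) <- gait_metrics()[1:k]
  m
}

# straight 1 Hz trace heading due north at `speed` m/s
straight_trace <- function(n = 50, speed = 3, lat0 = 40, lon0 = -86,
                           ele = 200) {
  dlat <- speed / 6371008.8 * 180 / pi
  tibble::tibble(time = seq_len(n), lat = lat0 + (seq_len(n) - 1) * dlat,
                 lon = lon0, ele = ele)
}

# minimal valid gait-record tibble
make_records <- function(n = 10, speed = 3, cadence = 170, t0 = 0) {
  tibble::tibble(
    timestamp = t0 + seq_len(n) - 1,
    speed = rep_len(speed, n), step_length = 1,
    vertical_oscillation = 0.09, stance_time = 0.25, leg_stiffness = 10,
    cadence = rep_len(cadence, n)
  )
}

# independent brute-force Tukey depth oracle in 2-D: dense sweep over
# half-plane normal angles (plus data-driven critical angles)
brute_depth_2d <- function(point, reference, n_angles = 20000) {
  d <- sweep(as.matrix(reference), 2, as.numeric(point))
  keep <- rowSums(d^2) > 1e-24
  n0 <- sum(!keep)
  n <- nrow(d)
  if (n0 == n) return(0.5)
  dd <- d[keep, , drop = FALSE]
  ang <- c(seq(0, 2 * pi, length.out = n_angles),
           atan2(dd[, 2], dd[, 1]) + pi / 2,
           atan2(dd[, 2], dd[, 1]) - pi / 2)
  u <- cbind(cos(ang), sin(ang))
  counts <- colSums(dd %*% t(u) >= 0)
  min((min(counts) + n0) / n, 0.5)
}
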