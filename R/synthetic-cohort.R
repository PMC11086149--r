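# Synthetic cohorts of runners.
#
# Each subject is summarised by a 5-vector of gait-metric means (speed m/s,
# step length m, vertical oscillation m, stance time s, leg stiffness kN/m)
# and a 5x5 within-subject covariance describing second-to-second variation
# of the joint gait pattern. Between-subject variation is itself
# multivariate Gaussian around population means.

# Correlation structure of the gait pattern: speed is coupled positively to
# step length (runners change speed mainly through step length) and leg
# stiffness, and negatively to ground contact time.
gait_correlation <- function() {
  r <- matrix(c(
    1.00,  0.85,  0.25, -0.65,  0.25,
    0.85,  1.00,  0.30, -0.55,  0.15,
    0.25,  0.30,  1.00, -0.10, -0.35,
   -0.65, -0.55, -0.10,  1.00, -0.45,
    0.25,  0.15, -0.35, -0.45,  1.00), 5, 5)
  dimnames(r) <- list(gait_metrics(), gait_metrics())
  r
}

corr_to_cov <- function(corr, sd) {
  v <- diag(sd) %*% corr %*% diag(sd)
  dimnames(v) <- dimnames(corr)
  v
}

#' Default population distribution for synthetic cohorts
#'
#' Population means and spreads chosen to be typical of adult recreational
#' runners: mean speed 3.0 m/s, step length 1.0 m, vertical oscillation
#' 0.09 m, stance time 0.25 s, leg stiffness 10 kN/m. Between-subject and
#' within-subject variation share the same correlation structure, with a
#' strong positive speed-step-length coupling (r = 0.85).
#'
#' @return A list with `mean`, `between_cov` (between-subject covariance of
#'   subject means) and `within_cov` (within-subject per-second covariance,
#'   shared across subjects).
#' @export
default_population <- function() {
  mu <- c(speed = 3.0, step_length = 1.0, vertical_oscillation = 0.09,
          stance_time = 0.25, leg_stiffness = 10.0)
  between_sd <- c(0.40, 0.08, 0.012, 0.020, 1.5)
  within_sd <- c(0.25, 0.05, 0.006, 0.012, 0.8)
  list(mean = mu,
       between_cov = corr_to_cov(gait_correlation(), between_sd),
       within_cov = corr_to_cov(gait_correlation(), within_sd))
}

#' Construct subject-level gait parameters
#'
#' @param subject_id Identifier.
#' @param mean_vector Named 5-vector of metric means (strictly positive).
#' @param covariance 5x5 symmetric positive-semidefinite within-subject
#'   covariance; the speed-step-length entry must be strictly positive.
#' @param preferred_speed Preferred running speed in m/s; defaults to the
#'   mean speed.
#' @return An object of class `subject_params`.
#' @export
subject_params <- function(subject_id, mean_vector, covariance,
                           preferred_speed = mean_vector[["speed"]]) {
  mean_vector <- mean_vector[gait_metrics()]
  if (anyNA(mean_vector) || any(mean_vector <= 0)) {
    stop("all metric means must be strictly positive", call. = FALSE)
  }
  check_psd(covariance, "within-subject covariance")
  if (covariance[1, 2] <= 0) {
    stop("speed-step-length covariance must be strictly positive",
         call. = FALSE)
  }
  structure(
    list(subject_id = subject_id, mean_vector = mean_vector,
         covariance = covariance, preferred_speed = preferred_speed),
    class = "subject_params"
  )
}

#' Generate a synthetic cohort of runners
#'
#' Draws subject mean vectors from the population's multivariate Gaussian
#' (rejecting the vanishingly rare draws with nonpositive means), assigns
#' every subject the population within-subject covariance, and sets the
#' preferred speed to the subject's mean speed.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param population A population distribution as from
#'   [default_population()].
#' @param seed Integer seed; fixed seed gives an identical cohort.
#' @param id_prefix Prefix for subject identifiers.
#' @return A list of [subject_params()] objects.
#' @export
generate_cohort <- function(n_subjects, population = default_population(),
                            seed = 1, id_prefix = "S") {
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  check_psd(population$between_cov, "between-subject covariance")
  check_psd(population$within_cov, "within-subject covariance")
  with_seed(seed, {
    lapply(seq_len(n_subjects), function(i) {
      repeat {
        mu <- drop(MASS::mvrnorm(1, population$mean, population$between_cov))
        if (all(mu > 0)) break
      }
      names(mu) <- gait_metrics()
      subject_params(sprintf("%s%03d", id_prefix, i), mu,
                     population$within_cov)
    })
  })
}

#' Specify a distributional shift between in-lab and real-world gait
#'
#' A shift has three components, all applied only in the real-world
#' condition: a mean shift added to the metric means, an elementwise scale
#' applied to the within-subject covariance, and a correlation rotation
#' t in [0, 1] that remaps every correlation involving step length — most
#' importantly the speed-step-length coupling r — to (1 - 2t) r: t = 0
#' leaves the coupling untouched, t = 1 reverses it, and every marginal
#' stays unchanged (the rotated covariance is a convex combination of the
#' original and its reflection through the step-length axis, hence always
#' positive semidefinite). The zero shift
#' (defaults) makes real-world gait identical in distribution to in-lab
#' gait.
#'
#' @param mean_shift Named numeric vector (any subset of the five metrics)
#'   or full 5-vector added to the means.
#' @param covariance_scale 5x5 matrix of elementwise variance multipliers,
#'   or a single scalar.
#' @param correlation_rotation Scalar in [0, 1].
#' @return An object of class `shift_spec`.
#' @export
shift_spec <- function(mean_shift = numeric(0), covariance_scale = 1,
                       correlation_rotation = 0) {
  ms <- stats::setNames(rep(0, 5), gait_metrics())
  if (length(mean_shift) > 0) {
    if (is.null(names(mean_shift))) {
      if (length(mean_shift) != 5) {
        stop("unnamed mean_shift must have length 5", call. = FALSE)
      }
      ms[] <- mean_shift
    } else {
      bad <- setdiff(names(mean_shift), gait_metrics())
      if (length(bad) > 0) {
        stop("unknown metric(s) in mean_shift: ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      ms[names(mean_shift)] <- mean_shift
    }
  }
  if (length(covariance_scale) == 1) {
    covariance_scale <- matrix(covariance_scale, 5, 5)
  }
  if (any(covariance_scale <= 0)) {
    stop("covariance_scale entries must be positive", call. = FALSE)
  }
  if (correlation_rotation < 0 || correlation_rotation > 1) {
    stop("correlation_rotation must be in [0, 1]", call. = FALSE)
  }
  structure(list(mean_shift = ms, covariance_scale = covariance_scale,
                 correlation_rotation = correlation_rotation),
            class = "shift_spec")
}

is_zero_shift <- function(shift) {
  all(shift$mean_shift == 0) && all(shift$covariance_scale == 1) &&
    shift$correlation_rotation == 0
}

# Apply a shift_spec to a subject's (mean, covariance), returning the
# shifted pair. The correlation rotation interpolates between the original
# covariance and its image under reflection of the step-length axis,
# Sigma(t) = (1 - t) Sigma + t F Sigma F with F = diag(1, -1, 1, 1, 1):
# a convex combination of PSD matrices (hence always PSD) that leaves
# every marginal untouched while mapping each correlation involving step
# length to (1 - 2t) times its original value. The elementwise covariance
# scale can in principle leave the PSD cone; that case is projected back
# with Matrix::nearPD (keeping variances).
apply_shift <- function(subject, shift) {
  mu <- subject$mean_vector + shift$mean_shift
  sigma <- subject$covariance * shift$covariance_scale
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(ev)) {
    sigma <- as.matrix(Matrix::nearPD(sigma, keepDiag = TRUE)$mat)
    dimnames(sigma) <- dimnames(subject$covariance)
  }
  t <- shift$correlation_rotation
  if (t > 0) {
    f <- c(1, -1, 1, 1, 1)
    reflected <- sigma * tcrossprod(f)
    sigma <- (1 - t) * sigma + t * reflected
  }
  list(mean = mu, covariance = sigma)
}
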