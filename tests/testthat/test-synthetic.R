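# Synthetic cohorts, shifts and run generation.

test_that("cohort generation honours counts, invariants and determinism", {
  coh <- generate_cohort(49, seed = 1)
  expect_length(coh, 49)
  for (s in coh[c(1, 25, 49)]) {
    expect_true(all(s$mean_vector > 0))
    expect_gt(s$covariance[1, 2], 0)   # speed-step-length coupling
    ev <- eigen(s$covariance, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
  }
  expect_identical(generate_cohort(5, seed = 3), generate_cohort(5, seed = 3))
  expect_false(identical(generate_cohort(5, seed = 3),
                         generate_cohort(5, seed = 4)))
})

test_that("zero between-subject variance collapses subjects onto the population mean", {
  pop <- default_population()
  pop$between_cov <- matrix(0, 5, 5)
  coh <- generate_cohort(3, pop, seed = 9)
  for (s in coh) expect_equal(unname(s$mean_vector), unname(pop$mean))
})

test_that("cohort means concentrate around the population mean (law of large numbers)", {
  pop <- default_population()
  coh <- generate_cohort(200, pop, seed = 5)
  means <- t(vapply(coh, `[[`, numeric(5), "mean_vector"))
  se <- sqrt(diag(pop$between_cov) / 200)
  expect_true(all(abs(colMeans(means) - pop$mean) < 3.5 * se))
})

test_that("non-PSD population covariance is rejected with a clear message", {
  pop <- default_population()
  pop$between_cov[1, 2] <- pop$between_cov[2, 1] <- 10   # breaks PSD
  expect_error(generate_cohort(2, pop), "positive semidefinite")
})

test_that("the zero shift leaves a subject's distribution untouched", {
  s <- generate_cohort(1, seed = 2)[[1]]
  out <- gaitoverlap:::apply_shift(s, shift_spec())
  expect_identical(out$mean, s$mean_vector)
  expect_identical(out$covariance, s$covariance)
})

test_that("correlation rotation reverses the speed-step coupling but keeps marginals", {
  s <- generate_cohort(1, seed = 2)[[1]]
  full <- gaitoverlap:::apply_shift(s, shift_spec(correlation_rotation = 1))
  expect_identical(diag(full$covariance), diag(s$covariance))
  expect_equal(full$covariance[1, 2], -s$covariance[1, 2])
  half <- gaitoverlap:::apply_shift(s, shift_spec(correlation_rotation = 0.5))
  expect_equal(half$covariance[1, 2], 0)
  ev <- eigen(full$covariance, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
  expect_error(shift_spec(correlation_rotation = 1.2), "0, 1")
})

test_that("in-lab runs reproduce the 12-speed ladder after trimming", {
  s <- generate_cohort(1, seed = 4)[[1]]
  run <- generate_run(s, run_spec("in_lab"), seed = 11)
  expect_null(run$trace)
  b <- run$trial_boundaries
  expect_equal(nrow(b), 12)
  expect_equal(sort(b$target_speed),
               s$preferred_speed * seq(0.70, 1.25, length.out = 12))
  # slowest two first, fastest two last
  expect_equal(rank(b$target_speed)[c(1, 2, 11, 12)], c(1, 2, 11, 12))
  trimmed <- trim_treadmill_trial(run$records, b)
  for (i in c(1, 6, 12)) {
    in_trial <- trimmed$timestamp >= b$start[i] & trimmed$timestamp < b$end[i]
    expect_lt(abs(mean(trimmed$speed[in_trial]) - b$target_speed[i]), 0.03)
  }
})

test_that("run generation is bitwise reproducible under a fixed seed", {
  s <- generate_cohort(1, seed = 4)[[1]]
  r1 <- generate_run(s, run_spec("real_world", duration = 300),
                     course = default_course(), seed = 21)
  r2 <- generate_run(s, run_spec("real_world", duration = 300),
                     course = default_course(), seed = 21)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$trace, r2$trace)
})

test_that("zero-shift real-world records match in-lab records at matched speeds", {
  s <- generate_cohort(1, seed = 6)[[1]]
  lab <- generate_run(s, run_spec("in_lab"), seed = 31)
  ref <- trim_treadmill_trial(lab$records, lab$trial_boundaries)
  rw <- generate_run(s, run_spec("real_world", duration = 2400),
                     course = default_course(), seed = 32)
  new <- exclude_walking(rw$records)$records
  # compare step length residuals around the shared speed model in a
  # narrow speed band near preferred speed
  band <- function(df) df[abs(df$speed - s$preferred_speed) < 0.1, ]
  a <- band(ref); b <- band(new)
  p <- t.test(a$step_length, b$step_length)$p.value
  expect_gt(p, 0.001)
})

test_that("a large leg-stiffness mean shift collapses its univariate overlap as predicted", {
  s <- generate_cohort(1, seed = 7)[[1]]
  within_sd <- sqrt(s$covariance[5, 5])
  sh <- shift_spec(mean_shift = c(leg_stiffness = 2 * within_sd))
  lab <- generate_run(s, run_spec("in_lab"), seed = 41)
  ref <- trim_treadmill_trial(lab$records, lab$trial_boundaries)
  rw <- generate_run(s, run_spec("real_world", duration = 2400), shift = sh,
                     course = default_course(), seed = 42)
  new <- exclude_walking(rw$records)$records
  ov <- univariate_overlap(ref$leg_stiffness, new$leg_stiffness)
  # independent oracle: Gaussian coverage of the reference central interval
  # by the shifted marginal, using the design's actual marginal moments
  beta <- s$covariance[5, 1] / s$covariance[1, 1]
  ref_sd <- sqrt(beta^2 * var(ref$speed) + s$covariance[5, 5] -
                   beta^2 * s$covariance[1, 1])
  new_sd <- sqrt(beta^2 * var(new$speed) + s$covariance[5, 5] -
                   beta^2 * s$covariance[1, 1])
  shift_sds <- 2 * within_sd / new_sd
  predicted <- pnorm((1.96 * ref_sd / new_sd) - shift_sds) -
    pnorm((-1.96 * ref_sd / new_sd) - shift_sds)
  expect_lt(abs(ov - predicted), 0.07)
  expect_lt(ov, 0.65)   # far below the 0.95 null
})

test_that("univariate overlap is monotone non-increasing in mean-shift magnitude", {
  s <- generate_cohort(1, seed = 8)[[1]]
  lab <- generate_run(s, run_spec("in_lab"), seed = 51)
  ref <- trim_treadmill_trial(lab$records, lab$trial_boundaries)
  within_sd <- sqrt(s$covariance[5, 5])
  ov <- vapply(c(0, 1, 2, 4), function(k) {
    rw <- generate_run(s, run_spec("real_world", duration = 1500),
                       shift = shift_spec(mean_shift = c(leg_stiffness = k * within_sd)),
                       course = default_course(), seed = 52)
    univariate_overlap(ref$leg_stiffness,
                       exclude_walking(rw$records)$records$leg_stiffness)
  }, numeric(1))
  expect_true(all(diff(ov) <= 0.02))   # allow tiny Monte-Carlo wiggle
  expect_lt(ov[4], 0.10)
})

test_that("walking bouts are inserted below the running thresholds", {
  s <- generate_cohort(1, seed = 9)[[1]]
  rw <- generate_run(s, run_spec("real_world", duration = 1000,
                                 walking_fraction = 0.1),
                     course = default_course(), seed = 61)
  ex <- exclude_walking(rw$records)
  expect_gte(ex$report$n_excluded_walking, 0.08 * 1000)
  expect_true(all(ex$records$speed >= 1.56))
  # cadence is derived from speed and step length
  expect_equal(rw$records$cadence,
               60 * rw$records$speed / rw$records$step_length)
})

test_that("runs with a trace require a course and produce aligned 1 Hz traces", {
  s <- generate_cohort(1, seed = 10)[[1]]
  expect_error(generate_run(s, run_spec("real_world")), "course")
  rw <- generate_run(s, run_spec("measured_course", duration = 200),
                     course = default_course(), seed = 71)
  expect_equal(nrow(rw$trace), nrow(rw$records))
  expect_equal(rw$trace$time, rw$records$timestamp)
})

test_that("course specs validate their geometry", {
  expect_error(course_spec("left_turn", 100), "radius")
  expect_error(course_spec("flat_straight", -5), "> 0")
  expect_error(course_spec("incline", 100, grade = 0), "positive grade")
  expect_error(course_spec(c("flat_straight", "incline"), c(100, 100),
                           grade = c(3, 2)), "exceed")
  expect_error(course_spec("sideways", 10), "unknown segment kind")
})
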