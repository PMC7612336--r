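# Synthetic head-kinematics generator: pulse construction, peak extraction,
# cohort assembly, calibration.

test_that("peak_resultant matches a brute-force norm scan", {
  # constant (3, 4, 0) acceleration: resultant norm 5
  n <- 101
  tr <- kinematics_trace(seq(0, 0.005, length.out = n),
                         cbind(rep(3, n), rep(4, n), 0),
                         matrix(0, n, 3))
  expect_equal(peak_resultant(tr)$peak_lin_acc, 5)

  # all-zero trace: all peaks zero
  tr0 <- kinematics_trace(seq(0, 0.005, length.out = n),
                          matrix(0, n, 3), matrix(0, n, 3))
  expect_true(all(unlist(peak_resultant(tr0)) == 0))

  # random 200-sample trace equals an explicit loop over samples
  set.seed(5)
  la <- matrix(rnorm(600), 200, 3)
  ra <- matrix(rnorm(600), 200, 3)
  tr <- kinematics_trace(seq(0, 0.01, length.out = 200), la, ra)
  brute <- function(m) {
    best <- 0
    for (i in seq_len(nrow(m))) best <- max(best, sqrt(sum(m[i, ]^2)))
    best
  }
  pk <- peak_resultant(tr)
  expect_equal(pk$peak_lin_acc, brute(la))
  expect_equal(pk$peak_rot_acc, brute(ra))
  expect_equal(pk$peak_lin_vel,
               brute(as.matrix(tr[, c("vx", "vy", "vz")])))
  expect_error(peak_resultant(tr[0, ]), "non-empty")
})

test_that("velocities are trapezoidal integrals of accelerations from rest", {
  t <- seq(0, 0.02, 1e-4)
  a <- cbind(sin(200 * t), cos(150 * t), t)
  tr <- kinematics_trace(t, a, a)
  expect_equal(tr$vx[1], 0)
  v_ref <- cumsum(c(0, diff(t) * (a[-1, 1] + a[-nrow(a), 1]) / 2))
  expect_equal(tr$vx, v_ref)
  expect_equal(tr$wy, tr$vy)  # identical input series integrate identically
})

test_that("zero-dispersion pulse realises the spec means and the half-sine integral", {
  spec <- delta_spec()
  ev <- generate_impact_pulse(spec, 1)
  # drawn peak linear velocity is exactly the profile mean (within integration
  # tolerance of the trapezoid rule on the half-sine)
  expect_equal(ev$summary$peak_lin_vel, 3.9, tolerance = 1e-5)
  expect_equal(ev$summary$peak_rot_vel, 25, tolerance = 1e-5)
  expect_equal(ev$summary$peak_rot_acc, 3000, tolerance = 1e-4)
  # half-sine closed form: peak velocity = 2 A T / pi
  expect_equal(ev$summary$peak_lin_vel,
               2 * ev$summary$peak_lin_acc * ev$pulse_duration / pi,
               tolerance = 1e-5)
  expect_equal(ev$summary$peak_rot_vel,
               2 * ev$summary$peak_rot_acc * ev$pulse_duration / pi,
               tolerance = 1e-5)
  # velocity class from the collision ladder
  expect_equal(ev$velocity_class, "low")
})

test_that("same spec and seed give identical traces", {
  spec <- default_profile_specs()[[1]]
  e1 <- generate_impact_pulse(spec, 77)
  e2 <- generate_impact_pulse(spec, 77)
  expect_identical(e1$trace, e2$trace)
  expect_identical(e1$summary, e2$summary)
  e3 <- generate_impact_pulse(spec, 78)
  expect_false(identical(e1$trace, e3$trace))
})

test_that("cohort assembly respects counts and degenerate specs", {
  specs <- default_profile_specs()
  co <- generate_cohort(specs, 9)
  expect_length(co, 148)
  man <- cohort_manifest(co)
  expect_equal(as.integer(table(man$profile)), c(49L, 69L, 30L))

  # n_impacts = 0 contributes nothing
  specs0 <- default_profile_specs(n_impacts = c(0L, 2L, 0L))
  expect_length(generate_cohort(specs0, 9), 2)
  expect_error(generate_cohort(list(), 9), "non-empty")

  # zero dispersion: identical summaries within a profile
  sd0 <- list(delta_spec(n = 3L))
  man0 <- cohort_manifest(generate_cohort(sd0, 4))
  expect_equal(man0$peak_lin_vel, rep(man0$peak_lin_vel[1], 3))
  expect_equal(man0$peak_rot_acc, rep(man0$peak_rot_acc[1], 3))

  # determinism: same master seed, bitwise-identical manifest
  expect_identical(man, cohort_manifest(generate_cohort(specs, 9)))
})

test_that("generator is calibrated to the profile means and preserves ordering", {
  specs <- default_profile_specs(n_impacts = c(3000L, 0L, 3000L))
  man <- cohort_manifest(generate_cohort(specs[c(1, 3)], 123))
  m1 <- man[man$profile == 1, ]
  m3 <- man[man$profile == 3, ]
  # empirical means within 3 SE of the calibrated (post-truncation) means
  expect_lt(abs(mean(m1$peak_lin_vel) - 3.9), 3 * sd(m1$peak_lin_vel) / sqrt(3000))
  expect_lt(abs(mean(m3$peak_lin_vel) - 2.8), 3 * sd(m3$peak_lin_vel) / sqrt(3000))
  expect_lt(abs(mean(m1$peak_rot_vel) - 25), 3 * sd(m1$peak_rot_vel) / sqrt(3000))
  # profile 1 exceeds profile 3 for all four peak quantities
  for (cl in c("peak_lin_vel", "peak_lin_acc", "peak_rot_vel", "peak_rot_acc"))
    expect_gt(mean(m1[[cl]]), mean(m3[[cl]]))
  # physical sanity: non-negative peaks
  expect_true(all(as.matrix(man[, 5:8]) >= 0))
})

test_that("parameter errors are raised for invalid specs", {
  expect_error(profile_spec(1, 5, c(3.9, -1), c(428, 295), c(25, 14), c(3000, 2000)),
               "dispersion")
  expect_error(profile_spec(1, 5, c(-3.9, 1), c(428, 295), c(25, 14), c(3000, 2000)),
               "positive")
  expect_error(profile_spec(1, 5, c(3.9, 1), c(428, 295), c(25, 14), c(3000, 2000),
                            pulse_range = c(-0.01, 0.02)), "pulse_range")
})

test_that("speed classes follow the collision and fall ladders", {
  expect_equal(velocity_class(c(1.5, 3, 5.5, 8, 11), "collision"),
               c("very_low", "low", "moderate", "high", "very_high"))
  expect_equal(velocity_class(c(1.5, 3, 5.5, 7, 9), "fall"),
               c("very_low", "low", "moderate", "high", "very_high"))
})

test_that("kinematics CSV round-trips through the interchange format", {
  spec <- default_profile_specs()[[2]]
  ev <- generate_impact_pulse(spec, 31)
  path <- withr::local_tempfile(fileext = ".csv")
  write_kinematics_csv(ev$trace, path)
  expect_identical(readLines(path, n = 1), "\"t\",\"ax\",\"ay\",\"az\",\"alx\",\"aly\",\"alz\"")
  tr2 <- read_kinematics_csv(path)
  expect_equal(as.data.frame(tr2), as.data.frame(ev$trace), tolerance = 1e-12)
})
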