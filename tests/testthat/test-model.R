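# Integration, schedules, peaks, knockouts.

test_that("integration reproduces the exponential-decay closed form", {
  ld <- linear_decay_model(k = 0.5)
  tr <- integrate_variant(ld$variant, times = seq(0, 1 / 0.5, length.out = 11))
  expect_equal(unname(tr$states[11, 1]), exp(-1), tolerance = 1e-8)
  expect_equal(unname(tr$states[, 1]), exp(-0.5 * tr$times), tolerance = 1e-8)
})

test_that("bad initial states and grids are input errors", {
  ld <- linear_decay_model()
  expect_error(integrate_variant(ld$variant, times = seq(0, 1, 0.1), x0 = c(1, 2)),
               class = "cv_input_error")
  expect_error(integrate_variant(ld$variant, times = c(0, 0, 1)),
               class = "cv_input_error")
  expect_error(ge_variant(ld$model, "bad", "transient", horizon = 1),
               class = "cv_input_error")
})

test_that("parameter-space invariants are enforced", {
  expect_error(parameter_space(c(a = 1, b = -2)), class = "cv_input_error")
  expect_error(parameter_space(c(1, 2)), class = "cv_input_error")
  expect_error(parameter_space(c(a = 1), fixed = "zz"), class = "cv_input_error")
})

test_that("input schedules are right-open and repeat exactly", {
  sch <- input_schedule(data.frame(start = 0, end = 5, level = 1),
                        period = 60, default_level = 0)
  lv <- constraintvalue:::schedule_level
  expect_equal(lv(sch, c(0, 4.999, 5, 59.9, 60, 64.9, 65)),
               c(1, 1, 0, 0, 1, 1, 0))
  # one-shot schedule
  sch1 <- input_schedule(data.frame(start = 2, end = 4, level = 3))
  expect_equal(lv(sch1, c(0, 2, 3.9, 4, 100)), c(0, 3, 3, 0, 0))
  expect_error(input_schedule(data.frame(start = 0, end = 0, level = 1)),
               class = "cv_input_error")
  expect_error(
    input_schedule(data.frame(start = c(0, 3), end = c(4, 6), level = 1)),
    class = "cv_input_error"
  )
})

test_that("time-rescaling: doubled rates compress trajectories by two", {
  fx <- goodwin3_fixture()
  v <- fx$variants$wt_free
  ref <- fx$model$params$reference
  p2 <- ref
  p2[1:6] <- 2 * p2[1:6]
  t1 <- seq(0, 80, by = 0.2)
  tr1 <- integrate_variant(v, ref, t1)
  tr2 <- integrate_variant(v, p2, t1 / 2)
  expect_equal(tr2$states, tr1$states, tolerance = 1e-7)
})

test_that("peak detection matches the sine closed form and handles degenerate input", {
  t <- seq(0, 20, by = 0.01)
  traj <- structure(
    list(times = t, states = cbind(x = sin(t)), variant_id = "toy", params = NULL),
    class = "cv_trajectory"
  )
  pk <- detect_peaks(traj, 1)
  expect_equal(pk$time, pi / 2 + 2 * pi * (0:2), tolerance = 1e-3)
  expect_equal(pk$level, rep(1, 3), tolerance = 1e-5)

  flat <- structure(
    list(times = t, states = cbind(x = rep(2, length(t))), variant_id = "f", params = NULL),
    class = "cv_trajectory"
  )
  expect_equal(nrow(detect_peaks(flat, 1)), 0)

  tiny <- structure(
    list(times = c(0, 1), states = cbind(x = c(0, 1)), variant_id = "t", params = NULL),
    class = "cv_trajectory"
  )
  expect_error(detect_peaks(tiny, 1), class = "cv_input_error")
})

test_that("refined peaks agree with a dense-grid oracle on the pulsed fixture", {
  fx <- pulsefb2_fixture()
  v <- fx$variants$const
  tr <- integrate_variant(v, times = seq(0, 400, by = 0.1))
  pk <- detect_peaks(tr, 1)
  expect_gte(nrow(pk), 5)
  # peak levels decay monotonically by design of the fixture's damping
  expect_true(all(diff(pk$level) < 0))

  # dense-resampling oracle: 10x finer grid
  trd <- integrate_variant(v, times = seq(0, 400, by = 0.01))
  pkd <- detect_peaks(trd, 1)
  expect_equal(nrow(pk), nrow(pkd))
  expect_equal(pk$time, pkd$time, tolerance = 1e-3)
  expect_equal(pk$level, pkd$level, tolerance = 1e-4)
})

test_that("average peak period follows its definition and contract", {
  pk <- tibble::tibble(time = seq(0, 50, 10), level = 1, grid_index = seq(1, 51, 10))
  expect_equal(average_peak_period(pk, first_index = 3), 10)
  expect_error(average_peak_period(pk[1:2, ], first_index = 3),
               class = "cv_input_error")

  t <- seq(0, 100, by = 0.005)
  traj <- structure(
    list(times = t, states = cbind(x = sin(t)), variant_id = "s", params = NULL),
    class = "cv_trajectory"
  )
  expect_equal(average_peak_period(detect_peaks(traj, 1)), 2 * pi, tolerance = 1e-3)
})

test_that("knockouts zero the rate, mask the axis, and kill the downstream cascade", {
  fx <- goodwin3_fixture()
  ko <- apply_knockout(fx$variants$ko_k3)
  expect_equal(unname(ko$params["k3"]), 0)
  expect_false(ko$mask[["k3"]])
  expect_false(ko$mask[["nh"]]) # fixed Hill exponent is never perturbable
  expect_true(all(ko$mask[c("k1", "k2", "k4", "k5", "k6")]))

  # empty knockout set: identity
  ko0 <- apply_knockout(fx$variants$wt_free)
  expect_equal(ko0$params, fx$model$params$reference)
  expect_true(all(ko0$mask[c("k1", "k2", "k3", "k4", "k5", "k6")]))

  expect_error(ge_variant(fx$model, "x", "transient", knockouts = "nope",
                          x0 = c(1, 1, 1), horizon = 10),
               class = "cv_input_error")

  # downstream variables decay to zero
  tr <- integrate_variant(fx$variants$ko_k3, times = seq(0, 300, 1))
  expect_lt(max(abs(tr$states[nrow(tr$states), 2:3])), 1e-6)
})

test_that("trajectories convert to tibbles and export CSV with the standard header", {
  ld <- linear_decay_model()
  tr <- integrate_variant(ld$variant, times = seq(0, 2, 0.5))
  tbl <- tibble::as_tibble(tr)
  expect_equal(names(tbl), c("time", "x"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  expect_equal(readLines(path, n = 1), "time,var_1")
})
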