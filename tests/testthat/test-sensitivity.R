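# Finite-difference sensitivities and feature gradients.

test_that("solution sensitivity matches the exponential-decay closed form", {
  k <- 0.5
  ld <- linear_decay_model(k = k)
  times <- c(0.5, 1, 2, 4)
  sens <- solution_sensitivity(ld$variant, times = times)
  # d x(t) / d log k = -k t x0 exp(-k t)
  expected <- -k * times * exp(-k * times)
  expect_equal(unname(sens$array[, 1, "k"]), expected, tolerance = 1e-6)
})

test_that("level gradients are exact extractions with no silent interpolation", {
  ld <- linear_decay_model(k = 0.5)
  sens <- solution_sensitivity(ld$variant, times = c(1, 2))
  g <- level_gradient(sens, 1, 2)
  expect_equal(unname(g["k"]), unname(sens$array[2, 1, "k"]))
  expect_error(level_gradient(sens, 1, 1.5), class = "cv_input_error")
})

test_that("transient level sensitivities obey the time-rescaling identity", {
  # single-rate-per-term vector field: scaling all rates by lambda maps
  # g(t) to g(lambda t), so sum_l dg_j(t)/dlog k_l = +t * gdot_j(t)
  fx <- pulsefb2_fixture()
  v <- fx$variants$const
  times <- c(40, 80, 150)
  sens <- solution_sensitivity(v, times = times)
  eps <- 1e-4
  grid <- sort(unique(c(seq(0, 400, length.out = 2001), times, times + eps, times - eps)))
  tr <- integrate_variant(v, times = grid)
  for (i in seq_along(times)) {
    for (j in 1:3) {
      gdot <- (tr$states[match(times[i] + eps, grid), j] -
               tr$states[match(times[i] - eps, grid), j]) / (2 * eps)
      lhs <- sum(sens$array[i, j, ])
      expect_equal(lhs, unname(times[i] * gdot), tolerance = 5e-3)
    }
  }
})

test_that("finite differences agree with the variational-equation oracle", {
  # goodwin3 transient: augment the ODE with the forward variational
  # equations (analytic Jacobian) and compare dg/dlog k entry-wise
  fx <- goodwin3_fixture()
  v <- fx$variants$wt_transient
  k <- fx$model$params$reference
  nh <- k[["nh"]]
  times <- c(30, 90)
  sens <- solution_sensitivity(v, times = times)

  pert <- c("k1", "k2", "k3", "k4", "k5", "k6")
  aug_rhs <- function(t, y, parms) {
    x <- y[1:3]
    S <- matrix(y[-(1:3)], nrow = 3) # dX/dk_l for the 6 rates
    hill <- 1 / (1 + x[3]^nh)
    dhill <- -nh * x[3]^(nh - 1) / (1 + x[3]^nh)^2
    f <- c(
      k[["k1"]] * hill - k[["k2"]] * x[1],
      k[["k3"]] * x[1] - k[["k4"]] * x[2],
      k[["k5"]] * x[2] - k[["k6"]] * x[3]
    )
    J <- rbind(
      c(-k[["k2"]], 0, k[["k1"]] * dhill),
      c(k[["k3"]], -k[["k4"]], 0),
      c(0, k[["k5"]], -k[["k6"]])
    )
    dfdk <- cbind(c(hill, 0, 0), c(-x[1], 0, 0), c(0, x[1], 0),
                  c(0, -x[2], 0), c(0, 0, x[2]), c(0, 0, -x[3]))
    dS <- J %*% S + dfdk # column l = df/dk_l
    list(c(f, as.vector(dS)))
  }
  y0 <- c(v$x0, rep(0, 18))
  sol <- deSolve::lsoda(y0, c(0, times), aug_rhs, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  for (i in seq_along(times)) {
    S <- matrix(sol[i + 1, -1][-(1:3)], nrow = 3)
    # convert d/dk to d/dlog k
    Slog <- S * rep(k[pert], each = 3)
    fd <- sens$array[i, , pert]
    big <- abs(Slog) > 1e-6
    expect_lt(max(abs(fd - Slog)[big] / abs(Slog)[big]), 1e-4)
  }
})

test_that("the period gradient obeys its sum rule and step-halving consistency", {
  fx <- goodwin3_fixture()
  v <- fx$variants$wt_free
  orbit <- find_periodic_orbit(v)
  g <- period_gradient(v)
  expect_false(attr(g, "entrained"))
  expect_equal(unname(g[["nh"]]), 0) # fixed parameter masked
  expect_equal(sum(g), -orbit$period, tolerance = 5e-3)

  g2 <- period_gradient(v, config = cv_config(fd_step = 5e-4))
  expect_lt(max(abs(g2 - g)) / max(abs(g)), 1e-3)
})

test_that("entrained variants have a flagged zero period gradient", {
  fx <- goodwin3_fixture()
  g <- period_gradient(fx$variants$wt_entrained)
  expect_true(attr(g, "entrained"))
  expect_equal(as.vector(g), rep(0, 7))
})

test_that("peak-time gradients obey time rescaling and flag degenerate peaks", {
  fx <- pulsefb2_fixture()
  v <- fx$variants$const
  g <- peak_time_gradient(v, j = 1, n = 2)
  tr <- integrate_variant(v, times = seq(0, 400, length.out = 4001))
  phi <- detect_peaks(tr, 1)$time[2]
  expect_equal(sum(g), -phi, tolerance = 0.01 * phi)

  # the zero-input variant is flat: no peak to differentiate
  expect_error(peak_time_gradient(fx$variants$zero, j = 1, n = 1),
               class = "cv_degenerate_peak_error")
})

test_that("output-scaling homogeneity: amplitude scales, ratios are invariant", {
  toy <- output_scaling_toy()
  # k3 scales x2 linearly: dA/dlog k3 = A, and ratio gradients vanish
  ga <- amplitude_gradient(toy$variant, j = 2)
  tr <- integrate_variant(toy$variant, times = seq(0, 60, length.out = 2001))
  A <- diff(range(tr$states[, 2]))
  expect_equal(unname(ga[["k3"]]), A, tolerance = 1e-4)

  gr <- peak_ratio_gradient(toy$variant, j = 2, n2 = 2, n1 = 1)
  expect_lt(abs(gr[["k3"]]), 1e-8 * max(abs(gr)))

  gf <- fall_ratio_gradient(toy$variant, j = 2, delta = 2)
  expect_lt(abs(gf[["k3"]]), 1e-6)
})

test_that("trivial ratio features have zero gradients", {
  fx <- pulsefb2_fixture()
  v <- fx$variants$const
  g <- fall_ratio_gradient(v, j = 1, delta = 0)
  expect_equal(unname(g), rep(0, 7))
  g <- peak_ratio_gradient(v, j = 1, n2 = 1, n1 = 1)
  expect_equal(unname(g), rep(0, 7))
})

test_that("sensitivity errors name the failing parameter", {
  ps <- parameter_space(c(a = 1))
  bad_model <- ode_model(
    name = "bad",
    rhs = function(t, x, k, u) {
      if (k[["a"]] > 1) stop("boom")
      -x[1]
    },
    state_names = "x", params = ps, nominal_period = 1
  )
  v <- ge_variant(bad_model, "bad", "transient", x0 = 1, horizon = 5)
  err <- tryCatch(
    solution_sensitivity(v, times = c(1, 2)),
    cv_sensitivity_error = function(e) conditionMessage(e)
  )
  expect_match(err, "'a'")
})
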