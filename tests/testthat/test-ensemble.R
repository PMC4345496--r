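# Sloppy-ensemble generator, decay, and small-norm concentration.

test_that("the generator is reproducible and honours special gamma choices", {
  e1 <- sloppy_ensemble(10, 6, 0.5, seed = 42)
  e2 <- sloppy_ensemble(10, 6, 0.5, seed = 42)
  expect_identical(cm_matrix(e1$matrix), cm_matrix(e2$matrix))
  expect_equal(tcrossprod(e1$W), diag(10), tolerance = 1e-12)
  expect_equal(e1$mu, 0.5^(0:9))

  # rho = 1 with orthonormal basis-vector gammas: all ordered values 1
  gamma <- cbind(diag(6), matrix(0, 6, 4))
  en <- sloppy_ensemble(10, 6, 1, seed = 1, gamma = gamma)
  ord <- order_constraints(en$matrix)
  expect_equal(ord$values, rep(1, 6), tolerance = 1e-12)
})

test_that("ordered ensemble values inherit the geometric decay of mu", {
  # the strict per-rank bound v_i <= K mu_i holds for the vast majority of
  # ranks; occasional O(1) excursions at deep ranks are expected
  ratios <- c()
  for (seed in 1:20) {
    en <- sloppy_ensemble(30, 20, 0.5, seed = seed)
    ord <- order_constraints(en$matrix)
    pos <- ord$values > 0
    ratios <- c(ratios, (ord$values / (en$K * en$mu[1:20]))[pos])
  }
  expect_lt(max(ratios), 2)
  expect_gte(mean(ratios <= 1), 0.95)
  # v_1 = max row norm <= K mu_1 always
  for (seed in 1:20) {
    en <- sloppy_ensemble(12, 8, 0.6, seed = seed)
    ord <- order_constraints(en$matrix)
    expect_lte(ord$values[1], en$K * en$mu[1] + 1e-12)
  }
})

test_that("the decay profile recovers exact and approximate geometric slopes", {
  dp <- decay_profile(2^-(1:10))
  expect_equal(dp$slope, -log(2), tolerance = 1e-12)
  dp <- decay_profile(rep(3, 8))
  expect_equal(dp$slope, 0, tolerance = 1e-12)
  expect_error(decay_profile(c(1)), class = "cv_input_error")
  # zeros are excluded from the fit
  dp <- decay_profile(c(2^-(1:10), 0, 0))
  expect_equal(dp$n_used, 10)

  # ensemble slope tracks log rho to within a few percent
  sl <- vapply(1:10, function(seed) {
    en <- sloppy_ensemble(30, 25, 0.5, seed = seed)
    decay_profile(order_constraints(en$matrix)$values)$slope
  }, numeric(1))
  expect_lt(abs(mean(sl) - log(0.5)) / abs(log(0.5)), 0.05)
})

test_that("small-norm fractions match a direct recount and the Monte-Carlo reference", {
  # rho = 1 orthonormal case: no small norms
  gamma <- cbind(diag(5), matrix(0, 5, 3))
  en <- sloppy_ensemble(8, 5, 1, seed = 1, gamma = gamma)
  sn <- small_norm_fraction(en, frac = 0.1, n_mc = 200, seed = 1)
  expect_equal(sn$empirical, 0)

  en <- sloppy_ensemble(25, 20, 0.5, seed = 5)
  sn0 <- small_norm_fraction(en, frac = 0, n_mc = 100, seed = 1)
  expect_equal(sn0$empirical, 0)

  sn <- small_norm_fraction(en, frac = 0.1, n_mc = 2000, seed = 1)
  nr <- sqrt(rowSums(cm_matrix(en$matrix)^2))
  expect_equal(sn$empirical, mean(nr < 0.1 * max(nr)))
  expect_true(is.finite(sn$reference_mean) && sn$reference_se > 0)

  # stronger decay -> larger expected small-norm fraction
  frac_at <- function(rho) {
    mean(vapply(1:50, function(seed) {
      e <- sloppy_ensemble(25, 20, rho, seed = seed)
      nr <- sqrt(rowSums(cm_matrix(e$matrix)^2))
      mean(nr < 0.1 * max(nr))
    }, numeric(1)))
  }
  expect_gt(frac_at(0.5), frac_at(0.8))
})
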