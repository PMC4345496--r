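# Constraint value, orthogonal decomposition and ordering.

test_that("constraint value matches closed forms and the least-squares oracle", {
  expect_equal(constraint_value(c(3, 4, 0), NULL), 5)
  expect_equal(constraint_value(c(1, 0, 0), rbind(c(1, 0, 0))), 0)

  # residual-norm oracle on seeded random instances
  for (seed in 1:40) {
    set.seed(seed)
    s <- sample(3:10, 1)
    m <- sample(1:4, 1)
    rows <- matrix(rnorm(m * s), m, s)
    cc <- rnorm(s)
    expect_equal(constraint_value(cc, rows), ls_residual_norm(cc, rows),
                 tolerance = 1e-10)
  }
})

test_that("constraint value respects monotonicity, the norm bound and rotation invariance", {
  for (seed in 1:20) {
    set.seed(seed)
    s <- 8
    rows <- matrix(rnorm(3 * s), 3, s)
    extra <- rnorm(s)
    cc <- rnorm(s)
    v1 <- constraint_value(cc, rows)
    v2 <- constraint_value(cc, rbind(rows, extra))
    expect_lte(v2, v1 + 1e-12)
    expect_lte(v1, sqrt(sum(cc^2)) + 1e-12)
    # orthogonal invariance
    Q <- qr.Q(qr(matrix(rnorm(s * s), s, s)))
    expect_equal(constraint_value(drop(cc %*% Q), rows %*% Q), v1,
                 tolerance = 1e-10)
  }
  # v = ||c|| iff c orthogonal to the rows
  rows <- rbind(c(1, 0, 0), c(0, 1, 0))
  expect_equal(constraint_value(c(0, 0, 2), rows), 2)
})

test_that("decomposition reconstructs the constraint and is orthogonal to the rows", {
  for (seed in 1:20) {
    set.seed(seed)
    rows <- matrix(rnorm(4 * 9), 4, 9)
    cc <- rnorm(9)
    dec <- decompose_constraint(cc, rows)
    recon <- dec$c_perp + drop(t(rows) %*% dec$coefficients)
    expect_equal(recon, cc, tolerance = 1e-12)
    expect_lt(max(abs(rows %*% dec$c_perp)), 1e-10)
  }
  # c orthogonal to rows -> a = 0, c_perp = c
  dec <- decompose_constraint(c(0, 0, 3), rbind(c(1, 0, 0)))
  expect_equal(dec$coefficients, 0)
  expect_equal(dec$c_perp, c(0, 0, 3))
  # c in span -> c_perp = 0
  dec <- decompose_constraint(c(2, 0, 0), rbind(c(1, 0, 0)))
  expect_equal(dec$value, 0)
  expect_lt(max(abs(dec$c_perp)), 1e-12)
  # dependent rows: minimum-norm coefficients
  rows <- rbind(c(1, 0), c(1, 0))
  dec <- decompose_constraint(c(1, 1), rows)
  expect_equal(dec$coefficients, c(0.5, 0.5), tolerance = 1e-12)
})

test_that("axis mismatches are input errors", {
  expect_error(constraint_value(c(1, 2), rbind(c(1, 2, 3))), class = "cv_input_error")
  M <- as_constraint_tbl(rbind(c(1, 2)), params = c("a", "b"))
  cc <- c(x = 1, y = 2)
  expect_error(constraint_value(cc, M), class = "cv_input_error")
})

test_that("ordering reproduces the worked example and simple geometries", {
  ord <- order_constraints(rbind(c(1, 0), c(0, 2), c(1, 1)))
  expect_equal(ord$permutation, c(2L, 1L, 3L))
  expect_equal(ord$values, c(2, 1, 0))

  # two identical rows of norm 7
  ord <- order_constraints(rbind(c(7, 0), c(7, 0)))
  expect_equal(ord$values, c(7, 0))

  # mutually orthogonal rows: values are the sorted norms
  M <- diag(c(3, 1, 5))
  ord <- order_constraints(M)
  expect_equal(ord$values, c(5, 3, 1))
  expect_equal(ord$permutation, c(3L, 1L, 2L))

  expect_error(order_constraints(matrix(0, 0, 3)), class = "cv_input_error")
})

test_that("greedy ordering is the lexicographic maximum over all permutations", {
  for (seed in 1:12) {
    set.seed(seed)
    m <- sample(2:5, 1)
    s <- sample(m:7, 1)
    M <- matrix(rnorm(m * s), m, s)
    ord <- order_constraints(M)
    expect_equal(ord$values, brute_force_ordering(M), tolerance = 1e-9)
  }
})

test_that("greedy ordering agrees with LAPACK column-pivoted QR of the transpose", {
  for (seed in 1:10) {
    set.seed(seed)
    M <- matrix(rnorm(6 * 9), 6, 9)
    ord <- order_constraints(M)
    qp <- qr(t(M), LAPACK = TRUE)
    expect_equal(ord$permutation, qp$pivot)
    expect_equal(ord$values, abs(diag(qr.R(qp))), tolerance = 1e-9)
  }
})

test_that("ordering handles m > s with exact zero values after rank exhaustion", {
  set.seed(4)
  M <- matrix(rnorm(6 * 3), 6, 3)
  ord <- order_constraints(M)
  expect_true(all(diff(ord$values) <= 1e-12))
  expect_identical(ord$values[4:6], c(0, 0, 0))
  expect_equal(sum(ord$values > 0), 3)
})

test_that("ties are broken toward the lowest original index and logged", {
  M <- rbind(c(0, 1), c(1, 0), c(2, 0) / 2)
  ord <- order_constraints(M)
  expect_equal(ord$permutation[1], 1L)
  expect_gte(length(ord$ties), 1)
})

test_that("norm screening drops rows below the fractional threshold", {
  scr <- screen_norms(rbind(c(10, 0), c(2, 0), c(0.5, 0)), frac = 0.1)
  expect_equal(scr$n_dropped, 1)
  expect_equal(scr$dropped$norm, 0.5)

  scr <- screen_norms(rbind(c(1, 0), c(0, 1)), frac = 0.1)
  expect_equal(scr$n_dropped, 0)

  # recount oracle on an ensemble
  en <- sloppy_ensemble(20, 15, 0.5, seed = 3)
  scr <- screen_norms(en$matrix, frac = 0.1)
  nr <- sqrt(rowSums(cm_matrix(en$matrix)^2))
  expect_equal(scr$n_dropped, sum(nr < 0.1 * max(nr)))
})

test_that("effective-constraint cut-offs follow the absolute and relative rules", {
  eff <- effective_constraints(c(5, 2, 0.5), mode = "absolute")
  expect_equal(which(eff$effective_absolute), 1:2)

  eff <- effective_constraints(c(100, 0.9), mode = "both")
  expect_equal(which(eff$effective_absolute), 1L)
  expect_equal(which(eff$effective_relative), 1L) # 0.9 is below 1% of 100

  # filter oracle on a random ordering
  set.seed(9)
  ord <- order_constraints(matrix(rnorm(5 * 8), 5, 8))
  eff <- effective_constraints(ord)
  expect_equal(eff$effective_absolute, ord$values >= 1)
  expect_equal(eff$effective_relative, ord$values > 0.01 * ord$values[1])
})

test_that("tidy and glance summarise an ordering", {
  ord <- order_constraints(rbind(c(1, 0), c(0, 2), c(1, 1)))
  td <- tidy(ord)
  expect_equal(td$value, c(2, 1, 0))
  gl <- glance(ord)
  expect_equal(gl$m, 3)
  expect_equal(gl$rank, 2)
  expect_equal(gl$v_top, 2)
})
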