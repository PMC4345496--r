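# Ellipsoidal geometry of the approximate solution set.

test_that("the ellipsoid model exposes axes, membership and rank checks", {
  em <- ellipsoid_model(diag(c(2, 1)), eps = 0.1)
  expect_equal(em$semi_axes, c(0.05, 0.1))
  expect_true(em$membership(c(0, 0)))
  expect_false(em$membership(c(0.06, 0)))
  expect_equal(tcrossprod(em$W), diag(2), tolerance = 1e-12)

  # k* is a member for any eps
  for (eps in c(1e-3, 1, 100)) {
    em <- ellipsoid_model(rbind(c(1, 2, 0)), eps = eps, k_star = c(1, 1, 1))
    expect_true(em$membership(c(1, 1, 1)))
  }

  # unconstrained directions do not affect membership
  em <- ellipsoid_model(rbind(c(1, 0, 0)), eps = 0.1)
  expect_true(em$membership(c(0, 50, -50)))

  expect_error(ellipsoid_model(rbind(c(1, 0), c(1, 0)), eps = 0.1),
               class = "cv_rank_error")
  expect_error(ellipsoid_model(diag(2), eps = -1), class = "cv_input_error")
})

test_that("for a linear constraint map the ellipsoid is exact", {
  set.seed(21)
  M <- matrix(rnorm(3 * 5), 3, 5)
  k_star <- rnorm(5)
  C <- function(k) drop(M %*% (k - k_star))
  res <- validate_ellipsoid(C, k_star, eps_list = c(0.1, 0.01),
                            n_samples = 2000, seed = 7, M = M)
  expect_equal(res$agreement, c(1, 1))
})

test_that("agreement with the exact set improves as eps decreases on a quadratic map", {
  # well-conditioned Jacobian with mild curvature, so the ellipsoid's
  # asymptotic regime is reached within the tested eps range
  set.seed(22)
  M <- qr.Q(qr(matrix(rnorm(16), 4, 4)))[, 1:3]
  M <- t(M) * c(1.5, 1, 0.7)
  A <- array(rnorm(3 * 4 * 4, sd = 0.1), c(3, 4, 4))
  k_star <- rep(0, 4)
  C <- function(k) {
    lin <- drop(M %*% k)
    quad <- vapply(1:3, function(i) 0.5 * drop(t(k) %*% A[i, , ] %*% k), numeric(1))
    lin + quad
  }
  res <- validate_ellipsoid(C, k_star, eps_list = c(1e-1, 1e-2),
                            n_samples = 4000, seed = 5)
  expect_gte(res$agreement[res$eps == 1e-2], res$agreement[res$eps == 1e-1])
  expect_gt(res$agreement[res$eps == 1e-2], 0.95)

  expect_error(validate_ellipsoid(C, k_star, eps_list = c(-1), n_samples = 10),
               class = "cv_input_error")
})
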