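# FIM, singular spectra, and the m -> m+1 transition.

test_that("the FIM is M^T M with eigenvalues equal to squared singular values", {
  expect_equal(build_fim(diag(3)), diag(3))
  expect_equal(build_fim(rbind(c(2, 0))), diag(c(4, 0)))
  for (seed in 1:15) {
    set.seed(seed)
    M <- matrix(rnorm(5 * 7), 5, 7)
    ev <- sort(eigen(build_fim(M), symmetric = TRUE)$values, decreasing = TRUE)
    sv2 <- c(svd(M)$d^2, rep(0, 7 - 5))
    expect_equal(ev, sv2, tolerance = 1e-10)
  }
})

test_that("spectral reports expose singular values, rank and condition number", {
  sp <- constraint_spectrum(diag(c(3, 1)))
  expect_equal(sp$singular_values, c(3, 1))
  expect_equal(sp$condition, 3)
  expect_equal(sp$rank, 2)

  Q <- qr.Q(qr(rand_cm(2, 4, 4)))
  sp <- constraint_spectrum(Q)
  expect_equal(sp$singular_values, rep(1, 4), tolerance = 1e-12)

  # two independent factorization routes
  M <- rand_cm(5, 6, 8)
  sp <- constraint_spectrum(M)
  ev <- sqrt(pmax(eigen(crossprod(M), symmetric = TRUE)$values, 0))
  expect_equal(sp$singular_values, sort(ev, decreasing = TRUE)[1:6], tolerance = 1e-8)
})

test_that("transition reports reproduce the orthogonal and duplicate cases", {
  tr <- transition_add(rbind(c(1, 0, 0)), c(0, 1, 0))
  expect_equal(tr$sigma_after, c(1, 1))
  expect_equal(tr$value, 1)
  expect_true(tr$interlacing_ok && tr$new_smallest_ok && tr$condition_ok)

  tr <- transition_add(rbind(c(1, 0, 0)), c(1, 0, 0))
  expect_equal(tr$sigma_after, c(sqrt(2), 0), tolerance = 1e-12)
  expect_equal(tr$value, 0)
  expect_true(tr$interlacing_ok && tr$new_smallest_ok)
})

test_that("interlacing and both bounds hold on seeded random additions", {
  for (seed in 1:60) {
    set.seed(seed)
    m <- sample(2:8, 1)
    s <- sample(m:12, 1)
    M <- matrix(rnorm(m * s), m, s)
    cc <- rnorm(s)
    tr <- transition_add(M, cc)
    expect_true(tr$interlacing_ok)
    expect_true(tr$new_smallest_ok)
    expect_true(tr$condition_ok)
    # direct oracle recomputation (zero-padded when m + 1 > s)
    d_b <- c(svd(M)$d, rep(0, max(0, m - s)))
    d_a <- c(svd(rbind(M, cc))$d, rep(0, max(0, m + 1 - s)))
    tol <- 1e-9 * d_a[1]
    expect_true(all(d_a[1:m] >= d_b - tol))
    expect_true(all(d_b >= d_a[2:(m + 1)] - tol))
    expect_lte(d_a[m + 1], ls_residual_norm(cc, M) + tol)
  }
})

test_that("the improvement verdict flags constraints exceeding the smallest singular value", {
  M <- diag(c(3, 1, 2))
  dup <- c(3, 0, 0)
  iv <- improvement_verdict(M, dup)
  expect_false(iv$improves)
  expect_equal(iv$value, 0)

  M2 <- rbind(c(2, 0, 0, 0), c(0, 1, 0, 0))
  iv <- improvement_verdict(M2, c(0, 0, 1.5, 0))
  expect_true(iv$improves)
  expect_equal(iv$margin, 0.5)

  # consistency with recomputed condition numbers across a random sweep
  for (seed in 1:10) {
    set.seed(seed)
    M <- matrix(rnorm(3 * 5), 3, 5)
    cc <- rnorm(5)
    iv <- improvement_verdict(M, cc)
    d <- svd(M)$d
    expect_equal(iv$improves, ls_residual_norm(cc, M) > min(d))
  }
})

test_that("design reports rank candidates and agree with per-candidate recomputation", {
  M <- rbind(c(1, 0, 0), c(0, 1, 0))
  cand <- as_constraint_tbl(
    rbind(dup = c(1, 0, 0), new = c(0, 0, 2)),
    params = c("p1", "p2", "p3")
  )
  rep <- design_report(as_constraint_tbl(M, params = c("p1", "p2", "p3")), cand)
  expect_equal(rep$id[1], "new")
  expect_equal(rep$value[rep$id == "dup"], 0)
  expect_false(rep$improves[rep$id == "dup"])
  # orthogonal candidate with norm exceeding v_1 lands at rank 1
  expect_equal(rep$rank_after[rep$id == "new"], 1)
  expect_equal(rep$frac_of_top[rep$id == "new"], 1)

  # random battery vs independent recomputation
  set.seed(11)
  M <- matrix(rnorm(4 * 6), 4, 6)
  cands <- matrix(rnorm(3 * 6), 3, 6)
  rep <- design_report(M, cands)
  for (i in seq_len(3)) {
    id <- paste0("cand", i)
    row <- rep[rep$id == id, ]
    expect_equal(row$value, ls_residual_norm(cands[i, ], M), tolerance = 1e-10)
    ord <- order_constraints(rbind(M, cands[i, ]))
    pos <- which(ord$permutation == 5)
    expect_equal(row$rank_after, pos)
    expect_equal(row$value_after, ord$values[pos])
  }
})
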