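# Catalogue linearization, masking, se-normalization and rank stability.

test_that("the fixture study is reproducible and spans every constraint kind", {
  s1 <- make_fixture_study(seed = 3)
  s2 <- make_fixture_study(seed = 3)
  expect_identical(s1$catalogue, s2$catalogue)
  expect_setequal(
    unique(s1$catalogue$kind),
    c("level", "period", "peak_time", "amplitude", "fall_ratio",
      "peak_level", "peak_ratio")
  )
  expect_gte(nrow(s1$catalogue), 12)
  expect_true(all(s1$catalogue$se > 0))

  s3 <- make_fixture_study(seed = 4)
  expect_false(identical(s1$catalogue$se, s3$catalogue$se))
})

test_that("linearization se-normalizes, masks knockouts, and is linear in 1/se", {
  study <- fast_transient_study(seed = 2)
  M <- linearize_constraints(study)
  expect_equal(M$id, study$catalogue$id)
  pc <- cm_params(M)
  expect_setequal(pc, names(study$model$params$reference))

  # fixed Hill exponent masked everywhere
  expect_true(all(M$nh == 0))
  # knockout row masked at the knocked-out rate, exactly
  ko_row <- M[M$id == "lev_ko", ]
  expect_identical(ko_row$k3, 0)
  # non-masked coordinates are generically non-zero
  expect_gt(sum(abs(cm_matrix(M))), 0)

  # se linearity: doubling se halves the row
  cat2 <- study$catalogue[study$catalogue$id == "lev_t20", ]
  base <- linearize_constraint(cat2, study)
  cat2$se <- 2 * cat2$se
  halved <- linearize_constraint(cat2, study)
  expect_equal(cm_matrix(halved), cm_matrix(base) / 2, tolerance = 1e-12)

  # raw gradients attached and consistent with se scaling
  raw <- attr(M, "raw_gradients")
  expect_equal(raw["lev_t20", ] / study$catalogue$se[study$catalogue$id == "lev_t20"],
               cm_matrix(M)["lev_t20", ], tolerance = 1e-12)
})

test_that("invalid catalogue entries are rejected", {
  study <- fast_transient_study(seed = 2)
  bad <- study$catalogue
  bad$se[1] <- -1
  expect_error(linearize_constraints(study, catalogue = bad),
               class = "cv_input_error")
  expect_error(
    constraint_study(study$model, study$variants,
                     dplyr::mutate(study$catalogue, variant = "nope")),
    class = "cv_input_error"
  )
})

test_that("duplicated constraint specifications land at the bottom with value zero", {
  study <- fast_transient_study(seed = 5)
  dup <- study$catalogue[study$catalogue$id == "lev_t20", ]
  dup$id <- "lev_t20_dup"
  cat2 <- dplyr::bind_rows(study$catalogue, dup)
  M <- linearize_constraints(study, catalogue = cat2)
  ord <- order_constraints(M)
  expect_equal(min(ord$values), 0)
  bottom_ids <- ord$ordering$id[ord$ordering$value == 0]
  expect_true(any(c("lev_t20", "lev_t20_dup") %in% bottom_ids))
})

test_that("rank stability reporting: zero perturbation reproduces the reference ranking", {
  study <- fast_transient_study(seed = 6)
  rs <- rank_stability(study, n_sets = 2, sd_frac = 0, seed = 9, top_n = 4)
  ref <- rs$ranks[rs$ranks$draw == 0, ]
  for (d in 1:2) {
    drawn <- rs$ranks[rs$ranks$draw == d, ]
    expect_equal(drawn$id, ref$id)
    expect_equal(drawn$value, ref$value, tolerance = 1e-12)
  }
  expect_equal(rs$top_overlap$top_overlap, c(1, 1))

  rs2 <- rank_stability(study, n_sets = 2, sd_frac = 0, seed = 9, top_n = 4)
  expect_identical(rs$ranks, rs2$ranks)
})
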