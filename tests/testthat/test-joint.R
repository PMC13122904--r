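test_that("exhausted trial time collapses the joint prediction", {
  d <- trial_design(200, 20, 0.3, c(NW = 0.3, H = 0.1))
  i <- interim_data(150, 20, c(NW = 45, H = 15))
  pred <- predict_joint(d, i, s = 1000, seed = 1)
  expect_true(all(pred$sample_size == 150L))
  expect_true(all(pred$rubr == (45 + 15) / 150))
  expect_identical(pred$category_totals$NW, rep(45L, 1000))
})

test_that("every rUBR draw equals its recomputed component ratio", {
  d <- big_design()
  i <- interim_data(300, 12, c(NW = 90, H = 60))
  pred <- predict_joint(d, i, s = 4000, seed = 8)
  recomputed <- (pred$category_totals$NW + pred$category_totals$H) /
    pred$sample_size
  expect_identical(pred$rubr, recomputed)
  # conservation: observed <= total <= sample size per category per draw
  expect_true(all(pred$category_totals$NW >= 90L))
  expect_true(all(pred$category_totals$NW <= pred$sample_size))
  expect_true(all(pred$sample_size >= 300L))
})

test_that("flat-prior joint predictions persist the observed rates", {
  d <- flat_design(n_target = 1000, horizon = 100)
  i <- interim_data(100, 10, c(NW = 30, H = 10))
  pred <- predict_joint(d, i, s = 20000, seed = 13)
  expect_equal(mean(pred$rubr), 0.40, tolerance = 0.01)
})

test_that("joint predictions are reproducible under a seed", {
  d <- big_design()
  i <- interim_data(300, 12, c(NW = 90, H = 60))
  a <- predict_joint(d, i, s = 2000, seed = 5)
  b <- predict_joint(d, i, s = 2000, seed = 5)
  expect_identical(a$sample_size, b$sample_size)
  expect_identical(a$rubr, b$rubr)
  expect_identical(a$category_totals, b$category_totals)
})

test_that("improper posteriors propagate from either sub-model", {
  flat <- flat_design()
  expect_error(predict_joint(flat, interim_data(0, 0, c(NW = 0, H = 0)),
                             s = 10),
               class = "ubr_improper_posterior")
  # accrual informed but one category count at the boundary
  expect_error(predict_joint(flat, interim_data(10, 5, c(NW = 0, H = 3)),
                             s = 10),
               class = "ubr_improper_posterior")
  expect_error(predict_joint(flat, interim_data(10, 5, c(NW = 2)), s = 10),
               class = "ubr_validation_error")  # missing category count
})

test_that("final rUBR is the sum of category proportions", {
  expect_equal(round(final_rubr(final_counts(1100, c(NW = 302, H = 244))), 3),
               0.496)
  expect_equal(round(final_rubr(final_counts(455, c(NW = 226, H = 0))), 3),
               0.497)
  expect_equal(final_rubr(final_counts(100, c(NW = 0, H = 0, R = 0))), 0)
})

test_that("meeting probabilities use the at-or-above convention", {
  d <- trial_design(100, 10, 0, c(NW = 0.3))
  pred <- predict_joint(d, interim_data(40, 2, c(NW = 10)),
                        s = 3000, seed = 2)
  # hand-built draw vector checks the tie contract exactly
  fake <- pred
  fake$sample_size <- c(99L, 100L, 101L)
  fake$rubr <- c(0.2, 0.3, 0.4)
  pm <- prob_meeting(fake, n_target = 100, rubr_target = 0.5)
  expect_equal(pm[["p_accrual"]], 2 / 3)
  expect_equal(pm[["p_rubr"]], 0)

  # degenerate draws exactly at the target count as meeting
  dd <- trial_design(150, 20, 0.3, c(NW = 0.3), rubr_target = 45 / 150)
  done <- predict_joint(dd, interim_data(150, 20, c(NW = 45)),
                        s = 500, seed = 3)
  pm2 <- prob_meeting(done)
  expect_equal(pm2[["p_accrual"]], 1)
  expect_equal(pm2[["p_rubr"]], 1)
})

test_that("interim reports tighten as looks accumulate and are stable", {
  tr <- adore_like_trial(seed = 31)
  log <- generate_trial(tr$config)
  looks <- look_times(log, tr$look_spec$after_m, tr$look_spec$every,
                      tr$look_spec$n_looks, horizon = 48)
  interims <- lapply(looks, aggregate_at, log = log)
  rep1 <- summarize_interims(tr$design, interims, s = 2000, seed = 41)
  rep2 <- summarize_interims(tr$design, interims, s = 2000, seed = 41)
  expect_identical(as.data.frame(rep1), as.data.frame(rep2))

  widths <- rep1$rubr_upper95 - rep1$rubr_lower95
  expect_lt(widths[length(widths)], widths[1])
  expect_lte(sum(diff(widths) > 0), 2)

  # out-of-order interims are rejected
  expect_error(summarize_interims(tr$design, rev(interims), s = 100),
               class = "ubr_validation_error")
})

test_that("single exhausted interim yields a degenerate report row", {
  d <- trial_design(200, 20, 0.3, c(NW = 0.3, H = 0.1), rubr_target = 0.4)
  rep <- summarize_interims(d, list(interim_data(180, 20,
                                                 c(NW = 54, H = 18))),
                            s = 500, seed = 6)
  expect_equal(rep$n_lower95, rep$n_upper95)
  expect_equal(rep$rubr_lower95, rep$rubr_upper95)
  expect_equal(rep$rubr_median, 72 / 180)
})

test_that("overlapping categories surface as an above-one rUBR warning", {
  config <- synth_trial_config(theta = 0.05, p = c(NW = 0.7, H = 0.7),
                               horizon = 20,
                               overlap_pairs = list(c("NW", "H")),
                               seed = 51)
  log <- generate_trial(config)
  d <- trial_design(400, 40, 0, c(NW = 0.7, H = 0.7))
  i <- aggregate_at(log, 10)
  expect_warning(pred <- predict_joint(d, i, s = 2000, seed = 52),
                 "double")
  # the additive combined rate exceeds the true any-category proportion
  any_cat <- mean(pmin(log$NW + log$H, 1))
  expect_gt(mean(pred$rubr), any_cat)
})
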