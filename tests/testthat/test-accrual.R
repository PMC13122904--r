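test_that("the accrual prior scales the design by the confidence", {
  expect_equal(unclass(accrual_prior(big_design()))[c("shape", "scale")],
               list(shape = 406.5, scale = 14.4))
  q2l <- trial_design(455, 30, 0.3, c(NW = 0.5))
  expect_equal(accrual_prior(q2l)$shape, 136.5)
  expect_equal(accrual_prior(q2l)$scale, 9.0)
  flat <- trial_design(100, 10, 0, c(NW = 0.5))
  expect_equal(accrual_prior(flat)$shape, 0)
  expect_equal(accrual_prior(flat)$scale, 0)
})

test_that("the conjugate update adds observed enrollments to the prior", {
  post <- accrual_posterior(accrual_prior(big_design()),
                            interim_data(300, 12.0, c(NW = 90, H = 60)))
  expect_equal(post$shape, 706.5)
  expect_equal(post$scale, 26.4)

  # flat prior reduces to the data-only posterior, mean B/(A-1)
  flat_post <- post_ab(10, 5.0)
  expect_equal(flat_post$shape, 10)
  expect_equal(flat_post$scale, 5.0)
  expect_equal(mean(flat_post), 5 / 9)

  expect_error(accrual_posterior(accrual_prior(flat_design()),
                                 interim_data(0, 0)),
               class = "ubr_improper_posterior")
})

test_that("exhausted budget collapses every sample-size draw to m", {
  post <- post_ab(50, 20)
  pred <- draw_sample_sizes(post, interim_data(50, 20), horizon = 20,
                            s = 500, seed = 1)
  expect_true(all(pred$draws == 50L))
  expect_equal(pred$summary[["lower95"]], 50)
  expect_equal(pred$summary[["upper95"]], 50)
})

test_that("sample-size draws match the closed-form predictive mean", {
  # Poisson-gamma mixture: E[n^p] = m + (T - t_m) * A / B
  post <- post_ab(10, 5)
  s <- 10000
  pred <- draw_sample_sizes(post, interim_data(10, 5), horizon = 10,
                            s = s, seed = 11)
  mc_se <- stats::sd(pred$draws) / sqrt(s)
  expect_lt(abs(mean(pred$draws) - 20), 3 * mc_se)
  expect_true(all(pred$draws >= 10L))

  # brute-force confirmation via explicit waiting-time counting
  seq_pred <- draw_sample_sizes(post, interim_data(10, 5), horizon = 10,
                                s = s, seed = 12, method = "sequential")
  seq_se <- stats::sd(seq_pred$draws) / sqrt(s)
  expect_lt(abs(mean(seq_pred$draws) - 20), 3 * seq_se)
})

test_that("identical seeds reproduce identical draw vectors", {
  post <- accrual_posterior(accrual_prior(big_design()),
                            interim_data(300, 12, c(NW = 90, H = 60)))
  i <- interim_data(300, 12, c(NW = 90, H = 60))
  a <- draw_sample_sizes(post, i, horizon = 48, s = 2000, seed = 99)
  b <- draw_sample_sizes(post, i, horizon = 48, s = 2000, seed = 99)
  expect_identical(a$draws, b$draws)
})

test_that("the exact predictive count pmf has the stated closed form", {
  # L = 0: point mass at zero
  expect_equal(dpredcount(0:3, post_ab(5, 2), budget = 0), c(1, 0, 0, 0))
  expect_equal(predictive_count_pmf(post_ab(5, 2), 0),
               data.frame(count = 0L, prob = 1))

  # A = 1, B = 1, L = 1: P(0) = B/(B+L) = 1/2; independent oracle by
  # numeric integration of the Poisson-inverse-gamma mixture
  p0_integral <- stats::integrate(function(theta)
    exp(-1 / theta) * theta^-2 * exp(-1 / theta), 0, Inf)$value
  expect_equal(p0_integral, 0.5, tolerance = 1e-6)
  expect_equal(dpredcount(0, post_ab(1, 1), budget = 1), 0.5)

  # mixture pmf at several counts agrees with numeric integration
  A <- 3; B <- 2; L <- 1.5
  post <- post_ab(A, B)
  for (k in 0:4) {
    mix <- stats::integrate(function(theta)
      stats::dpois(k, L / theta) *
        B^A / gamma(A) * theta^-(A + 1) * exp(-B / theta),
      0, Inf, rel.tol = 1e-10)$value
    expect_equal(dpredcount(k, post, L), mix, tolerance = 1e-7)
  }

  # pmf mean equals L * A / B and matches the sampler
  pmf <- predictive_count_pmf(post_ab(10, 5), budget = 5)
  expect_equal(sum(pmf$count * pmf$prob), 10, tolerance = 1e-6)
  pred <- draw_sample_sizes(post_ab(10, 5), interim_data(10, 5),
                            horizon = 10, s = 10000, seed = 3)
  expect_equal(mean(pred$draws - 10), 10,
               tolerance = 4 * stats::sd(pred$draws) / sqrt(10000) / 10)
})

test_that("sequential counting and the Poisson shortcut agree in law", {
  post <- post_ab(10, 5)
  i <- interim_data(10, 5)
  s <- 50000
  pois <- draw_sample_sizes(post, i, horizon = 10, s = s, seed = 21)$draws
  sequ <- draw_sample_sizes(post, i, horizon = 10, s = s, seed = 22,
                            method = "sequential")$draws
  expect_gt(two_sample_pvalue(pois, sequ), 0.001)
})

test_that("slower observed accrual lowers the predicted sample size", {
  prior <- accrual_prior(big_design())
  means <- vapply(c(8, 12, 16, 20), function(t_m) {
    interim <- interim_data(300, t_m, c(NW = 90, H = 60))
    post <- accrual_posterior(prior, interim)
    # closed-form predictive mean over the remaining budget
    300 + (48 - t_m) * post$shape / post$scale
  }, numeric(1))
  expect_true(all(diff(means) < 0))

  # and the Monte-Carlo sampler reproduces the ordering
  mc <- vapply(c(8, 16), function(t_m) {
    interim <- interim_data(300, t_m, c(NW = 90, H = 60))
    post <- accrual_posterior(prior, interim)
    mean(draw_sample_sizes(post, interim, 48, s = 5000, seed = 5)$draws)
  }, numeric(1))
  expect_gt(mc[1], mc[2])
})

test_that("a flat prior recovers the true mean waiting time", {
  theta_true <- 0.4
  m <- 2000
  rel_err <- vapply(1:100, function(r) {
    set.seed(1000 + r)
    w <- rexp(m, rate = 1 / theta_true)
    post <- post_ab(m, sum(w))
    abs(mean(post) - theta_true) / theta_true
  }, numeric(1))
  expect_lt(mean(rel_err), 0.05)
})
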