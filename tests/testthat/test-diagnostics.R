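fake_records <- function(obs, pred) {
  tibble::tibble(id = "A", occ = 1, time = seq_along(obs), obs = obs,
                 pop_pred = pred, ind_pred = pred)
}

test_that("observed-vs-predicted regression matches closed-form OLS", {
  # identity line
  r <- suppressWarnings(gof_regression(fake_records(c(1, 2, 3, 4), c(1, 2, 3, 4))))
  expect_equal(r$slope, 1)
  expect_equal(r$intercept, 0, tolerance = 1e-12)
  expect_equal(r$r2, 1)
  # pure scaling
  r2 <- suppressWarnings(gof_regression(fake_records(c(2, 4, 6), c(1, 2, 3))))
  expect_equal(r2$slope, 2)
  expect_equal(r2$intercept, 0, tolerance = 1e-12)
  # hand-worked OLS on {(1,1.1),(2,1.9),(3,3.2)}
  r3 <- gof_regression(fake_records(c(1.1, 1.9, 3.2), c(1, 2, 3)))
  expect_equal(r3$slope, 2.1 / 2)
  expect_equal(r3$intercept, mean(c(1.1, 1.9, 3.2)) - 1.05 * 2)
  expect_error(gof_regression(fake_records(c(1, 2, 3), c(2, 2, 2))), "constant")
  expect_error(gof_regression(fake_records(1:2, 1:2)), "3")
})

test_that("VPC bands are nested and collapse in the degenerate case", {
  coh <- tiny_cohort(n = 10, seed = 16)
  fit <- npag_fit(coh, control = npag_control(max_cycles = 6), seed = 16)
  v <- vpc(coh, fit, n_sim = 200, seed = 2)
  expect_true(all(v$bands$q05 <= v$bands$q50 & v$bands$q50 <= v$bands$q95))
  expect_true(v$coverage >= 0 && v$coverage <= 1)

  # one support point and (near) zero residual noise: the band is a curve
  p <- ref_params()
  fit1 <- structure(list(
    support = tibble::tibble(CL = p$CL, V = p$V, KCP = p$KCP, KPC = p$KPC,
                             weight = 1),
    use_covariate = FALSE, crcl_ref = 60,
    error_model = error_model(gamma = 1e-9)
  ), class = "npag_fit")
  v1 <- vpc(one_subject_table(), fit1, n_sim = 200, seed = 2)
  expect_lt(max(v1$bands$q95 - v1$bands$q05), 1e-6)
  expect_error(vpc(coh, fit, n_sim = 50), "at least 100")
})

test_that("npde boundary, finiteness and normal-range behaviour", {
  # observations far below every simulated replicate hit the finite floor
  p <- ref_params()
  fit1 <- structure(list(
    support = tibble::tibble(CL = p$CL, V = p$V, KCP = p$KCP, KPC = p$KPC,
                             weight = 1),
    use_covariate = FALSE, crcl_ref = 60,
    error_model = error_model(gamma = 0.1)
  ), class = "npag_fit")
  n_sim <- 500
  tab_lo <- one_subject_table(obs_times = c(1, 3), obs = c(0.001, 0.001))
  np_lo <- npde(tab_lo, fit1, n_sim = n_sim, seed = 5)
  expect_equal(np_lo$records$npde, rep(qnorm(1 / (2 * n_sim)), 2))

  # larger observation, same simulations -> npde non-decreasing
  vals <- c(50, 90, 120, 400)
  npde_at <- vapply(vals, function(v) {
    npde(one_subject_table(obs_times = 1, obs = v), fit1,
         n_sim = n_sim, seed = 5)$records$npde
  }, numeric(1))
  expect_true(all(diff(npde_at) >= 0))

  # self-simulated data give roughly standard-normal npde
  coh <- tiny_cohort(n = 20, seed = 18)
  fit <- npag_fit(coh, control = npag_control(max_cycles = 8), seed = 18)
  self <- generate_cohort(cohort_design(n_subjects = 20, population = fit),
                          seed = 19)
  np <- npde(self, fit, n_sim = 600, seed = 6)
  expect_lt(abs(np$summary$mean), 0.35)
  expect_gt(np$summary$variance, 0.55)
  expect_lt(np$summary$variance, 1.45)
})

test_that("Bland-Altman matches hand arithmetic in both scales", {
  # perfect agreement
  ba0 <- bland_altman(c(10, 20, 30), c(10, 20, 30))
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$lloa, 0)
  expect_equal(ba0$uloa, 0)

  # percent-of-pair-mean: pairs (10,8), (8,10)
  ba <- bland_altman(c(10, 8), c(8, 10))
  expect_equal(ba$bias, 0)
  sd_hand <- sd(c(100 * 2 / 9, -100 * 2 / 9))
  expect_equal(ba$uloa, 1.96 * sd_hand, tolerance = 1e-9)
  expect_equal(ba$uloa, 61.60, tolerance = 1e-3)

  # absolute scale with zero variance
  ba1 <- bland_altman(c(2, 3, 4), c(1, 2, 3), scale = "absolute")
  expect_equal(ba1$bias, 1)
  expect_equal(ba1$lloa, 1)
  expect_equal(ba1$uloa, 1)

  expect_warning(bland_altman(c(0, 5), c(0, 4)), "zero mean")
  expect_error(bland_altman(1, 2), ">= 2")
})

test_that("weighted bias and imprecision follow their definitions", {
  em0 <- error_model(C0 = 1, C1 = 0, gamma = 5) # constant SD 5
  r0 <- bias_imprecision(fake_records(c(10, 20), c(10, 20)), error_model = em0)
  expect_equal(r0$bias, 0)
  expect_equal(r0$imprecision, 0)
  # weighted errors +1 and -1: bias 0, sample variance 2
  r1 <- bias_imprecision(fake_records(c(15, 15), c(10, 20)), error_model = em0)
  expect_equal(r1$bias, 0)
  expect_equal(r1$imprecision, 2)
  # constant weighted error c
  r2 <- bias_imprecision(fake_records(c(15, 25), c(10, 20)), error_model = em0)
  expect_equal(r2$bias, 1)
  expect_equal(r2$imprecision, 0)
})

test_that("Bland-Altman absolute bias equals the MPE sign convention", {
  obs <- c(30, 50, 90); pred <- c(35, 45, 100)
  ba <- bland_altman(obs, pred, scale = "absolute")
  m <- mpe(prediction_errors(fake_records(obs, pred)))
  expect_equal(ba$bias, m$mpe)
})
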