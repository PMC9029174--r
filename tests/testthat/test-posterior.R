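make_point_fit <- function(support, use_covariate = FALSE) {
  structure(list(
    support = support, use_covariate = use_covariate, crcl_ref = 60,
    error_model = error_model()
  ), class = "npag_fit")
}

test_that("posterior follows Bayes' rule over the support points", {
  p <- ref_params()
  # single support point: posterior weight forced to 1
  fit1 <- make_point_fit(tibble::tibble(
    CL = p$CL, V = p$V, KCP = p$KCP, KPC = p$KPC, weight = 1
  ))
  tab <- one_subject_table()
  post <- individual_posterior(tab, fit1)
  expect_equal(post$posterior_weight, 1)

  # two points with equal prior: posterior proportional to the likelihoods
  fit2 <- make_point_fit(tibble::tibble(
    CL = c(2, 5), V = c(8, 20), KCP = c(1, 1.3), KPC = c(0.05, 0.1),
    weight = c(0.5, 0.5)
  ))
  post2 <- individual_posterior(tab, fit2)
  s <- pippk:::.split_subjects(tab)[[1]]
  ll <- pippk:::.loglik_rows(fit2$support[, 1:4], s, error_model())
  lik <- exp(ll - max(ll))
  expect_equal(post2$posterior_weight, lik / sum(lik), tolerance = 1e-12)
  expect_equal(sum(post2$posterior_weight), 1, tolerance = 1e-12)

  # identical likelihoods leave the prior untouched
  fit3 <- make_point_fit(tibble::tibble(
    CL = c(3, 3), V = c(10, 10), KCP = c(1, 1), KPC = c(0.1, 0.1),
    weight = c(0.3, 0.7)
  ))
  post3 <- individual_posterior(tab, fit3)
  expect_equal(post3$posterior_weight, c(0.3, 0.7), tolerance = 1e-12)
})

test_that("posterior computation survives extreme likelihood magnitudes", {
  # a subject whose data sit ~30 residual SDs from one support point:
  # the raw likelihood underflows but the log-domain update must not
  fit <- make_point_fit(tibble::tibble(
    CL = c(3.33, 0.4), V = c(10.69, 45), KCP = c(1.15, 4), KPC = c(0.08, 2),
    weight = c(0.5, 0.5)
  ))
  tab <- one_subject_table(obs_times = c(1, 3), obs = c(150, 140))
  post <- individual_posterior(tab, fit)
  expect_true(all(is.finite(post$posterior_weight)))
  expect_equal(sum(post$posterior_weight), 1, tolerance = 1e-12)
})

test_that("population and individual predictions are weighted means", {
  p <- ref_params()
  fit1 <- make_point_fit(tibble::tibble(
    CL = p$CL, V = p$V, KCP = p$KCP, KPC = p$KPC, weight = 1
  ))
  tab <- one_subject_table()
  recs <- predict_concentrations(tab, fit1)
  truth <- steady_state_profile(p, regimen(4000, 8, 0.5), times = c(1, 3))$conc
  expect_equal(recs$pop_pred, truth, tolerance = 1e-12)
  expect_equal(recs$ind_pred, truth, tolerance = 1e-12)

  # noise-free observations concentrate the posterior on the generating point
  fit2 <- make_point_fit(tibble::tibble(
    CL = c(3.33, 6), V = c(10.69, 25), KCP = c(1.15, 1.15), KPC = c(0.08, 0.08),
    weight = c(0.5, 0.5)
  ))
  tab2 <- one_subject_table(obs_times = c(1, 3), obs = truth)
  em_tight <- error_model(gamma = 0.2)
  recs2 <- predict_concentrations(tab2, fit2, error_model = em_tight)
  expect_lt(max(abs(recs2$ind_pred - truth) / truth), 1e-3)
})

test_that("individual predictions beat population predictions on average", {
  coh <- tiny_cohort(n = 20, seed = 14)
  fit <- npag_fit(coh, control = npag_control(max_cycles = 8), seed = 14)
  recs <- predict_concentrations(coh, fit)
  sse_ind <- sum((recs$obs - recs$ind_pred)^2)
  sse_pop <- sum((recs$obs - recs$pop_pred)^2)
  expect_lte(sse_ind, sse_pop)
})

test_that("posterior mean parameters summarise the posterior table", {
  fit <- make_point_fit(tibble::tibble(
    CL = c(2, 4), V = c(10, 20), KCP = c(1, 2), KPC = c(0.1, 0.2),
    weight = c(0.5, 0.5)
  ))
  tab <- one_subject_table()
  post <- individual_posterior(tab, fit)
  pm <- posterior_mean_params(post)
  w <- post$posterior_weight
  expect_equal(pm$CL, sum(w * c(2, 4)))
  expect_equal(pm$V, sum(w * c(10, 20)))
})
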