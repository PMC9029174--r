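test_that("hybrid rate constants satisfy their defining identities", {
  # one-compartment degeneracy
  ab <- macro_constants(pk_params(CL = 10, V = 10))
  expect_equal(unname(ab), c(1, 0))

  # quadratic-root oracle at the reference parameter set
  p <- ref_params()
  ke <- p$CL / p$V
  disc <- sqrt((ke + p$KCP + p$KPC)^2 - 4 * ke * p$KPC)
  ab <- macro_constants(p)
  expect_equal(unname(ab["alpha"]), (ke + p$KCP + p$KPC + disc) / 2, tolerance = 1e-10)
  expect_equal(unname(ab["beta"]), (ke + p$KCP + p$KPC - disc) / 2, tolerance = 1e-10)
  expect_equal(unname(ab["alpha"]), 1.5252, tolerance = 1e-4)
  expect_equal(unname(ab["beta"]), 0.01634, tolerance = 1e-3)

  # defining identities on random draws
  set.seed(2)
  for (i in 1:25) {
    p <- pk_params(runif(1, 0.5, 10), runif(1, 3, 40), runif(1, 0, 4), runif(1, 0, 4))
    ab <- macro_constants(p)
    ke <- p$CL / p$V
    expect_equal(sum(ab), ke + p$KCP + p$KPC, tolerance = 1e-10)
    expect_equal(prod(ab), ke * p$KPC, tolerance = 1e-8)
    expect_true(ab["alpha"] >= ab["beta"], label = "alpha >= beta")
  }
  expect_error(pk_params(CL = -1, V = 10), "CL")
  expect_error(pk_params(CL = 1, V = 0), "V")
})

test_that("closed-form profiles match elementary solutions", {
  # mono-exponential bolus
  pr <- simulate_profile(pk_params(CL = 5, V = 10), dose_events(0, 1000, 0), 2)
  expect_equal(pr$conc, 100 * exp(-1), tolerance = 1e-12)

  # mass balance with negligible elimination
  pr <- simulate_profile(pk_params(CL = 1e-9, V = 10), dose_events(0, 4000, 0.5), 0.5)
  expect_equal(pr$conc, 400, tolerance = 1e-6)

  # linearity in dose
  p <- ref_params()
  tt <- seq(0.25, 12, 0.25)
  c1 <- simulate_profile(p, dose_events(c(0, 6), 2000, 0.5), tt)$conc
  c2 <- simulate_profile(p, dose_events(c(0, 6), 4000, 0.5), tt)$conc
  expect_equal(c2, 2 * c1, tolerance = 1e-12)
  expect_true(all(c1 >= 0))
})

test_that("superposition: multi-dose profile is the sum of single-dose profiles", {
  p <- ref_params()
  tt <- seq(0.1, 20, 0.37)
  both <- simulate_profile(p, dose_events(c(0, 6), c(4000, 2000), c(0.5, 1)), tt)$conc
  d1 <- simulate_profile(p, dose_events(0, 4000, 0.5), tt)$conc
  d2 <- simulate_profile(p, dose_events(6, 2000, 1), tt)$conc
  expect_equal(both, d1 + d2, tolerance = 1e-12)
})

test_that("two-compartment profile converges to one compartment as KCP -> 0", {
  tt <- seq(0.1, 12, 0.1)
  one <- simulate_profile(pk_params(CL = 3.33, V = 10.69), dose_events(0, 4000, 0.5), tt)$conc
  two <- simulate_profile(pk_params(CL = 3.33, V = 10.69, KCP = 1e-10, KPC = 0.08),
                          dose_events(0, 4000, 0.5), tt)$conc
  expect_lt(max(abs(one - two)), 1e-6)
})

test_that("closed form matches the numeric ODE oracle on random draws", {
  set.seed(11)
  pop <- sample_population(NULL, n = 5, crcl = 60, seed = 11)
  d <- dose_events(c(0, 6, 12), 4000, 0.5)
  tt <- seq(0.2, 18, 0.4)
  for (i in 1:5) {
    p <- pk_params(pop$CL[i], pop$V[i], pop$KCP[i], pop$KPC[i])
    cf <- simulate_profile(p, d, tt)$conc
    oc <- ode_oracle_conc(p, d, tt)
    expect_lt(max(abs(cf - oc)) / max(cf), 1e-6)
  }
})

test_that("concentration is continuous across infusion start and stop", {
  p <- ref_params()
  eps <- 1e-9
  for (edge in c(0.5, 6)) { # end of infusion, next dose start
    cc <- simulate_profile(p, dose_events(c(0, 6), 4000, 0.5),
                           c(edge - eps, edge + eps))$conc
    expect_equal(cc[1], cc[2], tolerance = 1e-6)
  }
})

test_that("steady state reproduces the geometric accumulation of a bolus", {
  ke <- 0.3115
  p <- pk_params(CL = ke * 10, V = 10)
  single <- simulate_profile(p, dose_events(0, 1000, 0), 7.999)$conc
  ss <- steady_state_profile(p, regimen(1000, 8, 0), times = 7.999)$conc
  expect_equal(ss / single, 1 / (1 - exp(-ke * 8)), tolerance = 1e-4)
})

test_that("steady-state interval is periodic and matches a long run-in", {
  p <- ref_params()
  rg <- regimen(4000, 6, 0.5)
  tt <- seq(0, 6, 0.25)
  ss <- steady_state_profile(p, rg, times = tt)$conc
  expect_equal(ss[1], ss[length(tt)], tolerance = 1e-6) # trough(0) == trough(tau)

  n_doses <- 200 # terminal half-life ~42 h needs a long run-in
  runin <- simulate_profile(
    p, dose_events(seq(0, by = 6, length.out = n_doses), 4000, 0.5),
    (n_doses - 1) * 6 + tt
  )$conc
  expect_lt(max(abs(ss - runin) / max(ss)), 1e-3)

  # KPC = 0 branch: closed form vs run-in of the decoupled central compartment
  p1 <- pk_params(CL = 3, V = 12, KCP = 0.4, KPC = 0)
  ss1 <- steady_state_profile(p1, rg, times = tt)$conc
  runin1 <- simulate_profile(
    p1, dose_events(seq(0, by = 6, length.out = 40), 4000, 0.5), 39 * 6 + tt
  )$conc
  expect_lt(max(abs(ss1 - runin1) / max(ss1)), 1e-3)
})

test_that("invalid dose tables and regimens are rejected", {
  expect_error(dose_events(c(0, 0.2), 4000, c(0.5, 0.5)), "overlap")
  expect_error(dose_events(numeric(0), numeric(0), numeric(0)), "at least one")
  expect_error(dose_events(0, -5, 0), "positive")
  expect_error(regimen(4000, 6, 6), "duration")
  expect_error(simulate_profile(ref_params(), dose_events(0, 100, 0), -1), "non-negative")
})
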