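test_that("MIC distributions validate their grid and breakpoint", {
  d <- mic_distribution(c(1, 2, 4), c(10, 20, 5), breakpoint = 16)
  expect_equal(attr(d, "breakpoint"), 16)
  expect_error(mic_distribution(c(2, 1), c(1, 1)), "increasing")
  expect_error(mic_distribution(c(1, 2), c(-1, 1)), "counts")
  expect_error(mic_distribution(c(8, 16), c(1, 1), breakpoint = 2), "breakpoint")
  expect_error(pd_target(0), "fraction")
  expect_error(pd_target(0.5, fu = 1.2), "fu")
})

test_that("population sampling honours the covariate link and the moments", {
  # degenerate single support point: all draws identical
  fit <- structure(list(support = tibble::tibble(
    CL = 3, V = 10, KCP = 1, KPC = 0.1, weight = 1
  )), class = "npag_fit")
  s <- sample_population(fit, n = 50, crcl = 60, seed = 1)
  expect_equal(unique(s$TVCL), 3)
  expect_equal(unique(s$CL), 3)

  # law of large numbers against the matched log-normal moments
  big <- sample_population(NULL, n = 1e5, crcl = 60, seed = 2)
  expect_equal(mean(big$TVCL), 3.33, tolerance = 0.01)
  expect_equal(sd(big$TVCL), 1.24, tolerance = 0.02)
  expect_equal(mean(big$V), 10.69, tolerance = 0.01)

  # doubling CrCL doubles every clearance at the same seed
  a <- sample_population(NULL, n = 100, crcl = 60, seed = 3)
  b <- sample_population(NULL, n = 100, crcl = 120, seed = 3)
  expect_equal(b$CL, 2 * a$CL)
  expect_equal(b$TVCL, a$TVCL)
})

test_that("fT>MIC handles boundaries and matches a hand-solved crossing", {
  p <- ref_params()
  pr <- steady_state_profile(p, regimen(4000, 6, 0.5))
  expect_equal(ft_above_mic(pr, 0), 1)

  # free concentration 56 e^{-0.5 t} over tau = 6, MIC 7:
  # crossing at ln(8)/0.5, fraction = ln(8)/(0.5*6)
  decay <- tibble::tibble(time = seq(0, 6, 0.25), conc = 80 * exp(-0.5 * seq(0, 6, 0.25)))
  attr(decay, "cfun") <- function(t) 80 * exp(-0.5 * t)
  attr(decay, "tau") <- 6
  class(decay) <- c("pk_profile", class(decay))
  expect_equal(ft_above_mic(decay, 7, fu = 0.7), log(8) / 3, tolerance = 1e-5)

  # constant free concentration exactly at the MIC: strict inequality
  const <- tibble::tibble(time = seq(0, 6, 0.5), conc = 10)
  attr(const, "cfun") <- function(t) rep(10, length(t))
  attr(const, "tau") <- 6
  class(const) <- c("pk_profile", class(const))
  expect_equal(ft_above_mic(const, 7, fu = 0.7), 0)

  # grid fallback when no evaluator is attached
  plain <- tibble::tibble(time = seq(0, 6, 0.01), conc = 80 * exp(-0.5 * seq(0, 6, 0.01)))
  class(plain) <- c("pk_profile", class(plain))
  expect_equal(ft_above_mic(plain, 7, fu = 0.7), log(8) / 3, tolerance = 1e-3)
})

test_that("fT>MIC bisection agrees with a fine grid oracle", {
  rg <- regimen(4000, 6, 0.5)
  pop <- sample_population(NULL, n = 20, crcl = 90, seed = 9)
  grid <- seq(0, 6, by = 1e-4)
  for (i in 1:20) {
    pr <- steady_state_profile(
      pk_params(pop$CL[i], pop$V[i], pop$KCP[i], pop$KPC[i]), rg
    )
    cfun <- attr(pr, "cfun")
    for (mic in c(8, 64)) {
      expect_lt(abs(ft_above_mic(pr, mic) - mean(0.7 * cfun(grid) > mic)), 0.001)
    }
  }
})

test_that("PTA is monotone, deterministic and bounded", {
  rg <- regimen(4000, 6, 0.5)
  p1 <- pta(NULL, rg, crcl = 90, target = pd_target(0.5), n_sim = 200, seed = 5)
  expect_true(all(diff(p1$pta) <= 0)) # non-increasing in MIC
  expect_true(all(p1$pta >= 0 & p1$pta <= 1))
  p2 <- pta(NULL, rg, crcl = 90, target = pd_target(0.5), n_sim = 200, seed = 5)
  expect_identical(p1, p2) # bitwise reproducible at a fixed seed

  # a regimen overwhelming every MIC on the grid
  strong <- pta(NULL, regimen(4e5, 6, 0.5), crcl = 30,
                target = pd_target(0.5), mic_grid = c(1, 4, 16),
                n_sim = 100, seed = 1)
  expect_equal(strong$pta, rep(1, 3))
  expect_error(pta(NULL, rg, n_sim = 50), "at least 100")
})

test_that("FTA weights PTA by isolate frequency up to the breakpoint", {
  pta_tab <- tibble::tibble(
    mic = c(1, 8, 16, 32), pta = c(1, 0.5, 0, 0),
    dose = 4000, interval = 6, infusion_duration = 0.5, crcl = 60,
    target_fraction = 0.5, fu = 0.7, n_sim = 1000, seed = 1
  )
  class(pta_tab) <- c("pta_result", class(pta_tab))
  d <- mic_distribution(c(1, 8, 16), c(50, 30, 20), breakpoint = 16)
  f <- fta(pta_tab, d)
  expect_equal(f$fta_pct, 65)
  expect_false(f$optimal)

  # isolates above the breakpoint are excluded
  d2 <- mic_distribution(c(1, 8, 16, 32), c(50, 30, 20, 1000), breakpoint = 16)
  expect_equal(fta(pta_tab, d2)$fta_pct, 65)

  # full attainment
  pta_tab$pta <- 1
  expect_true(fta(pta_tab, d)$optimal)
  expect_equal(fta(pta_tab, d)$fta_pct, 100)

  # PTA missing at a required MIC
  d3 <- mic_distribution(c(1, 2), c(5, 5), breakpoint = 16)
  expect_error(fta(pta_tab, d3), "MIC")
})
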