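# Monte Carlo dosing simulation: PTA over MIC grids and FTA against an MIC
# frequency distribution, driven by the fT>MIC pharmacodynamic target for
# unbound piperacillin (fu = 0.70, i.e. 30% protein binding).

#' MIC frequency distribution
#'
#' @param mic MIC values, mg/L, strictly increasing and positive.
#' @param count Isolate counts (frequencies), `>= 0`.
#' @param breakpoint Clinical susceptibility breakpoint, mg/L (16 for
#'   *P. aeruginosa* and piperacillin); must lie within or above the MIC grid.
#' @return A `mic_distribution` tibble with the breakpoint as an attribute.
#' @export
mic_distribution <- function(mic, count, breakpoint = 16) {
  if (any(mic <= 0) || is.unsorted(mic, strictly = TRUE)) {
    stop("MIC values must be positive and strictly increasing")
  }
  if (any(count < 0)) stop("isolate counts must be >= 0")
  if (breakpoint < min(mic)) stop("breakpoint must lie within or above the MIC grid")
  out <- tibble::tibble(mic = mic, count = count)
  attr(out, "breakpoint") <- breakpoint
  class(out) <- c("mic_distribution", class(out))
  out
}

#' Read an MIC frequency table from CSV
#'
#' Expects columns `mic_mg_per_L` and `count`.
#'
#' @param path CSV path.
#' @inheritParams mic_distribution
#' @return A [mic_distribution()].
#' @export
read_mic_table <- function(path, breakpoint = 16) {
  raw <- utils::read.csv(path)
  need <- c("mic_mg_per_L", "count")
  if (!all(need %in% names(raw))) {
    stop("MIC table must have columns mic_mg_per_L and count")
  }
  raw <- raw[order(raw$mic_mg_per_L), ]
  mic_distribution(raw$mic_mg_per_L, raw$count, breakpoint = breakpoint)
}

#' Synthetic MIC distribution in the EUCAST style
#'
#' A synthetic stand-in for a wild-type-shaped *P. aeruginosa* piperacillin
#' MIC frequency distribution (doubling dilutions, mode at 4 mg/L, clinical
#' breakpoint 16 mg/L). Isolate counts are invented: use a current
#' surveillance distribution for real dosing decisions.
#'
#' @return A [mic_distribution()].
#' @export
synthetic_mic_pseudomonas <- function() {
  mic_distribution(
    mic = c(0.25, 0.5, 1, 2, 4, 8, 16, 32, 64),
    count = c(2, 12, 120, 480, 900, 650, 310, 150, 60),
    breakpoint = 16
  )
}

#' Pharmacodynamic target
#'
#' @param fraction Required fraction of the dosing interval with unbound
#'   concentration above the MIC: `0.5` (50% fT>MIC) or `1.0` (100% fT>MIC),
#'   or any value in (0, 1].
#' @param fu Unbound drug fraction (0.70 for piperacillin: 30% protein
#'   binding).
#' @return A list of class `pd_target`.
#' @export
pd_target <- function(fraction = 0.5, fu = 0.70) {
  if (fraction <= 0 || fraction > 1) stop("`fraction` must be in (0, 1]")
  if (fu <= 0 || fu > 1) stop("`fu` must be in (0, 1]")
  structure(list(fraction = fraction, fu = fu), class = "pd_target")
}

#' Sample parameter sets from the population model
#'
#' Draws `n` structural parameter sets and applies the renal covariate link
#' `CL = TVCL * (CRCL/60)` at the requested creatinine-clearance scenario.
#' With an `npag_fit` the support points are resampled by weight
#' (`mode = "support"`); `mode = "moments"` instead draws each parameter from
#' an independent log-normal matched to the population mean/SD (defaults:
#' [pip_population_moments()]), so dosing simulations can run without a fit.
#'
#' @param prior An [npag_fit()], or a moments tibble (`parameter`, `mean`,
#'   `sd`), or `NULL` for the default moments.
#' @param n Number of draws.
#' @param crcl Creatinine-clearance scenario, mL/min/1.73 m^2.
#' @param seed Integer seed (draws are deterministic given the seed).
#' @param mode `"support"` or `"moments"` (auto-chosen from `prior`).
#' @param crcl_ref Covariate normalization point (default 60).
#' @return A tibble with `n` rows: `TVCL`, `CL`, `V`, `KCP`, `KPC`.
#' @export
sample_population <- function(prior = NULL, n = 1000, crcl = 60, seed = 1,
                              mode = NULL, crcl_ref = 60) {
  if (n < 1) stop("`n` must be >= 1")
  if (crcl <= 0) stop("`crcl` must be positive")
  if (is.null(mode)) {
    mode <- if (inherits(prior, "npag_fit")) "support" else "moments"
  }
  mode <- match.arg(mode, c("support", "moments"))
  withr::with_seed(seed, {
    if (mode == "support") {
      s <- prior$support
      if (is.null(s) || nrow(s) == 0) stop("prior has no support points")
      j <- sample.int(nrow(s), n, replace = TRUE, prob = s$weight)
      out <- tibble::tibble(TVCL = s$CL[j], V = s$V[j],
                            KCP = s$KCP[j], KPC = s$KPC[j])
    } else {
      mo <- prior %||% pip_population_moments()
      if (inherits(mo, "npag_fit")) mo <- mo$moments
      draw <- function(p) {
        m <- mo$mean[mo$parameter == p]
        s <- mo$sd[mo$parameter == p]
        if (!length(m)) stop(sprintf("moments table lacks parameter %s", p))
        if (s == 0) return(rep(m, n))
        sdlog <- sqrt(log(1 + (s / m)^2))
        meanlog <- log(m) - sdlog^2 / 2
        stats::rlnorm(n, meanlog, sdlog)
      }
      out <- tibble::tibble(TVCL = draw("CL"), V = draw("V"),
                            KCP = draw("KCP"), KPC = draw("KPC"))
    }
    dplyr::mutate(out, CL = apply_covariate(.data$TVCL, crcl, crcl_ref),
                  .after = "TVCL")
  })
}

#' Fraction of the dosing interval with unbound concentration above the MIC
#'
#' Computes `measure{t in [0, tau): fu * C(t) > MIC} / tau` for a steady-state
#' concentration profile. When the profile carries its closed-form evaluator
#' (profiles from [steady_state_profile()] do), threshold crossings are
#' located by bisection on the piecewise-exponential segments to a tolerance
#' of 1e-6 h; otherwise the sampled grid is interpolated linearly. The
#' inequality is strict: time at exactly the MIC does not count.
#'
#' @param profile A `pk_profile` over one dosing interval.
#' @param mic MIC, mg/L.
#' @param fu Unbound fraction.
#' @return Fraction in `[0, 1]`.
#' @export
ft_above_mic <- function(profile, mic, fu = 0.70) {
  stopifnot(inherits(profile, "pk_profile"))
  if (mic < 0) stop("`mic` must be >= 0")
  tau <- attr(profile, "tau")
  cfun <- attr(profile, "cfun")
  if (is.null(cfun) || is.na(tau)) {
    tau <- max(profile$time)
    return(.ft_grid(profile$time, fu * profile$conc, mic, tau))
  }
  .ft_bisect(function(t) fu * cfun(t), mic, tau)
}

# measure above threshold via exact evaluator + bisection at crossings;
# a precomputed scan (grid + free-concentration values) may be supplied so
# repeated calls at different MICs share one profile evaluation
.ft_bisect <- function(free_conc, mic, tau, n_scan = 201, tol = 1e-6,
                       grid = NULL, fvals = NULL) {
  if (is.null(grid)) grid <- seq(0, tau, length.out = n_scan)
  if (is.null(fvals)) fvals <- free_conc(grid)
  if (mic == 0) {
    # strict inequality; a positive profile is above MIC 0 everywhere
    return(mean(fvals > 0))
  }
  above <- fvals - mic > 0
  n_scan <- length(grid)
  # refine each sign change
  crossings <- c()
  for (i in seq_len(n_scan - 1)) {
    if (above[i] != above[i + 1]) {
      lo <- grid[i]; hi <- grid[i + 1]
      while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        if ((free_conc(mid) - mic > 0) == above[i]) lo <- mid else hi <- mid
      }
      crossings <- c(crossings, (lo + hi) / 2)
    }
  }
  pts <- c(0, crossings, tau)
  total <- 0
  for (i in seq_len(length(pts) - 1)) {
    mid <- (pts[i] + pts[i + 1]) / 2
    if (free_conc(mid) > mic) total <- total + (pts[i + 1] - pts[i])
  }
  total / tau
}

.ft_grid <- function(times, free_conc, mic, tau) {
  above <- free_conc > mic
  total <- 0
  for (i in seq_len(length(times) - 1)) {
    dt <- times[i + 1] - times[i]
    a <- above[i]; b <- above[i + 1]
    if (a && b) {
      total <- total + dt
    } else if (a != b) {
      # linear interpolation of the crossing
      f <- (mic - free_conc[i]) / (free_conc[i + 1] - free_conc[i])
      total <- total + if (a) f * dt else (1 - f) * dt
    }
  }
  total / tau
}

#' Probability of target attainment over an MIC grid
#'
#' Monte Carlo PTA: sample `n_sim` parameter sets from the population model at
#' a creatinine-clearance scenario, simulate one steady-state dosing interval
#' per draw, and report for each MIC the fraction of draws achieving the
#' fT>MIC target.
#'
#' @inheritParams sample_population
#' @param regimen A [regimen()].
#' @param target A [pd_target()].
#' @param mic_grid MIC grid, mg/L (default: doubling dilutions 0.0625-64).
#' @param n_sim Number of simulated subjects (>= 100).
#' @return A `pta_result` tibble: `mic`, `pta` in `[0, 1]`, plus scenario
#'   metadata columns (`dose`, `interval`, `infusion_duration`, `crcl`,
#'   `target_fraction`, `fu`, `n_sim`, `seed`).
#' @export
pta <- function(prior = NULL, regimen, crcl = 60, target = pd_target(0.5),
                mic_grid = 2^seq(-4, 6), n_sim = 1000, seed = 1,
                mode = NULL) {
  if (n_sim < 100) stop("`n_sim` must be at least 100")
  stopifnot(inherits(regimen, "pk_regimen"), inherits(target, "pd_target"))
  pop <- sample_population(prior, n = n_sim, crcl = crcl, seed = seed, mode = mode)
  tau <- regimen$interval
  hits <- matrix(FALSE, n_sim, length(mic_grid))
  grid <- seq(0, tau, length.out = 201)
  for (i in seq_len(n_sim)) {
    cfun <- .ss_cfun(pop$CL[i], pop$V[i], pop$KCP[i], pop$KPC[i], regimen)
    free <- function(t) target$fu * cfun(t)
    fvals <- free(grid)
    for (j in seq_along(mic_grid)) {
      ft <- .ft_bisect(free, mic_grid[j], tau, grid = grid, fvals = fvals)
      hits[i, j] <- ft >= target$fraction
    }
  }
  out <- tibble::tibble(
    mic = mic_grid,
    pta = colMeans(hits),
    dose = regimen$dose, interval = regimen$interval,
    infusion_duration = regimen$infusion_duration,
    crcl = crcl, target_fraction = target$fraction, fu = target$fu,
    n_sim = n_sim, seed = seed
  )
  class(out) <- c("pta_result", class(out))
  out
}

# Single-parameter-set steady-state evaluator closure. All interval-invariant
# quantities (hybrid constants, periodic initial amounts, end-of-infusion
# state) are precomputed once; each evaluation is a few exponentials,
# vectorized over t. The Monte Carlo loop calls this once per draw.
.ss_cfun <- function(CL, V, KCP, KPC, regimen) {
  dose <- regimen$dose
  tau <- regimen$interval
  dur <- regimen$infusion_duration
  ke <- CL / V
  if (KPC <= 1e-10) {
    # peripheral return absent: central follows one-compartment kinetics
    k <- ke + KCP
    rate <- if (dur > 0) dose / dur else NA_real_
    a1s <- function(t) {
      if (dur <= 0) return(dose * exp(-k * t))
      ifelse(t <= dur, rate * .gexp(k, t),
             rate * .gexp(k, dur) * exp(-k * (t - dur)))
    }
    a0 <- a1s(tau) / (1 - exp(-k * tau))
    return(function(t) {
      t <- t %% tau
      pmax((a0 * exp(-k * t) + a1s(t)) / V, 0)
    })
  }
  ab <- .hybrid_constants(ke, KCP, KPC)
  al <- ab$alpha; be <- ab$beta
  # single-dose amounts at time u (scalar params, vector u); .mat_entries is
  # elementwise, so it vectorizes over time when the parameters are scalars
  single <- function(u) {
    if (dur <= 0) {
      E <- .mat_entries(ke, KCP, KPC, al, be, u, "E")
      return(list(a1 = E$e11 * dose, a2 = E$e21 * dose))
    }
    rate <- dose / dur
    a1 <- a2 <- numeric(length(u))
    inf <- u <= dur
    if (any(inf)) {
      P <- .mat_entries(ke, KCP, KPC, al, be, u[inf], "P")
      a1[inf] <- P$e11 * rate
      a2[inf] <- P$e21 * rate
    }
    if (any(!inf)) {
      Pd <- .mat_entries(ke, KCP, KPC, al, be, dur, "P")
      E <- .mat_entries(ke, KCP, KPC, al, be, u[!inf] - dur, "E")
      a1[!inf] <- E$e11 * Pd$e11 * rate + E$e12 * Pd$e21 * rate
      a2[!inf] <- E$e21 * Pd$e11 * rate + E$e22 * Pd$e21 * rate
    }
    list(a1 = a1, a2 = a2)
  }
  As <- single(tau)
  Et <- .mat_entries(ke, KCP, KPC, al, be, tau, "E")
  det <- (1 - Et$e11) * (1 - Et$e22) - Et$e12 * Et$e21
  a01 <- ((1 - Et$e22) * As$a1 + Et$e12 * As$a2) / det
  a02 <- (Et$e21 * As$a1 + (1 - Et$e11) * As$a2) / det
  function(t) {
    t <- t %% tau
    E <- .mat_entries(ke, KCP, KPC, al, be, t, "E")
    sng <- single(t)
    pmax((E$e11 * a01 + E$e12 * a02 + sng$a1) / V, 0)
  }
}

#' Fractional target attainment against an MIC distribution
#'
#' Weights the PTA curve by the isolate frequencies of an MIC distribution,
#' restricted to MICs at or below the clinical breakpoint:
#' `FTA% = 100 * sum PTA(MIC) * count(MIC) / sum count(MIC)`. A dose is
#' called optimal when FTA >= 85%.
#'
#' @param pta_result A [pta()] result; it must cover every distribution MIC
#'   at or below the breakpoint.
#' @param mic_dist A [mic_distribution()].
#' @param optimal_pct Optimality threshold, percent (default 85).
#' @return A one-row `fta_result` tibble: `fta_pct`, `optimal`, and the
#'   scenario metadata of the PTA run.
#' @export
fta <- function(pta_result, mic_dist, optimal_pct = 85) {
  stopifnot(inherits(pta_result, "pta_result"), inherits(mic_dist, "mic_distribution"))
  bp <- attr(mic_dist, "breakpoint")
  d <- mic_dist[mic_dist$mic <= bp & mic_dist$count > 0, ]
  missing <- setdiff(d$mic, pta_result$mic)
  if (length(missing)) {
    stop("PTA not available at required MIC(s): ", paste(missing, collapse = ", "))
  }
  p <- pta_result$pta[match(d$mic, pta_result$mic)]
  fta_pct <- 100 * sum(p * d$count) / sum(d$count)
  out <- dplyr::bind_cols(
    tibble::tibble(fta_pct = fta_pct, optimal = fta_pct >= optimal_pct,
                   breakpoint = bp),
    dplyr::distinct(pta_result[, c("dose", "interval", "infusion_duration",
                                   "crcl", "target_fraction", "fu", "n_sim")])
  )
  class(out) <- c("fta_result", class(out))
  out
}
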