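# Shared fixtures: reference parameters, tiny cohorts, and independent
# oracles (brute-force simplex search, numeric ODE integration).

ref_params <- function() pk_params(CL = 3.33, V = 10.69, KCP = 1.15, KPC = 0.08)

# numeric ODE oracle for the two-compartment infusion system
ode_oracle_conc <- function(params, doses, times) {
  rhs <- function(t, y, parms) {
    rate <- 0
    for (i in seq_len(nrow(doses))) {
      if (doses$duration[i] > 0 &&
          t >= doses$start_time[i] &&
          t < doses$start_time[i] + doses$duration[i]) {
        rate <- rate + doses$amount[i] / doses$duration[i]
      }
    }
    ke <- params$CL / params$V
    list(c(
      rate - (ke + params$KCP) * y[1] + params$KPC * y[2],
      params$KCP * y[1] - params$KPC * y[2]
    ))
  }
  breaks <- sort(unique(c(0, times, doses$start_time,
                          doses$start_time + doses$duration)))
  out <- deSolve::lsoda(c(0, 0), breaks, rhs, NULL, rtol = 1e-10, atol = 1e-10)
  stats::approx(out[, 1], out[, 2], xout = times)$y / params$V
}

# exhaustive simplex search oracle for the mixing-weight subproblem
brute_force_weights <- function(L, step = 1e-3) {
  m <- ncol(L)
  stopifnot(m %in% c(2, 3))
  g <- seq(0, 1, by = step)
  if (m == 2) {
    W <- cbind(g, 1 - g)
  } else {
    W <- do.call(rbind, lapply(g, function(a) {
      b <- g[g <= 1 - a + 1e-12]
      cbind(a, b, 1 - a - b)
    }))
    W[W < 0] <- 0
  }
  obj <- colSums(log(L %*% t(W)))
  best <- which.max(obj)
  list(weights = W[best, ], objective = obj[best])
}

# bundled likelihood matrices exercising the weight optimizer
toy_likelihood_matrices <- function() {
  set.seed(401)
  list(
    identity2 = rbind(c(1, 0), c(0, 1)),
    dominated = rbind(c(0.2, 0.9), c(0.1, 0.8), c(0.3, 0.9)),
    random2 = matrix(stats::runif(8, 0.05, 1), 4, 2),
    random3 = matrix(stats::runif(15, 0.05, 1), 5, 3),
    peaked3 = rbind(c(1, 1e-3, 1e-3), c(1e-3, 1, 1e-3), c(1e-3, 1e-3, 1))
  )
}

# a tiny steady-state cohort that fits in well under a second
tiny_cohort <- function(n = 8, seed = 1) {
  generate_cohort(cohort_design(n_subjects = n), seed = seed)
}

# single-subject steady-state event table with explicit values
one_subject_table <- function(obs_times = c(1, 3), obs = c(80, 60),
                              crcl = 60, dose = 4000, tau = 8, dur = 0.5) {
  tibble::tibble(
    ID = "A",
    EVID = c(1, rep(0, length(obs_times))),
    TIME = c(0, obs_times),
    AMT = c(dose, rep(NA, length(obs_times))),
    DUR = c(dur, rep(NA, length(obs_times))),
    SS = c(1, rep(NA, length(obs_times))),
    II = c(tau, rep(NA, length(obs_times))),
    OUT = c(NA, obs),
    CRCL = crcl
  )
}
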