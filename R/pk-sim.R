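# Closed-form evaluation of the linear one/two-compartment system with
# zero-order (infusion) input.
#
# State: amounts A1 (central), A2 (peripheral), with
#   dA1/dt = R(t) - (ke + KCP) A1 + KPC A2
#   dA2/dt = KCP A1 - KPC A2,          ke = CL/V,  C = A1 / V.
# The system matrix M has eigenvalues -alpha, -beta; by Lagrange interpolation
#   exp(M t)     = [f(alpha,t) (M + beta I) - f(beta,t) (M + alpha I)] / (beta - alpha)
#   int_0^t exp(M s) ds uses g(lambda,t) = (1 - exp(-lambda t))/lambda in place of f.
# Both forms are valid for beta = 0 (g has a finite limit), so the only guarded
# degeneracy is the repeated root (see .hybrid_constants) and the absence of a
# periodic steady state when KPC = 0 (handled by a one-compartment branch on A1,
# whose kinetics decouple from the peripheral compartment in that case).

.fexp <- function(lambda, t) exp(-lambda * t)

# (1 - exp(-lambda t)) / lambda, stable near lambda t = 0 (limit t)
.gexp <- function(lambda, t) {
  x <- lambda * t
  out <- ifelse(abs(x) < 1e-8, t * (1 - x / 2), -expm1(-x) / lambda)
  # lambda exactly 0 with t = 0 gives NaN above
  out[t == 0] <- 0
  out
}

# Entries of exp(M t) (kind = "E") or int_0^t exp(M s) ds (kind = "P"),
# vectorized over parameter vectors for scalar time t.
.mat_entries <- function(ke, kcp, kpc, alpha, beta, t, kind = c("E", "P")) {
  kind <- match.arg(kind)
  m11 <- -(ke + kcp)
  m22 <- -kpc
  if (kind == "E") {
    fa <- .fexp(alpha, t)
    fb <- .fexp(beta, t)
  } else {
    fa <- .gexp(alpha, t)
    fb <- .gexp(beta, t)
  }
  den <- beta - alpha
  list(
    e11 = (fa * (m11 + beta) - fb * (m11 + alpha)) / den,
    e12 = (fa - fb) * kpc / den,
    e21 = (fa - fb) * kcp / den,
    e22 = (fa * (m22 + beta) - fb * (m22 + alpha)) / den
  )
}

.mat_apply <- function(E, a1, a2) {
  list(
    a1 = E$e11 * a1 + E$e12 * a2,
    a2 = E$e21 * a1 + E$e22 * a2
  )
}

# Amounts at time u (>= 0) after a single dose administered at u = 0 into a
# drug-free system. Vectorized over parameters, scalar u.
.single_dose_amounts <- function(ke, kcp, kpc, alpha, beta, amount, duration, u) {
  n <- length(ke)
  if (u <= 0) return(list(a1 = rep(0, n), a2 = rep(0, n)))
  if (duration <= 0) { # bolus
    E <- .mat_entries(ke, kcp, kpc, alpha, beta, u, "E")
    return(.mat_apply(E, amount, 0))
  }
  rate <- amount / duration
  if (u <= duration) {
    P <- .mat_entries(ke, kcp, kpc, alpha, beta, u, "P")
    return(list(a1 = P$e11 * rate, a2 = P$e21 * rate))
  }
  Pd <- .mat_entries(ke, kcp, kpc, alpha, beta, duration, "P")
  E <- .mat_entries(ke, kcp, kpc, alpha, beta, u - duration, "E")
  .mat_apply(E, Pd$e11 * rate, Pd$e21 * rate)
}

#' Dose event table
#'
#' Build a table of dosing events. `duration = 0` denotes an instantaneous
#' bolus; otherwise the amount is infused at a constant rate over
#' `[start_time, start_time + duration]`.
#'
#' @param start_time Start times in hours (non-negative, vectorized).
#' @param amount Dose amounts in mg (positive).
#' @param duration Infusion durations in hours (`>= 0`).
#' @return A tibble with columns `start_time`, `amount`, `duration`, sorted by
#'   `start_time`.
#' @examples
#' dose_events(start_time = c(0, 8, 16), amount = 4000, duration = 0.5)
#' @export
dose_events <- function(start_time, amount, duration = 0) {
  d <- tibble::tibble(
    start_time = as.numeric(start_time),
    amount = as.numeric(amount),
    duration = as.numeric(duration)
  )
  if (nrow(d) == 0) stop("dose table must contain at least one event")
  if (any(!is.finite(d$start_time)) || any(d$start_time < 0)) {
    stop("dose start times must be finite and non-negative")
  }
  if (any(d$amount <= 0)) stop("dose amounts must be positive (mg)")
  if (any(d$duration < 0)) stop("infusion durations must be >= 0 (h)")
  d <- dplyr::arrange(d, .data$start_time)
  ends <- d$start_time + d$duration
  if (nrow(d) > 1 && any(d$start_time[-1] < ends[-nrow(d)] - 1e-12)) {
    stop("overlapping infusions: each dose must start after the previous infusion ends")
  }
  d
}

#' Dosing regimen
#'
#' A repeated intermittent-infusion regimen: `dose` mg infused over
#' `infusion_duration` h at the start of every `interval`-h dosing interval.
#'
#' @param dose Dose per administration, mg.
#' @param interval Dosing interval tau, h.
#' @param infusion_duration Infusion duration, h; must be shorter than the
#'   interval. `0` denotes a bolus.
#' @return An object of class `pk_regimen`.
#' @examples
#' regimen(dose = 4000, interval = 6, infusion_duration = 0.5)
#' @export
regimen <- function(dose, interval, infusion_duration = 0.5) {
  if (!is.finite(dose) || dose <= 0) stop("`dose` must be positive (mg)")
  if (!is.finite(interval) || interval <= 0) stop("`interval` must be positive (h)")
  if (!is.finite(infusion_duration) || infusion_duration < 0 ||
      infusion_duration >= interval) {
    stop("`infusion_duration` must satisfy 0 <= duration < interval")
  }
  structure(
    list(dose = dose, interval = interval, infusion_duration = infusion_duration),
    class = "pk_regimen"
  )
}

#' @export
print.pk_regimen <- function(x, ...) {
  cat(sprintf(
    "<pk_regimen> %.4g mg every %.4g h, infused over %.4g h\n",
    x$dose, x$interval, x$infusion_duration
  ))
  invisible(x)
}

.new_profile <- function(times, conc, cfun = NULL, tau = NA_real_) {
  out <- tibble::tibble(time = times, conc = conc)
  attr(out, "cfun") <- cfun
  attr(out, "tau") <- tau
  class(out) <- c("pk_profile", class(out))
  out
}

#' Simulate a concentration-time profile
#'
#' Evaluates the closed-form solution of the compartment model under an
#' arbitrary sequence of bolus/infusion dose events, starting from a drug-free
#' system, by superposition of single-dose solutions.
#'
#' @param params A [pk_params()] object.
#' @param doses A dose table from [dose_events()] (or a data frame with
#'   `start_time`, `amount`, `duration` columns).
#' @param times Numeric vector of evaluation times, h (non-negative).
#' @return A `pk_profile` tibble with columns `time` (h) and `conc` (mg/L,
#'   total drug in the central compartment).
#' @examples
#' p <- pk_params(CL = 3.33, V = 10.69, KCP = 1.15, KPC = 0.08)
#' simulate_profile(p, dose_events(0, 4000, 0.5), times = seq(0, 8, 0.25))
#' @export
simulate_profile <- function(params, doses, times) {
  stopifnot(inherits(params, "pk_params"))
  doses <- dose_events(doses$start_time, doses$amount, doses$duration)
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("`times` must be finite and non-negative")
  }
  ke <- params$CL / params$V
  ab <- .hybrid_constants(ke, params$KCP, params$KPC)
  conc <- vapply(times, function(t) {
    a1 <- 0
    for (i in seq_len(nrow(doses))) {
      u <- t - doses$start_time[i]
      if (u > 0) {
        a <- .single_dose_amounts(
          ke, params$KCP, params$KPC, ab$alpha, ab$beta,
          doses$amount[i], doses$duration[i], u
        )
        a1 <- a1 + a$a1
      }
    }
    a1 / params$V
  }, numeric(1))
  .new_profile(times, pmax(conc, 0))
}

# Steady-state central/peripheral amounts at interval start, vectorized over
# parameter vectors. Returns list(a1, a2) plus the single-dose closure pieces.
.ss_initial_amounts <- function(ke, kcp, kpc, alpha, beta, dose, tau, dur) {
  As <- .single_dose_amounts(ke, kcp, kpc, alpha, beta, dose, dur, tau)
  E <- .mat_entries(ke, kcp, kpc, alpha, beta, tau, "E")
  det <- (1 - E$e11) * (1 - E$e22) - E$e12 * E$e21
  a01 <- ((1 - E$e22) * As$a1 + E$e12 * As$a2) / det
  a02 <- (E$e21 * As$a1 + (1 - E$e11) * As$a2) / det
  list(a1 = a01, a2 = a02)
}

# Steady-state concentration at times (vector, folded into [0, tau)) for
# parameter VECTORS; returns a length(CL) x length(times) matrix. This is the
# Monte Carlo workhorse.
.ss_conc_matrix <- function(CL, V, KCP, KPC, dose, tau, dur, times) {
  n <- length(CL)
  ke <- CL / V
  tmod <- times %% tau
  out <- matrix(0, n, length(times))

  deg <- KPC <= 1e-10 | ke <= 0
  if (any(deg & ke <= 0)) stop("steady state requires CL > 0")

  if (any(!deg)) {
    i <- which(!deg)
    ab <- .hybrid_constants(ke[i], KCP[i], KPC[i])
    a0 <- .ss_initial_amounts(ke[i], KCP[i], KPC[i], ab$alpha, ab$beta, dose, tau, dur)
    for (j in seq_along(tmod)) {
      t <- tmod[j]
      E <- .mat_entries(ke[i], KCP[i], KPC[i], ab$alpha, ab$beta, t, "E")
      hom <- .mat_apply(E, a0$a1, a0$a2)
      sng <- .single_dose_amounts(ke[i], KCP[i], KPC[i], ab$alpha, ab$beta, dose, dur, t)
      out[i, j] <- (hom$a1 + sng$a1) / V[i]
    }
  }
  if (any(deg)) {
    # KPC = 0: the peripheral compartment never returns drug; central amount
    # follows one-compartment kinetics with rate ke + KCP.
    i <- which(deg)
    k <- ke[i] + KCP[i]
    rate <- if (dur > 0) dose / dur else NA_real_
    a1_single <- function(t) {
      if (dur <= 0) return(dose * exp(-k * t))
      ifelse(t <= dur,
        rate * .gexp(k, t),
        rate * .gexp(k, dur) * exp(-k * (t - dur))
      )
    }
    a0 <- a1_single(tau) / (1 - exp(-k * tau))
    for (j in seq_along(tmod)) {
      t <- tmod[j]
      out[i, j] <- (a0 * exp(-k * t) + a1_single(t)) / V[i]
    }
  }
  pmax(out, 0)
}

#' Steady-state concentration profile over one dosing interval
#'
#' Evaluates the periodic steady state of a repeated intermittent-infusion
#' regimen in closed form (periodic initial conditions from the single-interval
#' solution), without simulating a run-in.
#'
#' @param params A [pk_params()] object; `CL` must be positive.
#' @param regimen A [regimen()] object.
#' @param times Evaluation times in h; values outside `[0, interval)` are
#'   folded into the interval by periodicity. Default: a 201-point grid over
#'   one interval.
#' @return A `pk_profile` tibble (`time`, `conc`). The profile carries the
#'   exact closed-form evaluator as an attribute, used by [ft_above_mic()] for
#'   threshold-crossing bisection.
#' @examples
#' p <- pk_params(CL = 3.33, V = 10.69, KCP = 1.15, KPC = 0.08)
#' ss <- steady_state_profile(p, regimen(4000, 6, 0.5))
#' head(ss)
#' @export
steady_state_profile <- function(params, regimen,
                                 times = seq(0, regimen$interval, length.out = 201)) {
  stopifnot(inherits(params, "pk_params"), inherits(regimen, "pk_regimen"))
  tau <- regimen$interval
  cfun <- .ss_cfun(params$CL, params$V, params$KCP, params$KPC, regimen)
  .new_profile(times, cfun(times), cfun = cfun, tau = tau)
}
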