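#' Renal-function covariate link on clearance
#'
#' The final covariate model scales the typical-value clearance by normalized
#' creatinine clearance: `CL = TVCL * (CRCL / 60)`, so `TVCL` is the clearance
#' of a patient with CrCL 60 mL/min/1.73 m^2.
#'
#' @param TVCL Typical-value clearance, L/h.
#' @param CRCL Creatinine clearance, mL/min/1.73 m^2; must be positive.
#' @param reference Normalization point, mL/min/1.73 m^2 (default 60).
#' @return Individual clearance, L/h (vectorized).
#' @examples
#' apply_covariate(3.33, 120) # 6.66 L/h
#' @export
apply_covariate <- function(TVCL, CRCL, reference = 60) {
  if (any(CRCL <= 0)) stop("CRCL must be positive")
  if (any(TVCL <= 0)) stop("TVCL must be positive")
  TVCL * (CRCL / reference)
}

#' Parameter search box for the nonparametric fit
#'
#' @param CL,V,KCP,KPC Length-2 numeric `c(lower, upper)` bounds. When the
#'   covariate link is active, the `CL` bounds apply to `TVCL`.
#' @return An object of class `parameter_space`.
#' @export
parameter_space <- function(CL = c(0.3, 15), V = c(2, 50),
                            KCP = c(1e-3, 5), KPC = c(1e-3, 5)) {
  b <- list(CL = CL, V = V, KCP = KCP, KPC = KPC)
  for (nm in names(b)) {
    if (length(b[[nm]]) != 2 || any(b[[nm]] <= 0) || b[[nm]][1] >= b[[nm]][2]) {
      stop(sprintf("bounds for %s must be positive with lower < upper", nm))
    }
  }
  structure(b, class = "parameter_space")
}

# Apply the covariate link to a support-point parameter data frame for one
# subject, returning the individualized parameter data frame.
.individualize <- function(par, subject, use_covariate, crcl_ref) {
  if (!use_covariate) return(par)
  crcl <- subject$covariates$CRCL
  if (is.null(crcl) || is.na(crcl)) {
    stop(sprintf("subject %s: covariate model requires CRCL", subject$id))
  }
  par$CL <- apply_covariate(par$CL, crcl, crcl_ref)
  par
}

#' Log-likelihood of one subject's observations under fixed parameters
#'
#' Gaussian observation model on untransformed concentrations with
#' heteroscedastic residual SD evaluated at the model prediction:
#' `sum_k dnorm(obs_k; pred_k, SD(pred_k), log = TRUE)`.
#'
#' @param subject A single-subject event table (one `ID`) or an element of the
#'   internal subject split.
#' @param params A [pk_params()] object (individual parameters; apply any
#'   covariate link first).
#' @param error_model An [error_model()].
#' @return The log-likelihood (scalar).
#' @export
subject_loglik <- function(subject, params, error_model = NULL) {
  if (is.null(error_model)) error_model <- error_model()
  if (is.data.frame(subject)) {
    subs <- .split_subjects(subject)
    if (length(subs) != 1) stop("`subject` must contain exactly one ID")
    subject <- subs[[1]]
  }
  stopifnot(inherits(params, "pk_params"))
  par <- tibble::tibble(CL = params$CL, V = params$V,
                        KCP = params$KCP, KPC = params$KPC)
  ll <- .loglik_rows(par, subject, error_model)
  if (!is.finite(ll)) {
    stop(sprintf("non-finite log-likelihood for subject %s (CL=%g, V=%g)",
                 subject$id, params$CL, params$V))
  }
  ll
}

# Log-likelihood of a subject under each row of a parameter data frame.
# The residual SD polynomial is evaluated at the model prediction, which makes
# the observation model a correctly specified heteroscedastic Gaussian when
# data are generated with noise scaled to the true concentration. (Evaluating
# the SD at the observed value instead over-weights randomly low observations
# and biases clearance upward under strong residual noise.)
.loglik_rows <- function(par, subject, error_model) {
  if (nrow(subject$obs) == 0) {
    stop(sprintf("subject %s has no observations", subject$id))
  }
  pred <- .predict_conc_matrix(par, subject)
  sd <- residual_sd(pred, error_model)
  rowSums(stats::dnorm(
    matrix(subject$obs$conc, nrow(pred), ncol(pred), byrow = TRUE),
    mean = pred, sd = sd, log = TRUE
  ))
}

# subjects x points matrix of log-likelihoods.
.loglik_matrix <- function(subjects, par, error_model, use_covariate, crcl_ref) {
  t(vapply(subjects, function(s) {
    .loglik_rows(.individualize(par, s, use_covariate, crcl_ref), s, error_model)
  }, numeric(nrow(par))))
}

#' Mixing weights of a discrete population distribution
#'
#' Solves the convex subproblem of nonparametric maximum likelihood: given a
#' matrix `L` of per-subject likelihoods at candidate support points, maximize
#' `sum_i log(sum_j w_j L[i, j])` over the probability simplex, by
#' expectation-maximization (multiplicative) updates, which increase the
#' objective monotonically.
#'
#' @param L Numeric matrix, subjects in rows, support points in columns;
#'   entries are (possibly row-scaled) likelihoods, `>= 0`, each row with at
#'   least one positive entry.
#' @param tol Relative objective-change convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @param w_init Optional initial weights (defaults to uniform).
#' @return A list with `weights`, `objective` (the maximized sum of row log
#'   mixture likelihoods of the scaled matrix), `iterations`, `converged`.
#' @examples
#' optimize_weights(rbind(c(1, 0), c(0, 1)))$weights # 0.5, 0.5
#' @export
optimize_weights <- function(L, tol = 1e-8, max_iter = 2000, w_init = NULL) {
  L <- as.matrix(L)
  if (any(L < 0) || any(!is.finite(L))) stop("likelihood matrix must be finite and >= 0")
  rmax <- apply(L, 1, max)
  zero_rows <- which(rmax == 0)
  if (length(zero_rows)) {
    stop("subject(s) ", paste(zero_rows, collapse = ", "),
         " have zero likelihood at every support point (data incompatible with grid)")
  }
  Ls <- L / rmax
  m <- ncol(Ls)
  w <- if (is.null(w_init)) rep(1 / m, m) else w_init / sum(w_init)
  obj <- function(w) sum(log(Ls %*% w))
  prev <- obj(w)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    denom <- as.vector(Ls %*% w)
    w <- w * as.vector(crossprod(Ls, 1 / denom)) / nrow(Ls)
    w <- w / sum(w)
    cur <- obj(w)
    if (abs(cur - prev) <= tol * (abs(prev) + 1e-12)) {
      converged <- TRUE
      prev <- cur
      break
    }
    prev <- cur
  }
  list(weights = w, objective = prev, iterations = it, converged = converged)
}

#' Information criteria for a population fit
#'
#' `AIC = -2LL + 2p`, `BIC = -2LL + p * log(n_obs)`. By the package's
#' convention `p` counts the structural parameters of a support point plus any
#' estimated error parameters; the number of support points is not penalized.
#'
#' @param minus2LL Minus twice the maximized log-likelihood.
#' @param p Number of penalized parameters.
#' @param n_obs Total number of observations.
#' @return A tibble with columns `AIC` and `BIC`.
#' @examples
#' fit_metrics(100, p = 4, n_obs = 24)
#' @export
fit_metrics <- function(minus2LL, p, n_obs) {
  stopifnot(p > 0, n_obs > 0)
  tibble::tibble(AIC = minus2LL + 2 * p, BIC = minus2LL + p * log(n_obs))
}

#' Control settings for the adaptive-grid fit
#'
#' @param n_init Initial number of quasi-random (Latin hypercube) grid points;
#'   default `20 * 2^4` for the four-parameter model.
#' @param delta_start,delta_min Initial and final perturbation radius of the
#'   adaptive refinement, as a fraction of each parameter's range. The radius
#'   halves whenever a cycle no longer improves the likelihood at the current
#'   resolution; the fit stops once it reaches `delta_min` and the objective
#'   has stabilized.
#' @param prune_rel Support points with weight below `prune_rel * max(weight)`
#'   are dropped each cycle.
#' @param max_cycles Hard cap on refinement cycles.
#' @param em_tol,em_max_iter Convergence settings of the weight solver.
#' @param min_weight Weight threshold for reporting a support point in the
#'   final distribution.
#' @param n_explore Fresh quasi-random candidate points added per cycle in
#'   addition to the local perturbations (0 disables global exploration).
#' @param n_polish Rounds of post-convergence mixture-EM polish, in which
#'   each support point is moved to a local optimum of its
#'   responsibility-weighted likelihood (0 disables).
#' @return A list of class `npag_control`.
#' @export
npag_control <- function(n_init = 320, delta_start = 0.2, delta_min = 0.001,
                         prune_rel = 1e-8, max_cycles = 50,
                         em_tol = 1e-8, em_max_iter = 2000,
                         min_weight = 1e-6, n_explore = 64, n_polish = 1) {
  structure(as.list(environment()), class = "npag_control")
}

# The search works in unit log coordinates: u = log(x/lo) / log(hi/lo).
# PK parameters are positive scale parameters, so candidate density and
# perturbation steps are geometric rather than additive.
.scale_box <- function(u, space) {
  nm <- c("CL", "V", "KCP", "KPC")
  cols <- lapply(seq_along(nm), function(i) {
    lo <- space[[nm[i]]][1]; hi <- space[[nm[i]]][2]
    lo * (hi / lo)^u[, i]
  })
  tibble::as_tibble(stats::setNames(cols, nm))
}

# unit log-box coordinates rounded to 9 decimals; used for deduplication and
# condensation distances
.unit_coords <- function(par, space, ranges) {
  m <- as.matrix(par[, c("CL", "V", "KCP", "KPC")])
  lo <- vapply(c("CL", "V", "KCP", "KPC"), function(p) space[[p]][1], numeric(1))
  hi <- vapply(c("CL", "V", "KCP", "KPC"), function(p) space[[p]][2], numeric(1))
  round(sweep(sweep(log(m), 2, log(lo)), 2, log(hi / lo), "/"), 9)
}

#' Nonparametric adaptive-grid population fit
#'
#' Estimates the nonparametric maximum-likelihood population distribution of
#' `(CL|TVCL, V, KCP, KPC)` as a discrete set of weighted support points. A
#' quasi-random grid over the search box is refined by cycles of weight
#' optimization (EM), pruning of negligible-weight points, and local
#' perturbation of the survivors with a halving radius. The mixture
#' log-likelihood is non-decreasing across cycles.
#'
#' @param data A subject event table (see [read_subject_table()]) with at
#'   least two subjects.
#' @param space A [parameter_space()].
#' @param error_model An [error_model()]; fixed during the fit.
#' @param use_covariate If `TRUE` (default), the clearance axis is `TVCL` and
#'   each subject's clearance is `TVCL * CRCL/60` (requires a `CRCL` column).
#' @param crcl_ref CrCL normalization point, mL/min/1.73 m^2.
#' @param control An [npag_control()].
#' @param seed Integer seed; the fit is deterministic given the seed.
#' @return An object of class `npag_fit`: a list with `support` (tibble of
#'   support points and weights), `minus2LL`, `AIC`, `BIC`, `n_cycles`,
#'   `converged`, `cycle_minus2LL`, `moments` (weighted mean/SD/median/CV% per
#'   parameter), and the fit inputs needed by downstream posteriors.
#' @seealso [tidy.npag_fit()], [glance.npag_fit()], [individual_posterior()]
#' @export
npag_fit <- function(data, space = parameter_space(),
                     error_model = NULL,
                     use_covariate = TRUE, crcl_ref = 60,
                     control = npag_control(), seed = 1) {
  if (is.null(error_model)) error_model <- error_model()
  subjects <- .split_subjects(data)
  if (length(subjects) < 2) stop("the population fit needs at least 2 subjects")
  n_obs <- sum(vapply(subjects, function(s) nrow(s$obs), integer(1)))

  withr::local_seed(seed)
  par <- .scale_box(lhs::randomLHS(control$n_init, 4), space)
  logL <- .loglik_matrix(subjects, par, error_model, use_covariate, crcl_ref)
  # row-scaled likelihoods; offsets re-enter the objective additively
  offsets <- apply(logL, 1, max)
  if (any(!is.finite(offsets))) {
    stop("a subject has non-finite likelihood at every grid point; widen the search box")
  }
  sol <- optimize_weights(exp(logL - offsets), tol = control$em_tol,
                          max_iter = control$em_max_iter)
  total_ll <- function(sol_obj, offs) sol_obj + sum(offs)
  m2ll_trace <- -2 * total_ll(sol$objective, offsets)
  delta <- control$delta_start
  ranges <- vapply(c("CL", "V", "KCP", "KPC"), function(p) diff(space[[p]]), numeric(1))
  converged <- FALSE
  cycle <- 0L
  m2ll_at_exhaustion <- Inf

  nm <- c("CL", "V", "KCP", "KPC")
  # expand survivors with axis-aligned +/- delta perturbations, evaluate the
  # new points, and re-solve the weights warm-started from the survivors
  refine <- function(par_k, w_k, L_k, delta) {
    base_u <- .unit_coords(par_k, space, ranges)
    blocks <- lapply(seq_along(nm), function(a) {
      up <- dn <- base_u
      up[, a] <- pmin(up[, a] + delta, 1)
      dn[, a] <- pmax(dn[, a] - delta, 0)
      rbind(up, dn)
    })
    cand <- .scale_box(do.call(rbind, blocks), space)
    if (control$n_explore > 0) {
      # fresh quasi-random points keep the search global; a purely local
      # axis-aligned refinement can stall in a secondary mixture configuration
      cand <- dplyr::bind_rows(
        cand, .scale_box(lhs::randomLHS(control$n_explore, 4), space)
      )
    }
    all_par <- dplyr::bind_rows(par_k, cand)
    dup <- duplicated(.unit_coords(all_par, space, ranges))
    new_idx <- which(!dup & seq_len(nrow(all_par)) > nrow(par_k))
    if (length(new_idx)) {
      new_par <- all_par[new_idx, , drop = FALSE]
      L_new <- .loglik_matrix(subjects, new_par, error_model, use_covariate, crcl_ref)
      par <- dplyr::bind_rows(par_k, new_par)
      logL <- cbind(L_k, L_new)
    } else {
      par <- par_k
      logL <- L_k
    }
    offsets <- apply(logL, 1, max)
    w0 <- c(w_k, rep(1e-10, ncol(logL) - length(w_k)))
    sol <- optimize_weights(exp(logL - offsets), tol = control$em_tol,
                            max_iter = control$em_max_iter, w_init = w0)
    list(par = par, logL = logL, sol = sol,
         m2ll = -2 * total_ll(sol$objective, offsets))
  }

  while (cycle < control$max_cycles) {
    cycle <- cycle + 1L
    keep <- which(sol$weights >= control$prune_rel * max(sol$weights))
    ord <- keep[order(sol$weights[keep], decreasing = TRUE)]
    # condense near-duplicate support points (within 0.5% of each parameter
    # range, max-norm, merged into the heavier point): the EM solution leaves
    # clusters of near-tied neighbours that would otherwise accumulate
    uc <- .unit_coords(par[ord, , drop = FALSE], space, ranges)
    sel <- rep(TRUE, length(ord))
    w_m <- sol$weights[ord]
    for (i in seq_along(ord)[-1]) {
      d <- apply(abs(uc[seq_len(i - 1), , drop = FALSE] -
                       matrix(uc[i, ], i - 1, 4, byrow = TRUE)), 1, max)
      d[!sel[seq_len(i - 1)]] <- Inf
      j <- which.min(d)
      if (d[j] < 0.005) {
        sel[i] <- FALSE
        w_m[j] <- w_m[j] + w_m[i]
      }
    }
    res <- refine(par[ord[sel], , drop = FALSE], w_m[sel],
                  logL[, ord[sel], drop = FALSE], delta)
    if (res$m2ll > m2ll_trace[length(m2ll_trace)] + 1e-9 && any(!sel)) {
      # a condensation merge lost likelihood; redo this cycle without merging
      res <- refine(par[ord, , drop = FALSE], sol$weights[ord],
                    logL[, ord, drop = FALSE], delta)
    }
    par <- res$par
    logL <- res$logL
    sol <- res$sol
    m2ll_trace <- c(m2ll_trace, res$m2ll)
    n <- length(m2ll_trace)
    improved <- (m2ll_trace[n - 1] - m2ll_trace[n]) > 0.1
    if (!improved) {
      if (delta > control$delta_min) {
        # refinement at this radius is exhausted; sharpen
        delta <- max(delta / 2, control$delta_min)
      } else if (m2ll_at_exhaustion - m2ll_trace[n] > 0.1) {
        # the sweep down to delta_min improved the fit: re-expand the radius
        # and sweep again (escapes local refinement stalls)
        m2ll_at_exhaustion <- m2ll_trace[n]
        delta <- control$delta_start / 4
      } else {
        converged <- TRUE
        break
      }
    }
  }

  # mixture-EM polish: with weights (and responsibilities) fixed, move each
  # support point to a local optimum of its responsibility-weighted
  # likelihood (the M-step of the mixture EM). Axis-aligned grid refinement
  # cannot follow curved likelihood ridges; this closes that gap. To keep the
  # many objective evaluations cheap, subjects sharing a sampling design are
  # evaluated in one vectorized call (their individualized parameter rows
  # differ only through the covariate link).
  if (control$n_polish > 0) {
    sig <- vapply(subjects, function(s) {
      paste(vapply(s$occasions, function(o) {
        paste(
          paste(round(o$doses$start_time, 9), o$doses$amount, o$doses$duration,
                o$doses$ss, o$doses$interval, collapse = ";"),
          paste(round(o$obs$time, 9), collapse = ","), sep = "|"
        )
      }, character(1)), collapse = "||")
    }, character(1))
    gdata <- lapply(split(seq_along(subjects), sig), function(idx) {
      list(
        tmpl = subjects[[idx[1]]],
        obs = do.call(rbind, lapply(idx, function(i) subjects[[i]]$obs$conc)),
        crcl = vapply(idx, function(i) {
          cv <- subjects[[i]]$covariates$CRCL
          if (is.null(cv)) NA_real_ else as.numeric(cv)
        }, numeric(1)),
        idx = idx
      )
    })
    # plain lists in place of tibbles: this objective runs thousands of times
    subj_ll_at <- function(th) {
      out <- numeric(length(subjects))
      for (g in gdata) {
        ng <- length(g$idx)
        par1 <- list(
          CL = if (use_covariate) th$CL * g$crcl / crcl_ref else rep(th$CL, ng),
          V = rep(th$V, ng), KCP = rep(th$KCP, ng), KPC = rep(th$KPC, ng)
        )
        pred <- .predict_conc_matrix(par1, g$tmpl)
        sd <- residual_sd(pred, error_model)
        out[g$idx] <- rowSums(stats::dnorm(g$obs, pred, sd, log = TRUE))
      }
      out
    }
    lob <- vapply(nm, function(p) space[[p]][1], numeric(1))
    hib <- vapply(nm, function(p) space[[p]][2], numeric(1))
  }
  for (round in seq_len(control$n_polish)) {
    keep <- which(sol$weights >= 0.01)
    offsets <- apply(logL, 1, max)
    lik <- exp(logL - offsets)
    denom <- as.vector(lik %*% sol$weights)
    moved <- FALSE
    for (j in keep) {
      resp <- sol$weights[j] * lik[, j] / denom
      if (sum(resp) < 1e-8) next
      u0 <- as.numeric(.unit_coords(par[j, , drop = FALSE], space, ranges))
      theta_at <- function(u) {
        uc <- pmin(pmax(u, 0), 1)
        stats::setNames(as.list(lob * (hib / lob)^uc), nm)
      }
      negq <- function(u) -sum(resp * subj_ll_at(theta_at(u)))
      opt <- tryCatch(
        stats::optim(u0, negq, method = "Nelder-Mead",
                     control = list(maxit = 100, reltol = 1e-10)),
        error = function(e) NULL
      )
      if (!is.null(opt) && opt$value < negq(u0) - 1e-10) {
        th <- theta_at(opt$par)
        par[j, ] <- tibble::as_tibble(th)
        logL[, j] <- subj_ll_at(th)
        moved <- TRUE
      }
    }
    if (!moved) break
    offsets <- apply(logL, 1, max)
    sol <- optimize_weights(exp(logL - offsets), tol = control$em_tol,
                            max_iter = control$em_max_iter, w_init = sol$weights)
    # the M-step cannot decrease the mixture likelihood (EM inequality);
    # the appended value is the honest post-polish objective
    m2ll_trace <- c(m2ll_trace, -2 * total_ll(sol$objective, offsets))
  }

  keep <- sol$weights >= control$min_weight
  support <- dplyr::mutate(par[keep, , drop = FALSE],
                           weight = sol$weights[keep] / sum(sol$weights[keep]))
  support <- dplyr::arrange(support, dplyr::desc(.data$weight))
  m2ll <- m2ll_trace[length(m2ll_trace)]
  ic <- fit_metrics(m2ll, p = 4, n_obs = n_obs)

  fit <- structure(list(
    support = support,
    minus2LL = m2ll,
    AIC = ic$AIC, BIC = ic$BIC,
    n_cycles = cycle,
    converged = converged,
    cycle_minus2LL = m2ll_trace,
    n_subjects = length(subjects),
    n_obs = n_obs,
    use_covariate = use_covariate,
    crcl_ref = crcl_ref,
    error_model = error_model,
    space = space,
    seed = seed
  ), class = "npag_fit")
  fit$moments <- fit_moments(fit)
  fit
}

#' Weighted summary moments of a fitted population distribution
#'
#' @param fit An `npag_fit` object (or any list with a `support` tibble).
#' @return A tibble with one row per parameter: weighted `mean`, `sd`
#'   (probability-weighted, i.e. of the discrete distribution), `median`
#'   (weighted), and `cv_pct = 100 * sd / mean`.
#' @export
fit_moments <- function(fit) {
  s <- fit$support
  w <- s$weight / sum(s$weight)
  purrr::map_dfr(c("CL", "V", "KCP", "KPC"), function(p) {
    x <- s[[p]]
    m <- sum(w * x)
    sd <- sqrt(sum(w * (x - m)^2))
    ord <- order(x)
    cw <- cumsum(w[ord])
    med <- x[ord][which(cw >= 0.5)[1]]
    tibble::tibble(parameter = p, mean = m, sd = sd, median = med,
                   cv_pct = 100 * sd / m)
  })
}

#' @export
print.npag_fit <- function(x, ...) {
  cat(sprintf(
    "<npag_fit> %d subjects, %d observations, %d support points\n",
    x$n_subjects, x$n_obs, nrow(x$support)
  ))
  cat(sprintf("  -2LL %.2f | AIC %.2f | BIC %.2f | %d cycles%s\n",
              x$minus2LL, x$AIC, x$BIC, x$n_cycles,
              if (x$converged) "" else " (not converged)"))
  if (x$use_covariate) {
    cat(sprintf("  covariate model: CL = TVCL * (CRCL / %g)\n", x$crcl_ref))
  }
  print(x$moments)
  invisible(x)
}

#' Tidy a nonparametric population fit
#'
#' @param x An `npag_fit`.
#' @param what `"support"` (default) for the weighted support points,
#'   `"moments"` for the parameter summary moments.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.npag_fit <- function(x, what = c("support", "moments"), ...) {
  what <- match.arg(what)
  if (what == "support") x$support else x$moments
}

#' One-row fit summary
#'
#' @param x An `npag_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `minus2LL`, `AIC`, `BIC`, `n_support`,
#'   `n_cycles`, `converged`, `n_subjects`, `n_obs`.
#' @export
glance.npag_fit <- function(x, ...) {
  tibble::tibble(
    minus2LL = x$minus2LL, AIC = x$AIC, BIC = x$BIC,
    n_support = nrow(x$support), n_cycles = x$n_cycles,
    converged = x$converged, n_subjects = x$n_subjects, n_obs = x$n_obs
  )
}

#' Screen covariate-parameter relationships
#'
#' For each (parameter, covariate) pair, fits candidate regression shapes --
#' linear, log (`y ~ log x`), power (`log y ~ log x`), quadratic -- to the
#' per-subject posterior parameter estimates and ranks pairs by the best
#' coefficient of determination. Categorical covariates use a group-mean
#' (one-way) linear model. Constant covariates are skipped with a warning.
#'
#' @param posterior_params Tibble with column `id` and one column per
#'   structural parameter (e.g. from [posterior_mean_params()]).
#' @param covariates Tibble with column `id` and covariate columns.
#' @return A tibble (`parameter`, `covariate`, `form`, `r2`), sorted by
#'   decreasing `r2`.
#' @export
covariate_screen <- function(posterior_params, covariates) {
  dat <- dplyr::inner_join(posterior_params, covariates, by = "id")
  if (nrow(dat) < 6) stop("covariate screening needs at least 6 subjects")
  params <- setdiff(names(posterior_params), "id")
  covs <- setdiff(names(covariates), "id")
  constant <- covs[vapply(covs, function(cc) {
    length(unique(dat[[cc]][!is.na(dat[[cc]])])) < 2
  }, logical(1))]
  if (length(constant)) {
    warning("covariate(s) ", paste(constant, collapse = ", "),
            " constant; skipped")
    covs <- setdiff(covs, constant)
  }
  out <- purrr::map_dfr(params, function(p) {
    purrr::map_dfr(covs, function(cc) {
      y <- dat[[p]]
      x <- dat[[cc]]
      ok <- stats::complete.cases(y, x)
      y <- y[ok]; x <- x[ok]
      if (length(unique(x)) < 2) return(NULL) # constant after NA removal
      if (!is.numeric(x) || length(unique(x)) <= 3) {
        r2 <- summary(stats::lm(y ~ factor(x)))$r.squared
        return(tibble::tibble(parameter = p, covariate = cc,
                              form = "categorical", r2 = r2))
      }
      r2_of <- function(fml) suppressWarnings(summary(stats::lm(fml))$r.squared)
      forms <- list(
        linear = function() r2_of(y ~ x),
        quadratic = function() r2_of(y ~ x + I(x^2)),
        log = function() if (all(x > 0)) r2_of(y ~ log(x)) else NA,
        power = function() if (all(x > 0) && all(y > 0))
          r2_of(log(y) ~ log(x)) else NA
      )
      r2s <- vapply(forms, function(f) f(), numeric(1))
      best <- which.max(r2s)
      tibble::tibble(parameter = p, covariate = cc,
                     form = names(forms)[best], r2 = unname(r2s[best]))
    })
  })
  dplyr::arrange(out, dplyr::desc(.data$r2))
}
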