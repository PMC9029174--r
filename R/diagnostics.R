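#' Observed-versus-predicted regression
#'
#' Ordinary least squares of observed on predicted concentrations, with a
#' t-based 95% confidence interval for the slope. A well-specified model gives
#' slope near 1, intercept near 0 and r-squared near 1.
#'
#' @param records A prediction-record tibble from [predict_concentrations()]
#'   (columns `obs` and `pop_pred`/`ind_pred`).
#' @param which `"population"` or `"individual"` predictions.
#' @return A one-row tibble: `slope`, `intercept`, `r2`, `slope_lo`,
#'   `slope_hi` (95% CI), `n`.
#' @export
gof_regression <- function(records, which = c("population", "individual")) {
  which <- match.arg(which)
  pred <- if (which == "population") records$pop_pred else records$ind_pred
  obs <- records$obs
  if (length(obs) < 3) stop("goodness-of-fit regression needs at least 3 records")
  if (stats::sd(pred) == 0) stop("predictions are constant; r-squared undefined")
  m <- stats::lm(obs ~ pred)
  ci <- stats::confint(m, "pred", level = 0.95)
  tibble::tibble(
    slope = unname(stats::coef(m)[2]),
    intercept = unname(stats::coef(m)[1]),
    r2 = summary(m)$r.squared,
    slope_lo = ci[1], slope_hi = ci[2],
    n = length(obs)
  )
}

# Simulate n_sim replicate concentrations for every observation: resample a
# support point per replicate (per subject), predict at the observation times,
# add heteroscedastic residual noise. Returns list(records, sims) where sims is
# an n_obs x n_sim matrix aligned with rows of records.
.simulate_observations <- function(data, fit, error_model, n_sim, seed) {
  subjects <- .split_subjects(data)
  em <- error_model %||% fit$error_model
  support <- fit$support
  prior <- support$weight / sum(support$weight)
  withr::with_seed(seed, {
    sims <- list()
    recs <- list()
    for (s in subjects) {
      par <- .individualize(support[, c("CL", "V", "KCP", "KPC")], s,
                            isTRUE(fit$use_covariate), fit$crcl_ref %||% 60)
      pred <- .predict_conc_matrix(par, s) # points x obs
      j <- sample.int(nrow(support), n_sim, replace = TRUE, prob = prior)
      base <- pred[j, , drop = FALSE] # n_sim x n_obs
      noise <- matrix(stats::rnorm(length(base), 0, residual_sd(base, em)),
                      nrow(base), ncol(base))
      sims[[length(sims) + 1]] <- t(pmax(base + noise, 0)) # n_obs x n_sim
      recs[[length(recs) + 1]] <- tibble::tibble(
        id = s$id, occ = s$obs$occ, time = s$obs$time, obs = s$obs$conc
      )
    }
    list(records = dplyr::bind_rows(recs), sims = do.call(rbind, sims))
  })
}

#' Visual predictive check
#'
#' Simulates `n_sim` replicate datasets from the fitted population model
#' (support-point resampling plus residual error), summarizes the simulated
#' concentrations at each nominal observation time as 5th/50th/95th percentile
#' bands, and reports the fraction of observations falling inside their own
#' simulated 5th-95th interval. An adequate model keeps that coverage near
#' 0.90.
#'
#' @param data A subject event table.
#' @param fit An [npag_fit()] result.
#' @param error_model Overrides the fit's error model if supplied.
#' @param n_sim Number of simulated replicates per observation (>= 100).
#' @param seed Integer seed.
#' @return An object of class `vpc_result`: a list with `bands` (tibble of
#'   per-time simulated percentiles), `observations` (with an `inside` flag),
#'   and `coverage`.
#' @export
vpc <- function(data, fit, error_model = NULL, n_sim = 1000, seed = 1) {
  if (n_sim < 100) stop("`n_sim` must be at least 100 for a VPC")
  sim <- .simulate_observations(data, fit, error_model, n_sim, seed)
  q <- t(apply(sim$sims, 1, stats::quantile, probs = c(0.05, 0.5, 0.95)))
  obs <- dplyr::mutate(sim$records,
    q05 = q[, 1], q50 = q[, 2], q95 = q[, 3],
    inside = .data$obs >= .data$q05 & .data$obs <= .data$q95
  )
  # plotting bands: percentiles of all simulated values pooled per nominal
  # (occasion, time) bin
  key <- dplyr::distinct(sim$records[, c("occ", "time")])
  key <- dplyr::arrange(key, .data$occ, .data$time)
  bands <- purrr::map_dfr(seq_len(nrow(key)), function(i) {
    in_bin <- sim$records$occ == key$occ[i] & sim$records$time == key$time[i]
    pooled <- as.vector(sim$sims[in_bin, , drop = FALSE])
    qs <- stats::quantile(pooled, c(0.05, 0.5, 0.95))
    tibble::tibble(occ = key$occ[i], time = key$time[i],
                   q05 = qs[1], q50 = qs[2], q95 = qs[3], n = sum(in_bin))
  })
  structure(list(
    bands = bands, observations = obs,
    coverage = mean(obs$inside), n_sim = n_sim
  ), class = "vpc_result")
}

#' @export
print.vpc_result <- function(x, ...) {
  cat(sprintf(
    "<vpc_result> %d observations, n_sim = %d, coverage of 5th-95th band = %.3f\n",
    nrow(x$observations), x$n_sim, x$coverage
  ))
  invisible(x)
}

#' Normalized prediction distribution errors
#'
#' Each observation is ranked among its `n_sim` simulated replicates
#' (mid-rank convention for ties) and the rank quantile is mapped through the
#' standard-normal quantile function. Boundary observations outside the whole
#' simulated range map to `qnorm(1/(2 n_sim))` and its mirror, keeping values
#' finite. Under a correct model the npde are approximately standard normal.
#' No decorrelation across an individual's observations is applied (the
#' sparse designs targeted here carry at most a few points per subject); the
#' values are marginal rank-based prediction discrepancies.
#'
#' @inheritParams vpc
#' @param n_sim Number of simulated replicates (>= 500).
#' @return An object of class `npde_result`: list with `records` (per
#'   observation `npde`), and `summary` (mean, variance, Shapiro-Wilk
#'   statistic and p-value).
#' @export
npde <- function(data, fit, error_model = NULL, n_sim = 1000, seed = 1) {
  if (n_sim < 500) stop("`n_sim` must be at least 500 for npde")
  sim <- .simulate_observations(data, fit, error_model, n_sim, seed)
  u <- vapply(seq_len(nrow(sim$sims)), function(i) {
    x <- sim$sims[i, ]
    o <- sim$records$obs[i]
    (sum(x < o) + 0.5 * sum(x == o)) / n_sim
  }, numeric(1))
  u <- pmin(pmax(u, 1 / (2 * n_sim)), 1 - 1 / (2 * n_sim))
  records <- dplyr::mutate(sim$records, npde = stats::qnorm(u))
  sw <- tryCatch(stats::shapiro.test(records$npde),
                 error = function(e) list(statistic = NA_real_, p.value = NA_real_))
  structure(list(
    records = records,
    summary = tibble::tibble(
      mean = mean(records$npde),
      variance = stats::var(records$npde),
      shapiro_w = unname(sw$statistic),
      shapiro_p = sw$p.value,
      n = nrow(records), n_sim = n_sim
    )
  ), class = "npde_result")
}

#' @export
print.npde_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<npde_result> n = %d | mean %.3f | variance %.3f | Shapiro-Wilk W %.3f (p %.3g)\n",
    s$n, s$mean, s$variance, s$shapiro_w, s$shapiro_p
  ))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Mean difference (bias) and +/- 1.96 SD limits of agreement between
#' observed and predicted concentrations. In `"percent_of_mean"` mode the
#' per-pair difference is expressed as a percentage of the pair mean,
#' `100 * (obs - pred) / ((obs + pred) / 2)`; pairs with zero mean are
#' excluded with a warning.
#'
#' @param obs,pred Numeric vectors of paired values, or pass a
#'   prediction-record tibble as `obs` (then `pred` selects
#'   `"population"`/`"individual"`).
#' @param scale `"percent_of_mean"` or `"absolute"`.
#' @return An object of class `bland_altman`: tibble fields `bias`, `lloa`,
#'   `uloa`, `sd`, `n`, plus the per-pair `differences` tibble as an
#'   attribute.
#' @export
bland_altman <- function(obs, pred = c("individual", "population"),
                         scale = c("percent_of_mean", "absolute")) {
  scale <- match.arg(scale)
  if (is.data.frame(obs)) {
    which <- match.arg(pred)
    records <- obs
    obs <- records$obs
    pred <- if (which == "population") records$pop_pred else records$ind_pred
  }
  if (length(obs) != length(pred) || length(obs) < 2) {
    stop("Bland-Altman needs >= 2 paired values")
  }
  pair_mean <- (obs + pred) / 2
  if (scale == "percent_of_mean") {
    drop <- pair_mean == 0
    if (any(drop)) {
      warning(sprintf("%d pair(s) with zero mean excluded from percent differences",
                      sum(drop)))
      obs <- obs[!drop]; pred <- pred[!drop]; pair_mean <- pair_mean[!drop]
    }
    diffs <- 100 * (obs - pred) / pair_mean
  } else {
    diffs <- obs - pred
  }
  bias <- mean(diffs)
  s <- stats::sd(diffs)
  out <- tibble::tibble(
    bias = bias, sd = s,
    lloa = bias - 1.96 * s, uloa = bias + 1.96 * s,
    n = length(diffs), scale = scale
  )
  attr(out, "differences") <- tibble::tibble(mean = pair_mean, difference = diffs)
  class(out) <- c("bland_altman", class(out))
  out
}

#' Weighted prediction-error bias and imprecision
#'
#' The weighted prediction error of an observation is
#' `(obs - pred) / SD(pred)` with the residual SD from the error model. Bias
#' is the mean weighted error; imprecision its sample variance.
#'
#' @param records A prediction-record tibble.
#' @param which `"population"` or `"individual"`.
#' @param error_model An [error_model()].
#' @return A one-row tibble: `bias`, `imprecision`, `n`.
#' @export
bias_imprecision <- function(records, which = c("population", "individual"),
                             error_model = NULL) {
  if (is.null(error_model)) error_model <- error_model()
  which <- match.arg(which)
  pred <- if (which == "population") records$pop_pred else records$ind_pred
  if (length(pred) < 2) stop("bias/imprecision needs at least 2 records")
  we <- (records$obs - pred) / residual_sd(pred, error_model)
  tibble::tibble(bias = mean(we), imprecision = stats::var(we), n = length(we))
}
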