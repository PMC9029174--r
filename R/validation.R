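#' Prediction errors of an external validation
#'
#' `pe = observed - predicted` (mg/L): a negative mean prediction error means
#' observed concentrations run below the model's predictions.
#'
#' @param records A prediction-record tibble from [predict_concentrations()].
#' @param which `"individual"` (posterior-weighted, the default used for
#'   external validation) or `"population"`.
#' @return Numeric vector of prediction errors, mg/L.
#' @export
prediction_errors <- function(records, which = c("individual", "population")) {
  which <- match.arg(which)
  pred <- if (which == "population") records$pop_pred else records$ind_pred
  records$obs - pred
}

#' Mean prediction error (bias) with 95% confidence interval
#'
#' `MPE = mean(pe)`; CI is `MPE +/- 1.96 * SD(pe) / sqrt(n)`.
#'
#' @param errors Numeric vector of prediction errors (mg/L).
#' @return One-row tibble: `mpe`, `lo`, `hi`, `n`. With a single error the CI
#'   is `NA`.
#' @examples
#' mpe(c(-4, -2)) # MPE -3, CI (-4.96, -1.04)
#' @export
mpe <- function(errors) {
  n <- length(errors)
  if (n < 1) stop("no prediction errors supplied")
  m <- mean(errors)
  if (n == 1) return(tibble::tibble(mpe = m, lo = NA_real_, hi = NA_real_, n = n))
  se <- stats::sd(errors) / sqrt(n)
  tibble::tibble(mpe = m, lo = m - 1.96 * se, hi = m + 1.96 * se, n = n)
}

#' Root mean squared prediction error (precision) with 95% confidence interval
#'
#' `RMSPE = sqrt(mean(pe^2))`. The CI is built on the mean squared error
#' (`mean(pe^2) +/- 1.96 * SD(pe^2)/sqrt(n)`) and its endpoints square-rooted,
#' clamping a negative lower endpoint to zero.
#'
#' @inheritParams mpe
#' @return One-row tibble: `rmspe`, `lo`, `hi`, `n`.
#' @examples
#' rmspe(c(3, -4)) # sqrt(12.5)
#' @export
rmspe <- function(errors) {
  n <- length(errors)
  if (n < 1) stop("no prediction errors supplied")
  sq <- errors^2
  r <- sqrt(mean(sq))
  if (n == 1) return(tibble::tibble(rmspe = r, lo = NA_real_, hi = NA_real_, n = n))
  se <- stats::sd(sq) / sqrt(n)
  tibble::tibble(
    rmspe = r,
    lo = sqrt(max(mean(sq) - 1.96 * se, 0)),
    hi = sqrt(mean(sq) + 1.96 * se),
    n = n
  )
}

#' Restrict prediction records to a concentration range
#'
#' Retains records with observed concentration strictly below `max_obs`
#' (e.g. the calibrated range of the assay behind the development data).
#'
#' @param records A prediction-record tibble.
#' @param max_obs Upper cutoff, mg/L.
#' @return The filtered tibble; errors if nothing remains.
#' @export
subset_by_concentration <- function(records, max_obs = 100) {
  if (max_obs <= 0) stop("`max_obs` must be positive")
  out <- dplyr::filter(records, .data$obs < max_obs)
  if (nrow(out) == 0) {
    stop(sprintf("no observations below %g mg/L", max_obs))
  }
  out
}

#' External-validation report
#'
#' Computes MPE and RMSPE with 95% confidence intervals for the full record
#' set and for the subset of observations below `cutoff` mg/L, and applies
#' the 20% bias acceptance rule: the model is accepted when
#' `100 * |MPE| / mean(observed)` of the evaluated subset is at most
#' `bias_limit_pct`.
#'
#' @param records A prediction-record tibble.
#' @param which Prediction type, `"individual"` (default) or `"population"`.
#' @param cutoff Concentration-range cutoff, mg/L (`NULL` to skip the subset
#'   row).
#' @param bias_limit_pct Acceptance limit on relative bias, percent.
#' @param label Dataset label carried into the report.
#' @return A `validation_report` tibble with one row per subset (`full`,
#'   `below_cutoff`): n, MPE and CI, RMSPE and CI, relative bias (%), and the
#'   acceptance verdict.
#' @export
validate_predictions <- function(records, which = c("individual", "population"),
                                 cutoff = 100, bias_limit_pct = 20,
                                 label = "external") {
  which <- match.arg(which)
  one <- function(recs, subset_name) {
    pe <- prediction_errors(recs, which)
    m <- mpe(pe)
    r <- rmspe(pe)
    ref <- mean(recs$obs)
    rel <- 100 * abs(m$mpe) / ref
    tibble::tibble(
      dataset = label, subset = subset_name, n = m$n,
      mpe = m$mpe, mpe_lo = m$lo, mpe_hi = m$hi,
      rmspe = r$rmspe, rmspe_lo = r$lo, rmspe_hi = r$hi,
      mean_obs = ref, rel_bias_pct = rel,
      accepted = rel <= bias_limit_pct
    )
  }
  out <- one(records, "full")
  if (!is.null(cutoff)) {
    out <- dplyr::bind_rows(out, one(subset_by_concentration(records, cutoff),
                                     sprintf("<%g mg/L", cutoff)))
  }
  class(out) <- c("validation_report", class(out))
  out
}

#' Bias acceptance verdict
#'
#' @param mpe_value Mean prediction error, mg/L.
#' @param reference_scale Mean observed concentration of the evaluated
#'   subset, mg/L.
#' @param bias_limit_pct Acceptance limit, percent (default 20).
#' @return Logical: `TRUE` when `100 * |MPE| / reference_scale` is within the
#'   limit.
#' @examples
#' acceptance_check(-3.3, 40) # 8.25% relative bias -> TRUE
#' @export
acceptance_check <- function(mpe_value, reference_scale, bias_limit_pct = 20) {
  if (reference_scale <= 0) stop("`reference_scale` must be positive")
  100 * abs(mpe_value) / reference_scale <= bias_limit_pct
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf(
      "  %s [%s] n=%d  MPE %.2f (%.2f to %.2f)  RMSPE %.2f (%.2f to %.2f)  bias %.1f%% -> %s\n",
      x$dataset[i], x$subset[i], x$n[i],
      x$mpe[i], x$mpe_lo[i], x$mpe_hi[i],
      x$rmspe[i], x$rmspe_lo[i], x$rmspe_hi[i],
      x$rel_bias_pct[i], if (x$accepted[i]) "accepted" else "rejected"
    ))
  }
  invisible(x)
}
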