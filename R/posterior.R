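#' Bayesian individual posteriors over the population support points
#'
#' For each subject, the population distribution acts as a discrete prior and
#' the posterior weight of support point `j` is
#' `prior_j * L_j / sum_k prior_k * L_k`, with the subject likelihood
#' evaluated in the log domain (max-subtraction) so that likelihood magnitudes
#' down to `exp(-700)` and beyond do not underflow. When the fit carries the
#' covariate link, each subject's clearance is recomputed from their own CrCL
#' before the likelihood is evaluated.
#'
#' @param data A subject event table (any number of subjects).
#' @param fit An [npag_fit()] result, or a list with a `support` tibble
#'   (columns `CL`, `V`, `KCP`, `KPC`, `weight`) plus `use_covariate`,
#'   `crcl_ref`, `error_model` entries.
#' @param error_model Overrides the fit's error model if supplied.
#' @return A tibble with one row per (subject, support point): `id`, the
#'   support-point parameters, `prior_weight`, `posterior_weight`.
#' @export
individual_posterior <- function(data, fit, error_model = NULL) {
  subjects <- .split_subjects(data)
  em <- error_model %||% fit$error_model
  support <- fit$support
  prior <- support$weight / sum(support$weight)
  purrr::map_dfr(subjects, function(s) {
    par <- .individualize(support[, c("CL", "V", "KCP", "KPC")], s,
                          isTRUE(fit$use_covariate), fit$crcl_ref %||% 60)
    ll <- .loglik_rows(par, s, em)
    lw <- log(prior) + ll
    lw <- lw - max(lw)
    w <- exp(lw)
    if (!any(is.finite(w)) || sum(w) == 0) {
      stop(sprintf("subject %s: zero posterior mass at every support point (model-data conflict)", s$id))
    }
    dplyr::mutate(support[, c("CL", "V", "KCP", "KPC")],
                  id = s$id, prior_weight = prior,
                  posterior_weight = w / sum(w), .before = 1)
  })
}

#' Posterior-mean parameters per subject
#'
#' @param posterior A tibble from [individual_posterior()].
#' @return A tibble with one row per subject: posterior-weighted mean `CL`
#'   (population scale, i.e. `TVCL` when the covariate link is active), `V`,
#'   `KCP`, `KPC`.
#' @export
posterior_mean_params <- function(posterior) {
  posterior |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(dplyr::across(
      dplyr::all_of(c("CL", "V", "KCP", "KPC")),
      ~ sum(.x * .data$posterior_weight)
    ), .groups = "drop")
}

#' Population- and individual-predicted concentrations
#'
#' For each observation, the population prediction is the prior-weighted mean
#' of the support-point predictions and the individual prediction the
#' posterior-weighted mean (the nonparametric analogues of PRED and IPRED).
#'
#' @inheritParams individual_posterior
#' @param posterior Optionally a precomputed [individual_posterior()] table.
#' @return A prediction-record tibble: `id`, `occ`, `time` (h), `obs` (mg/L),
#'   `pop_pred`, `ind_pred` (mg/L).
#' @export
predict_concentrations <- function(data, fit, error_model = NULL,
                                   posterior = NULL) {
  subjects <- .split_subjects(data)
  em <- error_model %||% fit$error_model
  if (is.null(posterior)) posterior <- individual_posterior(data, fit, em)
  support <- fit$support
  purrr::map_dfr(subjects, function(s) {
    par <- .individualize(support[, c("CL", "V", "KCP", "KPC")], s,
                          isTRUE(fit$use_covariate), fit$crcl_ref %||% 60)
    pred <- .predict_conc_matrix(par, s) # points x obs
    pw <- posterior$posterior_weight[posterior$id == s$id]
    prior <- support$weight / sum(support$weight)
    tibble::tibble(
      id = s$id,
      occ = s$obs$occ,
      time = s$obs$time,
      obs = s$obs$conc,
      pop_pred = as.vector(crossprod(pred, prior)),
      ind_pred = as.vector(crossprod(pred, pw))
    )
  })
}
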