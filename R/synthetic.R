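# Synthetic cohorts emulating the study design: sparse steady-state sampling
# in an ICU population with renal-function-linked clearance. The generator's
# defaults ARE the study conditions; change them only to explore.

# log-normal with a given median and interquartile ratio (q3/q1)
.rlnorm_med_iqr <- function(n, median, q1, q3) {
  sdlog <- log(q3 / q1) / (2 * stats::qnorm(0.75))
  stats::rlnorm(n, meanlog = log(median), sdlog = sdlog)
}

# log-normal matched by moments to mean m, sd s
.rlnorm_moments <- function(n, m, s) {
  if (s == 0) return(rep(m, n))
  sdlog <- sqrt(log(1 + (s / m)^2))
  stats::rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

#' Design of a synthetic sparse-sampling cohort
#'
#' Encodes the study conditions the generator emulates: 24 subjects at steady
#' state on day 5 of therapy, assigned to 4 g q8h (or the individually
#' designed 2 g q6h / 3.3 g q4h alternatives), each infused over 0.5 h, with
#' one to three samples per dosing interval drawn at pre-dose, 1 h and 3 h
#' after the start of infusion; covariates matched to the cohort's summary
#' statistics (CrCL median 60, IQR 47-83 mL/min/1.73 m^2; 38% male); true
#' parameters log-normal matched to the population moments with
#' `CL = TVCL * (CRCL/60)`; residual noise `SD = 5 * (1 + 0.1 C)`.
#'
#' @param n_subjects Number of subjects.
#' @param regimens List of [regimen()] objects on offer.
#' @param regimen_prob Assignment probabilities (sum to 1).
#' @param sample_times Nominal sampling times within the interval, h (the
#'   first is the pre-dose trough).
#' @param n_samples_prob Probabilities of a subject contributing 1, 2 or 3
#'   samples; with fewer than three, the latest times are kept.
#' @param crcl_median,crcl_q1,crcl_q3 CrCL summary, mL/min/1.73 m^2.
#' @param p_male Probability of male sex.
#' @param population Moments tibble for the true parameters (default
#'   [pip_population_moments()]).
#' @param error_model Residual-error model used to corrupt the observations.
#' @param steady_state If `TRUE` (default), observations are drawn from the
#'   periodic steady-state profile (the day-5 context); if `FALSE`, from the
#'   first dose of the regimen (a rich first-dose design).
#' @param day1_times Optional sampling times after the first dose (h). When
#'   given, each subject contributes a second, first-dose sampling occasion
#'   in addition to the occasion described by `sample_times` - the classic
#'   day-1 plus day-5 rich design, which identifies the central volume (from
#'   first-dose kinetics) jointly with clearance (from accumulation at steady
#'   state).
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(n_subjects = 24,
                          regimens = list(
                            regimen(4000, 8, 0.5),
                            regimen(2000, 6, 0.5),
                            regimen(3300, 4, 0.5)
                          ),
                          regimen_prob = c(0.5, 0.25, 0.25),
                          sample_times = c(0, 1, 3),
                          n_samples_prob = c(0.25, 0.5, 0.25),
                          crcl_median = 60, crcl_q1 = 47, crcl_q3 = 83,
                          p_male = 0.38,
                          population = pip_population_moments(),
                          error_model = NULL, steady_state = TRUE,
                          day1_times = NULL) {
  if (is.null(error_model)) error_model <- error_model()
  if (abs(sum(regimen_prob) - 1) > 1e-9) stop("regimen probabilities must sum to 1")
  if (length(regimen_prob) != length(regimens)) {
    stop("`regimen_prob` must match `regimens` in length")
  }
  max_tau <- min(vapply(regimens, function(r) r$interval, numeric(1)))
  if (any(sample_times < 0) || any(sample_times >= max_tau + 1e-9)) {
    stop("sampling times must fall within one dosing interval of every regimen")
  }
  structure(list(
    n_subjects = n_subjects, regimens = regimens, regimen_prob = regimen_prob,
    sample_times = sample_times, n_samples_prob = n_samples_prob,
    crcl_median = crcl_median, crcl_q1 = crcl_q1, crcl_q3 = crcl_q3,
    p_male = p_male, population = population, error_model = error_model,
    steady_state = steady_state, day1_times = day1_times
  ), class = "cohort_design")
}

.draw_covariates <- function(n, design) {
  tibble::tibble(
    AGE = .rlnorm_med_iqr(n, 72, 57, 78),
    WT = .rlnorm_med_iqr(n, 69, 57, 77),
    BMI = .rlnorm_med_iqr(n, 22, 21, 31),
    SEX = ifelse(stats::runif(n) < design$p_male, "male", "female"),
    SCR = .rlnorm_med_iqr(n, 0.9, 0.7, 1.2),
    CRCL = .rlnorm_med_iqr(n, design$crcl_median, design$crcl_q1, design$crcl_q3),
    SEPSIS = as.integer(stats::runif(n) < 0.5),
    SAPS3 = round(.rlnorm_med_iqr(n, 53, 45, 63)),
    SOFA = round(.rlnorm_med_iqr(n, 5, 4, 7)),
    MODS = round(.rlnorm_med_iqr(n, 3, 2, 4))
  ) |>
    dplyr::mutate(HT = sqrt(.data$WT / .data$BMI) * 100)
}

# population may be a moments tibble (parameter/mean/sd; log-normal marginals
# matched by moments) or a fitted nonparametric model (support points
# resampled by weight), so cohorts can be simulated from a fit itself.
.draw_truth <- function(n, population) {
  if (inherits(population, "npag_fit")) {
    s <- population$support
    j <- sample.int(nrow(s), n, replace = TRUE, prob = s$weight)
    return(tibble::tibble(TVCL = s$CL[j], V = s$V[j],
                          KCP = s$KCP[j], KPC = s$KPC[j]))
  }
  draw <- function(p) {
    .rlnorm_moments(n, population$mean[population$parameter == p],
                    population$sd[population$parameter == p])
  }
  tibble::tibble(TVCL = draw("CL"), V = draw("V"),
                 KCP = draw("KCP"), KPC = draw("KPC"))
}

# noise with resampling-truncation at zero; returns list(conc, n_resampled)
.add_noise <- function(true_conc, em) {
  conc <- true_conc + stats::rnorm(length(true_conc), 0, residual_sd(true_conc, em))
  n_res <- 0L
  bad <- which(conc < 0)
  while (length(bad)) {
    n_res <- n_res + length(bad)
    conc[bad] <- true_conc[bad] +
      stats::rnorm(length(bad), 0, residual_sd(true_conc[bad], em))
    bad <- bad[conc[bad] < 0]
  }
  list(conc = conc, n_resampled = n_res)
}

.assemble_cohort <- function(ids, occasions_list, cov, truth, em) {
  n_resampled <- 0L
  rows <- purrr::map_dfr(seq_along(ids), function(i) {
    p <- pk_params(truth$CL[i], truth$V[i], truth$KCP[i], truth$KPC[i])
    evt <- purrr::map_dfr(seq_along(occasions_list[[i]]), function(k) {
      o <- occasions_list[[i]][[k]]
      r <- o$regimen
      tt <- o$times
      true_c <- if (isTRUE(o$steady_state)) {
        steady_state_profile(p, r, times = tt)$conc
      } else {
        simulate_profile(p, dose_events(0, r$dose, r$infusion_duration), tt)$conc
      }
      noisy <- .add_noise(true_c, em)
      n_resampled <<- n_resampled + noisy$n_resampled
      dplyr::bind_rows(
        tibble::tibble(ID = ids[i], EVID = 1, TIME = 0, AMT = r$dose,
                       DUR = r$infusion_duration,
                       SS = if (isTRUE(o$steady_state)) 1 else NA_real_,
                       II = if (isTRUE(o$steady_state)) r$interval else NA_real_,
                       OCC = k, OUT = NA_real_),
        tibble::tibble(ID = ids[i], EVID = 0, TIME = tt, AMT = NA_real_,
                       DUR = NA_real_, SS = NA_real_, II = NA_real_,
                       OCC = k, OUT = noisy$conc)
      ) |>
        dplyr::arrange(.data$TIME, dplyr::desc(.data$EVID))
    })
    dplyr::bind_cols(evt, cov[rep(i, nrow(evt)), ])
  })
  first_reg <- lapply(occasions_list, function(x) x[[1]]$regimen)
  truth_tab <- dplyr::bind_cols(
    tibble::tibble(
      id = ids,
      dose = vapply(first_reg, function(r) r$dose, numeric(1)),
      interval = vapply(first_reg, function(r) r$interval, numeric(1)),
      infusion_duration = vapply(first_reg, function(r) r$infusion_duration, numeric(1)),
      CRCL = cov$CRCL
    ),
    truth
  )
  attr(rows, "truth") <- truth_tab
  attr(rows, "n_resampled") <- n_resampled
  rows
}

#' Generate a synthetic sparse-sampling cohort
#'
#' Draws covariates, true parameters and noisy steady-state observations
#' according to a [cohort_design()]. The returned event table follows the
#' subject CSV dialect (see [read_subject_table()]); the latent truth (per
#' subject regimen, CrCL, `TVCL`, `CL`, `V`, `KCP`, `KPC`) is attached as
#' `attr(x, "truth")` and the number of noise draws resampled to keep
#' concentrations non-negative as `attr(x, "n_resampled")`.
#'
#' @param design A [cohort_design()].
#' @param seed Integer seed; the dataset is reproducible bit for bit.
#' @return A subject event-table tibble with `truth` attribute.
#' @export
generate_cohort <- function(design = cohort_design(), seed = 1) {
  stopifnot(inherits(design, "cohort_design"))
  n <- design$n_subjects
  withr::with_seed(seed, {
    cov <- .draw_covariates(n, design)
    truth <- .draw_truth(n, design$population)
    truth$CRCL <- cov$CRCL
    truth$CL <- apply_covariate(truth$TVCL, cov$CRCL)
    reg_idx <- sample.int(length(design$regimens), n, replace = TRUE,
                          prob = design$regimen_prob)
    regs <- design$regimens[reg_idx]
    k <- sample(seq_along(design$n_samples_prob), n, replace = TRUE,
                prob = design$n_samples_prob)
    occasions_list <- lapply(seq_len(n), function(i) {
      occ <- list()
      if (!is.null(design$day1_times)) {
        occ <- c(occ, list(list(regimen = regs[[i]], times = design$day1_times,
                                steady_state = FALSE)))
      }
      c(occ, list(list(regimen = regs[[i]],
                       times = utils::tail(design$sample_times, k[i]),
                       steady_state = design$steady_state)))
    })
    .assemble_cohort(
      sprintf("S%02d", seq_len(n)), occasions_list, cov,
      truth[, c("TVCL", "CL", "V", "KCP", "KPC")], design$error_model
    )
  })
}

#' Generate a rich-sampling external-validation cohort
#'
#' Two designs emulating the external datasets used to probe interethnic
#' transferability of the model:
#' * `"rich_q6h"`: 20 subjects, 4 g every 6 h infused over 20 min, six
#'   samples per subject at pre-dose, end of infusion, 0.67, 1, 3.5 and 6 h.
#' * `"rich_tds"`: 10 subjects, 4 g every 8 h with infusion duration drawn
#'   uniformly between 0.5 and 1 h, twenty samples evenly spaced over two
#'   consecutive dosing intervals.
#'
#' Both default to a higher-clearance population (CrCL roughly 92-122
#' mL/min/1.73 m^2), the regime in which external cohorts typically differ
#' from the development cohort.
#'
#' @param style `"rich_q6h"` or `"rich_tds"`.
#' @param seed Integer seed.
#' @param crcl_median,crcl_q1,crcl_q3 CrCL summary of the external
#'   population, mL/min/1.73 m^2.
#' @param population Moments tibble for the true parameters.
#' @param error_model Residual-error model for the observations.
#' @return A subject event-table tibble with `truth` attribute, as
#'   [generate_cohort()].
#' @export
generate_external_cohort <- function(style = c("rich_q6h", "rich_tds"), seed = 1,
                                     crcl_median = 106, crcl_q1 = 92, crcl_q3 = 122,
                                     population = pip_population_moments(),
                                     error_model = NULL) {
  if (is.null(error_model)) error_model <- error_model()
  style <- match.arg(style)
  n <- if (style == "rich_q6h") 20L else 10L
  design <- cohort_design(crcl_median = crcl_median, crcl_q1 = crcl_q1,
                          crcl_q3 = crcl_q3, population = population,
                          error_model = error_model)
  withr::with_seed(seed, {
    cov <- .draw_covariates(n, design)
    truth <- .draw_truth(n, population)
    truth$CL <- apply_covariate(truth$TVCL, cov$CRCL)
    if (style == "rich_q6h") {
      regs <- rep(list(regimen(4000, 6, 1 / 3)), n)
      times_list <- rep(list(c(0, 1 / 3, 0.67, 1, 3.5, 6)), n)
    } else {
      durs <- stats::runif(n, 0.5, 1)
      regs <- lapply(durs, function(d) regimen(4000, 8, d))
      times_list <- rep(list(utils::head(seq(0, 16, length.out = 21), 20)), n)
    }
    occasions_list <- lapply(seq_len(n), function(i) {
      list(list(regimen = regs[[i]], times = times_list[[i]], steady_state = TRUE))
    })
    .assemble_cohort(
      sprintf("X%02d", seq_len(n)), occasions_list, cov,
      truth[, c("TVCL", "CL", "V", "KCP", "KPC")], error_model
    )
  })
}

#' Rich two-occasion study design for parameter-recovery studies
#'
#' The design used to verify that the nonparametric fit recovers a known
#' population: 50 subjects on 4 g q8h or 4 g q6h (0.5-h infusions), each
#' sampled on two occasions - five samples after the first dose (0.3, 0.55,
#' 1, 2, 4 h; identifies the central volume) and five across a steady-state
#' interval (pre-dose, 1, 2, 4, 5.9 h; identifies clearance through
#' accumulation) - with covariates and true parameters drawn as in
#' [cohort_design()].
#'
#' @param n_subjects Number of subjects (default 50).
#' @param ... Passed on to [cohort_design()].
#' @return A [cohort_design()].
#' @export
rich_recovery_design <- function(n_subjects = 50, ...) {
  cohort_design(
    n_subjects = n_subjects,
    regimens = list(regimen(4000, 8, 0.5), regimen(4000, 6, 0.5)),
    regimen_prob = c(0.5, 0.5),
    sample_times = c(0, 1, 2, 4, 5.9),
    n_samples_prob = c(0, 0, 0, 0, 1),
    day1_times = c(0.3, 0.55, 1, 2, 4),
    ...
  )
}
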