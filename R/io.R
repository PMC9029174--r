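# Subject event-table dialect (NONMEM/Pmetrics-flavoured, one CSV):
#   ID    subject label
#   EVID  1 = dose event, 0 = observation
#   TIME  h, relative to the first dose (or to interval start when SS = 1)
#   AMT   mg, dose rows only
#   DUR   h, dose rows only (0 = bolus)
#   SS    1 marks a steady-state dose: the row describes one interval of a
#         regimen repeated every II hours since long before TIME = 0
#   II    dosing interval, h (required when SS = 1)
#   OUT   mg/L, observation rows only
#   OCC   sampling occasion (optional, default 1): dose and observation rows
#         with the same OCC form one self-contained dosing/sampling episode
#         (e.g. OCC 1 = first dose, OCC 2 = a steady-state interval on day 5);
#         TIME restarts within each occasion
# plus per-subject covariate columns (constant within subject):
#   AGE WT HT SEX SCR CRCL BMI SEPSIS SAPS3 SOFA MODS

.covariate_cols <- c(
  "AGE", "WT", "HT", "SEX", "SCR", "CRCL", "BMI",
  "SEPSIS", "SAPS3", "SOFA", "MODS"
)

#' Read a subject event table
#'
#' Reads and validates the package's dose-event/observation CSV dialect (see
#' `vignette("pippk-methods")` for the column contract). Missing values may be
#' written as empty fields or `"."`.
#'
#' @param path Path to a CSV file.
#' @param strict If `TRUE` (default), observations occurring before any dose
#'   of the same subject are an error; if `FALSE`, a warning.
#' @return A validated tibble of events (one row per dose or observation).
#' @export
read_subject_table <- function(path, strict = TRUE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "."))
  validate_subject_table(tibble::as_tibble(raw), strict = strict)
}

#' Validate a subject event table
#'
#' @param data A data frame in the subject event-table dialect.
#' @inheritParams read_subject_table
#' @return The validated tibble, with numeric columns coerced.
#' @export
validate_subject_table <- function(data, strict = TRUE) {
  data <- tibble::as_tibble(data)
  need <- c("ID", "EVID", "TIME")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("subject table is missing columns: ", paste(miss, collapse = ", "))
  for (cc in c("AMT", "DUR", "OUT", "SS", "II", "OCC")) {
    if (!cc %in% names(data)) data[[cc]] <- NA_real_
  }
  num_cols <- intersect(c("EVID", "TIME", "AMT", "DUR", "OUT", "SS", "II", "OCC",
                          setdiff(.covariate_cols, "SEX")), names(data))
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(data[[cc]]))
    bad <- which(!is.na(data[[cc]]) & is.na(v))
    if (length(bad)) {
      stop(sprintf("column %s has non-numeric values (e.g. row %d: \"%s\"); %s",
                   cc, bad[1], data[[cc]][bad[1]],
                   "decimal commas are not accepted - use '.'"))
    }
    data[[cc]] <- v
  }
  if (!all(data$EVID %in% c(0, 1))) {
    bad <- which(!data$EVID %in% c(0, 1))[1]
    stop(sprintf("row %d: unknown EVID %s (must be 0 or 1)", bad, data$EVID[bad]))
  }
  if (any(is.na(data$TIME)) || any(data$TIME < 0)) {
    bad <- which(is.na(data$TIME) | data$TIME < 0)[1]
    stop(sprintf("row %d: TIME must be present and non-negative", bad))
  }
  dose <- data$EVID == 1
  if (any(dose & (is.na(data$AMT) | data$AMT <= 0))) {
    bad <- which(dose & (is.na(data$AMT) | data$AMT <= 0))[1]
    stop(sprintf("row %d: dose rows need AMT > 0", bad))
  }
  if (any(dose & !is.na(data$OUT))) {
    bad <- which(dose & !is.na(data$OUT))[1]
    stop(sprintf("row %d: dose rows must not carry an OUT value", bad))
  }
  if (any(!dose & !is.na(data$AMT))) {
    bad <- which(!dose & !is.na(data$AMT))[1]
    stop(sprintf("row %d: observation rows must not carry an AMT value", bad))
  }
  if (any(!dose & (is.na(data$OUT) | data$OUT < 0))) {
    bad <- which(!dose & (is.na(data$OUT) | data$OUT < 0))[1]
    stop(sprintf("row %d: observation rows need OUT >= 0", bad))
  }
  ssrow <- dose & !is.na(data$SS) & data$SS == 1
  if (any(ssrow & (is.na(data$II) | data$II <= 0))) {
    bad <- which(ssrow & (is.na(data$II) | data$II <= 0))[1]
    stop(sprintf("row %d: SS = 1 dose rows need II > 0 (dosing interval, h)", bad))
  }
  occ <- ifelse(is.na(data$OCC), 1, data$OCC)
  for (id in unique(data$ID)) {
    for (cc in intersect(.covariate_cols, names(data))) {
      u <- unique(data[[cc]][data$ID == id & !is.na(data[[cc]])])
      if (length(u) > 1) {
        stop(sprintf("subject %s: covariate %s is not constant within subject", id, cc))
      }
    }
    for (k in unique(occ[data$ID == id])) {
      sub <- data[data$ID == id & occ == k, ]
      if (is.unsorted(sub$TIME)) {
        stop(sprintf("subject %s occasion %s: TIME must be non-decreasing", id, k))
      }
      if (!any(sub$EVID == 1)) {
        stop(sprintf("subject %s occasion %s: no dose event", id, k))
      }
      has_obs_before_dose <- any(sub$EVID == 0) &&
        min(sub$TIME[sub$EVID == 0]) < min(sub$TIME[sub$EVID == 1]) &&
        !any(sub$EVID == 1 & !is.na(sub$SS) & sub$SS == 1)
      if (has_obs_before_dose) {
        msg <- sprintf("subject %s occasion %s: observation precedes the first dose", id, k)
        if (strict) stop(msg) else warning(msg)
      }
    }
  }
  data
}

#' Write a subject event table
#'
#' Writes RFC-4180-compliant CSV with missing values as empty fields, so a
#' write/read round trip is lossless.
#'
#' @param data A (validated) subject event table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_subject_table <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

# Split an event table into per-subject records:
# list(id, occasions = list of list(doses, obs), obs = flat tibble
# (occ, time, conc) in occasion-then-time order, covariates = named list)
.split_subjects <- function(data) {
  data <- validate_subject_table(data, strict = FALSE)
  occ_all <- ifelse(is.na(data$OCC), 1, data$OCC)
  lapply(unique(data$ID), function(id) {
    sub <- data[data$ID == id, ]
    occ <- occ_all[data$ID == id]
    cov <- lapply(intersect(.covariate_cols, names(sub)), function(cc) {
      u <- sub[[cc]][!is.na(sub[[cc]])]
      if (length(u)) u[1] else NA
    })
    names(cov) <- intersect(.covariate_cols, names(sub))
    occasions <- lapply(sort(unique(occ)), function(k) {
      dose <- sub[sub$EVID == 1 & occ == k, ]
      obs <- sub[sub$EVID == 0 & occ == k, ]
      list(
        occ = k,
        doses = tibble::tibble(
          start_time = dose$TIME,
          amount = dose$AMT,
          duration = ifelse(is.na(dose$DUR), 0, dose$DUR),
          ss = !is.na(dose$SS) & dose$SS == 1,
          interval = dose$II
        ),
        obs = tibble::tibble(time = obs$TIME, conc = obs$OUT)
      )
    })
    flat <- dplyr::bind_rows(lapply(occasions, function(o) {
      tibble::tibble(occ = o$occ, time = o$obs$time, conc = o$obs$conc)
    }))
    list(id = id, occasions = occasions, obs = flat, covariates = cov)
  })
}

# Predicted concentrations at a subject's observation times (all occasions,
# in flat-obs order) for a matrix of parameter sets (data frame with columns
# CL, V, KCP, KPC). Returns an n_params x n_obs matrix. CL here is the
# individual clearance (any covariate link must already have been applied).
.predict_conc_matrix <- function(par, subject) {
  do.call(cbind, lapply(subject$occasions, function(o) {
    .predict_occasion_matrix(par, o, subject$id)
  }))
}

.predict_occasion_matrix <- function(par, occasion, id) {
  d <- occasion$doses
  times <- occasion$obs$time
  if (nrow(d) == 0) stop(sprintf("subject %s has no dose events", id))
  n <- length(par$CL)
  if (any(d$ss)) {
    if (!all(d$ss)) {
      stop(sprintf("subject %s mixes steady-state and ordinary dose rows", id))
    }
    i <- which(d$ss)[1]
    return(.ss_conc_matrix(par$CL, par$V, par$KCP, par$KPC,
                           d$amount[i], d$interval[i], d$duration[i], times))
  }
  ke <- par$CL / par$V
  ab <- .hybrid_constants(ke, par$KCP, par$KPC)
  out <- matrix(0, n, length(times))
  for (j in seq_along(times)) {
    t <- times[j]
    a1 <- rep(0, n)
    for (i in seq_len(nrow(d))) {
      u <- t - d$start_time[i]
      if (u > 0) {
        a <- .single_dose_amounts(ke, par$KCP, par$KPC, ab$alpha, ab$beta,
                                  d$amount[i], d$duration[i], u)
        a1 <- a1 + a$a1
      }
    }
    out[, j] <- a1 / par$V
  }
  pmax(out, 0)
}
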