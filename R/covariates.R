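#' Creatinine clearance by Cockcroft-Gault
#'
#' Estimates creatinine clearance (mL/min) from age, body weight, sex and
#' serum creatinine using the Cockcroft-Gault equation
#' `(140 - age) * weight / (72 * SCr)`, multiplied by 0.85 for females.
#' Total body weight is used by convention; supply an adjusted weight if a
#' different convention is wanted.
#'
#' @param age Age in years.
#' @param weight Body weight in kg.
#' @param sex `"male"` or `"female"` (vectorized).
#' @param serum_creatinine Serum creatinine in mg/dL; must be positive.
#' @return Creatinine clearance in mL/min.
#' @examples
#' crcl_cockcroft_gault(40, 70, "male", 1.0)
#' @export
crcl_cockcroft_gault <- function(age, weight, sex, serum_creatinine) {
  sex <- .check_sex(sex)
  if (any(serum_creatinine <= 0)) stop("serum creatinine must be positive (mg/dL)")
  if (any(age <= 0) || any(weight <= 0)) stop("age and weight must be positive")
  crcl <- (140 - age) * weight / (72 * serum_creatinine)
  crcl * ifelse(sex == "female", 0.85, 1)
}

.check_sex <- function(sex) {
  sex <- tolower(as.character(sex))
  sex[sex %in% c("m", "1")] <- "male"
  sex[sex %in% c("f", "0")] <- "female"
  if (!all(sex %in% c("male", "female"))) {
    stop("`sex` must be \"male\" or \"female\"")
  }
  sex
}

#' Body surface area (DuBois)
#'
#' `BSA = 0.007184 * weight^0.425 * height^0.725` with weight in kg and height
#' in cm.
#'
#' @param weight Body weight, kg.
#' @param height Height, cm.
#' @return Body surface area in m^2.
#' @examples
#' bsa_dubois(70, 170)
#' @export
bsa_dubois <- function(weight, height) {
  if (any(weight <= 0) || any(height <= 0)) stop("weight and height must be positive")
  0.007184 * weight^0.425 * height^0.725
}

#' Normalize creatinine clearance to 1.73 m^2 body surface area
#'
#' @param crcl Creatinine clearance in mL/min.
#' @param weight Body weight, kg.
#' @param height Height, cm.
#' @return Creatinine clearance in mL/min/1.73 m^2.
#' @examples
#' bsa_normalize(crcl_cockcroft_gault(40, 70, "male", 1.0), 70, 170)
#' @export
bsa_normalize <- function(crcl, weight, height) {
  crcl * 1.73 / bsa_dubois(weight, height)
}

#' Estimated GFR by the CKD-EPI 2009 creatinine equation
#'
#' Two-level (sex and creatinine range) 2009 equation without the race
#' adjustment term, which is not applicable in admixed populations:
#' `eGFR = 141 * min(SCr/k, 1)^a * max(SCr/k, 1)^-1.209 * 0.993^age * 1.018[female]`
#' with `k = 0.7` (female) or `0.9` (male) and `a = -0.329` (female) or
#' `-0.411` (male).
#'
#' @inheritParams crcl_cockcroft_gault
#' @return eGFR in mL/min/1.73 m^2.
#' @examples
#' ckd_epi(50, "male", 1.2)
#' @export
ckd_epi <- function(age, sex, serum_creatinine) {
  sex <- .check_sex(sex)
  if (any(serum_creatinine <= 0)) stop("serum creatinine must be positive (mg/dL)")
  if (any(age <= 0)) stop("age must be positive")
  kappa <- ifelse(sex == "female", 0.7, 0.9)
  a <- ifelse(sex == "female", -0.329, -0.411)
  r <- serum_creatinine / kappa
  141 * pmin(r, 1)^a * pmax(r, 1)^(-1.209) * 0.993^age *
    ifelse(sex == "female", 1.018, 1)
}

#' Body mass index
#'
#' @param weight Body weight, kg.
#' @param height Height, cm.
#' @return BMI in kg/m^2.
#' @examples
#' bmi(70, 170)
#' @export
bmi <- function(weight, height) {
  if (any(weight <= 0) || any(height <= 0)) stop("weight and height must be positive")
  weight / (height / 100)^2
}
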