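# Body-size and renal-function descriptors used as candidate covariates.
# Units follow clinical-chemistry convention: weight kg, height m (converted
# to cm internally where a formula wants cm), serum creatinine umol/L,
# cystatin C mg/L, eGFR mL/s/1.73 m^2.

.check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be finite and strictly positive", name), call. = FALSE)
  }
  invisible(x)
}

.check_sex <- function(sex, n) {
  sex <- tolower(as.character(sex))
  if (!all(sex %in% c("male", "female"))) {
    stop("`sex` must be \"male\" or \"female\"", call. = FALSE)
  }
  rep_len(sex, n)
}

#' Body mass index
#'
#' @param weight Body weight (kg).
#' @param height Height (m).
#' @return BMI in kg/m^2.
#' @examples
#' compute_bmi(104, 1.74)
#' @export
compute_bmi <- function(weight, height) {
  .check_positive(weight, "weight")
  .check_positive(height, "height")
  weight / height^2
}

#' Body surface area (Du Bois)
#'
#' Du Bois & Du Bois power-law formula,
#' \eqn{BSA = 0.007184 \cdot W^{0.425} \cdot H_{cm}^{0.725}}.
#'
#' @inheritParams compute_bmi
#' @return BSA in m^2.
#' @examples
#' compute_bsa_dubois(104, 1.74)
#' @export
compute_bsa_dubois <- function(weight, height) {
  .check_positive(weight, "weight")
  .check_positive(height, "height")
  0.007184 * weight^0.425 * (height * 100)^0.725
}

#' Lean body mass (Boer)
#'
#' Sex-specific linear Boer formula on weight (kg) and height (cm).
#'
#' @inheritParams compute_bmi
#' @param sex "male" or "female" (recycled).
#' @return LBM in kg.
#' @examples
#' compute_lbm_boer(104, 1.74, "male")
#' @export
compute_lbm_boer <- function(weight, height, sex) {
  .check_positive(weight, "weight")
  .check_positive(height, "height")
  n <- max(length(weight), length(height), length(sex))
  sex <- .check_sex(sex, n)
  weight <- rep_len(weight, n)
  hcm <- rep_len(height, n) * 100
  ifelse(sex == "male",
         0.407 * weight + 0.267 * hcm - 19.2,
         0.252 * weight + 0.473 * hcm - 48.3)
}

#' Creatinine-based eGFR (CKD-EPI 2009)
#'
#' CKD-EPI 2009 creatinine equation. Serum creatinine is taken in umol/L and
#' converted to mg/dL by division by 88.4; the result is converted from
#' mL/min/1.73 m^2 to mL/s/1.73 m^2 (division by 60). The race coefficient
#' defaults to 1 (non-Black).
#'
#' @param serum_creatinine Serum creatinine (umol/L).
#' @param age Age (years), >= 18.
#' @param sex "male" or "female" (recycled).
#' @param race_factor Multiplicative race coefficient (default 1).
#' @return eGFR in mL/s/1.73 m^2.
#' @examples
#' compute_egfr_ckdepi_cr(72.3, 65, "male")
#' @export
compute_egfr_ckdepi_cr <- function(serum_creatinine, age, sex, race_factor = 1) {
  .check_positive(serum_creatinine, "serum_creatinine")
  .check_positive(age, "age")
  n <- max(length(serum_creatinine), length(age), length(sex))
  sex <- .check_sex(sex, n)
  scr <- rep_len(serum_creatinine, n) / 88.4
  age <- rep_len(age, n)
  kappa <- ifelse(sex == "female", 0.7, 0.9)
  alpha <- ifelse(sex == "female", -0.329, -0.411)
  sex_f <- ifelse(sex == "female", 1.018, 1)
  egfr_min <- 141 * pmin(scr / kappa, 1)^alpha * pmax(scr / kappa, 1)^-1.209 *
    0.993^age * sex_f * race_factor
  egfr_min / 60
}

#' Cystatin C-based eGFR (CKD-EPI 2012, cystatin only)
#'
#' @param serum_cystatin_c Serum cystatin C (mg/L).
#' @inheritParams compute_egfr_ckdepi_cr
#' @return eGFR in mL/s/1.73 m^2.
#' @examples
#' compute_egfr_ckdepi_cys(1.0, 60, "male")
#' @export
compute_egfr_ckdepi_cys <- function(serum_cystatin_c, age, sex) {
  .check_positive(serum_cystatin_c, "serum_cystatin_c")
  .check_positive(age, "age")
  n <- max(length(serum_cystatin_c), length(age), length(sex))
  sex <- .check_sex(sex, n)
  cys <- rep_len(serum_cystatin_c, n)
  age <- rep_len(age, n)
  sex_f <- ifelse(sex == "female", 0.932, 1)
  egfr_min <- 133 * pmin(cys / 0.8, 1)^-0.499 * pmax(cys / 0.8, 1)^-1.328 *
    0.996^age * sex_f
  egfr_min / 60
}

#' Derive all covariates for a cohort table
#'
#' Adds BMI, BSA (Du Bois), LBM (Boer), creatinine-based eGFR and, where
#' cystatin C is present, cystatin-based eGFR to a covariate table with
#' columns `SEX` ("male"/"female"), `AGE` (years), `WT` (kg), `HT` (m),
#' `SCR` (umol/L) and optionally `CYSC` (mg/L).
#'
#' @param covariates A data frame with the columns above.
#' @return The input with columns `BMI`, `BSA`, `LBM`, `EGFR`, `EGFR_CYS`
#'   appended (the last is `NA` where cystatin C is missing).
#' @export
derive_covariates <- function(covariates) {
  req <- c("SEX", "AGE", "WT", "HT", "SCR")
  miss <- setdiff(req, names(covariates))
  if (length(miss)) {
    stop("missing covariate columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  covariates$BMI <- compute_bmi(covariates$WT, covariates$HT)
  covariates$BSA <- compute_bsa_dubois(covariates$WT, covariates$HT)
  covariates$LBM <- compute_lbm_boer(covariates$WT, covariates$HT, covariates$SEX)
  covariates$EGFR <- compute_egfr_ckdepi_cr(covariates$SCR, covariates$AGE, covariates$SEX)
  covariates$EGFR_CYS <- NA_real_
  if ("CYSC" %in% names(covariates)) {
    has <- !is.na(covariates$CYSC)
    if (any(has)) {
      covariates$EGFR_CYS[has] <- compute_egfr_ckdepi_cys(
        covariates$CYSC[has], covariates$AGE[has], covariates$SEX[has])
    }
  }
  covariates
}
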