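# Cockcroft-Gault creatinine clearance with configurable weight policy.
#
# CrCl (ml/min) = (140 - age) * weight / (72 * SCr[mg/dL]), * 0.85 if female.
# National guidance is unresolved on whether actual or ideal body weight
# belongs in the formula; all three common policies are exposed and the
# policy used is recorded in batch output.

UMOL_PER_MGDL <- 88.4

#' Convert serum creatinine to mg/dL
#'
#' @param value positive creatinine value(s).
#' @param unit `"mg/dL"` or `"umol/L"` (the micro sign spelling is accepted);
#'   recycled against `value`.
#' @return numeric vector in mg/dL.
#' @export
convert_creatinine <- function(value, unit) {
  if (any(!is.finite(value) | value <= 0)) stop("creatinine must be positive", call. = FALSE)
  unit <- rep_len(unit, length(value))
  umol <- unit %in% c("umol/L", "µmol/L", "micromol/L")
  mgdl <- unit == "mg/dL"
  if (any(!umol & !mgdl)) {
    stop("unknown creatinine unit: ", paste(unique(unit[!umol & !mgdl]), collapse = ", "),
         call. = FALSE)
  }
  ifelse(umol, value / UMOL_PER_MGDL, value)
}

#' Ideal body weight (Devine)
#'
#' 50 kg (male) or 45.5 kg (female) plus 2.3 kg per inch of height over
#' 5 feet; heights at or below 152.4 cm return the sex base weight (the
#' negative-excess branch is floored at zero).
#'
#' @param height_cm height in cm, > 0.
#' @param sex `"female"` or `"male"` (recycled).
#' @return kg.
#' @export
ideal_body_weight <- function(height_cm, sex) {
  if (any(!is.finite(height_cm) | height_cm <= 0)) stop("height must be positive", call. = FALSE)
  sex <- rep_len(sex, length(height_cm))
  if (any(!sex %in% c("female", "male"))) stop("sex must be female or male", call. = FALSE)
  base <- ifelse(sex == "male", 50, 45.5)
  inches_over <- pmax(0, height_cm / 2.54 - 60)
  base + 2.3 * inches_over
}

effective_weight <- function(weight_kg, height_cm, sex, policy) {
  if (policy == "actual") return(weight_kg)
  if (any(is.na(height_cm))) {
    stop("weight policy '", policy, "' requires height_cm", call. = FALSE)
  }
  ibw <- ideal_body_weight(height_cm, sex)
  if (policy == "ideal") return(ibw)
  # adjusted: ideal + 0.4 * excess, only when actual exceeds ideal
  ifelse(weight_kg > ibw, ibw + 0.4 * (weight_kg - ibw), weight_kg)
}

#' Cockcroft-Gault creatinine clearance
#'
#' Vectorised over all inputs. Monotone decreasing in age and serum
#' creatinine, increasing in effective weight; the female result is exactly
#' 0.85 times the male result at identical covariates.
#'
#' @param age years, in `[18, 140)` (the `140 - age` term degenerates beyond).
#' @param weight_kg actual body weight, > 0.
#' @param sex `"female"` or `"male"`.
#' @param serum_creatinine positive value in `creatinine_unit`.
#' @param creatinine_unit `"mg/dL"` (default) or `"umol/L"`.
#' @param height_cm required for the `ideal` and `adjusted` weight policies.
#' @param weight_policy `"actual"` (default: what EHRs record), `"ideal"`
#'   (Devine), or `"adjusted"` (ideal + 0.4 x excess over ideal, applied only
#'   when actual > ideal).
#' @return CrCl in ml/min, full floating precision.
#' @export
cockcroft_gault <- function(age, weight_kg, sex, serum_creatinine,
                            creatinine_unit = "mg/dL", height_cm = NA_real_,
                            weight_policy = c("actual", "ideal", "adjusted")) {
  weight_policy <- match.arg(weight_policy)
  n <- max(length(age), length(weight_kg), length(sex), length(serum_creatinine))
  age <- rep_len(age, n); weight_kg <- rep_len(weight_kg, n); sex <- rep_len(sex, n)
  serum_creatinine <- rep_len(serum_creatinine, n)
  creatinine_unit <- rep_len(creatinine_unit, n); height_cm <- rep_len(height_cm, n)
  if (any(!sex %in% c("female", "male"))) stop("sex must be female or male", call. = FALSE)
  if (any(!is.finite(age) | age < 18 | age >= 140)) {
    stop("age must be in [18, 140)", call. = FALSE)
  }
  if (any(!is.finite(weight_kg) | weight_kg <= 0)) stop("weight must be positive", call. = FALSE)
  scr <- convert_creatinine(serum_creatinine, creatinine_unit)
  w <- effective_weight(weight_kg, height_cm, sex, weight_policy)
  crcl <- (140 - age) * w / (72 * scr)
  crcl * ifelse(sex == "female", 0.85, 1)
}

#' Batch Cockcroft-Gault over a table of inputs
#'
#' @param df data frame with columns `age`, `weight_kg`, `sex`,
#'   `serum_creatinine`, `creatinine_unit`, and optionally `height_cm`.
#' @param weight_policy see [cockcroft_gault()].
#' @return `df` with `crcl_ml_min` and `weight_policy` columns appended.
#' @export
crcl_batch <- function(df, weight_policy = "actual") {
  h <- if ("height_cm" %in% names(df)) df$height_cm else NA_real_
  u <- if ("creatinine_unit" %in% names(df)) df$creatinine_unit else "mg/dL"
  dplyr::mutate(tibble::as_tibble(df),
                crcl_ml_min = cockcroft_gault(df$age, df$weight_kg, df$sex,
                                              df$serum_creatinine, u, h, weight_policy),
                weight_policy = weight_policy)
}
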