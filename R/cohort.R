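# Monthly cohort construction: inclusion criteria, 12-month lookback
# parameter extraction, AF flag, and per-patient dose assessment.
#
# Inclusion for month m: a registration interval covers day 1 of m; age at
# day 1 in [18, 120]; death date absent or strictly after day 1 (death on
# day 1 excludes); >= 1 DOAC prescription dated within m.

AGE_BANDS <- c("18-29", "30-39", "40-49", "50-59", "60-69", "70-79", ">=80")
LOOKBACK_DAYS <- 365L

age_band <- function(age) {
  cut(age, breaks = c(18, 30, 40, 50, 60, 70, 80, Inf), right = FALSE,
      labels = AGE_BANDS, include.lowest = TRUE)
}

weight_band <- function(weight_kg) {
  dplyr::case_when(
    is.na(weight_kg) ~ NA_character_,
    weight_kg < 50 ~ "<50",
    weight_kg > 120 ~ ">120",
    TRUE ~ "50-120"
  )
}

# distinct patient-level view of the patients table (one row per interval)
patient_level <- function(patients) {
  p <- dplyr::distinct(patients, .data$patient_id, .data$sex, .data$birth_date,
                       .data$death_date)
  if (anyDuplicated(p$patient_id)) {
    stop("duplicate patient_id with conflicting demographics in patients table",
         call. = FALSE)
  }
  p
}

#' Cohort eligibility flags for one month
#'
#' Applies the four inclusion criteria to every patient and returns a flag
#' per patient; [in_cohort()] is the single-patient convenience wrapper.
#'
#' @param patients typed patients tibble (one row per registration interval).
#' @param prescriptions typed prescriptions tibble.
#' @param month month specification (see [as_month()]).
#' @return tibble `patient_id`, `age`, `sex`, `eligible`.
#' @export
cohort_eligibility <- function(patients, prescriptions, month) {
  m1 <- month_start(month); mend <- month_end(month)
  p <- patient_level(patients)
  reg <- patients[patients$reg_start <= m1 &
                    (is.na(patients$reg_end) | patients$reg_end >= m1), ]
  p$registered <- p$patient_id %in% reg$patient_id
  p$age <- age_years(p$birth_date, m1)
  p$alive <- is.na(p$death_date) | p$death_date > m1
  rx <- prescriptions[prescriptions$date >= m1 & prescriptions$date <= mend, ]
  p$prescribed <- p$patient_id %in% rx$patient_id
  p$eligible <- p$registered & p$alive & p$prescribed & p$age >= 18 & p$age <= 120
  p[, c("patient_id", "age", "sex", "eligible")]
}

#' Is a single patient in the cohort for a month?
#'
#' @param patient rows of the patients table for one patient.
#' @param prescriptions that patient's prescriptions.
#' @inheritParams cohort_eligibility
#' @return logical flag.
#' @export
in_cohort <- function(patient, prescriptions, month) {
  el <- cohort_eligibility(patient, prescriptions, month)
  if (nrow(el) != 1) stop("in_cohort expects one patient", call. = FALSE)
  el$eligible
}

#' Registered adult study population size for each month
#'
#' Denominator for the prevalence series: patients registered on day 1,
#' aged 18-120, not dead — the inclusion criteria without the DOAC
#' prescription requirement.
#'
#' @param patients typed patients tibble.
#' @param months vector of month starts.
#' @return tibble `month`, `population`.
#' @export
study_population <- function(patients, months) {
  months <- as_month(months)
  p <- patient_level(patients)
  purrr::map_dfr(months, function(m1) {
    reg <- patients$reg_start <= m1 & (is.na(patients$reg_end) | patients$reg_end >= m1)
    reg_ids <- unique(patients$patient_id[reg])
    age <- age_years(p$birth_date, m1)
    ok <- p$patient_id %in% reg_ids & (is.na(p$death_date) | p$death_date > m1) &
      age >= 18 & age <= 120
    tibble::tibble(month = m1, population = sum(ok))
  })
}

#' Most recent observation value within the 12-month lookback
#'
#' Window: `[month_end - 365 days, month_end]`, both ends inclusive. Ties on
#' the same date are broken by taking the last row in file order.
#'
#' @param observations typed observations tibble (any number of patients).
#' @param concept observation concept to extract.
#' @param month index month.
#' @return tibble `patient_id`, `value`, `date` (one row per patient with a
#'   record in the window).
#' @export
latest_in_window <- function(observations, concept, month) {
  mend <- month_end(month)
  lo <- mend - LOOKBACK_DAYS
  ev <- observations[observations$concept == concept &
                       !is.na(observations$date) &
                       observations$date >= lo & observations$date <= mend, ]
  if (nrow(ev) == 0) {
    return(tibble::tibble(patient_id = character(0), value = numeric(0),
                          date = as.Date(character(0))))
  }
  ev <- ev[order(ev$patient_id, ev$date), ]      # stable: file order breaks ties
  out <- ev[!duplicated(ev$patient_id, fromLast = TRUE), ]
  out[, c("patient_id", "value", "date")]
}

#' Build the audit cohort for one month
#'
#' One row per in-cohort patient with: age and band, sex, latest weight /
#' creatinine / eGFR / CrCl within the lookback, the ever-recorded AF flag,
#' the month's latest DOAC regimen, and the dose assessment (computed when
#' AF, a CrCl record and a regimen are all present).
#'
#' @param data named list with `patients`, `observations`, `prescriptions`,
#'   `diagnoses` tibbles (as returned by [read_events()] per kind or
#'   [generate_synthetic_ehr()]).
#' @param month month specification.
#' @param rules dose-rules tibble; default [doac_dose_rules()].
#' @return tibble of monthly cohort rows.
#' @export
build_monthly_cohort <- function(data, month, rules = doac_dose_rules()) {
  m1 <- month_start(month); mend <- month_end(month)
  el <- cohort_eligibility(data$patients, data$prescriptions, month)
  rows <- el[el$eligible, c("patient_id", "age", "sex")]
  if (nrow(rows) == 0) return(empty_cohort(m1))

  # the month's latest prescription wins; same-day ties broken by file order
  rx <- data$prescriptions[data$prescriptions$date >= m1 & data$prescriptions$date <= mend, ]
  rx <- rx[order(rx$patient_id, rx$date), ]      # stable: file order breaks ties
  rx <- rx[!duplicated(rx$patient_id, fromLast = TRUE), ]
  rows <- dplyr::left_join(rows, rx[, c("patient_id", "drug", "strength_mg",
                                        "frequency_per_day")], by = "patient_id")

  for (cn in OBS_CONCEPTS) {
    v <- latest_in_window(data$observations, cn, month)
    names(v)[names(v) == "value"] <- cn
    rows <- dplyr::left_join(rows, v[, c("patient_id", cn)], by = "patient_id")
  }
  names(rows)[names(rows) == "weight"] <- "weight_kg"
  names(rows)[names(rows) == "serum_creatinine"] <- "creatinine"

  af_ids <- unique(data$diagnoses$patient_id[data$diagnoses$concept == "af_diagnosis" &
                                               data$diagnoses$date <= mend])
  rows$af <- rows$patient_id %in% af_ids

  rows$month <- m1
  rows$age_band <- as.character(age_band(rows$age))
  rows$weight_band <- weight_band(rows$weight_kg)
  rows$crcl_below_15 <- !is.na(rows$crcl) & rows$crcl < 15
  rows$calculable <- rows$sex %in% c("female", "male") & !is.na(rows$strength_mg)

  assessable <- rows$af & !is.na(rows$crcl) & !is.na(rows$drug)
  rows$assessment <- NA_character_
  if (any(assessable)) {
    rows$assessment[assessable] <- classify_dose(
      rows$drug[assessable], rows$strength_mg[assessable],
      rows$frequency_per_day[assessable], rows$crcl[assessable], rules
    )
  }
  rows[, cohort_cols()]
}

cohort_cols <- function() {
  c("month", "patient_id", "age", "age_band", "sex", "weight_kg", "weight_band",
    "creatinine", "egfr", "crcl", "crcl_below_15", "af", "drug", "strength_mg",
    "frequency_per_day", "assessment", "calculable")
}

empty_cohort <- function(m1) {
  tibble::tibble(month = as.Date(character(0)), patient_id = character(0),
                 age = integer(0), age_band = character(0), sex = character(0),
                 weight_kg = numeric(0), weight_band = character(0),
                 creatinine = numeric(0), egfr = numeric(0), crcl = numeric(0),
                 crcl_below_15 = logical(0), af = logical(0), drug = character(0),
                 strength_mg = numeric(0), frequency_per_day = numeric(0),
                 assessment = character(0), calculable = logical(0))
}

#' Build the cohort over a study window
#'
#' @inheritParams build_monthly_cohort
#' @param from,to first and last study months.
#' @return long tibble, one row per patient-month.
#' @export
build_cohort <- function(data, from, to, rules = doac_dose_rules()) {
  purrr::map_dfr(month_seq(from, to), function(m) build_monthly_cohort(data, m, rules))
}
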