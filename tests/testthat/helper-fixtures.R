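# Hand-built event-table fixtures shared across test files.

fx_patients <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(
      patient_id = r$id, sex = r$sex %||% "female",
      birth_date = as.Date(r$birth %||% "1950-01-01"),
      death_date = if (is.null(r$death)) as.Date(NA) else as.Date(r$death),
      reg_start = as.Date(r$reg_start %||% "2010-01-01"),
      reg_end = if (is.null(r$reg_end)) as.Date(NA) else as.Date(r$reg_end)
    )
  }))
}

fx_obs <- function(id, date, concept, value,
                   unit = c(weight = "kg", serum_creatinine = "umol/L",
                            egfr = "ml/min/1.73m2", crcl = "ml/min")[concept]) {
  tibble::tibble(patient_id = id, date = as.Date(date), concept = concept,
                 value = value, unit = unname(unit))
}

fx_rx <- function(id, date, drug = "apixaban", strength = 5, freq = 2L) {
  tibble::tibble(patient_id = id, date = as.Date(date), drug = drug,
                 strength_mg = strength, frequency_per_day = as.integer(freq))
}

fx_dx <- function(id, date, concept = "af_diagnosis") {
  tibble::tibble(patient_id = id, date = as.Date(date), concept = concept)
}

fx_empty_obs <- function() fx_obs(character(0), as.Date(character(0)), character(0), numeric(0), character(0))
fx_empty_dx <- function() fx_dx(character(0), as.Date(character(0)), character(0))

`%||%` <- function(a, b) if (is.null(a)) b else a

# small fast generator config for pipeline tests
fx_config <- function(seed = 7, n = 200, ...) {
  synthetic_config(seed = seed, n_patients = n, study_start = "2022-07",
                   study_end = "2023-02", doac_prevalence = 0.6, ...)
}
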