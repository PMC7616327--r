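# Seeded synthetic primary-care EHR generator.
#
# Emulates the statistical structure the audit assumes: an age/sex structure
# concentrated in the 70+ bands, per-parameter 12-month recording
# probabilities, AF prevalence among DOAC users, and a configurable
# match/overdose/underdose mix among prescribed regimens. Regimens are
# sampled category-first (sample the label, then a catalogue regimen the
# classifier maps to that label at the patient's CrCl), so the classifier's
# expected output equals the configured mix exactly.
#
# Recording model: per patient and parameter, with the configured probability
# the patient is a "recorder" with a random phase and an observation every
# 365 days; every 12-month lookback window then contains a record with
# exactly that probability, for every study month.

#' Synthetic-data configuration
#'
#' Defaults describe a plausible English primary-care DOAC population:
#' age mass in the 70+ bands, 44.5% female, AF in 74% of DOAC users,
#' 12-month recording probabilities around 0.73 (weight), 0.92 (eGFR),
#' 0.94 (creatinine) and 0.735 (CrCl), and an 86.2/2.7/11.1 percent
#' match/overdose/underdose mix. These document typical conditions; they are
#' configuration, not ground truth about any real population.
#'
#' @param seed integer RNG seed; the generator is deterministic given it.
#' @param n_patients registered population size.
#' @param study_start,study_end first and last study months (`"YYYY-MM"`).
#' @param doac_prevalence monthly probability a patient is prescribed a DOAC;
#'   scalar or one value per study month. The default ramps linearly from
#'   1.15% to 2.10% across the window.
#' @param age_band_weights named probabilities over the seven adult age bands.
#' @param sex_split probability female (among patients with known sex).
#' @param unknown_sex_prob probability of unknown sex (drives the
#'   non-calculable bucket).
#' @param recording_prob named probabilities of a record in any 12-month
#'   window, for `weight`, `creatinine`, `egfr`, `crcl`.
#' @param af_prob probability of an AF diagnosis among DOAC users.
#' @param dose_mix named probabilities for `match`, `overdose`, `underdose`;
#'   must sum to 1.
#' @param weight_mean,weight_sd central weight distribution (kg), truncated
#'   to `[50, 120]`.
#' @param weight_p_below_50,weight_p_above_120 tail masses drawn uniformly on
#'   `[35, 50)` and `(120, 160]`.
#' @param creatinine_mean,creatinine_sd serum creatinine (umol/L), truncated
#'   to `[30, 400]`.
#' @param crcl_median,crcl_sdlog lognormal recorded-CrCl distribution
#'   (ml/min); the defaults put about 1% of mass below 15 ml/min.
#' @param drug_mix named probabilities over the four DOACs.
#' @param death_prob probability of death at a uniform date within the study.
#' @return a validated `list` of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 20180101,
                             n_patients = 2000,
                             study_start = "2018-01",
                             study_end = "2023-02",
                             doac_prevalence = NULL,
                             age_band_weights = c("18-29" = 0.003, "30-39" = 0.010,
                                                  "40-49" = 0.025, "50-59" = 0.069,
                                                  "60-69" = 0.114, "70-79" = 0.332,
                                                  ">=80" = 0.404),
                             sex_split = 0.445,
                             unknown_sex_prob = 0.002,
                             recording_prob = c(weight = 0.728, creatinine = 0.943,
                                                egfr = 0.924, crcl = 0.735),
                             af_prob = 0.74,
                             dose_mix = c(match = 0.862, overdose = 0.027,
                                          underdose = 0.111),
                             weight_mean = 81, weight_sd = 17.5,
                             weight_p_below_50 = 0.038, weight_p_above_120 = 0.015,
                             creatinine_mean = 85, creatinine_sd = 25,
                             crcl_median = 70, crcl_sdlog = 0.66,
                             drug_mix = c(apixaban = 0.57, rivaroxaban = 0.28,
                                          edoxaban = 0.11, dabigatran = 0.04),
                             death_prob = 0.01) {
  months <- month_seq(study_start, study_end)
  if (is.null(doac_prevalence)) {
    doac_prevalence <- seq(0.0115, 0.0210, length.out = length(months))
  }
  doac_prevalence <- rep_len(doac_prevalence, length(months))
  cfg <- list(seed = as.integer(seed), n_patients = as.integer(n_patients),
              study_start = as_month(study_start), study_end = as_month(study_end),
              months = months, doac_prevalence = doac_prevalence,
              age_band_weights = age_band_weights, sex_split = sex_split,
              unknown_sex_prob = unknown_sex_prob, recording_prob = recording_prob,
              af_prob = af_prob, dose_mix = dose_mix,
              weight_mean = weight_mean, weight_sd = weight_sd,
              weight_p_below_50 = weight_p_below_50,
              weight_p_above_120 = weight_p_above_120,
              creatinine_mean = creatinine_mean, creatinine_sd = creatinine_sd,
              crcl_median = crcl_median, crcl_sdlog = crcl_sdlog,
              drug_mix = drug_mix, death_prob = death_prob)
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  probs <- c(cfg$doac_prevalence, cfg$age_band_weights, cfg$sex_split,
             cfg$unknown_sex_prob, cfg$recording_prob, cfg$af_prob, cfg$dose_mix,
             cfg$weight_p_below_50, cfg$weight_p_above_120, cfg$death_prob)
  if (any(!is.finite(probs) | probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(cfg$dose_mix) - 1) > 1e-9) stop("dose_mix must sum to 1", call. = FALSE)
  need <- c("match", "overdose", "underdose")
  if (length(setdiff(need, names(cfg$dose_mix)))) {
    stop("dose_mix needs named entries match/overdose/underdose", call. = FALSE)
  }
  if (length(setdiff(OBS_CONCEPTS, c(names(cfg$recording_prob), "serum_creatinine")))
      > 1 || length(setdiff(c("weight", "creatinine", "egfr", "crcl"),
                            names(cfg$recording_prob)))) {
    stop("recording_prob needs named entries weight/creatinine/egfr/crcl", call. = FALSE)
  }
  if (cfg$weight_p_below_50 + cfg$weight_p_above_120 >= 1) {
    stop("weight tail masses must sum to less than 1", call. = FALSE)
  }
  if (cfg$study_start > cfg$study_end) stop("study months out of order", call. = FALSE)
  if (length(setdiff(names(cfg$age_band_weights), AGE_BANDS))) {
    stop("age_band_weights names must be the seven adult bands", call. = FALSE)
  }
  cfg
}

#' Read a synthetic-data configuration from a YAML file
#'
#' Keys mirror the arguments of [synthetic_config()]; unknown keys error.
#'
#' @param path YAML file path.
#' @return a `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(synthetic_config))
  extra <- setdiff(names(raw), known)
  if (length(extra)) stop("unknown config key(s): ", paste(extra, collapse = ", "),
                          call. = FALSE)
  for (k in c("age_band_weights", "recording_prob", "dose_mix", "drug_mix")) {
    if (!is.null(raw[[k]])) raw[[k]] <- unlist(raw[[k]])
  }
  do.call(synthetic_config, raw)
}

standard_regimen_catalogue <- function() {
  tibble::tibble(
    drug = c("apixaban", "apixaban", "dabigatran", "dabigatran",
             "edoxaban", "edoxaban", "rivaroxaban", "rivaroxaban"),
    strength_mg = c(2.5, 5, 110, 150, 30, 60, 15, 20),
    frequency_per_day = c(2L, 2L, 2L, 2L, 1L, 1L, 1L, 1L)
  )
}

rlnorm_trunc <- function(n, meanlog, sdlog, lo = 0, hi = Inf) {
  plo <- plnorm(lo, meanlog, sdlog); phi <- plnorm(hi, meanlog, sdlog)
  qlnorm(runif(n, plo, phi), meanlog, sdlog)
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(runif(n, plo, phi), mean, sd)
}

# category-first regimen sampling: for each patient pick a catalogue regimen
# the classifier maps to the target category at that CrCl, drugs weighted by
# drug_mix, regimens uniform within drug.
sample_regimens_for <- function(patient_id, crcl, target, drug_mix, rules) {
  cat_tab <- standard_regimen_catalogue()
  grid <- tidyr::crossing(tibble::tibble(patient_id = patient_id, crcl = crcl,
                                         target = target), cat_tab)
  grid$category <- classify_dose(grid$drug, grid$strength_mg,
                                 grid$frequency_per_day, grid$crcl, rules)
  cand <- grid[grid$category == grid$target, ]
  missing <- setdiff(patient_id, cand$patient_id)
  if (length(missing)) {
    i <- match(missing[1], patient_id)
    stop(sprintf(paste0("infeasible dose_mix: no catalogue regimen is a '%s' at ",
                        "CrCl %.1f ml/min"), target[i], crcl[i]), call. = FALSE)
  }
  # row weight: drug_mix share split evenly over that drug's candidate
  # regimens; one weighted draw per patient via the Gumbel-max trick
  per_drug <- dplyr::count(cand, .data$patient_id, .data$drug, name = ".k")
  cand <- dplyr::left_join(cand, per_drug, by = c("patient_id", "drug"))
  w <- unname(drug_mix[cand$drug]) / cand$.k
  key <- log(w) - log(-log(runif(nrow(cand))))
  cand <- cand[order(cand$patient_id, key), ]
  out <- cand[!duplicated(cand$patient_id, fromLast = TRUE), ]
  out[, c("patient_id", "drug", "strength_mg", "frequency_per_day")]
}

#' Generate a synthetic event-level EHR
#'
#' Deterministic given the config seed. Returns the four event tables plus a
#' patient-level ground-truth table recording, for every patient, the latent
#' parameter values, the recording flags, and the dose category assigned at
#' generation time (`NA` for patients never designated for classification:
#' no AF, or recorded CrCl below 15 ml/min).
#'
#' @param config a [synthetic_config()].
#' @param rules dose-rules table the regimen sampler classifies against.
#' @return named list `patients`, `observations`, `prescriptions`,
#'   `diagnoses`, `truth`.
#' @export
generate_synthetic_ehr <- function(config, rules = doac_dose_rules()) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, generate_impl(config, rules))
}

generate_impl <- function(cfg, rules) {
  n <- cfg$n_patients
  months <- cfg$months
  last_m1 <- months[length(months)]
  E <- month_end(last_m1)                         # anchor for recording phases
  window_floor <- month_end(months[1]) - LOOKBACK_DAYS

  ids <- sprintf("p%06d", seq_len(n))
  sex <- ifelse(runif(n) < cfg$unknown_sex_prob, "unknown",
                ifelse(runif(n) < cfg$sex_split, "female", "male"))
  band <- if (n) sample(names(cfg$age_band_weights), n, replace = TRUE,
                        prob = cfg$age_band_weights) else character(0)
  lo <- c("18-29" = 18, "30-39" = 30, "40-49" = 40, "50-59" = 50,
          "60-69" = 60, "70-79" = 70, ">=80" = 80)[band]
  hi <- c("18-29" = 30, "30-39" = 40, "40-49" = 50, "50-59" = 60,
          "60-69" = 70, "70-79" = 80, ">=80" = 100)[band]
  age_months <- floor(runif(n, lo * 12, hi * 12))
  birth_date <- add_months(rep(last_m1, n), -age_months)
  death_date <- as.Date(rep(NA_real_, n))
  dies <- runif(n) < cfg$death_prob
  study_days <- as.integer(E - months[1])
  death_date[dies] <- months[1] + floor(runif(sum(dies), 0, study_days + 1))

  patients <- tibble::tibble(
    patient_id = ids, sex = sex, birth_date = birth_date, death_date = death_date,
    reg_start = as.Date("2010-01-01"), reg_end = as.Date(NA)
  )

  # latent clinical values, constant over time per patient
  tail_draw <- runif(n)
  weight <- rnorm_trunc(n, cfg$weight_mean, cfg$weight_sd, 50, 120)
  weight[tail_draw < cfg$weight_p_below_50] <- runif(sum(tail_draw < cfg$weight_p_below_50), 35, 50)
  hi_tail <- tail_draw >= cfg$weight_p_below_50 &
    tail_draw < cfg$weight_p_below_50 + cfg$weight_p_above_120
  weight[hi_tail] <- runif(sum(hi_tail), 120, 160)
  weight <- round(weight, 1)
  creatinine <- round(rnorm_trunc(n, cfg$creatinine_mean, cfg$creatinine_sd, 30, 400), 0)
  egfr <- round(pmin(120, pmax(5, 7000 / creatinine + rnorm(n, 0, 8))), 0)
  crcl <- round(rlnorm_trunc(n, log(cfg$crcl_median), cfg$crcl_sdlog), 1)

  af <- runif(n) < cfg$af_prob
  diagnoses <- tibble::tibble(
    patient_id = ids[af],
    date = patients$reg_start[af] + floor(runif(sum(af), 0, 1500)),
    concept = "af_diagnosis"
  )

  # dose category and regimen (category-first); CrCl redrawn inside the band
  # where the category is feasible under the rules table
  category <- rep(NA_character_, n)
  designate <- af & crcl >= 15
  if (any(designate)) {
    category[designate] <- sample(names(cfg$dose_mix), sum(designate),
                                  replace = TRUE, prob = cfg$dose_mix)
  }
  ml <- log(cfg$crcl_median)
  redraw_ov <- !is.na(category) & category == "overdose"
  crcl[redraw_ov] <- pmin(pmax(round(
    rlnorm_trunc(sum(redraw_ov), ml, cfg$crcl_sdlog, 15, 50), 1), 15), 50)
  redraw_un <- !is.na(category) & category == "underdose"
  crcl[redraw_un] <- pmax(round(
    rlnorm_trunc(sum(redraw_un), ml, cfg$crcl_sdlog, 30, Inf), 1), 30)

  regimen <- tibble::tibble(patient_id = ids, drug = NA_character_,
                            strength_mg = NA_real_, frequency_per_day = NA_integer_)
  if (any(!is.na(category))) {
    idx <- which(!is.na(category))
    picked <- sample_regimens_for(ids[idx], crcl[idx], category[idx],
                                  cfg$drug_mix, rules)
    m <- match(picked$patient_id, regimen$patient_id)
    regimen$drug[m] <- picked$drug
    regimen$strength_mg[m] <- picked$strength_mg
    regimen$frequency_per_day[m] <- picked$frequency_per_day
  }
  # undesignated patients (no AF, or CrCl < 15): any standard regimen
  free <- is.na(category)
  if (any(free)) {
    cat_tab <- standard_regimen_catalogue()
    drug_f <- sample(names(cfg$drug_mix), sum(free), replace = TRUE, prob = cfg$drug_mix)
    pick2 <- vapply(drug_f, function(d) sample(which(cat_tab$drug == d), 1), integer(1))
    regimen$drug[free] <- cat_tab$drug[pick2]
    regimen$strength_mg[free] <- cat_tab$strength_mg[pick2]
    regimen$frequency_per_day[free] <- cat_tab$frequency_per_day[pick2]
  }

  # recorder/phase observation model: a recorder emits one observation every
  # 365 days at a random phase, so every 12-month window contains a record
  # with exactly the configured probability
  latent <- list(weight = weight, creatinine = creatinine, egfr = egfr, crcl = crcl)
  unit_of <- c(weight = "kg", creatinine = "umol/L", egfr = "ml/min/1.73m2",
               crcl = "ml/min")
  concept_of <- c(weight = "weight", creatinine = "serum_creatinine",
                  egfr = "egfr", crcl = "crcl")
  recorded <- list()
  obs <- list()
  n_back <- ceiling(as.numeric(E - window_floor) / 365) + 1
  for (p in names(latent)) {
    rec <- runif(n) < cfg$recording_prob[[p]]
    recorded[[p]] <- rec
    if (!any(rec)) next
    phase <- floor(runif(sum(rec), 0, 365))
    dates <- rep(E, sum(rec)) - phase
    per <- purrr::map_dfr(seq_len(n_back), function(k) {
      tibble::tibble(patient_id = ids[rec], date = dates - 365 * (k - 1),
                     concept = concept_of[[p]], value = latent[[p]][rec],
                     unit = unit_of[[p]])
    })
    obs[[p]] <- per[per$date >= window_floor, ]
  }
  observations <- dplyr::bind_rows(obs)
  if (nrow(observations)) {
    dd <- death_date[match(observations$patient_id, ids)]
    observations <- observations[is.na(dd) | observations$date <= dd, ]
    observations <- dplyr::arrange(observations, .data$patient_id, .data$date,
                                   .data$concept)
  } else {
    observations <- tibble::tibble(patient_id = character(0),
                                   date = as.Date(character(0)),
                                   concept = character(0), value = numeric(0),
                                   unit = character(0))
  }

  # monthly prescriptions: independent Bernoulli per patient-month at the
  # configured prevalence; one dated prescription per on-month
  on <- matrix(runif(n * length(months)) <
                 rep(cfg$doac_prevalence, each = n), nrow = n)
  pm <- which(on, arr.ind = TRUE)
  prescriptions <- if (nrow(pm)) {
    m1 <- months[pm[, 2]]
    ndays <- as.integer(month_end(m1) - m1) + 1L
    date <- m1 + floor(runif(nrow(pm)) * ndays)
    pid <- ids[pm[, 1]]
    keep <- is.na(death_date[pm[, 1]]) | date < death_date[pm[, 1]]
    tibble::tibble(
      patient_id = pid[keep], date = date[keep],
      drug = regimen$drug[pm[, 1]][keep],
      strength_mg = regimen$strength_mg[pm[, 1]][keep],
      frequency_per_day = regimen$frequency_per_day[pm[, 1]][keep]
    )
  } else {
    tibble::tibble(patient_id = character(0), date = as.Date(character(0)),
                   drug = character(0), strength_mg = numeric(0),
                   frequency_per_day = integer(0))
  }
  prescriptions <- dplyr::arrange(prescriptions, .data$date, .data$patient_id)

  truth <- tibble::tibble(
    patient_id = ids, sex = sex, birth_date = birth_date, death_date = death_date,
    af = af, weight_kg = weight, creatinine = creatinine, egfr = egfr,
    crcl = crcl, category = category, drug = regimen$drug,
    strength_mg = regimen$strength_mg,
    frequency_per_day = regimen$frequency_per_day,
    weight_recorded = recorded$weight %||% rep(FALSE, n),
    creatinine_recorded = recorded$creatinine %||% rep(FALSE, n),
    egfr_recorded = recorded$egfr %||% rep(FALSE, n),
    crcl_recorded = recorded$crcl %||% rep(FALSE, n)
  )

  list(patients = patients, observations = observations,
       prescriptions = prescriptions, diagnoses = diagnoses, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ground-truth monthly summary of a generated dataset
#'
#' Bookkeeping from the generation-time assignments, independent of the
#' cohort module: per month, the number of eligible patients on a DOAC, the
#' AF count, per-parameter recorded counts, and the dose-category counts
#' among patients designated for classification whose CrCl is recorded in
#' that month's lookback window.
#'
#' @param data list from [generate_synthetic_ehr()] (must carry `truth`).
#' @param months months to summarise; default every month with a prescription.
#' @return tibble, one row per month.
#' @export
summarize_truth <- function(data, months = NULL) {
  tr <- data$truth
  if (is.null(tr)) stop("data has no truth table; was it generated here?", call. = FALSE)
  rx <- data$prescriptions
  if (is.null(months)) {
    months <- sort(unique(as_month(rx$date)))
  } else {
    months <- as_month(months)
  }
  purrr::map_dfr(months, function(m1) {
    mend <- month_end(m1)
    on_ids <- unique(rx$patient_id[rx$date >= m1 & rx$date <= mend])
    t <- tr[tr$patient_id %in% on_ids, ]
    age <- age_years(t$birth_date, m1)
    t <- t[(is.na(t$death_date) | t$death_date > m1) & age >= 18 & age <= 120, ]
    # a crcl record exists in this month's window iff the patient is a
    # recorder whose phased schedule puts a date in [mend - 365, mend];
    # with 365-day spacing that is every recorder still alive
    crcl_obs <- data$observations[data$observations$concept == "crcl" &
                                    data$observations$date >= mend - LOOKBACK_DAYS &
                                    data$observations$date <= mend, ]
    classified <- t[!is.na(t$category) & t$patient_id %in% crcl_obs$patient_id, ]
    tibble::tibble(
      month = m1, n_on_doac = nrow(t), n_af = sum(t$af),
      n_weight_recorded = sum(t$weight_recorded),
      n_creatinine_recorded = sum(t$creatinine_recorded),
      n_egfr_recorded = sum(t$egfr_recorded),
      n_crcl_recorded = sum(t$crcl_recorded),
      n_match = sum(classified$category == "match"),
      n_overdose = sum(classified$category == "overdose"),
      n_underdose = sum(classified$category == "underdose")
    )
  })
}

#' Write a generated dataset to a directory of CSVs
#'
#' Writes `patients.csv`, `observations.csv`, `prescriptions.csv`,
#' `diagnoses.csv` and `truth.csv`.
#'
#' @param data list from [generate_synthetic_ehr()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in c("patients", "observations", "prescriptions", "diagnoses")) {
    write_events(data[[k]], file.path(dir, paste0(k, ".csv")))
  }
  readr::write_csv(data$truth, file.path(dir, "truth.csv"), na = "", progress = FALSE)
  invisible(dir)
}

#' Read a generated dataset back from a directory of CSVs
#'
#' @param dir directory written by [write_synthetic()] (or holding real
#'   extracts in the documented schemas); `truth.csv` is optional.
#' @param quiet passed to [read_events()].
#' @return named list of typed tables.
#' @export
read_ehr_dir <- function(dir, quiet = TRUE) {
  out <- list(
    patients = read_events(file.path(dir, "patients.csv"), "patients", quiet = quiet),
    observations = read_events(file.path(dir, "observations.csv"), "observations", quiet = quiet),
    prescriptions = read_events(file.path(dir, "prescriptions.csv"), "prescriptions", quiet = quiet),
    diagnoses = read_events(file.path(dir, "diagnoses.csv"), "diagnoses", quiet = quiet)
  )
  tpath <- file.path(dir, "truth.csv")
  if (file.exists(tpath)) {
    out$truth <- readr::read_csv(tpath, col_types = readr::cols(
      patient_id = "c", sex = "c", birth_date = "D", death_date = "D",
      af = "l", weight_kg = "d", creatinine = "d", egfr = "d", crcl = "d",
      category = "c", drug = "c", strength_mg = "d", frequency_per_day = "i",
      weight_recorded = "l", creatinine_recorded = "l", egfr_recorded = "l",
      crcl_recorded = "l"
    ), progress = FALSE)
  }
  out
}
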