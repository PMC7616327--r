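test_that("config validation rejects bad probabilities and infeasible settings", {
  expect_error(synthetic_config(af_prob = 1.2), "\\[0, 1\\]")
  expect_error(synthetic_config(dose_mix = c(match = 0.5, overdose = 0.2, underdose = 0.2)),
               "sum to 1")
  expect_error(synthetic_config(study_start = "2023-05", study_end = "2023-02"),
               "must not be after")
  expect_error(synthetic_config(weight_p_below_50 = 0.6, weight_p_above_120 = 0.5),
               "tail masses")
})

test_that("generation is deterministic given the seed, byte-identical on disk", {
  cfg <- fx_config(seed = 99, n = 150)
  d1 <- generate_synthetic_ehr(cfg)
  d2 <- generate_synthetic_ehr(cfg)
  expect_identical(d1, d2)

  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  write_synthetic(d1, dir1); write_synthetic(d2, dir2)
  for (f in list.files(dir1)) {
    expect_identical(readLines(file.path(dir1, f)), readLines(file.path(dir2, f)),
                     label = f)
  }
  d3 <- generate_synthetic_ehr(fx_config(seed = 100, n = 150))
  expect_false(identical(d1$observations, d3$observations))
})

test_that("generated tables pass the readers with zero rejects", {
  cfg <- fx_config(seed = 21, n = 150)
  dir <- withr::local_tempdir()
  write_synthetic(generate_synthetic_ehr(cfg), dir)
  for (kind in c("patients", "observations", "prescriptions", "diagnoses")) {
    tab <- read_events(file.path(dir, paste0(kind, ".csv")), kind, quiet = TRUE)
    expect_equal(nrow(attr(tab, "rejects")), 0, label = kind)
    expect_gt(nrow(tab), 0)
  }
})

test_that("events respect chronology: no observations or prescriptions after death", {
  cfg <- fx_config(seed = 31, n = 400, death_prob = 0.5)
  d <- generate_synthetic_ehr(cfg)
  dd <- d$patients$death_date[match(d$observations$patient_id, d$patients$patient_id)]
  expect_true(all(is.na(dd) | d$observations$date <= dd))
  ddr <- d$patients$death_date[match(d$prescriptions$patient_id, d$patients$patient_id)]
  expect_true(all(is.na(ddr) | d$prescriptions$date < ddr))
})

test_that("degenerate configs behave exactly: all-recorded and all-match", {
  cfg <- synthetic_config(seed = 8, n_patients = 250, study_start = "2022-09",
                          study_end = "2023-02", doac_prevalence = 0.8,
                          recording_prob = c(weight = 1, creatinine = 1, egfr = 1, crcl = 1),
                          af_prob = 1,
                          dose_mix = c(match = 1, overdose = 0, underdose = 0),
                          death_prob = 0)
  d <- generate_synthetic_ehr(cfg)
  co <- build_cohort(d, "2022-09", "2023-02")
  expect_gt(nrow(co), 0)
  # every cohort patient-month has all four parameters recorded
  expect_true(all(!is.na(co$weight_kg) & !is.na(co$creatinine) &
                    !is.na(co$egfr) & !is.na(co$crcl)))
  # AF everywhere and CrCl present: every row carries an assessment
  expect_true(all(!is.na(co$assessment)))
  # classifier reports 100% match on the classified denominator
  s <- dose_outcome_summary(co)
  expect_equal(s$percent[s$category == "match"], 100)
  expect_equal(unname(s$n[s$category %in% c("overdose", "underdose")]), c(0L, 0L))
})

test_that("zero patients produce empty tables and an empty truth summary", {
  cfg <- fx_config(seed = 1, n = 0)
  d <- generate_synthetic_ehr(cfg)
  expect_equal(nrow(d$patients), 0)
  expect_equal(nrow(d$prescriptions), 0)
  expect_equal(nrow(summarize_truth(d)), 0)
})

test_that("truth bookkeeping equals what the cohort pipeline computes", {
  cfg <- fx_config(seed = 13, n = 600)
  d <- generate_synthetic_ehr(cfg)
  tt <- summarize_truth(d, months = c("2022-12", "2023-02"))
  for (i in seq_len(nrow(tt))) {
    co <- build_monthly_cohort(d, tt$month[i])
    expect_equal(tt$n_on_doac[i], nrow(co))
    expect_equal(tt$n_af[i], sum(co$af))
    expect_equal(tt$n_match[i], sum(co$assessment == "match", na.rm = TRUE))
    expect_equal(tt$n_overdose[i], sum(co$assessment == "overdose", na.rm = TRUE))
    expect_equal(tt$n_underdose[i], sum(co$assessment == "underdose", na.rm = TRUE))
  }
})

test_that("configured probabilities are recovered within 3 binomial SEs (n >= 5000)", {
  cfg <- synthetic_config(seed = 17, n_patients = 6000, study_start = "2022-03",
                          study_end = "2023-02", doac_prevalence = 1)
  d <- generate_synthetic_ehr(cfg)
  co <- build_monthly_cohort(d, "2023-02")
  n <- nrow(co)
  within_3se <- function(est, p, n) abs(est - p) <= 3 * sqrt(p * (1 - p) / n)
  expect_true(within_3se(mean(!is.na(co$weight_kg)), cfg$recording_prob[["weight"]], n))
  expect_true(within_3se(mean(!is.na(co$creatinine)), cfg$recording_prob[["creatinine"]], n))
  expect_true(within_3se(mean(!is.na(co$egfr)), cfg$recording_prob[["egfr"]], n))
  expect_true(within_3se(mean(!is.na(co$crcl)), cfg$recording_prob[["crcl"]], n))
  expect_true(within_3se(mean(co$af), cfg$af_prob, n))
  cls <- co$assessment[co$assessment %in% c("match", "overdose", "underdose")]
  for (k in names(cfg$dose_mix)) {
    expect_true(within_3se(mean(cls == k), cfg$dose_mix[[k]], length(cls)), label = k)
  }
  # weight tail mass among weight-recorded patients
  wrec <- co$weight_kg[!is.na(co$weight_kg)]
  expect_true(within_3se(mean(wrec < 50), cfg$weight_p_below_50, length(wrec)))
})

test_that("configured prevalence trajectory is recovered from monthly cohort sizes", {
  cfg <- synthetic_config(seed = 23, n_patients = 6000, study_start = "2022-10",
                          study_end = "2023-02", doac_prevalence = c(0.0115, 0.014, 0.017, 0.019, 0.021),
                          death_prob = 0)
  d <- generate_synthetic_ehr(cfg)
  months <- month_seq("2022-10", "2023-02")
  sizes <- vapply(months, function(m) nrow(build_monthly_cohort(d, m)), integer(1))
  pop <- study_population(d$patients, months)$population
  for (i in seq_along(months)) {
    p <- cfg$doac_prevalence[i]
    expect_true(abs(sizes[i] / pop[i] - p) <= 3 * sqrt(p * (1 - p) / pop[i]),
                label = format(months[i]))
  }
})

test_that("YAML config round-trips and rejects unknown keys", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "cfg.yaml")
  yaml::write_yaml(list(seed = 5, n_patients = 50, study_start = "2022-01",
                        study_end = "2022-03",
                        dose_mix = list(match = 0.9, overdose = 0.04, underdose = 0.06)), p)
  cfg <- read_synthetic_config(p)
  expect_equal(cfg$n_patients, 50L)
  expect_equal(cfg$dose_mix[["match"]], 0.9)
  yaml::write_yaml(list(seed = 5, n_patients = 50, bogus_key = 1), p)
  expect_error(read_synthetic_config(p), "unknown config key")
})
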