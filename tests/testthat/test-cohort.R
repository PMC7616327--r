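test_that("inclusion criteria: registration, age bounds, death, prescription", {
  m <- "2022-07"
  # all criteria met
  p <- fx_patients(list(id = "a", birth = "1947-03-01"))
  rx <- fx_rx("a", "2022-07-14")
  expect_true(in_cohort(p, rx, m))

  # death on day 1 of the month excludes (as does any earlier death)
  p2 <- fx_patients(list(id = "a", birth = "1947-03-01", death = "2022-07-01"))
  expect_false(in_cohort(p2, rx, m))
  p2b <- fx_patients(list(id = "a", birth = "1947-03-01", death = "2022-07-02"))
  expect_true(in_cohort(p2b, rx, m))

  # aged 17 years 11 months at month start is out; 18 exactly is in
  p3 <- fx_patients(list(id = "a", birth = "2004-08-01"))
  expect_false(in_cohort(p3, rx, m))
  p4 <- fx_patients(list(id = "a", birth = "2004-07-01"))
  expect_true(in_cohort(p4, rx, m))
  # above 120 is out
  p5 <- fx_patients(list(id = "a", birth = "1901-06-01"))
  expect_false(in_cohort(p5, rx, m))

  # registration interval must cover day 1
  p6 <- fx_patients(list(id = "a", birth = "1947-03-01", reg_start = "2022-07-02"))
  expect_false(in_cohort(p6, rx, m))
  p7 <- fx_patients(list(id = "a", birth = "1947-03-01", reg_end = "2022-06-30"))
  expect_false(in_cohort(p7, rx, m))

  # prescription must fall inside the month
  expect_false(in_cohort(p, fx_rx("a", "2022-06-30"), m))
  expect_false(in_cohort(p, fx_rx("a", "2022-08-01"), m))
})

test_that("latest_in_window takes the most recent value inside the 365-day lookback", {
  m <- "2023-02"                     # month end 2023-02-28
  mend <- as.Date("2023-02-28")
  obs <- dplyr::bind_rows(
    fx_obs("a", mend - 400, "crcl", 30),
    fx_obs("a", mend - 100, "crcl", 55),
    fx_obs("a", mend - 200, "crcl", 40)
  )
  out <- latest_in_window(obs, "crcl", m)
  expect_equal(out$value, 55)

  # nothing in window -> absent
  expect_equal(nrow(latest_in_window(fx_obs("a", mend - 400, "crcl", 30), "crcl", m)), 0)
  expect_equal(nrow(latest_in_window(fx_empty_obs(), "crcl", m)), 0)

  # boundary: exactly 365 days before month end is included; 366 is not
  expect_equal(latest_in_window(fx_obs("a", mend - 365, "crcl", 22), "crcl", m)$value, 22)
  expect_equal(nrow(latest_in_window(fx_obs("a", mend - 366, "crcl", 22), "crcl", m)), 0)
  # events after month end never leak in
  expect_equal(nrow(latest_in_window(fx_obs("a", mend + 1, "crcl", 22), "crcl", m)), 0)

  # same-date ties resolve to the last in file order
  ties <- dplyr::bind_rows(fx_obs("a", mend - 10, "crcl", 41),
                           fx_obs("a", mend - 10, "crcl", 42))
  expect_equal(latest_in_window(ties, "crcl", m)$value, 42)
})

test_that("build_monthly_cohort assembles parameters, AF flag and assessment", {
  m <- "2023-02"
  patients <- fx_patients(
    list(id = "af_ok", sex = "female", birth = "1948-05-01"),
    list(id = "no_crcl", sex = "male", birth = "1952-02-01"),
    list(id = "no_af", sex = "male", birth = "1940-11-01"),
    list(id = "unk", sex = "unknown", birth = "1955-01-01")
  )
  obs <- dplyr::bind_rows(
    fx_obs("af_ok", "2022-11-10", "crcl", 45),
    fx_obs("af_ok", "2022-11-10", "weight", 67),
    fx_obs("no_crcl", "2022-12-01", "serum_creatinine", 95),
    fx_obs("no_af", "2022-10-05", "crcl", 80)
  )
  rx <- dplyr::bind_rows(
    fx_rx("af_ok", "2023-02-10", "apixaban", 5, 2),
    fx_rx("no_crcl", "2023-02-11", "rivaroxaban", 20, 1),
    fx_rx("no_af", "2023-02-12", "rivaroxaban", 20, 1),
    fx_rx("unk", "2023-02-13", "edoxaban", 60, 1)
  )
  dx <- dplyr::bind_rows(fx_dx("af_ok", "2015-01-01"), fx_dx("no_crcl", "2016-01-01"))
  data <- list(patients = patients, observations = obs, prescriptions = rx, diagnoses = dx)

  co <- build_monthly_cohort(data, m)
  co <- co[order(co$patient_id), ]
  expect_equal(nrow(co), 4)

  r1 <- co[co$patient_id == "af_ok", ]
  expect_true(r1$af)
  expect_equal(r1$crcl, 45)
  expect_equal(r1$assessment, "match")

  # creatinine recorded but no CrCl -> no assessment even with AF
  r2 <- co[co$patient_id == "no_crcl", ]
  expect_true(r2$af)
  expect_equal(r2$creatinine, 95)
  expect_true(is.na(r2$crcl) && is.na(r2$assessment))

  # CrCl recorded but no AF -> no assessment
  r3 <- co[co$patient_id == "no_af", ]
  expect_false(r3$af)
  expect_true(is.na(r3$assessment))

  # unknown sex -> non-calculable but retained
  expect_false(co$calculable[co$patient_id == "unk"])
  expect_true(all(co$calculable[co$patient_id != "unk"]))
})

test_that("the month's latest prescription wins when several DOACs appear", {
  m <- "2023-02"
  patients <- fx_patients(list(id = "a", birth = "1948-05-01"))
  rx <- dplyr::bind_rows(
    fx_rx("a", "2023-02-03", "rivaroxaban", 20, 1),
    fx_rx("a", "2023-02-20", "apixaban", 5, 2)
  )
  data <- list(patients = patients, observations = fx_empty_obs(),
               prescriptions = rx, diagnoses = fx_empty_dx())
  co <- build_monthly_cohort(data, m)
  expect_equal(co$drug, "apixaban")
})

test_that("AF is an ever-recorded flag; parameters are window-limited", {
  m <- "2023-02"
  patients <- fx_patients(list(id = "a", birth = "1948-05-01"))
  data <- list(patients = patients,
               observations = fx_obs("a", "2020-01-01", "crcl", 50),  # stale
               prescriptions = fx_rx("a", "2023-02-10"),
               diagnoses = fx_dx("a", "2005-06-01"))                  # old AF code
  co <- build_monthly_cohort(data, m)
  expect_true(co$af)
  expect_true(is.na(co$crcl))
})

test_that("empty cohorts and duplicate patients are handled", {
  patients <- fx_patients(list(id = "a", birth = "1948-05-01"))
  data <- list(patients = patients, observations = fx_empty_obs(),
               prescriptions = fx_rx("a", "2021-01-05"), diagnoses = fx_empty_dx())
  expect_equal(nrow(build_monthly_cohort(data, "2023-02")), 0)

  dup <- dplyr::bind_rows(patients, fx_patients(list(id = "a", sex = "male", birth = "1950-01-01")))
  data$patients <- dup
  expect_error(build_monthly_cohort(data, "2023-02"), "duplicate")
})

test_that("creatinine-recorded rows partition into with- and without-CrCl", {
  cfg <- fx_config(seed = 11, n = 400)
  d <- generate_synthetic_ehr(cfg)
  co <- build_monthly_cohort(d, "2023-02")
  n_cr <- sum(!is.na(co$creatinine))
  n_both <- sum(!is.na(co$creatinine) & !is.na(co$crcl))
  n_cr_only <- sum(!is.na(co$creatinine) & is.na(co$crcl))
  expect_equal(n_both + n_cr_only, n_cr)
  # denominator identity: calculable + non-calculable = total
  expect_equal(sum(co$calculable) + sum(!co$calculable), nrow(co))
})
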