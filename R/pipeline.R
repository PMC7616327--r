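# End-to-end wiring: generate -> cohort -> measures, with file outputs.
# These functions back the inst/cli/doacaudit.R command-line wrapper
# (subcommands generate / run / report).

#' Generate a synthetic dataset and write it to disk
#'
#' Writes the four event CSVs plus `truth.csv` and a `manifest.yaml`
#' recording the seed and a hash of the configuration, so reruns are
#' verifiably identical.
#'
#' @param config a [synthetic_config()] or path to a YAML config file.
#' @param out_dir output directory.
#' @return the output directory, invisibly.
#' @export
audit_generate <- function(config, out_dir) {
  if (is.character(config)) config <- read_synthetic_config(config)
  data <- generate_synthetic_ehr(config)
  write_synthetic(data, out_dir)
  plain <- unclass(config)
  plain$study_start <- format(plain$study_start)
  plain$study_end <- format(plain$study_end)
  plain$months <- NULL
  manifest <- list(seed = config$seed,
                   config_hash = rlang::hash(plain),
                   n_patients = config$n_patients)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' Run the audit over a study window
#'
#' Builds the monthly cohorts, the measure series, the prevalence series, the
#' characteristics tables for the first and last month, and the dose-outcome
#' summary for the last month. When `out_dir` is given, writes
#' `cohort.csv`, `measures.csv`, `prevalence.csv`,
#' `characteristics_<month>.csv` and `dose_outcomes.csv`.
#'
#' @param input a directory of event CSVs (see [read_ehr_dir()]) or an
#'   in-memory dataset list.
#' @param from,to study window months.
#' @param rules `"builtin"` or path to a rules CSV (see [read_dose_rules()]).
#' @param out_dir optional output directory.
#' @param quiet suppress progress messages.
#' @return list with `cohort`, `measures`, `prevalence`, `characteristics`
#'   (named by month), `dose_outcomes`.
#' @export
run_audit <- function(input, from, to, rules = "builtin", out_dir = NULL,
                      quiet = FALSE) {
  data <- if (is.character(input)) read_ehr_dir(input) else input
  rules_tab <- if (identical(rules, "builtin")) doac_dose_rules() else read_dose_rules(rules)
  validate_dose_rules(rules_tab)
  months <- month_seq(from, to)

  cohort <- build_cohort(data, from, to, rules_tab)
  if (!quiet) {
    message(sprintf("run_audit: %d patient-months over %d months", nrow(cohort),
                    length(months)))
  }
  measures <- measure_series(cohort)
  sizes <- dplyr::count(cohort, .data$month)
  sizes <- dplyr::full_join(tibble::tibble(month = months), sizes, by = "month")
  sizes$n[is.na(sizes$n)] <- 0L
  pop <- study_population(data$patients, months)
  prevalence <- prevalence_series(sizes, pop)

  chars <- list()
  for (m in c(months[1], months[length(months)])) {
    key <- format(as.Date(m, origin = "1970-01-01"), "%Y-%m")
    rows <- cohort[cohort$month == m, ]
    chars[[key]] <- characteristics_table(rows, as.Date(m, origin = "1970-01-01"))
  }
  dose_out <- dose_outcome_summary(cohort[cohort$month == months[length(months)], ])

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(cohort, file.path(out_dir, "cohort.csv"), na = "", progress = FALSE)
    readr::write_csv(measures, file.path(out_dir, "measures.csv"), na = "", progress = FALSE)
    readr::write_csv(prevalence, file.path(out_dir, "prevalence.csv"), na = "", progress = FALSE)
    for (key in names(chars)) {
      readr::write_csv(chars[[key]], file.path(out_dir, paste0("characteristics_", key, ".csv")),
                       na = "", progress = FALSE)
    }
    readr::write_csv(dose_out, file.path(out_dir, "dose_outcomes.csv"), na = "", progress = FALSE)
  }
  list(cohort = cohort, measures = measures, prevalence = prevalence,
       characteristics = chars, dose_outcomes = dose_out)
}

#' Change summary between two audited months
#'
#' @param run result of [run_audit()], or a directory containing its outputs.
#' @param t1,t2 the two months to compare (`t1` before `t2`).
#' @param out optional CSV path for the summary.
#' @return the [change_summary()] tibble.
#' @export
audit_report <- function(run, t1, t2, out = NULL) {
  t1 <- as_month(t1); t2 <- as_month(t2)
  if (t1 > t2) stop("t1 must not be after t2", call. = FALSE)
  get_chars <- function(m) {
    key <- format(m, "%Y-%m")
    if (is.list(run) && !is.null(run$characteristics[[key]])) {
      return(run$characteristics[[key]])
    }
    if (is.list(run)) {
      rows <- run$cohort[run$cohort$month == m, ]
      if (nrow(rows) == 0 && !any(run$cohort$month == m)) {
        stop("no cohort rows for month ", key, call. = FALSE)
      }
      return(characteristics_table(rows, m))
    }
    path <- file.path(run, paste0("characteristics_", key, ".csv"))
    if (!file.exists(path)) stop("missing characteristics file for ", key, call. = FALSE)
    readr::read_csv(path, col_types = readr::cols(
      month = "D", characteristic = "c", category = "c", numerator = "i",
      denominator = "i", percent = "d"
    ), progress = FALSE)
  }
  cs <- change_summary(get_chars(t1), get_chars(t2))
  if (!is.null(out)) readr::write_csv(cs, out, na = "", progress = FALSE)
  cs
}
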