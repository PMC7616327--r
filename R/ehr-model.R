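# Event-level EHR data model: typed readers/writers for the four delimited
# tables shared by every pipeline stage, plus codelist filtering.
#
# File dialect: comma-delimited, UTF-8, mandatory header, ISO-8601 dates.
# Month-precision birth dates are stored as the first of the month.

DOAC_DRUGS <- c("apixaban", "dabigatran", "edoxaban", "rivaroxaban")
SEX_LEVELS <- c("female", "male", "unknown")
OBS_CONCEPTS <- c("weight", "serum_creatinine", "egfr", "crcl")
OBS_UNITS <- list(
  weight = "kg",
  serum_creatinine = c("umol/L", "µmol/L", "mg/dL"),
  egfr = "ml/min/1.73m2",
  crcl = "ml/min"
)

#' Column schemas for the event tables
#'
#' The four table kinds and their documented CSV columns:
#' * `patients`: `patient_id,sex,birth_date,death_date,reg_start,reg_end`
#'   (one row per registration interval; `reg_end` empty means still registered)
#' * `observations`: `patient_id,date,concept,value,unit`
#' * `prescriptions`: `patient_id,date,drug,strength_mg,frequency_per_day`
#' * `diagnoses`: `patient_id,date,concept`
#'
#' @return named list of character vectors (column names per table kind).
#' @export
event_schemas <- function() {
  list(
    patients = c("patient_id", "sex", "birth_date", "death_date", "reg_start", "reg_end"),
    observations = c("patient_id", "date", "concept", "value", "unit"),
    prescriptions = c("patient_id", "date", "drug", "strength_mg", "frequency_per_day"),
    diagnoses = c("patient_id", "date", "concept")
  )
}

parse_date_col <- function(x) {
  out <- as.Date(rep(NA_real_, length(x)))
  ok <- !is.na(x) & x != ""
  out[ok] <- as.Date(vapply(x[ok], function(s) {
    d <- tryCatch(as.Date(s, format = "%Y-%m-%d"), error = function(e) as.Date(NA))
    as.numeric(d)
  }, numeric(1)))
  out
}

# Per-kind row validators: return a character vector of problems ("" = ok),
# one message per row, naming the offending field.
validate_rows <- function(df, kind) {
  n <- nrow(df)
  bad <- character(n)
  note <- function(cond, msg) {
    cond[is.na(cond)] <- FALSE
    bad[cond & bad == ""] <<- msg
  }
  if (kind == "patients") {
    note(!df$sex %in% SEX_LEVELS, "sex: not one of female/male/unknown")
    note(is.na(df$birth_date), "birth_date: missing or unparseable date")
    note(!is.na(df$death_date_raw) & df$death_date_raw != "" & is.na(df$death_date),
         "death_date: unparseable date")
    note(!is.na(df$death_date) & df$death_date < df$birth_date,
         "death_date: before birth_date")
    note(is.na(df$reg_start), "reg_start: missing or unparseable date")
    note(!is.na(df$reg_end_raw) & df$reg_end_raw != "" & is.na(df$reg_end),
         "reg_end: unparseable date")
    note(!is.na(df$reg_end) & df$reg_end < df$reg_start, "reg_end: before reg_start")
  } else if (kind == "observations") {
    note(is.na(df$date), "date: missing or unparseable")
    note(!df$concept %in% OBS_CONCEPTS,
         paste0("concept: not one of ", paste(OBS_CONCEPTS, collapse = "/")))
    note(is.na(df$value) | !is.finite(df$value) | df$value < 0,
         "value: must be a finite non-negative number")
    unit_ok <- mapply(function(cn, u) {
      if (!cn %in% OBS_CONCEPTS) TRUE else u %in% OBS_UNITS[[cn]]
    }, df$concept, df$unit)
    note(!unit_ok, "unit: not recognised for this concept")
  } else if (kind == "prescriptions") {
    note(is.na(df$date), "date: missing or unparseable")
    note(!df$drug %in% DOAC_DRUGS,
         paste0("drug: not one of ", paste(DOAC_DRUGS, collapse = "/")))
    note(is.na(df$strength_mg) | df$strength_mg <= 0, "strength_mg: must be > 0")
    note(is.na(df$frequency_per_day) | df$frequency_per_day < 1 |
           df$frequency_per_day != round(df$frequency_per_day),
         "frequency_per_day: must be a positive integer")
  } else if (kind == "diagnoses") {
    note(is.na(df$date), "date: missing or unparseable")
    note(is.na(df$concept) | df$concept == "", "concept: missing")
  }
  note(is.na(df$patient_id) | df$patient_id == "", "patient_id: missing")
  bad
}

type_rows <- function(raw, kind) {
  df <- raw
  if ("birth_date" %in% names(df)) {
    df$birth_date <- parse_date_col(raw$birth_date)
    df$death_date_raw <- raw$death_date
    df$death_date <- parse_date_col(raw$death_date)
    df$reg_start <- parse_date_col(raw$reg_start)
    df$reg_end_raw <- raw$reg_end
    df$reg_end <- parse_date_col(raw$reg_end)
  }
  if ("date" %in% names(df)) df$date <- parse_date_col(raw$date)
  if ("value" %in% names(df)) df$value <- suppressWarnings(as.numeric(raw$value))
  if ("strength_mg" %in% names(df)) df$strength_mg <- suppressWarnings(as.numeric(raw$strength_mg))
  if ("frequency_per_day" %in% names(df)) {
    df$frequency_per_day <- suppressWarnings(as.numeric(raw$frequency_per_day))
  }
  df
}

#' Read one event table from CSV into the typed model
#'
#' Every row is either accepted into the typed collection or rejected with a
#' row-numbered diagnostic; nothing is silently dropped. The rejects (row
#' number, field message, raw row) are attached as `attr(x, "rejects")` and
#' the accepted/rejected counts are reported via `message()`.
#'
#' @param path path to a CSV file with the documented header.
#' @param kind one of `"patients"`, `"observations"`, `"prescriptions"`,
#'   `"diagnoses"`.
#' @param quiet suppress the count message.
#' @return a tibble of accepted, typed rows with a `rejects` attribute.
#' @export
read_events <- function(path, kind = c("patients", "observations", "prescriptions", "diagnoses"),
                        quiet = FALSE) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  want <- event_schemas()[[kind]]
  extra <- setdiff(names(raw), want)
  if (length(extra)) stop("unknown column(s) in ", basename(path), ": ",
                          paste(extra, collapse = ", "), call. = FALSE)
  if (length(setdiff(want, names(raw)))) {
    stop("missing column(s) in ", basename(path), ": ",
         paste(setdiff(want, names(raw)), collapse = ", "), call. = FALSE)
  }
  raw <- raw[want]
  typed <- type_rows(raw, kind)
  problems <- if (nrow(typed)) validate_rows(typed, kind) else character(0)
  keep <- problems == ""
  rejects <- tibble::tibble(row = which(!keep), problem = problems[!keep])
  out <- typed[keep, want, drop = FALSE]
  out <- tibble::as_tibble(out)
  if ("frequency_per_day" %in% names(out)) {
    out$frequency_per_day <- as.integer(out$frequency_per_day)
  }
  if (!quiet) {
    message(sprintf("read_events(%s): %d accepted, %d rejected", kind, nrow(out), nrow(rejects)))
    if (nrow(rejects)) {
      for (i in seq_len(nrow(rejects))) {
        message(sprintf("  row %d rejected: %s", rejects$row[i], rejects$problem[i]))
      }
    }
  }
  attr(out, "rejects") <- rejects
  out
}

#' Write one event table to CSV
#'
#' Inverse of [read_events()] for the documented dialect: dates serialise as
#' ISO-8601 `YYYY-MM-DD`, so `read_events(write_events(x))` round-trips.
#'
#' @param x a typed event tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(x, path) {
  readr::write_csv(x, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a two-column codelist (code, concept)
#'
#' Stub codelists stand in for hosted SNOMED CT / dm+d lists: each code maps
#' to exactly one concept.
#'
#' @param path CSV with columns `code,concept`.
#' @return tibble with columns `code`, `concept`.
#' @export
read_codelist <- function(path) {
  cl <- readr::read_csv(path, col_types = "cc", progress = FALSE)
  if (!identical(names(cl), c("code", "concept"))) {
    stop("codelist must have columns code,concept", call. = FALSE)
  }
  if (nrow(cl) == 0) stop("codelist is empty", call. = FALSE)
  if (anyDuplicated(cl$code)) stop("codelist maps a code to more than one concept", call. = FALSE)
  cl
}

#' Built-in stub codelists
#'
#' The synthetic tables use concept names directly as codes, so the stub
#' lists are identity mappings for the DOAC drugs and the audited concepts.
#'
#' @return named list of codelist tibbles (`doacs`, `observations`, `af`).
#' @export
stub_codelists <- function() {
  list(
    doacs = tibble::tibble(code = DOAC_DRUGS, concept = DOAC_DRUGS),
    observations = tibble::tibble(code = OBS_CONCEPTS, concept = OBS_CONCEPTS),
    af = tibble::tibble(code = "af_diagnosis", concept = "af_diagnosis")
  )
}

#' Keep only events whose code belongs to a codelist
#'
#' The matching column is auto-detected (`code`, then `concept`, then `drug`);
#' input order is preserved.
#'
#' @param events an event tibble.
#' @param codelist a codelist tibble from [read_codelist()] or [stub_codelists()].
#' @param code_col optional explicit name of the column to match.
#' @return the filtered tibble, original order.
#' @export
filter_by_codelist <- function(events, codelist, code_col = NULL) {
  if (is.null(code_col)) {
    code_col <- intersect(c("code", "concept", "drug"), names(events))[1]
    if (is.na(code_col)) stop("no code/concept/drug column to match on", call. = FALSE)
  }
  events[events[[code_col]] %in% codelist$code, , drop = FALSE]
}
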