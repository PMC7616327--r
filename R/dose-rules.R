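# Renal dose rules for DOACs in atrial fibrillation, and classification of a
# prescribed regimen against them.
#
# The built-in table encodes the CrCl-banded recommended regimens for the
# four DOACs. Printed integer band edges are made unambiguous and gapless:
#   apixaban    [15,30) 2.5 mg BID | [30,Inf) 5 mg BID
#   dabigatran  [30,50] and (50,Inf): both 110 mg BID and 150 mg BID
#   edoxaban    [15,50] 30 mg OD   | (50,Inf) 60 mg OD
#   rivaroxaban [15,50) 15 mg OD   | [50,Inf) 20 mg OD
# No drug has a recommended dose below 15 ml/min (all DOACs avoided there);
# dabigatran additionally has no recommended dose below 30 ml/min.

STANDARD_FREQUENCY <- c(apixaban = 2L, dabigatran = 2L, edoxaban = 1L, rivaroxaban = 1L)

#' Built-in DOAC renal dose rules (atrial fibrillation)
#'
#' One row per drug x CrCl band x recommended regimen; dabigatran lists both
#' of its strengths in both bands, so the table has 10 rows.
#'
#' @return tibble with columns `drug`, `crcl_low`, `low_inclusive`,
#'   `crcl_high`, `high_inclusive`, `strength_mg`, `frequency_per_day`.
#' @export
doac_dose_rules <- function() {
  tibble::tribble(
    ~drug,         ~crcl_low, ~low_inclusive, ~crcl_high, ~high_inclusive, ~strength_mg, ~frequency_per_day,
    "apixaban",           30,           TRUE,        Inf,           FALSE,            5,                 2L,
    "apixaban",           15,           TRUE,         30,           FALSE,          2.5,                 2L,
    "dabigatran",         50,          FALSE,        Inf,           FALSE,          110,                 2L,
    "dabigatran",         50,          FALSE,        Inf,           FALSE,          150,                 2L,
    "dabigatran",         30,           TRUE,         50,            TRUE,          110,                 2L,
    "dabigatran",         30,           TRUE,         50,            TRUE,          150,                 2L,
    "edoxaban",           50,          FALSE,        Inf,           FALSE,           60,                 1L,
    "edoxaban",           15,           TRUE,         50,            TRUE,           30,                 1L,
    "rivaroxaban",        50,           TRUE,        Inf,           FALSE,           20,                 1L,
    "rivaroxaban",        15,           TRUE,         50,           FALSE,           15,                 1L
  )
}

#' Validate a dose-rules table
#'
#' Checks the structural invariants: no band starts below 15 ml/min, and per
#' drug the band union covers `[15, Inf)` (dabigatran: `[30, Inf)`) without
#' gaps. Overlapping bands are allowed only where they recommend different
#' strengths of the same drug.
#'
#' @param rules a rules tibble (see [doac_dose_rules()] for columns).
#' @return `rules`, invisibly; errors describing the violated constraint.
#' @export
validate_dose_rules <- function(rules) {
  need <- names(doac_dose_rules())
  if (length(setdiff(need, names(rules)))) {
    stop("rules table missing column(s): ", paste(setdiff(need, names(rules)), collapse = ", "),
         call. = FALSE)
  }
  if (any(rules$crcl_low < 15)) stop("rule with crcl_low < 15 ml/min", call. = FALSE)
  if (any(rules$crcl_high <= rules$crcl_low)) stop("rule with empty CrCl band", call. = FALSE)
  for (d in unique(rules$drug)) {
    rd <- rules[rules$drug == d, ]
    floor_d <- min(rd$crcl_low)
    # walk the band union upwards from the drug's floor; a gap is a point not
    # covered by any band
    probe <- floor_d
    if (!any(rd$low_inclusive & rd$crcl_low == probe)) {
      stop(d, ": band union does not start at its floor ", probe, call. = FALSE)
    }
    repeat {
      covering <- rd$crcl_low < probe | (rd$low_inclusive & rd$crcl_low == probe)
      covering <- covering & (probe < rd$crcl_high | (rd$high_inclusive & probe == rd$crcl_high))
      if (!any(covering)) stop(d, ": coverage gap at CrCl ", probe, call. = FALSE)
      hi <- max(rd$crcl_high[covering])
      hi_incl <- any(rd$high_inclusive[covering] & rd$crcl_high[covering] == hi)
      if (is.infinite(hi)) break
      # next point just above the covered prefix
      nxt <- if (hi_incl) hi + 1e-9 else hi
      if (nxt <= probe) break
      probe <- nxt
    }
  }
  invisible(rules)
}

#' Read a dose-rules table from CSV
#'
#' Allows swapping in an alternative national table; columns as in
#' [doac_dose_rules()], with `crcl_high` empty or `Inf` for open-ended bands.
#'
#' @param path CSV path.
#' @return validated rules tibble.
#' @export
read_dose_rules <- function(path) {
  rules <- readr::read_csv(path, col_types = readr::cols(
    drug = "c", crcl_low = "d", low_inclusive = "l", crcl_high = "d",
    high_inclusive = "l", strength_mg = "d", frequency_per_day = "i"
  ), progress = FALSE)
  rules$crcl_high[is.na(rules$crcl_high)] <- Inf
  validate_dose_rules(rules)
  rules
}

band_contains <- function(rules, crcl) {
  lo_ok <- rules$crcl_low < crcl | (rules$low_inclusive & rules$crcl_low == crcl)
  hi_ok <- crcl < rules$crcl_high | (rules$high_inclusive & crcl == rules$crcl_high)
  lo_ok & hi_ok
}

#' Recommended regimens for a drug at a given CrCl
#'
#' @param drug one of the four DOACs.
#' @param crcl CrCl in ml/min, > 0 (scalar).
#' @param rules rules tibble; default the built-in table.
#' @return tibble of `strength_mg`, `frequency_per_day` (zero rows when no
#'   recommended dose exists: any drug below 15 ml/min, dabigatran below 30).
#' @export
recommended_regimens <- function(drug, crcl, rules = doac_dose_rules()) {
  if (!drug %in% DOAC_DRUGS) stop("unknown drug: ", drug, call. = FALSE)
  if (!is.finite(crcl) || crcl <= 0) stop("crcl must be positive", call. = FALSE)
  rd <- rules[rules$drug == drug, ]
  rd[band_contains(rd, crcl), c("strength_mg", "frequency_per_day")]
}

#' Classify prescribed DOAC regimens against the recommended dose
#'
#' Vectorised. Category logic, in order of precedence:
#' * `contraindicated_crcl_below_15` — CrCl < 15 ml/min (all DOACs avoided);
#'   excluded from match/over/under denominators and surfaced as a safety count.
#' * `non_standard_regimen` — frequency differs from the drug's licensed
#'   schedule (BID for apixaban/dabigatran, OD for edoxaban/rivaroxaban);
#'   excluded from match/over/under so a wrong-frequency regimen is never
#'   silently called a match.
#' * `no_recommended_dose` — CrCl >= 15 but the drug has no recommended band
#'   (dabigatran below 30 ml/min); excluded from match/over/under.
#' * `match` — the prescribed (strength, frequency) is in the recommended set.
#' * `overdose` / `underdose` — prescribed daily dose (strength x frequency)
#'   above the maximum / below the minimum recommended daily dose.
#' * `unclassifiable` — residual (a non-catalogue strength whose daily dose
#'   falls strictly between recommended daily doses without matching any).
#'
#' @param drug,strength_mg,frequency_per_day prescribed regimen (vectors).
#' @param crcl recorded CrCl in ml/min, > 0.
#' @param rules rules tibble; default [doac_dose_rules()].
#' @return character vector of categories.
#' @export
classify_dose <- function(drug, strength_mg, frequency_per_day, crcl,
                          rules = doac_dose_rules()) {
  n <- max(length(drug), length(strength_mg), length(frequency_per_day), length(crcl))
  drug <- rep_len(drug, n); strength_mg <- rep_len(strength_mg, n)
  frequency_per_day <- rep_len(frequency_per_day, n); crcl <- rep_len(crcl, n)
  if (any(!drug %in% DOAC_DRUGS)) {
    stop("unknown drug: ", paste(unique(drug[!drug %in% DOAC_DRUGS]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(crcl) | crcl <= 0)) stop("crcl must be positive", call. = FALSE)

  # recommended daily-dose envelope and membership per row: one vectorised
  # pass per rule (the table is small, the input can be large)
  min_daily <- rep(Inf, n); max_daily <- rep(-Inf, n); member <- rep(FALSE, n)
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    sel <- drug == r$drug &
      (r$crcl_low < crcl | (r$low_inclusive & r$crcl_low == crcl)) &
      (crcl < r$crcl_high | (r$high_inclusive & crcl == r$crcl_high))
    if (!any(sel)) next
    rd <- r$strength_mg * r$frequency_per_day
    min_daily[sel] <- pmin(min_daily[sel], rd)
    max_daily[sel] <- pmax(max_daily[sel], rd)
    member[sel] <- member[sel] | (strength_mg[sel] == r$strength_mg &
                                    frequency_per_day[sel] == r$frequency_per_day)
  }
  no_band <- !is.finite(min_daily)
  min_daily[no_band] <- NA_real_
  max_daily[no_band] <- NA_real_

  daily <- strength_mg * frequency_per_day
  std <- STANDARD_FREQUENCY[drug]
  out <- rep("unclassifiable", n)
  out[!is.na(max_daily) & daily > max_daily] <- "overdose"
  out[!is.na(min_daily) & daily < min_daily] <- "underdose"
  out[member] <- "match"
  out[is.na(min_daily)] <- "no_recommended_dose"
  out[frequency_per_day != std] <- "non_standard_regimen"
  out[crcl < 15] <- "contraindicated_crcl_below_15"
  out
}

#' Full dose assessment for a single prescription
#'
#' Scalar companion to [classify_dose()] returning the recommended set used.
#'
#' @inheritParams classify_dose
#' @return list with `category`, `recommended` (tibble, zero rows when no
#'   recommended dose exists), `prescribed` (tibble) and `crcl`.
#' @export
assess_dose <- function(drug, strength_mg, frequency_per_day, crcl,
                        rules = doac_dose_rules()) {
  category <- classify_dose(drug, strength_mg, frequency_per_day, crcl, rules)
  rec <- if (crcl < 15) {
    tibble::tibble(strength_mg = numeric(0), frequency_per_day = integer(0))
  } else {
    recommended_regimens(drug, crcl, rules)
  }
  list(category = category,
       recommended = rec,
       prescribed = tibble::tibble(drug = drug, strength_mg = strength_mg,
                                   frequency_per_day = frequency_per_day),
       crcl = crcl)
}
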