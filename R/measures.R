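# Monthly proportion series, the characteristics table, change summaries and
# the dose-outcome summary. Every percentage in every report travels with its
# numerator and denominator (the printed tables this mirrors mix denominators
# between rows, so transparency is enforced here), and all rounding is
# half-up to one decimal, applied only at report time.

#' Percentage of a numerator over a denominator
#'
#' @param numerator,denominator non-negative counts, `numerator <= denominator`.
#' @return `100 * numerator / denominator` rounded half-up to 1 decimal;
#'   `NA` when the denominator is zero.
#' @export
proportion <- function(numerator, denominator) {
  n <- max(length(numerator), length(denominator))
  numerator <- rep_len(numerator, n)
  denominator <- rep_len(denominator, n)
  if (any(numerator < 0 | denominator < 0, na.rm = TRUE)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (any(numerator > denominator, na.rm = TRUE)) {
    stop("numerator exceeds denominator", call. = FALSE)
  }
  ifelse(denominator > 0, round_half_up(100 * numerator / denominator, 1), NA_real_)
}

#' Relative change between two counts, as a signed percentage
#'
#' @param count_t1 baseline count, > 0.
#' @param count_t2 later count.
#' @return `100 * (count_t2 - count_t1) / count_t1`, half-up to 1 decimal.
#' @export
relative_change <- function(count_t1, count_t2) {
  if (any(count_t1 <= 0)) stop("baseline count must be positive", call. = FALSE)
  round_half_up(100 * (count_t2 - count_t1) / count_t1, 1)
}

#' Percentage-point change between two percentages
#'
#' @param pct_t1,pct_t2 percentages in `[0, 100]`.
#' @return `pct_t2 - pct_t1`, half-up to 1 decimal, signed.
#' @export
pp_change <- function(pct_t1, pct_t2) {
  if (any(pct_t1 < 0 | pct_t1 > 100 | pct_t2 < 0 | pct_t2 > 100, na.rm = TRUE)) {
    stop("percentages must be in [0, 100]", call. = FALSE)
  }
  round_half_up(pct_t2 - pct_t1, 1)
}

#' Match / overdose / underdose summary for one month's cohort
#'
#' Percentages are over the classified denominator (rows whose assessment is
#' match, overdose or underdose); contraindicated, no-recommended-dose and
#' non-standard rows are reported separately and never dilute the split.
#'
#' @param rows monthly cohort rows from [build_monthly_cohort()].
#' @return tibble `category`, `n`, `denominator`, `percent`.
#' @export
dose_outcome_summary <- function(rows) {
  classified <- c("match", "overdose", "underdose")
  other <- c("contraindicated_crcl_below_15", "no_recommended_dose",
             "non_standard_regimen", "unclassifiable")
  a <- rows$assessment
  den <- sum(a %in% classified, na.rm = TRUE)
  count_of <- function(keys) {
    vapply(keys, function(k) sum(a == k, na.rm = TRUE), integer(1), USE.NAMES = FALSE)
  }
  main <- tibble::tibble(
    category = classified,
    n = count_of(classified),
    denominator = den,
    percent = proportion(count_of(classified), den)
  )
  extra <- tibble::tibble(
    category = other,
    n = count_of(other),
    denominator = NA_integer_,
    percent = NA_real_
  )
  dplyr::bind_rows(main, extra)
}

char_row <- function(characteristic, category, n, den) {
  tibble::tibble(characteristic = characteristic, category = category,
                 numerator = as.integer(n), denominator = as.integer(den),
                 percent = proportion(n, den))
}

#' Characteristics table for one month's cohort
#'
#' The full block mirrored by the report: totals, calculable split, sex, age
#' bands, weight recorded with the <50 / 50-120 / >120 split (over the
#' weight-recorded denominator), eGFR / creatinine / CrCl recorded, CrCl < 15
#' (over the CrCl-recorded denominator), creatinine-but-no-CrCl, indication
#' (AF vs other), AF-and-CrCl (reported against both the total and the
#' calculable denominator), and the match/over/under block (over the
#' classified denominator). Sex, age and indication counts are taken among
#' calculable patients; their percentages use the total-cohort denominator.
#'
#' @param rows monthly cohort rows.
#' @param month month the rows belong to (used to label the output).
#' @return tibble `month`, `characteristic`, `category`, `numerator`,
#'   `denominator`, `percent`.
#' @export
characteristics_table <- function(rows, month) {
  total <- nrow(rows)
  calc <- rows[rows$calculable, , drop = FALSE]
  n_calc <- nrow(calc)
  w_rec <- sum(!is.na(rows$weight_kg))
  crcl_rec <- sum(!is.na(rows$crcl))
  out <- dplyr::bind_rows(
    char_row("total_on_doac", "all", total, total),
    char_row("non_calculable", "all", total - n_calc, total),
    char_row("calculable", "all", n_calc, total),
    char_row("sex", "female", sum(calc$sex == "female"), total),
    char_row("sex", "male", sum(calc$sex == "male"), total),
    purrr::map_dfr(AGE_BANDS, function(b) {
      char_row("age_band", b, sum(calc$age_band == b), total)
    }),
    char_row("weight", "recorded", w_rec, total),
    char_row("weight_band", "<50", sum(!is.na(rows$weight_band) & rows$weight_band == "<50"), w_rec),
    char_row("weight_band", "50-120", sum(!is.na(rows$weight_band) & rows$weight_band == "50-120"), w_rec),
    char_row("weight_band", ">120", sum(!is.na(rows$weight_band) & rows$weight_band == ">120"), w_rec),
    char_row("egfr", "recorded", sum(!is.na(rows$egfr)), total),
    char_row("creatinine", "recorded", sum(!is.na(rows$creatinine)), total),
    char_row("crcl", "recorded", crcl_rec, total),
    char_row("crcl_band", "<15", sum(rows$crcl_below_15), crcl_rec),
    char_row("creatinine_no_crcl", "recorded",
             sum(!is.na(rows$creatinine) & is.na(rows$crcl)), total),
    char_row("indication", "af", sum(calc$af), total),
    char_row("indication", "other", sum(!calc$af), total),
    char_row("af_and_crcl", "recorded", sum(rows$af & !is.na(rows$crcl)), total),
    char_row("af_and_crcl_calculable_denominator", "recorded",
             sum(calc$af & !is.na(calc$crcl)), n_calc)
  )
  dose <- dose_outcome_summary(rows)
  dose_rows <- tibble::tibble(
    characteristic = "dose_vs_recommended", category = dose$category,
    numerator = dose$n, denominator = dose$denominator, percent = dose$percent
  )
  out <- dplyr::bind_rows(out, dose_rows)
  out$month <- month_start(month)
  out[, c("month", "characteristic", "category", "numerator", "denominator", "percent")]
}

#' Monthly measure series from a long cohort table
#'
#' One row per measure per month with numerator, denominator and percentage.
#' Measures: `weight_recorded`, `egfr_recorded`, `creatinine_recorded`,
#' `crcl_recorded`, `creatinine_no_crcl`, `af_recorded` (all over the monthly
#' cohort), `af_and_crcl` (over the cohort), and `dose_match` / `dose_overdose`
#' / `dose_underdose` (over the classified denominator).
#'
#' @param cohort long cohort tibble from [build_cohort()].
#' @return tibble `measure`, `month`, `numerator`, `denominator`, `percent`.
#' @export
measure_series <- function(cohort) {
  per_month <- function(f, den_f, name) {
    dplyr::bind_rows(lapply(split(cohort, cohort$month), function(rows) {
      tibble::tibble(measure = name, month = rows$month[1],
                     numerator = f(rows), denominator = den_f(rows))
    }))
  }
  n_all <- function(rows) nrow(rows)
  n_classified <- function(rows) {
    sum(rows$assessment %in% c("match", "overdose", "underdose"), na.rm = TRUE)
  }
  specs <- list(
    weight_recorded = list(function(r) sum(!is.na(r$weight_kg)), n_all),
    egfr_recorded = list(function(r) sum(!is.na(r$egfr)), n_all),
    creatinine_recorded = list(function(r) sum(!is.na(r$creatinine)), n_all),
    crcl_recorded = list(function(r) sum(!is.na(r$crcl)), n_all),
    creatinine_no_crcl = list(function(r) sum(!is.na(r$creatinine) & is.na(r$crcl)), n_all),
    af_recorded = list(function(r) sum(r$af), n_all),
    af_and_crcl = list(function(r) sum(r$af & !is.na(r$crcl)), n_all),
    dose_match = list(function(r) sum(r$assessment == "match", na.rm = TRUE), n_classified),
    dose_overdose = list(function(r) sum(r$assessment == "overdose", na.rm = TRUE), n_classified),
    dose_underdose = list(function(r) sum(r$assessment == "underdose", na.rm = TRUE), n_classified)
  )
  out <- dplyr::bind_rows(lapply(names(specs), function(nm) {
    per_month(specs[[nm]][[1]], specs[[nm]][[2]], nm)
  }))
  out$percent <- proportion(out$numerator, out$denominator)
  dplyr::arrange(out, .data$measure, .data$month)
}

#' Monthly DOAC prevalence out of the registered adult population
#'
#' @param cohort_sizes tibble `month`, `n` (monthly cohort sizes).
#' @param population tibble `month`, `population` from [study_population()].
#' @return tibble `measure`, `month`, `numerator`, `denominator`, `percent`.
#' @export
prevalence_series <- function(cohort_sizes, population) {
  if (!setequal(cohort_sizes$month, population$month)) {
    stop("cohort and population months do not match", call. = FALSE)
  }
  j <- dplyr::inner_join(cohort_sizes, population, by = "month")
  tibble::tibble(measure = "doac_prevalence", month = j$month, numerator = j$n,
                 denominator = j$population,
                 percent = proportion(j$n, j$population))
}

#' Change summary between two months
#'
#' Joins two characteristics tables and emits, per characteristic row, the
#' count difference, the percentage-point difference and the relative count
#' change as three separate named columns (a single "(%)" column would be
#' ambiguous between the last two conventions).
#'
#' @param chars_t1,chars_t2 outputs of [characteristics_table()] for the two
#'   months.
#' @return tibble with `characteristic`, `category`, counts and percentages
#'   at both months, `count_diff`, `pp_diff`, `relative_pct_change`.
#' @export
change_summary <- function(chars_t1, chars_t2) {
  j <- dplyr::inner_join(
    chars_t1[, c("characteristic", "category", "numerator", "percent")],
    chars_t2[, c("characteristic", "category", "numerator", "percent")],
    by = c("characteristic", "category"), suffix = c("_t1", "_t2")
  )
  j$count_diff <- j$numerator_t2 - j$numerator_t1
  j$pp_diff <- ifelse(is.na(j$percent_t1) | is.na(j$percent_t2), NA_real_,
                      round_half_up(j$percent_t2 - j$percent_t1, 1))
  j$relative_pct_change <- ifelse(j$numerator_t1 > 0,
                                  relative_change(pmax(j$numerator_t1, 1),
                                                  j$numerator_t2), NA_real_)
  j
}

#' Plot a measure series
#'
#' Simple line plot of the monthly percentages, one line per measure.
#'
#' @param series tibble from [measure_series()] or [prevalence_series()].
#' @return a ggplot object.
#' @export
plot_measure_series <- function(series) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  ggplot2::ggplot(series, ggplot2::aes(x = .data$month, y = .data$percent,
                                       colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = NULL, y = "% of denominator", colour = NULL) +
    ggplot2::theme_minimal()
}
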