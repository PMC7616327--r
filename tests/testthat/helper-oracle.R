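# Independent brute-force dose classifier: a literal scan over a hand-copied
# banded table, structured nothing like the package implementation. Used as
# the oracle for the exhaustive grid-equivalence checks.

oracle_table <- list(
  apixaban = list(
    std_freq = 2,
    bands = list(
      list(lo = 15, lo_in = TRUE, hi = 30, hi_in = FALSE, strengths = 2.5),
      list(lo = 30, lo_in = TRUE, hi = Inf, hi_in = FALSE, strengths = 5)
    )
  ),
  dabigatran = list(
    std_freq = 2,
    bands = list(
      list(lo = 30, lo_in = TRUE, hi = 50, hi_in = TRUE, strengths = c(110, 150)),
      list(lo = 50, lo_in = FALSE, hi = Inf, hi_in = FALSE, strengths = c(110, 150))
    )
  ),
  edoxaban = list(
    std_freq = 1,
    bands = list(
      list(lo = 15, lo_in = TRUE, hi = 50, hi_in = TRUE, strengths = 30),
      list(lo = 50, lo_in = FALSE, hi = Inf, hi_in = FALSE, strengths = 60)
    )
  ),
  rivaroxaban = list(
    std_freq = 1,
    bands = list(
      list(lo = 15, lo_in = TRUE, hi = 50, hi_in = FALSE, strengths = 15),
      list(lo = 50, lo_in = TRUE, hi = Inf, hi_in = FALSE, strengths = 20)
    )
  )
)

oracle_classify <- function(drug, strength, freq, crcl) {
  entry <- oracle_table[[drug]]
  if (crcl < 15) return("contraindicated_crcl_below_15")
  if (freq != entry$std_freq) return("non_standard_regimen")
  rec <- c()
  for (b in entry$bands) {
    above <- if (b$lo_in) crcl >= b$lo else crcl > b$lo
    below <- if (b$hi_in) crcl <= b$hi else crcl < b$hi
    if (above && below) rec <- c(rec, b$strengths)
  }
  if (length(rec) == 0) return("no_recommended_dose")
  if (strength %in% rec) return("match")
  daily <- strength * freq
  if (daily > max(rec) * entry$std_freq) return("overdose")
  if (daily < min(rec) * entry$std_freq) return("underdose")
  "unclassifiable"
}

# crcl evaluation grid: integers plus the band edges and their neighbourhoods
oracle_crcl_grid <- function() {
  sort(unique(c(1:200, 14.999, 15, 29.999, 30, 49.999, 50, 50.001)))
}

# the 8 standard catalogue regimens
oracle_regimens <- function() {
  data.frame(
    drug = rep(c("apixaban", "dabigatran", "edoxaban", "rivaroxaban"), each = 2),
    strength_mg = c(2.5, 5, 110, 150, 30, 60, 15, 20),
    frequency_per_day = c(2, 2, 2, 2, 1, 1, 1, 1)
  )
}
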