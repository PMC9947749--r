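# Independent brute-force oracles and small fixture builders.
# The oracles deliberately use explicit loops and textbook formulas,
# sharing no code path with the package implementations they check.

oracle_eta_squared <- function(values, groups) {
  groups <- as.character(groups)
  grand <- sum(values) / length(values)
  ss_total <- 0
  for (v in values) ss_total <- ss_total + (v - grand)^2
  ss_between <- 0
  for (g in unique(groups)) {
    vg <- values[groups == g]
    mg <- sum(vg) / length(vg)
    ss_between <- ss_between + length(vg) * (mg - grand)^2
  }
  ss_between / ss_total
}

oracle_cohen_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  ma <- sum(a) / na; mb <- sum(b) / nb
  ssa <- 0; for (v in a) ssa <- ssa + (v - ma)^2
  ssb <- 0; for (v in b) ssb <- ssb + (v - mb)^2
  (ma - mb) / sqrt((ssa + ssb) / (na + nb - 2))
}

# a small, well-formed in-memory puff table
toy_puffs <- function() {
  tibble::tibble(
    device_id = c("A", "A", "A", "B", "B", "C"),
    timestamp = as.POSIXct("2022-03-01 10:00:00", tz = "UTC") + (0:5) * 3600,
    duration_s = c(2, 3, 4, 3.5, 10, 1.2),
    power_setting = factor(c("low", "medium", "high", "high", "medium", "low"),
                           levels = c("low", "medium", "high")),
    nicotine_conc_mg_ml = c(0, 6, NA, 18, 3, NA),
    pg_vg_ratio = NA_character_,
    brand = NA_character_
  )
}

write_temp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
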