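# Ingestion, validation, joining, binning and filtering of puff logs.

test_that("read_puff_log accepts well-formed rows and collects violations", {
  path <- write_temp_csv(c(
    "device_id,timestamp,duration_s,power_setting,nicotine_conc_mg_ml",
    "A,2022-03-01T10:00:00,2.5,low,6",
    "A,2022-03-01T10:05:00,3.0,HIGH,",       # case-insensitive power, missing conc
    "B,2022-03-01T11:00:00,12.0,medium,3",   # beyond the firmware cutoff
    "B,2022-03-01T11:05:00,0,low,3",         # nonpositive duration
    "B,not-a-time,3.0,low,3",                # bad timestamp
    "C,2022-03-01T12:00:00,3.0,turbo,3",     # unknown power
    "C,2022-03-01T12:05:00,3.0,low,-1"       # negative concentration
  ))
  suppressMessages(puffs <- read_puff_log(path))
  expect_equal(nrow(puffs), 2)
  expect_true(is.na(puffs$nicotine_conc_mg_ml[2]))
  expect_equal(as.character(puffs$power_setting), c("low", "high"))

  rej <- attr(puffs, "rejections")
  expect_equal(nrow(rej), 5)
  expect_setequal(rej$reason, c("exceeds 10 s device cutoff",
                                "nonpositive duration",
                                "unparseable timestamp",
                                "unknown power setting",
                                "negative nicotine concentration"))
  # a 10-s puff (the shutoff itself) is legal, inclusive bound
  path2 <- write_temp_csv(c(
    "device_id,timestamp,duration_s,power_setting,nicotine_conc_mg_ml",
    "A,2022-03-01T10:00:00,10.0,low,6"
  ))
  expect_equal(nrow(read_puff_log(path2)), 1)
})

test_that("read_puff_log fails fast on a missing mandatory column", {
  path <- write_temp_csv(c(
    "device_id,timestamp,power_setting",
    "A,2022-03-01T10:00:00,low"
  ))
  expect_error(read_puff_log(path), class = "pufftopo_format_error")
})

test_that("puff log round-trips through write and read", {
  puffs <- toy_puffs()
  path <- withr::local_tempfile(fileext = ".csv")
  write_puff_log(puffs, path)
  back <- read_puff_log(path)
  expect_equal(back$device_id, puffs$device_id)
  expect_equal(back$timestamp, puffs$timestamp)
  expect_equal(back$duration_s, puffs$duration_s)
  expect_equal(back$power_setting, puffs$power_setting)
  expect_equal(back$nicotine_conc_mg_ml, puffs$nicotine_conc_mg_ml)
})

test_that("read_survey canonicalises categories and rejects duplicates", {
  path <- write_temp_csv(c(
    "device_id,sex,age_band,smoking_history,ends_years_band",
    "A,Female,36-55,,6-10y",
    "B,male,18-25,no,definitely-not-a-band",
    "C,dragon,26-35,yes,>10y"
  ))
  suppressWarnings(profiles <- read_survey(path))
  expect_equal(nrow(profiles), 3)
  expect_equal(as.character(profiles$smoking_history), c("missing", "no", "yes"))
  expect_equal(as.character(profiles$ends_years_band)[2], "missing")
  expect_equal(as.character(profiles$sex), c("female", "male", "missing"))

  dup <- write_temp_csv(c(
    "device_id,sex,age_band,smoking_history,ends_years_band",
    "A,female,36-55,yes,6-10y",
    "A,male,18-25,no,1-5y"
  ))
  expect_error(read_survey(dup), "A", class = "pufftopo_format_error")

  empty <- write_temp_csv("device_id,sex,age_band,smoking_history,ends_years_band")
  expect_warning(p0 <- read_survey(empty), "no rows")
  expect_equal(nrow(p0), 0)
})

test_that("join_cohort conserves puffs and reports mismatches both ways", {
  puffs <- toy_puffs() # devices A, B, C
  profiles <- tibble::tibble(
    device_id = c("A", "B", "D"),
    sex = factor("female", levels = c("female", "male", "prefer_not_to_say", "missing")),
    age_band = factor("36-55", levels = c("18-25", "26-35", "36-55", ">=56", "missing")),
    smoking_history = factor("yes", levels = c("yes", "no", "missing")),
    ends_years_band = factor("6-10y", levels = c("6mo-1y", "1-5y", "6-10y", ">10y", "missing"))
  )
  cohort <- join_cohort(puffs, profiles)
  expect_equal(nrow(cohort$puffs), nrow(puffs))
  expect_equal(cohort$unmatched_device_ids, "C")
  expect_equal(cohort$zero_puff_device_ids, "D")
  expect_equal(sum(cohort$puffs$matched) + sum(!cohort$puffs$matched), nrow(puffs))
  # unmatched puffs keep their fields and stay usable
  expect_equal(cohort$puffs$duration_s[!cohort$puffs$matched], 1.2)
  # empty puff set is a valid cohort
  empty <- join_cohort(puffs[0, ], profiles)
  expect_equal(nrow(empty$puffs), 0)
})

test_that("concentration bins partition [0, Inf) with the printed boundaries", {
  expect_equal(as.character(bin_concentration(c(0, 3, 6, 11, 14, 18))),
               c("zero", "low", "low", "medium", "high", "high"))
  expect_equal(as.character(bin_concentration(NA_real_)), "unknown")
  expect_error(bin_concentration(-0.1), class = "pufftopo_domain_error")
  # partition property: exactly one non-unknown label for any conc >= 0
  set.seed(42)
  conc <- c(0, 6, 14, runif(500, 0, 30))
  bins <- bin_concentration(conc)
  expect_false(anyNA(bins))
  expect_true(all(bins %in% c("zero", "low", "medium", "high")))
  expect_true(all((conc == 0) == (bins == "zero")))
  expect_true(all((conc > 0 & conc <= 6) == (bins == "low")))
  expect_true(all((conc > 6 & conc < 14) == (bins == "medium")))
  expect_true(all((conc >= 14) == (bins == "high")))
})

test_that("filter_puffs applies declarative criteria and reports removals", {
  puffs <- toy_puffs()
  # identity under an empty criteria list
  expect_equal(nrow(filter_puffs(puffs)), nrow(puffs))

  # hand-enumerated membership on the 6-record toy set:
  # conc = {0, 6, NA, 18, 3, NA}
  f1 <- filter_puffs(puffs, list(nonmissing_conc = TRUE))
  expect_equal(f1$nicotine_conc_mg_ml, c(0, 6, 18, 3))
  expect_equal(attr(f1, "removed"), c(nonmissing_conc = 2L))

  # nonzero_conc alone removes the 0 mg/mL puff but keeps missing ones
  f2 <- filter_puffs(puffs, list(nonzero_conc = TRUE))
  expect_equal(nrow(f2), 5)
  expect_equal(attr(f2, "removed"), c(nonzero_conc = 1L))

  f3 <- filter_puffs(puffs, list(nonmissing_conc = TRUE, nonzero_conc = TRUE))
  expect_equal(f3$nicotine_conc_mg_ml, c(6, 18, 3))

  f4 <- filter_puffs(puffs, list(power = "high", users = c("A", "B")))
  expect_equal(nrow(f4), 2)

  # conservation: filtering never alters surviving records
  expect_equal(f4, puffs[puffs$power_setting == "high", ],
               ignore_attr = TRUE)

  expect_error(filter_puffs(puffs, list(nope = 1)),
               class = "pufftopo_config_error")
  expect_error(filter_puffs(puffs, list(date_range = c("2022-03-05", "2022-03-01"))),
               class = "pufftopo_config_error")
  expect_error(filter_puffs(puffs, list(power = "turbo")),
               class = "pufftopo_config_error")
})
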