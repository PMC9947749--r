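# Seeded synthetic cohort generator: determinism, truncation, marginal
# fidelity, and the stated adaptation structure.

test_that("identical config and seed regenerate identical cohorts", {
  cfg <- synthetic_cohort_config(n_users = 6, n_days = 14, seed = 31)
  s1 <- generate_cohort(cfg)
  s2 <- generate_cohort(cfg)
  expect_identical(s1$puffs, s2$puffs)
  expect_identical(s1$survey, s2$survey)
  expect_identical(s1$truth$users, s2$truth$users)
  # and byte-identical on disk
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(s1, d1); write_cohort(s2, d2)
  for (f in c("puffs.csv", "survey.csv", "truth.json")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
  }
})

test_that("adding users never perturbs existing users' data", {
  small <- generate_cohort(synthetic_cohort_config(n_users = 4, n_days = 14, seed = 9))
  big <- generate_cohort(synthetic_cohort_config(n_users = 9, n_days = 14, seed = 9))
  ids <- unique(small$puffs$device_id)
  expect_identical(small$puffs, big$puffs[big$puffs$device_id %in% ids, ])
  expect_identical(small$truth$users, big$truth$users[1:4, ])
})

test_that("durations respect the 10-s cutoff and the censored-moment targets", {
  cfg <- synthetic_cohort_config(n_users = 2, seed = 12)
  dm <- cfg$duration_model
  # the solver reproduces the configured censored moments
  mom <- censored_lnorm_moments(dm$meanlog, dm$sdlog, dm$cap)
  expect_equal(mom$mean, 3.44, tolerance = 1e-9)
  expect_equal(mom$sd, 1.65, tolerance = 1e-9)
  # Monte-Carlo convergence of the sampled law to the configured target
  set.seed(55)
  n <- 1e5
  x <- pmin(rlnorm(n, dm$meanlog, dm$sdlog), dm$cap)
  se <- dm$target_sd / sqrt(n)
  expect_lt(abs(mean(x) - dm$target_mean), 3 * se)
  expect_true(all(x <= dm$cap))
  # generated cohorts never exceed the cutoff and show the censored spike
  sim <- generate_cohort(synthetic_cohort_config(n_users = 20, n_days = 21,
                                                 seed = 77))
  expect_true(all(sim$puffs$duration_s > 0 & sim$puffs$duration_s <= 10))
  expect_gt(sum(sim$puffs$duration_s == 10), 0)
})

test_that("power and concentration-bin shares match the mixture (iid mode)", {
  cfg <- synthetic_cohort_config(n_users = 40, n_days = 21, seed = 101,
                                 per_user_preference = FALSE,
                                 conc_missing_prob = 0)
  sim <- generate_cohort(cfg)
  n <- nrow(sim$puffs)
  mix <- cfg$usage_mixture
  # power marginal, 3 multinomial SEs
  pow_target <- tapply(mix$prob, mix$power, sum)
  pow_obs <- table(sim$puffs$power_setting)[names(pow_target)] / n
  for (p in names(pow_target)) {
    se <- sqrt(pow_target[[p]] * (1 - pow_target[[p]]) / n)
    expect_lt(abs(pow_obs[[p]] - pow_target[[p]]), 3 * se)
  }
  # concentration-bin marginal
  bin_target <- tapply(mix$prob, as.character(bin_concentration(mix$conc)), sum)
  bin_obs <- table(as.character(bin_concentration(sim$puffs$nicotine_conc_mg_ml)))
  for (b in names(bin_target)) {
    se <- sqrt(bin_target[[b]] * (1 - bin_target[[b]]) / n)
    expect_lt(abs(bin_obs[[b]] / n - bin_target[[b]]), 3 * se)
  }
})

test_that("per-user preferences keep population shares near the mixture", {
  # with personal (power, conc) subsets the effective sample size is the
  # number of users, not puffs: compare at 3 SEs of the across-user share
  cfg <- synthetic_cohort_config(n_users = 150, n_days = 14, seed = 88)
  sim <- generate_cohort(cfg)
  mix <- cfg$usage_mixture
  pow_target <- tapply(mix$prob, mix$power, sum)
  per_user <- sim$puffs |>
    dplyr::group_by(device_id) |>
    dplyr::summarise(high = mean(power_setting == "high"), .groups = "drop")
  se <- sd(per_user$high) / sqrt(nrow(per_user))
  expect_lt(abs(mean(per_user$high) - pow_target[["high"]]), 3 * se)
})

test_that("a no-skip user is active every day and day 1 is deflated", {
  cfg <- synthetic_cohort_config(
    n_users = 1, n_days = 3, seed = 3,
    intensity_model = list(p_skip = 0, span_weeks_probs = c(`1` = 1))
  )
  sim <- generate_cohort(cfg)
  days <- summarize_user_days(sim$puffs)
  expect_equal(nrow(days), 3)
  expect_equal(days$relative_day, 1:3)

  # expected count on the first active day is delta * lambda: average the
  # generated day-1 counts over many users against the truth expectation
  cfg2 <- synthetic_cohort_config(n_users = 120, n_days = 10, seed = 21,
                                  intensity_model = list(span_weeks_probs = c(`2` = 1)))
  sim2 <- generate_cohort(cfg2)
  day1 <- summarize_user_days(sim2$puffs) |> dplyr::filter(relative_day == 1)
  diff <- day1$puff_count - sim2$truth$users$expected_day1_count
  expect_lt(abs(mean(diff)), 3 * sd(diff) / sqrt(length(diff)))
})

test_that("cohort mean is low on day 1 and trendless on the plateau", {
  sim <- generate_cohort(synthetic_cohort_config(n_users = 58, n_days = 21,
                                                 seed = 14))
  series <- cohort_series(summarize_user_days(sim$puffs))
  am <- adaptation_metrics(series, "puffs", plateau_window = c(8, 21))
  expect_lt(am$day1_mean, am$plateau_mean)
  # slope consistent with zero within ~3 of its standard error
  expect_lt(abs(am$plateau_slope), 3 * am$plateau_slope_se)
})

test_that("invalid configurations fail before any sampling", {
  expect_error(synthetic_cohort_config(conc_missing_prob = 1.2),
               class = "pufftopo_config_error")
  expect_error(
    synthetic_cohort_config(intensity_model = list(day1_deflation = 1.5)),
    class = "pufftopo_config_error"
  )
  bad_mix <- default_usage_mixture()
  bad_mix$prob <- bad_mix$prob * 2
  expect_error(synthetic_cohort_config(usage_mixture = bad_mix),
               class = "pufftopo_config_error")
  expect_error(
    synthetic_cohort_config(intensity_model = list(family = "gaussian")),
    class = "pufftopo_config_error"
  )
})

test_that("YAML config round-trips through read_cohort_config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_users: 4",
    "seed: 17",
    "n_days: 10",
    "start_date: 2022-02-22",
    "conc_missing_prob: 0.2",
    "intensity_model:",
    "  p_skip: 0.1"
  ), path)
  cfg <- read_cohort_config(path)
  expect_equal(cfg$n_users, 4L)
  expect_equal(cfg$intensity_model$p_skip, 0.1)
  expect_equal(cfg$intensity_model$family, "nbinom") # defaults preserved
  expect_identical(generate_cohort(cfg)$puffs,
                   generate_cohort(cfg)$puffs)
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("n_puffs_wanted: 10", bad)
  expect_error(read_cohort_config(bad), class = "pufftopo_config_error")
})

test_that("default cohort lands at the emulated study's scale", {
  sim <- generate_cohort(synthetic_cohort_config(seed = 1))
  expect_gt(nrow(sim$puffs), 1e5)
  expect_lt(nrow(sim$puffs), 3e5)
  expect_equal(nrow(sim$survey), 58)
  # about 41% of puffs lack a concentration record
  p_miss <- mean(is.na(sim$puffs$nicotine_conc_mg_ml))
  expect_lt(abs(p_miss - 0.41), 3 * sqrt(0.41 * 0.59 / nrow(sim$puffs)))
})
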