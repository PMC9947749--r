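# Seeded synthetic cohort generator.
#
# Emulates the statistical structure of the observed study so every
# downstream stage is testable without the raw device data: ~58 users
# over ~2 months, demographic marginals matching the published
# participant table, a (power x concentration) usage mixture proportional
# to the published cross-tabulation, right-skewed puff durations censored
# at the 10-s firmware cutoff (lognormal; the censored mass reproduces the
# spike at exactly 10 s), and a day-1-low -> short-ramp -> stable-plateau
# daily-use time course. Every latent parameter is emitted as ground
# truth, because parameter recovery is the acceptance surface for the
# analysis pipeline.

#' Moments of a lognormal censored from above
#'
#' Mean and SD of min(X, cap) with X ~ Lognormal(meanlog, sdlog): the
#' duration law, where the firmware cutoff piles the upper tail exactly at
#' `cap`. Closed form via the lognormal partial expectation.
#'
#' @param meanlog,sdlog lognormal parameters.
#' @param cap censoring point (s).
#' @return list with `mean` and `sd`.
#' @export
censored_lnorm_moments <- function(meanlog, sdlog, cap = DURATION_CAP_S) {
  lc <- log(cap)
  p_over <- stats::pnorm((lc - meanlog) / sdlog, lower.tail = FALSE)
  m1 <- exp(meanlog + sdlog^2 / 2) *
    stats::pnorm((lc - meanlog - sdlog^2) / sdlog) + cap * p_over
  m2 <- exp(2 * meanlog + 2 * sdlog^2) *
    stats::pnorm((lc - meanlog - 2 * sdlog^2) / sdlog) + cap^2 * p_over
  list(mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
}

#' Solve lognormal parameters for target censored moments
#'
#' Finds (meanlog, sdlog) such that the censored law has the requested
#' mean and SD, by nested root finding: for each candidate sdlog the
#' censored mean is monotone in meanlog (inner root), and the resulting
#' censored SD is monotone in sdlog (outer root).
#'
#' @param target_mean,target_sd target censored moments (s).
#' @param cap censoring point (s).
#' @return list with `meanlog`, `sdlog`.
#' @export
#' @examples
#' p <- solve_duration_params(3.44, 1.65)
#' censored_lnorm_moments(p$meanlog, p$sdlog)
solve_duration_params <- function(target_mean = 3.44, target_sd = 1.65,
                                  cap = DURATION_CAP_S) {
  if (!(target_mean > 0 && target_sd > 0 && target_mean < cap)) {
    abort_pufftopo("need 0 < target_mean < cap and target_sd > 0",
                   "pufftopo_config_error")
  }
  meanlog_for <- function(sdlog) {
    stats::uniroot(
      function(ml) censored_lnorm_moments(ml, sdlog, cap)$mean - target_mean,
      lower = log(target_mean) - 5, upper = log(cap) + 5, tol = 1e-12
    )$root
  }
  sd_gap <- function(sdlog) {
    censored_lnorm_moments(meanlog_for(sdlog), sdlog, cap)$sd - target_sd
  }
  sdlog <- stats::uniroot(sd_gap, lower = 1e-3, upper = 3, tol = 1e-12)$root
  list(meanlog = meanlog_for(sdlog), sdlog = sdlog)
}

#' Default demographic marginals
#'
#' Participant proportions of the published demographic table (61
#' enrolled users), one probability vector per survey factor.
#'
#' @return named list of named probability vectors.
#' @export
default_demographics <- function() {
  t1 <- fixture_table1()
  split(t1, t1$factor)[c("sex", "age_band", "smoking_history", "ends_years_band")] |>
    lapply(function(df) stats::setNames(df$participants / sum(df$participants),
                                        df$level))
}

#' Default (power, concentration) usage mixture
#'
#' Joint probability over power setting and e-liquid concentration value,
#' built from the published 12-cell power-by-bin cross-tabulation with each
#' bin's mass split over its observed concentration values (mg/mL):
#' zero = \{0\}, low = \{1, 3, 6\}, medium = \{10, 11\}, high = \{14, 18\}.
#' Within-bin weights follow the published whole-cohort prevalences of
#' 3, 6, 11, 14 and 18 mg/mL; 1 and 10 mg/mL (reported only as "less used"
#' than their neighbours) are fixed at 2.5% and 2.0% of total puffs.
#'
#' @return tibble with columns `power`, `conc`, `prob` (sums to 1).
#' @export
default_usage_mixture <- function() {
  t2 <- fixture_table2()
  cell <- t2$count / sum(t2$count)
  # within-bin concentration weights, proportional to whole-cohort shares
  bin_values <- list(
    zero = c(`0` = 1),
    low = c(`1` = 2.5, `3` = 16.26, `6` = 16.13),
    medium = c(`10` = 2.0, `11` = 7.22),
    high = c(`14` = 4.32, `18` = 6.75)
  )
  out <- purrr::map_dfr(seq_len(nrow(t2)), function(i) {
    w <- bin_values[[t2$conc_bin[i]]]
    tibble::tibble(
      power = t2$power[i],
      conc = as.numeric(names(w)),
      prob = cell[i] * w / sum(w)
    )
  })
  out <- out[out$prob > 0, ]
  out$prob <- out$prob / sum(out$prob)
  dplyr::arrange(out, .data$power, .data$conc)
}

# internal: adaptation multiplier, = day1_factor on relative day 1 and 1
# from relative day (ramp_days + 1) onward
ramp_multiplier <- function(day, day1_factor, ramp_days) {
  day1_factor + (1 - day1_factor) * pmin(1, (day - 1) / ramp_days)
}

check_prob_table <- function(p, what) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    abort_pufftopo(paste0(what, " must be a probability table summing to 1"),
                   "pufftopo_config_error")
  }
  invisible(p)
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults state the emulated study: 58 users observed over a 60-day
#' window starting 2022-02-22; durations lognormal censored at the 10-s
#' cutoff with stabilized (post-ramp) mean 3.44 s and SD 1.65 s; per-user
#' baseline intensity lambda_u lognormal with mean 250 puffs/day (clamped
#' to [5, 600], matching the reported 5 to >400 puffs/day range), a day-1
#' deflation of 120/250 and a 2-day ramp for counts, and a 0.8 deflation
#' with a 6-day ramp for durations (2.8 s -> ~3.5 s over ~1 week); daily
#' counts zero-truncated negative binomial around the ramped mean with a
#' per-user dispersion; sporadic non-use days with probability `p_skip`;
#' usage spans mostly 3 weeks (the trial length) with a tail of shorter
#' and extended spans; 41% of puffs lack a concentration record.
#'
#' @param n_users number of users.
#' @param seed integer seed; each user gets an RNG stream derived from
#'   (seed, user index), so adding users never perturbs existing users.
#' @param start_date first calendar date of the observation window.
#' @param n_days length of the observation window, days.
#' @param demographic_marginals named list of probability vectors, see
#'   [default_demographics()].
#' @param usage_mixture tibble (`power`, `conc`, `prob`), see
#'   [default_usage_mixture()].
#' @param duration_model list: `target_mean`, `target_sd`, `cap`,
#'   `day1_factor`, `ramp_days`.
#' @param intensity_model list: `lambda_meanlog`, `lambda_sdlog`,
#'   `lambda_range`, `day1_deflation`, `ramp_days`, `dispersion_range`
#'   (per-user NB size, log-uniform), `family` ("nbinom" or "poisson"),
#'   `p_skip`, `span_weeks_probs` (named probability vector over use-span
#'   weeks).
#' @param conc_missing_prob probability a puff's concentration is
#'   unrecorded.
#' @param per_user_preference if TRUE (default) each user mixes among a
#'   small personal subset of (power, concentration) pairs, one pair per
#'   day; if FALSE every puff draws i.i.d. from the population mixture
#'   (used by oracle tests, where multinomial standard errors are exact).
#' @return a `synthetic_cohort_config` (validated list).
#' @export
synthetic_cohort_config <- function(
    n_users = 58,
    seed = 1L,
    start_date = as.Date("2022-02-22"),
    n_days = 60,
    demographic_marginals = default_demographics(),
    usage_mixture = default_usage_mixture(),
    duration_model = list(),
    intensity_model = list(),
    conc_missing_prob = 0.41,
    per_user_preference = TRUE) {
  dm_default <- list(target_mean = 3.44, target_sd = 1.65,
                     cap = DURATION_CAP_S, day1_factor = 2.8 / 3.5,
                     ramp_days = 6)
  im_default <- list(
    lambda_meanlog = log(250) - 0.9^2 / 2, lambda_sdlog = 0.9,
    lambda_range = c(5, 600),
    day1_deflation = 120 / 250, ramp_days = 2,
    dispersion_range = c(0.5, 10), family = "nbinom",
    p_skip = 0.33,
    span_weeks_probs = c(`1` = 0.12, `2` = 0.22, `3` = 0.38, `4` = 0.08,
                         `5` = 0.06, `6` = 0.05, `7` = 0.05, `8` = 0.04)
  )
  dm <- utils::modifyList(dm_default, duration_model)
  im <- utils::modifyList(im_default, intensity_model)

  for (f in names(demographic_marginals)) {
    check_prob_table(demographic_marginals[[f]],
                     paste0("demographic_marginals$", f))
  }
  check_prob_table(usage_mixture$prob, "usage_mixture$prob")
  check_prob_table(im$span_weeks_probs, "span_weeks_probs")
  if (!(conc_missing_prob >= 0 && conc_missing_prob <= 1)) {
    abort_pufftopo("conc_missing_prob must be in [0, 1]",
                   "pufftopo_config_error")
  }
  if (!(im$day1_deflation > 0 && im$day1_deflation < 1)) {
    abort_pufftopo("day1_deflation must be in (0, 1)", "pufftopo_config_error")
  }
  if (!im$family %in% c("nbinom", "poisson")) {
    abort_pufftopo("intensity family must be 'nbinom' or 'poisson'",
                   "pufftopo_config_error")
  }
  sol <- solve_duration_params(dm$target_mean, dm$target_sd, dm$cap)
  dm$meanlog <- sol$meanlog
  dm$sdlog <- sol$sdlog

  structure(
    list(n_users = as.integer(n_users), seed = as.integer(seed),
         start_date = as.Date(start_date), n_days = as.integer(n_days),
         demographic_marginals = demographic_marginals,
         usage_mixture = usage_mixture,
         duration_model = dm, intensity_model = im,
         conc_missing_prob = conc_missing_prob,
         per_user_preference = isTRUE(per_user_preference)),
    class = "synthetic_cohort_config"
  )
}

# internal: stream seed for user i, kept below 2^31
user_stream_seed <- function(seed, i) {
  (as.numeric(seed) * 48271 + i * 10007) %% 2147483647
}

# internal: zero-truncated count draw via inverse CDF, mean mu, NB size
draw_positive_counts <- function(n, mu, size, family) {
  if (n == 0) return(integer(0))
  if (family == "poisson") {
    p0 <- stats::dpois(0, mu)
    stats::qpois(stats::runif(n, p0, 1), mu)
  } else {
    p0 <- stats::dnbinom(0, mu = mu, size = size)
    stats::qnbinom(stats::runif(n, p0, 1), mu = mu, size = size)
  }
}

# internal: expected value of the zero-truncated count law
expected_positive_count <- function(mu, size, family) {
  p0 <- if (family == "poisson") stats::dpois(0, mu) else
    stats::dnbinom(0, mu = mu, size = size)
  mu / (1 - p0)
}

#' Generate a synthetic puff log, survey table and ground truth
#'
#' Per-user generation from an RNG stream derived from (seed, user index):
#' demographics, baseline intensity lambda_u, dispersion, use span and
#' start offset, a personal (power, concentration) preference subset, then
#' day-by-day counts, durations, timestamps and concentration missingness.
#' The first active day is forced (it defines relative day 1) and its
#' count is drawn as 1 + NB(mean = delta * lambda_u - 1), so its
#' expectation is exactly delta * lambda_u; later non-skipped days draw a
#' zero-truncated count around the ramped mean, whose expectation per user
#' is recorded in the ground truth.
#'
#' @param config a [synthetic_cohort_config()].
#' @return a `synthetic_cohort`: list with `puffs` (tibble of puff
#'   records), `survey` (tibble of profiles), `truth` (list: `users`
#'   tibble of latent parameters, `duration_model`, `intensity_model`,
#'   `config` echo).
#' @export
#' @examples
#' sim <- generate_cohort(synthetic_cohort_config(n_users = 3, n_days = 7))
#' nrow(sim$puffs)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  dm <- config$duration_model
  im <- config$intensity_model
  mix <- config$usage_mixture
  max_offset <- max(0L, config$n_days - 21L)
  id_fmt <- "U%04d"

  users <- vector("list", config$n_users)
  puffs <- vector("list", config$n_users)
  for (i in seq_len(config$n_users)) {
    set.seed(user_stream_seed(config$seed, i))
    device_id <- sprintf(id_fmt, i)

    demo <- lapply(config$demographic_marginals, function(p) {
      sample(names(p), 1, prob = p)
    })
    lambda <- min(max(stats::rlnorm(1, im$lambda_meanlog, im$lambda_sdlog),
                      im$lambda_range[1]), im$lambda_range[2])
    size <- exp(stats::runif(1, log(im$dispersion_range[1]),
                             log(im$dispersion_range[2])))
    offset <- if (max_offset > 0) sample.int(max_offset + 1L, 1) - 1L else 0L
    weeks <- as.integer(sample(names(im$span_weeks_probs), 1,
                               prob = im$span_weeks_probs))
    span <- min(7L * weeks, config$n_days - offset)
    first_date <- config$start_date + offset

    n_pairs <- sample.int(3L, 1)
    pair_idx <- sample.int(nrow(mix), n_pairs, replace = TRUE, prob = mix$prob)
    pair_w <- stats::rgamma(n_pairs, 1)
    pair_w <- pair_w / sum(pair_w)

    rel_day <- seq_len(span)
    active <- c(TRUE, stats::runif(span - 1) > im$p_skip)
    rel_active <- rel_day[active]
    n_active <- length(rel_active)

    count_mult <- ramp_multiplier(rel_active, 1, im$ramp_days)
    mu <- lambda * count_mult
    counts <- integer(n_active)
    mu1 <- im$day1_deflation * lambda
    counts[1] <- 1L + (if (im$family == "poisson") {
      stats::rpois(1, mu1 - 1)
    } else {
      stats::rnbinom(1, mu = mu1 - 1, size = size)
    })
    if (n_active > 1) {
      counts[-1] <- draw_positive_counts(n_active - 1, mu[-1], size, im$family)
    }
    n_puffs <- sum(counts)

    day_of_puff <- rep(rel_active, counts)
    if (config$per_user_preference) {
      day_pair <- pair_idx[sample.int(n_pairs, n_active, replace = TRUE,
                                      prob = pair_w)]
      puff_pair <- rep(day_pair, counts)
    } else {
      puff_pair <- sample.int(nrow(mix), n_puffs, replace = TRUE,
                              prob = mix$prob)
    }
    dur_mult <- ramp_multiplier(day_of_puff, dm$day1_factor, dm$ramp_days)
    duration <- pmin(stats::rlnorm(n_puffs, dm$meanlog + log(dur_mult),
                                   dm$sdlog), dm$cap)
    conc <- mix$conc[puff_pair]
    conc[stats::runif(n_puffs) < config$conc_missing_prob] <- NA_real_
    secs <- unlist(lapply(split(
      round(stats::runif(n_puffs, 0, 86399)), day_of_puff
    ), sort), use.names = FALSE)
    ts <- as.POSIXct(first_date, tz = "UTC") +
      (day_of_puff - 1) * 86400 + secs

    puffs[[i]] <- tibble::tibble(
      device_id = device_id,
      timestamp = ts,
      duration_s = duration,
      power_setting = factor(mix$power[puff_pair], levels = POWER_LEVELS),
      nicotine_conc_mg_ml = conc,
      pg_vg_ratio = NA_character_,
      brand = NA_character_
    )
    users[[i]] <- tibble::tibble(
      device_id = device_id,
      sex = demo$sex, age_band = demo$age_band,
      smoking_history = demo$smoking_history,
      ends_years_band = demo$ends_years_band,
      lambda = lambda, dispersion = size,
      day1_deflation = im$day1_deflation,
      expected_day1_count = mu1,
      expected_plateau_count = expected_positive_count(lambda, size, im$family),
      first_date = first_date, span_days = span,
      n_active_days = n_active, n_puffs = n_puffs,
      pref_pairs = paste(
        sprintf("%s:%g:%.4f", mix$power[pair_idx], mix$conc[pair_idx], pair_w),
        collapse = ";"
      )
    )
  }

  puffs <- dplyr::bind_rows(puffs)
  users <- dplyr::bind_rows(users)
  survey <- tibble::tibble(
    device_id = users$device_id,
    sex = factor(users$sex, levels = SEX_LEVELS),
    age_band = factor(users$age_band, levels = AGE_LEVELS),
    smoking_history = factor(users$smoking_history, levels = SMOKING_LEVELS),
    ends_years_band = factor(users$ends_years_band, levels = ENDS_LEVELS)
  )
  structure(
    list(
      puffs = puffs,
      survey = survey,
      truth = list(
        users = users,
        duration_model = dm,
        intensity_model = im,
        config = config
      )
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$truth$users), " users, ",
      nrow(x$puffs), " puffs, seed ", x$truth$config$seed, "\n", sep = "")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes `puffs.csv`, `survey.csv` and `truth.json` (latent parameters)
#' to a directory. Output is byte-identical for identical (config, seed).
#'
#' @param sim a `synthetic_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_puff_log(sim$puffs, file.path(dir, "puffs.csv"))
  readr::write_csv(sim$survey, file.path(dir, "survey.csv"), na = "",
                   progress = FALSE)
  truth <- sim$truth
  truth$users$first_date <- as.character(truth$users$first_date)
  cfg <- truth$config
  truth$config <- list(
    n_users = cfg$n_users, seed = cfg$seed,
    start_date = as.character(cfg$start_date), n_days = cfg$n_days,
    conc_missing_prob = cfg$conc_missing_prob,
    per_user_preference = cfg$per_user_preference
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' Read a generator configuration from YAML
#'
#' The YAML keys mirror [synthetic_cohort_config()] argument names; absent
#' keys take the defaults. `usage_mixture` may be given as a list of
#' \{power, conc, prob\} records.
#'
#' @param path YAML file.
#' @return a `synthetic_cohort_config`.
#' @export
read_cohort_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("n_users", "seed", "start_date", "n_days",
             "demographic_marginals", "usage_mixture", "duration_model",
             "intensity_model", "conc_missing_prob", "per_user_preference")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    abort_pufftopo(paste0("unknown config key(s): ",
                          paste(unknown, collapse = ", ")),
                   "pufftopo_config_error")
  }
  if (!is.null(cfg$usage_mixture)) {
    cfg$usage_mixture <- dplyr::bind_rows(lapply(cfg$usage_mixture, tibble::as_tibble))
  }
  if (!is.null(cfg$demographic_marginals)) {
    cfg$demographic_marginals <- lapply(cfg$demographic_marginals, unlist)
  }
  if (!is.null(cfg$intensity_model$span_weeks_probs)) {
    cfg$intensity_model$span_weeks_probs <- unlist(cfg$intensity_model$span_weeks_probs)
  }
  do.call(synthetic_cohort_config, cfg)
}
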