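# Domain types and I/O for per-puff device logs and baseline surveys.
#
# A puff record is one timed activation of the device: device_id, ISO 8601
# timestamp, duration in seconds (the firmware cuts power at 10 s, so
# durations are in (0, 10]), one of three discrete power settings, and the
# self-reported e-liquid nicotine concentration (mg/mL), which may be
# missing. Surveys are keyed by device ID and carry demographic covariates.

PUFF_REQUIRED_COLS <- c("device_id", "timestamp", "duration_s", "power_setting")
PUFF_OPTIONAL_COLS <- c("nicotine_conc_mg_ml", "pg_vg_ratio", "brand")
POWER_LEVELS <- c("low", "medium", "high")
CONC_BIN_LEVELS <- c("zero", "low", "medium", "high", "unknown")
DURATION_CAP_S <- 10

SURVEY_COLS <- c("device_id", "sex", "age_band", "smoking_history", "ends_years_band")
SEX_LEVELS <- c("female", "male", "prefer_not_to_say", "missing")
AGE_LEVELS <- c("18-25", "26-35", "36-55", ">=56", "missing")
SMOKING_LEVELS <- c("yes", "no", "missing")
ENDS_LEVELS <- c("6mo-1y", "1-5y", "6-10y", ">10y", "missing")

#' Canonical device power bands
#'
#' The device offers three discrete power settings; each supplies a wattage
#' range. The representative wattage (`watt_rep`, the band midpoint) is the
#' scalar the emission model uses for a band.
#'
#' @return tibble with columns `setting`, `watt_lo`, `watt_hi`, `watt_rep`.
#' @export
#' @examples
#' power_bands()
power_bands <- function() {
  tibble::tibble(
    setting  = POWER_LEVELS,
    watt_lo  = c(7, 9, 11),
    watt_hi  = c(9, 11, 13),
    watt_rep = c(8, 10, 12)
  )
}

#' Bin an e-liquid nicotine concentration
#'
#' Concentrations partition into `zero` = {0}, `low` = (0, 6],
#' `medium` = (6, 14), `high` = [14, Inf) mg/mL — disjoint and exhaustive,
#' honouring the printed bin labels "<=6" and ">=14". A missing
#' concentration maps to the explicit `unknown` level, never to zero.
#'
#' @param conc numeric vector of concentrations in mg/mL (NA allowed).
#' @return factor with levels zero, low, medium, high, unknown.
#' @export
#' @examples
#' bin_concentration(c(0, 3, 6, 11, 14, NA))
bin_concentration <- function(conc) {
  if (any(conc < 0, na.rm = TRUE)) {
    abort_pufftopo("nicotine concentration must be >= 0 mg/mL",
                   "pufftopo_domain_error")
  }
  lab <- dplyr::case_when(
    is.na(conc) ~ "unknown",
    conc == 0   ~ "zero",
    conc <= 6   ~ "low",
    conc < 14   ~ "medium",
    TRUE        ~ "high"
  )
  factor(lab, levels = CONC_BIN_LEVELS)
}

# internal: validate a parsed puff tibble, returning list(records, rejections)
validate_puff_rows <- function(raw) {
  n <- nrow(raw)
  duration <- suppressWarnings(as.numeric(raw$duration_s))
  ts <- suppressWarnings(readr::parse_datetime(as.character(raw$timestamp)))
  power <- tolower(trimws(as.character(raw$power_setting)))
  conc_chr <- if ("nicotine_conc_mg_ml" %in% names(raw)) {
    as.character(raw$nicotine_conc_mg_ml)
  } else {
    rep(NA_character_, n)
  }
  conc_chr[!is.na(conc_chr) & trimws(conc_chr) == ""] <- NA_character_
  conc <- suppressWarnings(as.numeric(conc_chr))

  reason <- rep(NA_character_, n)
  flag <- function(bad, why) {
    bad <- bad & is.na(reason)
    reason[bad] <<- why
  }
  flag(is.na(ts), "unparseable timestamp")
  flag(is.na(duration), "unparseable duration")
  flag(!is.na(duration) & duration > DURATION_CAP_S, "exceeds 10 s device cutoff")
  flag(!is.na(duration) & duration <= 0, "nonpositive duration")
  flag(!power %in% POWER_LEVELS, "unknown power setting")
  flag(!is.na(conc_chr) & is.na(conc), "unparseable nicotine concentration")
  flag(!is.na(conc) & conc < 0, "negative nicotine concentration")

  keep <- is.na(reason)
  records <- tibble::tibble(
    device_id = as.character(raw$device_id)[keep],
    timestamp = ts[keep],
    duration_s = duration[keep],
    power_setting = factor(power[keep], levels = POWER_LEVELS),
    nicotine_conc_mg_ml = conc[keep],
    pg_vg_ratio = if ("pg_vg_ratio" %in% names(raw)) {
      as.character(raw$pg_vg_ratio)[keep]
    } else {
      NA_character_
    },
    brand = if ("brand" %in% names(raw)) {
      as.character(raw$brand)[keep]
    } else {
      NA_character_
    }
  )
  rejections <- tibble::tibble(
    row = which(!keep),
    device_id = as.character(raw$device_id)[!keep],
    reason = reason[!keep]
  )
  list(records = records, rejections = rejections)
}

#' Read a per-puff device log
#'
#' Expects delimited text with a header and at least the columns
#' `device_id,timestamp,duration_s,power_setting`; optional columns
#' `nicotine_conc_mg_ml,pg_vg_ratio,brand`. Rows violating the puff-record
#' invariants (duration outside (0, 10] s, unknown power setting,
#' unparseable fields, negative concentration) are rejected with a per-row
#' reason, collected in `attr(., "rejections")` — not silently dropped and
#' not fatal. An empty concentration field is legal and becomes NA.
#'
#' @param path path to the log file.
#' @param delim field delimiter (default comma).
#' @return tibble of valid puff records with a `rejections` attribute
#'   (tibble of `row`, `device_id`, `reason`).
#' @export
read_puff_log <- function(path, delim = ",") {
  if (!file.exists(path)) {
    abort_pufftopo(paste0("puff log not found: ", path), "pufftopo_io_error")
  }
  raw <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  missing_cols <- setdiff(PUFF_REQUIRED_COLS, names(raw))
  if (length(missing_cols) > 0) {
    abort_pufftopo(
      paste0("puff log is missing mandatory column(s): ",
             paste(missing_cols, collapse = ", ")),
      "pufftopo_format_error"
    )
  }
  out <- validate_puff_rows(raw)
  if (nrow(out$rejections) > 0) {
    message(nrow(out$rejections), " of ", nrow(raw),
            " rows rejected during validation; see attr(x, \"rejections\")")
  }
  structure(out$records, rejections = out$rejections)
}

#' Write a puff log
#'
#' Inverse of [read_puff_log()]: timestamps are serialised as ISO 8601 to
#' whole seconds; numeric fields round-trip at full double precision.
#'
#' @param puffs tibble of puff records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_puff_log <- function(puffs, path) {
  out <- dplyr::mutate(
    puffs,
    timestamp = format(.data$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    power_setting = as.character(.data$power_setting)
  )
  readr::write_csv(out[, c(PUFF_REQUIRED_COLS, PUFF_OPTIONAL_COLS)], path,
                   na = "", progress = FALSE)
  invisible(path)
}

# internal: canonicalise one survey column against a level set
canon_level <- function(x, levels, synonyms = character()) {
  x <- trimws(as.character(x))
  x[is.na(x) | x == ""] <- "missing"
  x <- tolower(x)
  x[x %in% names(synonyms)] <- synonyms[x[x %in% names(synonyms)]]
  x[!x %in% levels] <- "missing"
  factor(x, levels = levels)
}

#' Read a baseline survey table
#'
#' CSV with columns `device_id,sex,age_band,smoking_history,ends_years_band`.
#' Blank or unrecognised category strings map to the explicit `missing`
#' level (mirroring "did not respond" rows in published demographic
#' summaries). Duplicate device IDs are an error.
#'
#' @param path path to the survey CSV.
#' @return tibble of user profiles, one row per device ID.
#' @export
read_survey <- function(path) {
  if (!file.exists(path)) {
    abort_pufftopo(paste0("survey not found: ", path), "pufftopo_io_error")
  }
  raw <- readr::read_csv(path,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing_cols <- setdiff(SURVEY_COLS, names(raw))
  if (length(missing_cols) > 0) {
    abort_pufftopo(
      paste0("survey is missing column(s): ", paste(missing_cols, collapse = ", ")),
      "pufftopo_format_error"
    )
  }
  if (nrow(raw) == 0) {
    warning("survey file ", path, " contains no rows")
  }
  dup <- unique(raw$device_id[duplicated(raw$device_id)])
  if (length(dup) > 0) {
    abort_pufftopo(
      paste0("duplicate device_id in survey: ", paste(dup, collapse = ", ")),
      "pufftopo_format_error"
    )
  }
  tibble::tibble(
    device_id = as.character(raw$device_id),
    sex = canon_level(raw$sex, SEX_LEVELS),
    age_band = canon_level(raw$age_band, AGE_LEVELS,
                           c("≥56" = ">=56", "56+" = ">=56")),
    smoking_history = canon_level(raw$smoking_history, SMOKING_LEVELS),
    ends_years_band = canon_level(
      raw$ends_years_band, ENDS_LEVELS,
      c("6 months to 1 year" = "6mo-1y", "1-5 years" = "1-5y",
        "6-10 years" = "6-10y", ">10 years" = ">10y")
    )
  )
}

#' Join puff records to survey profiles
#'
#' Left-joins profile covariates onto puffs by device ID. Device IDs seen
#' in only one of the two tables are reported, not treated as failure:
#' unmatched puffs remain usable for profile-free analyses (participants
#' who never supplied their device ID are data, not errors). Total puff
#' count is conserved.
#'
#' @param puffs tibble of puff records.
#' @param profiles tibble of user profiles.
#' @return a `cohort_dataset`: list with `puffs` (joined tibble, logical
#'   `matched` column), `profiles`, `unmatched_device_ids` (in puffs but
#'   not survey) and `zero_puff_device_ids` (in survey but no puffs).
#' @export
join_cohort <- function(puffs, profiles) {
  joined <- dplyr::left_join(puffs, profiles, by = "device_id")
  joined$matched <- joined$device_id %in% profiles$device_id
  structure(
    list(
      puffs = joined,
      profiles = profiles,
      unmatched_device_ids = sort(setdiff(unique(puffs$device_id),
                                          profiles$device_id)),
      zero_puff_device_ids = sort(setdiff(profiles$device_id,
                                          unique(puffs$device_id)))
    ),
    class = "cohort_dataset"
  )
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("<cohort_dataset>\n")
  cat("  puffs:   ", nrow(x$puffs), " (", sum(x$puffs$matched),
      " matched to a profile)\n", sep = "")
  cat("  profiles:", nrow(x$profiles), "\n")
  cat("  unmatched device IDs in puffs: ",
      length(x$unmatched_device_ids), "\n", sep = "")
  cat("  profiles with zero puffs:      ",
      length(x$zero_puff_device_ids), "\n", sep = "")
  invisible(x)
}

#' Filter puffs by declarative criteria
#'
#' Criteria are applied in order; the count removed by each criterion is
#' recorded in `attr(., "removed")`. Supported criteria:
#' `nonmissing_conc` (TRUE drops puffs with unrecorded concentration),
#' `nonzero_conc` (TRUE additionally drops 0 mg/mL puffs; missing-
#' concentration puffs are *not* implicitly dropped by this criterion),
#' `power` (character subset of low/medium/high), `date_range`
#' (length-2, inclusive calendar dates), `users` (device ID set).
#' An empty criteria list is the identity.
#'
#' @param puffs tibble of puff records.
#' @param criteria named list of criteria.
#' @return filtered tibble with attribute `removed`, a named integer
#'   vector of per-criterion removal counts.
#' @export
#' @examples
#' # filter_puffs(puffs, list(nonmissing_conc = TRUE, power = "high"))
filter_puffs <- function(puffs, criteria = list()) {
  allowed <- c("nonmissing_conc", "nonzero_conc", "power", "date_range", "users")
  unknown <- setdiff(names(criteria), allowed)
  if (length(unknown) > 0) {
    abort_pufftopo(paste0("unknown filter criterion: ",
                          paste(unknown, collapse = ", ")),
                   "pufftopo_config_error")
  }
  removed <- integer(0)
  out <- puffs
  drop_by <- function(keep, label) {
    removed[label] <<- sum(!keep)
    out <<- out[keep, , drop = FALSE]
  }
  if (isTRUE(criteria$nonmissing_conc)) {
    drop_by(!is.na(out$nicotine_conc_mg_ml), "nonmissing_conc")
  }
  if (isTRUE(criteria$nonzero_conc)) {
    drop_by(is.na(out$nicotine_conc_mg_ml) | out$nicotine_conc_mg_ml != 0,
            "nonzero_conc")
  }
  if (!is.null(criteria$power)) {
    bad <- setdiff(criteria$power, POWER_LEVELS)
    if (length(bad) > 0) {
      abort_pufftopo(paste0("unknown power setting in filter: ",
                            paste(bad, collapse = ", ")),
                     "pufftopo_config_error")
    }
    drop_by(as.character(out$power_setting) %in% criteria$power, "power")
  }
  if (!is.null(criteria$date_range)) {
    dr <- as.Date(criteria$date_range)
    if (length(dr) != 2 || anyNA(dr) || dr[1] > dr[2]) {
      abort_pufftopo("date_range must be two ordered dates",
                     "pufftopo_config_error")
    }
    d <- as.Date(out$timestamp)
    drop_by(d >= dr[1] & d <= dr[2], "date_range")
  }
  if (!is.null(criteria$users)) {
    drop_by(out$device_id %in% criteria$users, "users")
  }
  structure(out, removed = removed)
}
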