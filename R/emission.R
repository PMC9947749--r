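# Per-puff nicotine-emission estimation, anchored to a laboratory
# calibration point. The device's bench aerosol test yields 0.0952 mg of
# nicotine per puff with 12 mg/mL e-liquid at the high power setting under
# the Coresta machine-puffing regime (55 mL volume / 3 s puff / 30 s
# interval). Field puffs are scaled off that anchor with a separable
# model: emission proportional to nicotine concentration, puff duration
# and representative coil wattage,
#
#   e = E_ref * (c / c_ref) * (d / d_ref) * (w(P) / w(P_ref)).
#
# The model uses exactly the four inputs the device records (duration,
# concentration, power, plus the bench anchor); puff volume enters only
# through the calibration constant. It is injected as a replaceable
# strategy (`model` argument) so a refined formula — e.g. with nonlinear
# wattage or duty-cycle terms — can be swapped in without touching
# callers.

#' Laboratory calibration anchor for the emission model
#'
#' @param conc_ref reference e-liquid concentration, mg/mL.
#' @param power_ref reference power setting.
#' @param duration_ref reference puff duration, s (Coresta regime puff).
#' @param emission_ref bench-measured emission at the reference condition,
#'   mg/puff.
#' @return an `emission_calibration` object.
#' @export
#' @examples
#' emission_calibration()
emission_calibration <- function(conc_ref = 12, power_ref = "high",
                                 duration_ref = 3, emission_ref = 0.0952) {
  if (!(conc_ref > 0 && duration_ref > 0 && emission_ref > 0)) {
    abort_pufftopo("calibration constants must all be positive",
                   "pufftopo_config_error")
  }
  if (!power_ref %in% POWER_LEVELS) {
    abort_pufftopo("power_ref must be one of low/medium/high",
                   "pufftopo_domain_error")
  }
  structure(
    list(conc_ref = conc_ref, power_ref = power_ref,
         duration_ref = duration_ref, emission_ref = emission_ref),
    class = "emission_calibration"
  )
}

#' @export
print.emission_calibration <- function(x, ...) {
  cat("<emission_calibration> ", x$emission_ref, " mg/puff at ",
      x$conc_ref, " mg/mL, ", x$power_ref, " power, ",
      x$duration_ref, " s puff\n", sep = "")
  invisible(x)
}

# default separable strategy; any replacement must accept the same args
separable_emission_model <- function(conc, duration_s, watt, cal, watt_ref) {
  cal$emission_ref * (conc / cal$conc_ref) *
    (duration_s / cal$duration_ref) * (watt / watt_ref)
}

#' Estimate nicotine emission for puffs
#'
#' Vectorised per-puff emission (mg/puff). Puffs with a missing
#' concentration are explicitly not estimable and return NA — missingness
#' is never imputed. Zero concentration gives zero emission exactly. The
#' result is monotone nondecreasing in concentration, duration and band
#' wattage, and reproduces `emission_ref` exactly at the calibration
#' point.
#'
#' @param conc nicotine concentration, mg/mL (NA = not estimable).
#' @param duration_s puff duration, s.
#' @param power power setting (low/medium/high), recycled if scalar.
#' @param cal an [emission_calibration()].
#' @param bands power-band table; see [power_bands()].
#' @param model emission strategy function; the default is the separable
#'   calibration-anchored model described above.
#' @return numeric vector of emissions, mg/puff (NA where not estimable).
#' @export
#' @examples
#' puff_emission(12, 3, "high")   # 0.0952, the calibration identity
#' puff_emission(6, 3, "high")    # 0.0476
puff_emission <- function(conc, duration_s, power, cal = emission_calibration(),
                          bands = power_bands(),
                          model = separable_emission_model) {
  power <- as.character(power)
  if (length(power) == 1) power <- rep(power, length(conc))
  bad_power <- !is.na(power) & !power %in% bands$setting
  if (any(bad_power)) {
    abort_pufftopo(paste0("unknown power setting: ",
                          paste(unique(power[bad_power]), collapse = ", ")),
                   "pufftopo_domain_error")
  }
  if (any(conc < 0, na.rm = TRUE)) {
    abort_pufftopo("nicotine concentration must be >= 0 mg/mL",
                   "pufftopo_domain_error")
  }
  watt <- bands$watt_rep[match(power, bands$setting)]
  watt_ref <- bands$watt_rep[match(cal$power_ref, bands$setting)]
  e <- model(conc, duration_s, watt, cal, watt_ref)
  e[is.na(conc)] <- NA_real_
  e
}

#' Append a per-puff emission column
#'
#' Adds `emission_mg` to a puff tibble; NA where the concentration is
#' unrecorded (not estimable).
#'
#' @param puffs tibble of puff records.
#' @inheritParams puff_emission
#' @return `puffs` with an `emission_mg` column.
#' @export
add_puff_emissions <- function(puffs, cal = emission_calibration(),
                               bands = power_bands(),
                               model = separable_emission_model) {
  puffs$emission_mg <- puff_emission(
    puffs$nicotine_conc_mg_ml, puffs$duration_s, puffs$power_setting,
    cal = cal, bands = bands, model = model
  )
  puffs
}

#' Total nicotine over one user-day
#'
#' Sums per-puff emissions for one user's puffs on one calendar day.
#' Puffs whose emission is not estimable (missing concentration) are
#' excluded from the sum and counted, never imputed.
#'
#' @param emissions numeric vector of per-puff emissions (mg), NA = not
#'   estimable.
#' @return list with `total_mg`, `n_estimable`, `n_excluded`.
#' @export
#' @examples
#' daily_nicotine(c(0.05, 0.05, 0.02))
daily_nicotine <- function(emissions) {
  est <- emissions[!is.na(emissions)]
  list(
    total_mg = sum(est),
    n_estimable = length(est),
    n_excluded = sum(is.na(emissions))
  )
}

#' Descriptive summary of per-puff emissions
#'
#' Mean, median, SD and n over estimable puffs. Right-skewed inputs are
#' expected (mean above median) but not enforced.
#'
#' @param emissions numeric vector of per-puff emissions (mg).
#' @return one-row tibble (`mean`, `median`, `sd`, `se`, `n`); all-NA with
#'   n = 0 for an empty input.
#' @export
emission_summary <- function(emissions) {
  describe(emissions)
}
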