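# Descriptive statistics, cross-tabulations and effect sizes for puff
# topography. The study's own analysis argues that with >200,000 puffs
# significance tests are uninformative, so this module deliberately
# carries no p-value machinery: magnitudes (eta-squared as the "R^2
# coefficient" of a categorical factor, pairwise Cohen's d) are the
# reporting currency, with |d| >= 0.5 read as medium and >= 0.8 as large.

#' Descriptive summary of a numeric sample
#'
#' Mean, median, sample (n-1) SD, SE = SD/sqrt(n), and n. NAs are dropped.
#' An empty sample yields an explicit all-NA row with n = 0 rather than
#' an error.
#'
#' @param x numeric vector.
#' @return one-row tibble with columns `mean`, `median`, `sd`, `se`, `n`.
#' @export
#' @examples
#' describe(c(2, 4, 6))
describe <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0) {
    return(tibble::tibble(mean = NA_real_, median = NA_real_,
                          sd = NA_real_, se = NA_real_, n = 0L))
  }
  s <- if (n > 1) stats::sd(x) else 0
  tibble::tibble(mean = mean(x), median = stats::median(x),
                 sd = s, se = s / sqrt(n), n = n)
}

#' Cross-tabulate puffs over two categorical factors
#'
#' Counts puffs per (row level, column level) cell and expresses each cell
#' as a percentage of the grand total. Puffs for which either factor is
#' missing are excluded from the table and their count reported; with
#' `denominator = "all"` percentages are still taken over all input puffs
#' (the excluded included in the denominator), with `"subset"` (default)
#' over the tabulated puffs only.
#'
#' @param data tibble of puff records.
#' @param row,col names of categorical columns in `data`.
#' @param denominator `"subset"` or `"all"`.
#' @return a `crosstab` object: list with `table` (tibble `row`, `col`,
#'   `n`, `pct`), `grand_total`, `excluded`, `row`, `col`.
#' @export
crosstab <- function(data, row, col, denominator = c("subset", "all")) {
  denominator <- match.arg(denominator)
  if (!row %in% names(data) || !col %in% names(data)) {
    abort_pufftopo(paste0("unknown factor column: ",
                          paste(setdiff(c(row, col), names(data)), collapse = ", ")),
                   "pufftopo_config_error")
  }
  r <- data[[row]]
  cc <- data[[col]]
  ok <- !is.na(r) & !is.na(cc)
  tab <- tibble::tibble(row = r[ok], col = cc[ok]) |>
    dplyr::count(.data$row, .data$col, name = "n")
  grand <- if (denominator == "all") nrow(data) else sum(tab$n)
  tab$pct <- 100 * tab$n / grand
  structure(
    list(table = tab, grand_total = grand, excluded = sum(!ok),
         row = row, col = col),
    class = "crosstab"
  )
}

#' Build a cross-tabulation from pre-aggregated integer counts
#'
#' For reproducing published tables whose underlying records are not
#' available: takes one count per cell and computes the percentage layer
#' exactly as [crosstab()] would.
#'
#' @param counts tibble with one row per cell.
#' @param row,col,n names of the row-factor, column-factor and count
#'   columns in `counts`.
#' @param grand_total denominator; defaults to the sum of counts.
#' @return a `crosstab` object.
#' @export
#' @examples
#' crosstab_from_counts(fixture_table2(), "conc_bin", "power", "count")
crosstab_from_counts <- function(counts, row, col, n, grand_total = NULL) {
  tab <- tibble::tibble(row = counts[[row]], col = counts[[col]],
                        n = as.integer(counts[[n]]))
  grand <- if (is.null(grand_total)) sum(tab$n) else grand_total
  tab$pct <- 100 * tab$n / grand
  structure(
    list(table = tab, grand_total = grand, excluded = 0L,
         row = row, col = col),
    class = "crosstab"
  )
}

#' @export
print.crosstab <- function(x, digits = 2, ...) {
  cat("<crosstab> ", x$row, " x ", x$col,
      " (n = ", x$grand_total, ", excluded = ", x$excluded, ")\n", sep = "")
  wide <- x$table |>
    dplyr::mutate(cell = sprintf(paste0("%d (%.", digits, "f)"),
                                 .data$n, round_half_up(.data$pct, digits))) |>
    dplyr::select("row", "col", "cell") |>
    tidyr::pivot_wider(names_from = "col", values_from = "cell")
  print(as.data.frame(wide), row.names = FALSE)
  invisible(x)
}

#' Eta-squared: variance in a continuous outcome explained by a factor
#'
#' One-way decomposition SS_between / SS_total — the construction reported
#' as the "R^2 coefficient" of a categorical variable. Always in [0, 1].
#' Undefined (NA with a warning) when fewer than two non-empty groups
#' remain or total variance is zero.
#'
#' @param values numeric outcome.
#' @param groups categorical labels, same length.
#' @return scalar in [0, 1], or NA when undefined.
#' @export
#' @examples
#' eta_squared(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
eta_squared <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- as.character(groups)[ok]
  if (length(unique(groups)) < 2) {
    warning("eta_squared undefined: fewer than two non-empty groups")
    return(NA_real_)
  }
  grand <- mean(values)
  ss_total <- sum((values - grand)^2)
  if (ss_total == 0) {
    warning("eta_squared undefined: zero total variance")
    return(NA_real_)
  }
  group_means <- tapply(values, groups, mean)
  group_n <- tapply(values, groups, length)
  ss_between <- sum(group_n * (group_means - grand)^2)
  ss_between / ss_total
}

#' Cohen's d: standardized mean difference between two groups
#'
#' (mean(a) - mean(b)) / pooled SD, with the pooled SD
#' sqrt(((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a + n_b - 2)). Antisymmetric
#' under swapping the groups. `correction = TRUE` applies the Hedges
#' small-sample factor 1 - 3/(4(n_a+n_b) - 9); off by default.
#'
#' @param a,b numeric vectors, each of length >= 2 after NA removal.
#' @param correction apply the small-sample correction factor.
#' @return scalar d, or NA (with a warning) when the pooled SD is zero.
#' @export
#' @examples
#' cohen_d(c(2, 4), c(5, 7)) # -3 / sqrt(2)
cohen_d <- function(a, b, correction = FALSE) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) {
    abort_pufftopo("cohen_d requires at least 2 observations per group",
                   "pufftopo_domain_error")
  }
  pooled <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
                   (na + nb - 2))
  if (pooled == 0) {
    warning("cohen_d undefined: pooled SD is zero")
    return(NA_real_)
  }
  d <- (mean(a) - mean(b)) / pooled
  if (correction) d <- d * (1 - 3 / (4 * (na + nb) - 9))
  d
}

#' Effect-size report for one categorical factor
#'
#' Eta-squared for the factor plus all pairwise Cohen's d values between
#' its levels. Mirroring the published reporting convention, the
#' `d_reported` column suppresses small effects: values with |d| below
#' `min_d` (default 0.5, the medium-effect threshold) become NA.
#'
#' @param values numeric outcome (e.g. puff duration or per-puff emission).
#' @param groups categorical labels.
#' @param min_d reporting threshold on |d|.
#' @param correction passed to [cohen_d()].
#' @return list with `factor_eta_squared`, `pairwise` (tibble `level_a`,
#'   `level_b`, `n_a`, `n_b`, `d`, `d_reported`).
#' @export
effect_size_report <- function(values, groups, min_d = 0.5, correction = FALSE) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- as.character(groups)[ok]
  levels_ <- names(sort(table(groups), decreasing = TRUE))
  pairs <- utils::combn(levels_, 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(pairs, function(p) {
    a <- values[groups == p[1]]
    b <- values[groups == p[2]]
    d <- suppressWarnings(cohen_d(a, b, correction = correction))
    tibble::tibble(level_a = p[1], level_b = p[2],
                   n_a = length(a), n_b = length(b), d = d)
  })
  pairwise$d_reported <- ifelse(!is.na(pairwise$d) & abs(pairwise$d) >= min_d,
                                pairwise$d, NA_real_)
  list(
    factor_eta_squared = eta_squared(values, groups),
    pairwise = pairwise
  )
}

#' Per-user coefficient-of-variation variability
#'
#' For each user, the CV% (100 * sample SD / mean) of daily puff count,
#' daily mean puff duration and daily nicotine consumption over that
#' user's own active days. CVs are undefined (NA, with the reason
#' recorded) for users with fewer than two active days or a non-positive
#' mean — never silently zeroed.
#'
#' @param summaries tibble of daily user summaries
#'   (see [summarize_user_days()]).
#' @return tibble with one row per user: `device_id`, `n_active_days`,
#'   `cv_puffs`, `cv_duration`, `cv_nicotine`, `cv_undefined_reason`.
#' @export
user_cv <- function(summaries) {
  summaries |>
    dplyr::group_by(.data$device_id) |>
    dplyr::summarise(
      n_active_days = dplyr::n(),
      cv_puffs = cv_pct(.data$puff_count),
      cv_duration = cv_pct(.data$mean_duration_s),
      cv_nicotine = cv_pct(.data$total_nicotine_mg),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      cv_undefined_reason = dplyr::case_when(
        .data$n_active_days < 2 ~ "fewer than 2 active days",
        is.na(.data$cv_puffs) | is.na(.data$cv_duration) | is.na(.data$cv_nicotine) ~
          "non-positive mean for at least one metric",
        TRUE ~ NA_character_
      )
    )
}

#' Participant and puff distribution per demographic factor
#'
#' Reproduces the published "Table 1" layout from a joined cohort: for each
#' survey factor, participant counts (share of all surveyed participants)
#' and puff counts (share of all profile-matched puffs). Puffs from device
#' IDs without a survey profile are excluded and their count reported in
#' `attr(., "unmatched_puffs")`; profiles with zero puffs still count as
#' participants.
#'
#' @param cohort a `cohort_dataset` from [join_cohort()].
#' @return tibble with columns `factor`, `level`, `participants`,
#'   `participants_pct`, `puffs`, `puffs_pct`.
#' @export
demographic_puff_distribution <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  matched <- cohort$puffs[cohort$puffs$matched, , drop = FALSE]
  n_part <- nrow(cohort$profiles)
  n_puff <- nrow(matched)
  fac_cols <- c("sex", "age_band", "smoking_history", "ends_years_band")
  out <- purrr::map_dfr(fac_cols, function(f) {
    part <- cohort$profiles |>
      dplyr::count(level = as.character(.data[[f]]), name = "participants")
    puff <- matched |>
      dplyr::count(level = as.character(.data[[f]]), name = "puffs")
    dplyr::full_join(part, puff, by = "level") |>
      dplyr::mutate(
        factor = f,
        participants = dplyr::coalesce(.data$participants, 0L),
        puffs = dplyr::coalesce(.data$puffs, 0L),
        participants_pct = 100 * .data$participants / n_part,
        puffs_pct = if (n_puff > 0) 100 * .data$puffs / n_puff else NA_real_
      ) |>
      dplyr::select("factor", "level", "participants", "participants_pct",
                    "puffs", "puffs_pct")
  })
  structure(out, unmatched_puffs = sum(!cohort$puffs$matched))
}
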