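#' Decimal age at assessment
#'
#' Elapsed years (days / 365.25) from date of birth to the first day of
#' accelerometer assessment. When a source is missing, falls back in order
#' of preference: date of birth + assessment date, an age supplied by the
#' original investigators, then date of birth + a proxy date (e.g., of
#' questionnaire completion).
#'
#' @param dob,assessment_date,proxy_date `Date` vectors (or `NA`).
#' @param provided_age Numeric years (or `NA`).
#' @return Numeric vector of decimal ages.
#' @export
#' @examples
#' decimal_age(as.Date("2000-01-01"), as.Date("2010-01-01"))  # 3653/365.25
decimal_age <- function(dob = NULL, assessment_date = NULL,
                        provided_age = NULL, proxy_date = NULL) {
  n <- max(length(dob), length(assessment_date),
           length(provided_age), length(proxy_date))
  blank_date <- function(x) {
    if (is.null(x)) rep(as.Date(NA), n) else rep_len(as.Date(x), n)
  }
  dob <- blank_date(dob)
  assessment_date <- blank_date(assessment_date)
  proxy_date <- blank_date(proxy_date)
  provided_age <- if (is.null(provided_age)) rep(NA_real_, n)
                  else rep_len(as.numeric(provided_age), n)
  years <- function(from, to) as.numeric(to - from) / 365.25
  age <- years(dob, assessment_date)
  age <- ifelse(is.na(age), provided_age, age)
  age <- ifelse(is.na(age), years(dob, proxy_date), age)
  if (anyNA(age)) {
    abort(sprintf("%d record(s) with no resolvable age source", sum(is.na(age))),
          class = "actichange_missing_age_error")
  }
  age
}

#' Child/adolescent dichotomy at baseline
#'
#' @param baseline_age Numeric years.
#' @param threshold Split point; ages at or above it are `adolescent`.
#' @return Factor with levels `child`, `adolescent`.
#' @export
age_group <- function(baseline_age, threshold = 10) {
  stopifnot(all(baseline_age >= 0, na.rm = TRUE))
  factor(ifelse(baseline_age < threshold, "child", "adolescent"),
         levels = c("child", "adolescent"))
}

#' Meteorological season of a measurement date
#'
#' Northern hemisphere: Dec-Feb winter, Mar-May spring, Jun-Aug summer,
#' Sep-Nov autumn; southern hemisphere shifted six months.
#'
#' @param date `Date` vector (or month number 1-12).
#' @param hemisphere `"north"` or `"south"`, per study.
#' @return Factor with levels `spring`, `summer`, `autumn`, `winter`.
#' @export
season_of <- function(date, hemisphere = c("north", "south")) {
  hemisphere <- match.arg(hemisphere)
  month <- if (inherits(date, "Date")) as.POSIXlt(date)$mon + 1L else as.integer(date)
  stopifnot(all(month %in% 1:12))
  if (hemisphere == "south") month <- (month + 5L) %% 12L + 1L
  north <- c("winter", "winter", "spring", "spring", "spring", "summer",
             "summer", "summer", "autumn", "autumn", "autumn", "winter")
  factor(north[month], levels = c("spring", "summer", "autumn", "winter"))
}

#' LMS z-score
#'
#' Converts a measurement into an age- and sex-standardised z-score given
#' the matched growth-reference row: power `L`, median `M`, coefficient of
#' variation `S`. `z = ((x/M)^L - 1) / (L * S)` for `L != 0`, with the
#' limiting form `z = log(x/M) / S` at `L = 0`.
#'
#' Reference values (e.g., British 1990 or IOTF BMI references) are
#' external inputs matched to the child's age and sex by the caller.
#'
#' @param x Positive measurement (e.g., BMI).
#' @param L,M,S Reference parameters; `M > 0`, `S > 0`.
#' @return Numeric z-score(s), strictly increasing in `x`.
#' @export
lms_zscore <- function(x, L, M, S) {
  if (any(x <= 0) || any(M <= 0) || any(S <= 0)) {
    abort("x, M and S must be positive", class = "actichange_domain_error")
  }
  ifelse(L == 0, log(x / M) / S, ((x / M)^L - 1) / (L * S))
}

#' Weight category from a BMI z-score
#'
#' Three-way classification against injected cutoffs. Real reference
#' cutoffs (UK1990 / IOTF) are licensed external tables; a synthetic
#' fixture (-2 / +1.33) is used in tests.
#'
#' @param bmi_z Numeric z-scores.
#' @param cutoffs Named numeric: `lower` (below = underweight) and `upper`
#'   (above = overweight/obese); the closed interval between is normal.
#' @return Factor with levels `underweight`, `normal`, `overweight_obese`.
#' @export
weight_category <- function(bmi_z, cutoffs = c(lower = -2, upper = 1.33)) {
  if (!all(c("lower", "upper") %in% names(cutoffs))) {
    abort("cutoffs must name 'lower' and 'upper'", class = "actichange_config_error")
  }
  factor(
    ifelse(bmi_z < cutoffs[["lower"]], "underweight",
           ifelse(bmi_z > cutoffs[["upper"]], "overweight_obese", "normal")),
    levels = c("underweight", "normal", "overweight_obese")
  )
}

#' Apply cohort inclusion rules
#'
#' Restricts the analysis set to (1) participants outside intervention
#' arms (for intervention studies only control-group children are
#' analysable), (2) the first `max_waves` waves of measurement per
#' participant, and (3) participants retaining at least `min_waves` valid
#' waves after that cap. Idempotent.
#'
#' @param waves Wave-level tibble with `participant_id`, `wave_index`
#'   (rows only for waves that passed the valid-file rule).
#' @param records Participant tibble with `participant_id`, `study_id` and
#'   `intervention_arm` (`"control"`, `"intervention"` or `"none"`).
#' @param min_waves,max_waves Inclusion bounds on valid waves.
#' @return The filtered wave tibble with `study_id` joined on.
#' @export
apply_inclusion <- function(waves, records, min_waves = 2L, max_waves = 3L) {
  keep <- records |>
    dplyr::filter(.data$intervention_arm != "intervention") |>
    dplyr::select(dplyr::all_of(c("participant_id", "study_id")))
  out <- waves
  out$study_id <- NULL
  out <- out |>
    dplyr::inner_join(keep, by = "participant_id") |>
    dplyr::mutate(
      wave_rank = rank(.data$wave_index, ties.method = "min"),
      .by = dplyr::all_of(intersect(c("participant_id", "stream"), names(out)))
    ) |>
    dplyr::filter(.data$wave_rank <= max_waves) |>
    dplyr::select(-"wave_rank")
  n_waves <- out |>
    dplyr::distinct(.data$participant_id, .data$wave_index) |>
    dplyr::count(.data$participant_id)
  enough <- n_waves$participant_id[n_waves$n >= min_waves]
  dplyr::filter(out, .data$participant_id %in% enough)
}

#' Baseline-to-follow-up change per participant
#'
#' Baseline is each participant's first retained valid wave; follow-up is
#' the last (for three-wave participants, the third). Absolute change is
#' follow-up minus baseline (min/day); relative change is absolute change
#' over baseline, in percent.
#'
#' @param waves Analysis-set tibble with `participant_id`, `wave_index` and
#'   a standardized outcome column per behaviour.
#' @param outcome One of `"sed"`, `"lpa"`, `"mvpa"`.
#' @param prefix Prefix of the outcome columns (default `"std_"`).
#' @return Tibble: `participant_id`, `outcome`, `baseline_min`,
#'   `followup_min`, `abs_change`, `rel_change_pct`.
#' @export
change_summary <- function(waves, outcome = c("sed", "lpa", "mvpa"),
                           prefix = "std_") {
  outcome <- match.arg(outcome)
  col <- paste0(prefix, outcome)
  if (!col %in% names(waves)) {
    abort(sprintf("outcome column '%s' not found", col),
          class = "actichange_config_error")
  }
  n_per <- table(waves$participant_id)
  if (any(n_per < 2L)) {
    abort("change requires at least two valid waves per participant",
          class = "actichange_insufficient_data_error")
  }
  waves |>
    dplyr::arrange(.data$participant_id, .data$wave_index) |>
    dplyr::summarise(
      baseline_min = .data[[col]][1L],
      followup_min = .data[[col]][dplyr::n()],
      .by = "participant_id"
    ) |>
    dplyr::mutate(
      outcome = outcome,
      abs_change = .data$followup_min - .data$baseline_min,
      rel_change_pct = .data$abs_change / .data$baseline_min * 100,
      .after = "participant_id"
    )
}

#' Cohort-level change table
#'
#' Mean (SD) for baseline, follow-up and absolute change; median (IQR,
#' reported as Q3 - Q1) for relative change, for each behaviour, overall
#' and optionally within groups.
#'
#' @param waves Analysis-set tibble (one stream).
#' @param by Optional grouping column name (e.g., `"sex"`).
#' @inheritParams change_summary
#' @return Tibble with one row per outcome (x group).
#' @export
cohort_change_table <- function(waves, by = NULL, prefix = "std_") {
  per <- dplyr::bind_rows(lapply(c("sed", "lpa", "mvpa"), function(o) {
    change_summary(waves, o, prefix)
  }))
  if (!is.null(by)) {
    groups <- waves |>
      dplyr::distinct(.data$participant_id, .data[[by]])
    per <- dplyr::left_join(per, groups, by = "participant_id")
  }
  per |>
    dplyr::summarise(
      n = dplyr::n(),
      baseline_mean = mean(.data$baseline_min),
      baseline_sd = sd(.data$baseline_min),
      followup_mean = mean(.data$followup_min),
      followup_sd = sd(.data$followup_min),
      change_mean = mean(.data$abs_change),
      change_sd = sd(.data$abs_change),
      rel_change_median = median(.data$rel_change_pct),
      rel_change_iqr = quantile(.data$rel_change_pct, 0.75) -
        quantile(.data$rel_change_pct, 0.25),
      .by = dplyr::all_of(c("outcome", by))
    )
}
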