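#' Evenson youth intensity cut-points
#'
#' Counts-per-minute thresholds separating sedentary time (<= `sed_max`),
#' light activity, and MVPA (>= `mvpa_min`).
#'
#' @param sed_max Upper bound (inclusive) of the sedentary band, CPM.
#' @param mvpa_min Lower bound (inclusive) of the MVPA band, CPM.
#' @return A named list usable as the `cutpoints` argument downstream.
#' @export
cutpoints_evenson <- function(sed_max = 100, mvpa_min = 2295) {
  if (sed_max >= mvpa_min) abort("sed_max must be below mvpa_min",
                                 class = "actichange_parameter_error")
  list(sed_max = sed_max, mvpa_min = mvpa_min)
}

#' Classify counts-per-minute into intensity bands
#'
#' @param cpm Numeric vector of counts per 60-s epoch.
#' @param cutpoints See [cutpoints_evenson()].
#' @return Factor with levels `sedentary`, `light`, `mvpa`; the partition is
#'   exhaustive and exclusive.
#' @export
#' @examples
#' classify_intensity(c(0, 100, 101, 2294, 2295))
classify_intensity <- function(cpm, cutpoints = cutpoints_evenson()) {
  if (anyNA(cpm) || any(cpm < 0)) {
    abort("cpm must be non-negative and non-missing", class = "actichange_domain_error")
  }
  out <- ifelse(cpm <= cutpoints$sed_max, "sedentary",
                ifelse(cpm >= cutpoints$mvpa_min, "mvpa", "light"))
  factor(out, levels = c("sedentary", "light", "mvpa"))
}

#' Summarize a flagged epoch series into day records
#'
#' For each calendar date, tallies worn non-excluded minutes in each
#' intensity band. A day is valid when it has at least `min_wear` wear
#' minutes; Saturday and Sunday are weekend days.
#'
#' @param series An [epoch_series()] at 60-s epochs with [flag_nonwear()]
#'   and [flag_overnight()] already applied.
#' @param cutpoints See [cutpoints_evenson()].
#' @param min_wear Valid-day wear threshold in minutes.
#' @return A tibble with one row per date: `participant_id`, `wave_index`,
#'   `date`, `day_type`, `wear_min`, `sed_min`, `lpa_min`, `mvpa_min`,
#'   `valid`. `sed_min + lpa_min + mvpa_min == wear_min` exactly.
#' @export
summarize_days <- function(series, cutpoints = cutpoints_evenson(),
                           min_wear = 600) {
  stopifnot(inherits(series, "epoch_series"))
  require_60s(series)
  worn <- series$wear & !series$excluded
  band <- classify_intensity(series$counts, cutpoints)
  tibble::tibble(
    date = epoch_dates(series),
    worn = worn,
    band = band
  ) |>
    dplyr::summarise(
      wear_min = sum(.data$worn),
      sed_min = sum(.data$worn & .data$band == "sedentary"),
      lpa_min = sum(.data$worn & .data$band == "light"),
      mvpa_min = sum(.data$worn & .data$band == "mvpa"),
      .by = "date"
    ) |>
    dplyr::mutate(
      participant_id = series$participant_id,
      wave_index = series$wave_index,
      day_type = day_type_of(.data$date),
      valid = .data$wear_min >= min_wear,
      .before = 1L
    ) |>
    dplyr::relocate("date", .after = "wave_index")
}

day_type_of <- function(date) {
  wd <- as.POSIXlt(date)$wday  # 0 = Sunday
  factor(ifelse(wd %in% c(0L, 6L), "weekend", "weekday"),
         levels = c("weekday", "weekend"))
}

#' Valid-file rule
#'
#' A participant-wave file is valid when it contributes at least two valid
#' weekdays and at least one valid weekend day.
#'
#' @param days Day-summary tibble for one participant-wave
#'   (see [summarize_days()]).
#' @param min_weekdays,min_weekend_days Required counts of valid days.
#' @return Logical scalar.
#' @export
valid_file <- function(days, min_weekdays = 2L, min_weekend_days = 1L) {
  if (nrow(days) == 0L) return(FALSE)
  sum(days$valid & days$day_type == "weekday") >= min_weekdays &&
    sum(days$valid & days$day_type == "weekend") >= min_weekend_days
}

#' Build per-wave, per-stream raw behaviour summaries
#'
#' Averages valid days within each participant-wave for three streams: all
#' valid days, weekdays only, weekend days only. Waves failing the
#' valid-file rule (assessed on all days) are dropped; the weekday/weekend
#' streams inherit that gate. A stream with zero valid days in an otherwise
#' valid wave is omitted with a warning.
#'
#' @param days Day-summary tibble (possibly many participants/waves).
#' @param streams Subset of `c("all", "weekday", "weekend")`.
#' @return A tibble keyed by `participant_id`, `wave_index`, `stream` with
#'   `n_valid_days`, `mean_wear_min` and `raw_sed`/`raw_lpa`/`raw_mvpa`
#'   mean minutes per day.
#' @export
build_wave_summaries <- function(days, streams = c("all", "weekday", "weekend")) {
  streams <- match.arg(streams, several.ok = TRUE)
  gate <- days |>
    dplyr::summarise(file_valid = valid_file(dplyr::pick(dplyr::everything())),
                     .by = c("participant_id", "wave_index"))
  dropped <- sum(!gate$file_valid)
  if (dropped > 0L) {
    inform(sprintf("dropping %d wave(s) failing the valid-file rule", dropped))
  }
  days <- days |>
    dplyr::inner_join(dplyr::filter(gate, .data$file_valid),
                      by = c("participant_id", "wave_index")) |>
    dplyr::filter(.data$valid)
  out <- lapply(streams, function(s) {
    d <- if (s == "all") days else dplyr::filter(days, .data$day_type == s)
    d |>
      dplyr::summarise(
        n_valid_days = dplyr::n(),
        mean_wear_min = mean(.data$wear_min),
        raw_sed = mean(.data$sed_min),
        raw_lpa = mean(.data$lpa_min),
        raw_mvpa = mean(.data$mvpa_min),
        .by = c("participant_id", "wave_index")
      ) |>
      dplyr::mutate(stream = s, .after = "wave_index")
  })
  out <- dplyr::bind_rows(out)
  expected <- length(streams) * nrow(gate[gate$file_valid, ])
  if (nrow(out) < expected) {
    warn("some streams had zero valid days and were omitted")
  }
  dplyr::arrange(out, .data$participant_id, .data$wave_index, .data$stream)
}

#' Wear-time standardization across waves
#'
#' Rescales each wave's intensity minutes so that behaviour is expressed at
#' the participant's pooled mean daily wear time, removing between-wave
#' differences in how long the device was worn:
#' `std_I(w) = raw_I(w) / wear(w) * pooled_wear`, where `pooled_wear` is the
#' mean wear over the participant's valid days pooled across waves
#' (day-count weighted), computed separately per stream.
#'
#' @param waves Wave-summary tibble from [build_wave_summaries()] (or any
#'   tibble with `participant_id`, `stream`, `mean_wear_min`, optional
#'   `n_valid_days`, and `raw_sed`/`raw_lpa`/`raw_mvpa`).
#' @return The input with `pooled_wear_min` and `std_sed`/`std_lpa`/
#'   `std_mvpa` columns added. Standardized intensities of a wave sum to
#'   `pooled_wear_min` whenever the raw intensities sum to that wave's wear.
#' @export
#' @examples
#' w <- tibble::tibble(
#'   participant_id = "P1", wave_index = 1:2, stream = "all",
#'   n_valid_days = 4, mean_wear_min = c(600, 720),
#'   raw_sed = c(400, 500), raw_lpa = c(170, 190), raw_mvpa = c(30, 30)
#' )
#' standardize_wear(w)$std_mvpa  # 33.0, 27.5
standardize_wear <- function(waves) {
  if (any(waves$mean_wear_min <= 0)) {
    abort("wave with zero mean wear: proportion of wear time undefined",
          class = "actichange_domain_error")
  }
  if (!"n_valid_days" %in% names(waves)) waves$n_valid_days <- 1L
  waves |>
    dplyr::mutate(
      pooled_wear_min = sum(.data$mean_wear_min * .data$n_valid_days) /
        sum(.data$n_valid_days),
      std_sed = .data$raw_sed / .data$mean_wear_min * .data$pooled_wear_min,
      std_lpa = .data$raw_lpa / .data$mean_wear_min * .data$pooled_wear_min,
      std_mvpa = .data$raw_mvpa / .data$mean_wear_min * .data$pooled_wear_min,
      .by = c("participant_id", "stream")
    )
}
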