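#' Epoch-level accelerometer count series
#'
#' An `epoch_series` holds one participant-wave's contiguous sequence of
#' accelerometer counts at a fixed epoch length, together with per-epoch
#' wear and overnight-exclusion flags. Epoch `i` starts at
#' `start_time + (i - 1) * epoch_length` seconds; the series has no gaps
#' (gap handling happens at read time, see [read_epoch_csv()]).
#'
#' Timestamps are stored in UTC and interpreted as local clock time: the
#' overnight exclusion window and calendar-day boundaries are defined on
#' the clock the device displayed, so no DST arithmetic is wanted.
#'
#' @param counts Non-negative integer vector of activity counts per epoch.
#' @param start_time `POSIXct` (or string coercible to it, UTC) start of the
#'   first epoch.
#' @param epoch_length Epoch duration in seconds; must divide 60.
#' @param participant_id,wave_index Identifiers carried through the pipeline.
#' @param wear,excluded Optional logical vectors (recycled defaults: worn,
#'   not excluded).
#'
#' @return An object of class `epoch_series`.
#' @export
#' @examples
#' es <- epoch_series(c(0, 150, 3000), start_time = "2012-03-05 09:00:00")
#' es
epoch_series <- function(counts, start_time, epoch_length = 60,
                         participant_id = "P1", wave_index = 1L,
                         wear = TRUE, excluded = FALSE) {
  counts <- as.numeric(counts)
  if (anyNA(counts) || any(counts < 0)) {
    abort("counts must be non-negative and non-missing", class = "actichange_format_error")
  }
  if (!epoch_length %in% c(1L, 5L, 10L, 15L, 30L, 60L)) {
    abort(sprintf("unsupported epoch length %s s (must divide 60)", epoch_length),
          class = "actichange_epoch_error")
  }
  start_time <- as.POSIXct(start_time, tz = "UTC")
  if (length(start_time) != 1L || is.na(start_time)) {
    abort("start_time must be a single valid timestamp", class = "actichange_format_error")
  }
  n <- length(counts)
  wear <- rep_len(as.logical(wear), n)
  excluded <- rep_len(as.logical(excluded), n)
  structure(
    list(
      participant_id = as.character(participant_id),
      wave_index = as.integer(wave_index),
      start_time = start_time,
      epoch_length = as.integer(epoch_length),
      counts = counts,
      wear = wear,
      excluded = excluded
    ),
    class = "epoch_series"
  )
}

#' @export
#' @method print epoch_series
print.epoch_series <- function(x, ...) {
  cat(sprintf(
    "<epoch_series> participant %s wave %d: %d epochs of %d s from %s\n",
    x$participant_id, x$wave_index, length(x$counts), x$epoch_length,
    format(x$start_time, "%Y-%m-%d %H:%M:%S")
  ))
  cat(sprintf("  non-wear epochs: %d; overnight-excluded: %d\n",
              sum(!x$wear), sum(x$excluded)))
  invisible(x)
}

#' @export
length.epoch_series <- function(x) length(x$counts)

#' Epoch start times of a series
#'
#' @param series An [epoch_series()].
#' @return `POSIXct` vector, one start time per epoch.
#' @export
epoch_times <- function(series) {
  stopifnot(inherits(series, "epoch_series"))
  series$start_time + (seq_along(series$counts) - 1) * series$epoch_length
}

#' Convert an epoch series to a tibble
#'
#' @param x An [epoch_series()].
#' @param ... Unused.
#' @return A tibble with columns `timestamp`, `counts`, `wear`, `excluded`.
#' @export
as_tibble.epoch_series <- function(x, ...) {
  tibble::tibble(
    timestamp = epoch_times(x),
    counts = x$counts,
    wear = x$wear,
    excluded = x$excluded
  )
}

seconds_of_day <- function(times) as.numeric(times) %% 86400

epoch_dates <- function(series) as.Date(epoch_times(series), tz = "UTC")
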