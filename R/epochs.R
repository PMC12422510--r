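#' Read an epoch-level count CSV
#'
#' Accepts either a plain two-column `timestamp,counts` CSV (ISO timestamps)
#' or an ActiGraph-style export whose header block (lines of
#' `key value` pairs delimited by `---` rules) carries the start date/time
#' and epoch period, followed by a single counts column.
#'
#' The epoch length is inferred from consecutive timestamps (plain dialect)
#' or the header (ActiGraph dialect) unless supplied. Timestamp gaps are a
#' hard error by default because silently zero-filling a gap manufactures
#' non-wear time; pass `gap_action = "zero_fill"` to fill gaps with
#' zero-count epochs instead.
#'
#' @param path Path to the CSV file.
#' @param participant_id,wave_index Identifiers to stamp on the result.
#' @param epoch_length Epoch length in seconds; inferred when `NULL`.
#' @param gap_action `"error"` (default) or `"zero_fill"` for timestamp gaps.
#' @param counts_col,time_col Column names for the plain dialect.
#'
#' @return An [epoch_series()] with all epochs flagged worn / not excluded.
#' @export
read_epoch_csv <- function(path, participant_id = NULL, wave_index = 1L,
                           epoch_length = NULL,
                           gap_action = c("error", "zero_fill"),
                           counts_col = "counts", time_col = "timestamp") {
  gap_action <- match.arg(gap_action)
  if (is.null(participant_id)) {
    participant_id <- sub("\\.[^.]*$", "", basename(path))
  }
  first <- readLines(path, n = 1L)
  if (grepl("^-+", first)) {
    parsed <- read_actigraph_header(path)
    if (is.null(epoch_length)) epoch_length <- parsed$epoch_length
    if (is.null(epoch_length)) {
      abort("epoch length not in header and not supplied", class = "actichange_epoch_error")
    }
    return(epoch_series(parsed$counts, parsed$start_time, epoch_length,
                        participant_id, wave_index))
  }
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!counts_col %in% names(dat)) {
    abort(sprintf("missing counts column '%s' in %s", counts_col, path),
          class = "actichange_format_error")
  }
  if (!time_col %in% names(dat)) {
    abort(sprintf("missing timestamp column '%s' in %s", time_col, path),
          class = "actichange_format_error")
  }
  times <- as.POSIXct(dat[[time_col]], tz = "UTC")
  counts <- dat[[counts_col]]
  if (anyNA(times)) {
    abort("unparseable timestamps", class = "actichange_format_error")
  }
  if (anyNA(counts)) {
    abort("missing values in counts column", class = "actichange_format_error")
  }
  if (length(times) > 1L) {
    steps <- as.numeric(diff(times), units = "secs")
    if (any(steps <= 0)) {
      abort("timestamps are not strictly increasing", class = "actichange_format_error")
    }
    if (is.null(epoch_length)) epoch_length <- min(steps)
    if (any(steps %% epoch_length != 0)) {
      abort("timestamp spacing is not a multiple of the epoch length",
            class = "actichange_format_error")
    }
    if (any(steps > epoch_length)) {
      if (gap_action == "error") {
        abort(sprintf("%d timestamp gap(s) found; re-read with gap_action = 'zero_fill' to fill with zeros",
                      sum(steps > epoch_length)),
              class = "actichange_gap_error")
      }
      full <- seq(times[1L], times[length(times)], by = epoch_length)
      filled <- numeric(length(full))
      filled[match(as.numeric(times), as.numeric(full))] <- counts
      counts <- filled
      times <- full
    }
  } else if (is.null(epoch_length)) {
    epoch_length <- 60L
  }
  epoch_series(counts, times[1L], epoch_length, participant_id, wave_index)
}

# ActiGraph export header block: '---' rules around 'key value' lines, then data
read_actigraph_header <- function(path) {
  lines <- readLines(path)
  rules <- grep("^-+", lines)
  if (length(rules) < 2L) {
    abort("malformed ActiGraph header (expected two '---' rule lines)",
          class = "actichange_format_error")
  }
  header <- lines[(rules[1L] + 1L):(rules[2L] - 1L)]
  grab <- function(key) {
    hit <- grep(key, header, ignore.case = TRUE, value = TRUE)
    if (length(hit) == 0L) return(NULL)
    trimws(sub(".*?([0-9:/\\-]+)\\s*$", "\\1", hit[1L]))
  }
  start_time <- grab("Start Time")
  start_date <- grab("Start Date")
  epoch_txt <- grab("Epoch Period|Cycle Period")
  if (is.null(start_time) || is.null(start_date)) {
    abort("ActiGraph header lacks start date/time", class = "actichange_format_error")
  }
  epoch_length <- NULL
  if (!is.null(epoch_txt)) {
    hms <- as.numeric(strsplit(epoch_txt, ":")[[1L]])
    epoch_length <- sum(hms * c(3600, 60, 1)[seq_along(hms) + 3 - length(hms)])
  }
  # dates exported as m/d/Y or Y-m-d
  start <- suppressWarnings(as.POSIXct(paste(start_date, start_time),
                                       tz = "UTC",
                                       tryFormats = c("%m/%d/%Y %H:%M:%S",
                                                      "%d/%m/%Y %H:%M:%S",
                                                      "%Y-%m-%d %H:%M:%S")))
  if (is.na(start)) {
    abort("could not parse ActiGraph start date/time", class = "actichange_format_error")
  }
  body <- lines[(rules[2L] + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  counts <- suppressWarnings(as.numeric(vapply(strsplit(body, ","), `[`, "", 1L)))
  if (anyNA(counts)) {
    abort("non-numeric rows in ActiGraph data block", class = "actichange_format_error")
  }
  list(counts = counts, start_time = start, epoch_length = epoch_length)
}

#' Reintegrate a count series to a longer epoch
#'
#' Sums counts over consecutive non-overlapping windows so that, e.g., four
#' 15-s epochs become one 60-s epoch. Windows are anchored at the first
#' target-aligned boundary at or after the series start (any leading partial
#' window is dropped); a trailing partial window is dropped. Wear and
#' exclusion flags are reset: reintegration precedes flagging.
#'
#' @param series An [epoch_series()].
#' @param target Target epoch length in seconds (multiple of the source).
#' @return An [epoch_series()] at the target epoch length.
#' @export
#' @examples
#' es <- epoch_series(c(10, 20, 30, 40), "2012-03-05 09:00:00", epoch_length = 15)
#' reintegrate(es)$counts  # 100
reintegrate <- function(series, target = 60L) {
  stopifnot(inherits(series, "epoch_series"))
  if (target %% series$epoch_length != 0) {
    abort(sprintf("target %s s is not a multiple of the %s s source epoch",
                  target, series$epoch_length),
          class = "actichange_target_error")
  }
  counts <- series$counts
  start <- series$start_time
  misalign <- seconds_of_day(start) %% target
  if (misalign != 0) {
    skip_s <- target - misalign
    skip_n <- skip_s / series$epoch_length
    if (skip_n >= length(counts)) {
      abort("series shorter than one aligned target window", class = "actichange_target_error")
    }
    counts <- counts[-seq_len(skip_n)]
    start <- start + skip_s
  }
  per <- as.integer(target / series$epoch_length)
  m <- length(counts) %/% per
  if (m == 0L) {
    abort("series shorter than one target window", class = "actichange_target_error")
  }
  sums <- colSums(matrix(counts[seq_len(m * per)], nrow = per))
  epoch_series(sums, start, target, series$participant_id, series$wave_index)
}

#' Flag the overnight exclusion window
#'
#' Marks epochs whose start time falls in the half-open window
#' \[23:00, 06:00) as excluded, to avoid misclassifying overnight sleep as
#' sedentary time. An epoch starting exactly at 06:00 is retained.
#'
#' @param series An [epoch_series()] at 60-s epochs.
#' @param start_hour,end_hour Window bounds (hours, local clock).
#' @return The series with `excluded` set.
#' @export
flag_overnight <- function(series, start_hour = 23, end_hour = 6) {
  stopifnot(inherits(series, "epoch_series"))
  require_60s(series)
  sod <- seconds_of_day(epoch_times(series))
  series$excluded <- series$excluded | sod >= start_hour * 3600 | sod < end_hour * 3600
  series
}

require_60s <- function(series) {
  if (series$epoch_length != 60L) {
    abort("operation requires 60-s epochs; call reintegrate() first",
          class = "actichange_epoch_error")
  }
  invisible(series)
}

#' Detect non-wear bouts
#'
#' A non-wear bout is a maximal window of zero-count epochs spanning at
#' least `min_bout` minutes, in which zero runs may be merged across short
#' non-zero interruptions. Under the default `tolerance_scope =
#' "per_interruption"`, each interruption may last at most `tolerance`
#' consecutive non-zero epochs (any count magnitude, any number of
#' interruptions per bout); under `"per_bout"` the interruptions of a bout
#' may total at most `tolerance` minutes. Bouts always begin and end on a
#' zero epoch. Detection runs over all epochs, including the overnight
#' window: physical non-wear does not respect clock cut-offs, and the
#' exclusion flag removes overnight epochs from wear accounting regardless.
#'
#' @param series An [epoch_series()] at 60-s epochs.
#' @param min_bout Minimum bout span in minutes.
#' @param tolerance Maximum interruption length in minutes.
#' @param tolerance_scope `"per_interruption"` (default) or `"per_bout"`.
#' @return A tibble of bouts: `start_index`, `end_index` (half-open, 1-based),
#'   `span_min`, `interruption_min` (longest single interruption, or total
#'   under `"per_bout"`).
#' @export
#' @examples
#' es <- epoch_series(c(rep(500, 5), rep(0, 60), rep(500, 5)),
#'                    "2012-03-05 08:00:00")
#' detect_nonwear(es)
detect_nonwear <- function(series, min_bout = 60L, tolerance = 2L,
                           tolerance_scope = c("per_interruption", "per_bout")) {
  stopifnot(inherits(series, "epoch_series"))
  require_60s(series)
  tolerance_scope <- match.arg(tolerance_scope)
  if (min_bout < tolerance + 2L) {
    abort("min_bout must be at least tolerance + 2 minutes",
          class = "actichange_parameter_error")
  }
  r <- rle(series$counts == 0)
  k <- length(r$lengths)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  bouts <- list()
  i <- 1L
  while (i <= k) {
    if (!r$values[i]) {
      i <- i + 1L
      next
    }
    j <- i
    interrupt <- 0L
    repeat {
      if (j + 2L > k || r$values[j + 1L]) break
      gap <- r$lengths[j + 1L]
      ok <- if (tolerance_scope == "per_interruption") gap <= tolerance
            else interrupt + gap <= tolerance
      if (!ok || !r$values[j + 2L]) break
      interrupt <- if (tolerance_scope == "per_bout") interrupt + gap
                   else max(interrupt, gap)
      j <- j + 2L
    }
    span <- run_end[j] - run_start[i] + 1L
    if (span >= min_bout) {
      bouts[[length(bouts) + 1L]] <- tibble::tibble(
        start_index = run_start[i],
        end_index = run_end[j] + 1L,
        span_min = span,
        interruption_min = interrupt
      )
    }
    i <- j + 1L
  }
  if (length(bouts) == 0L) {
    return(tibble::tibble(start_index = integer(), end_index = integer(),
                          span_min = integer(), interruption_min = integer()))
  }
  dplyr::bind_rows(bouts)
}

#' Apply non-wear bouts to the wear flag
#'
#' Runs [detect_nonwear()] (unless bouts are supplied) and sets
#' `wear = FALSE` for every epoch inside each bout, interruption epochs
#' included.
#'
#' @inheritParams detect_nonwear
#' @param bouts Optional precomputed bout table from [detect_nonwear()].
#' @return The series with updated `wear`, with the bout table attached as
#'   attribute `"nonwear_bouts"`.
#' @export
flag_nonwear <- function(series, min_bout = 60L, tolerance = 2L,
                         tolerance_scope = c("per_interruption", "per_bout"),
                         bouts = NULL) {
  tolerance_scope <- match.arg(tolerance_scope)
  if (is.null(bouts)) {
    bouts <- detect_nonwear(series, min_bout, tolerance, tolerance_scope)
  }
  if (nrow(bouts) > 0L) {
    idx <- unlist(Map(seq.int, bouts$start_index, bouts$end_index - 1L))
    series$wear[idx] <- FALSE
  }
  attr(series, "nonwear_bouts") <- bouts
  series
}

#' Per-day wear-time accounting
#'
#' Counts, for each calendar date (of epoch start), the minutes that are
#' worn and not overnight-excluded, plus the non-wear and excluded
#' complements. At 60-s epochs inside the 06:00-23:00 analysis window the
#' maximum attainable wear is 1020 min/day.
#'
#' @param series An [epoch_series()] at 60-s epochs with wear and exclusion
#'   flags already applied.
#' @return A tibble: `date`, `wear_min`, `nonwear_min`, `excluded_min`,
#'   `total_min` (epochs recorded that day).
#' @export
wear_minutes <- function(series) {
  stopifnot(inherits(series, "epoch_series"))
  require_60s(series)
  tibble::tibble(
    date = epoch_dates(series),
    wear = series$wear & !series$excluded,
    nonwear = !series$wear & !series$excluded,
    excluded = series$excluded
  ) |>
    dplyr::summarise(
      wear_min = sum(.data$wear),
      nonwear_min = sum(.data$nonwear),
      excluded_min = sum(.data$excluded),
      total_min = dplyr::n(),
      .by = "date"
    )
}
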