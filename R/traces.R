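#' Trace-rendering configuration
#'
#' Options for [render_traces()].
#'
#' @param days Days to render per wave (7 from a Monday start gives five
#'   weekdays and a full weekend, so the valid-file rule can pass).
#' @param start_date First day (default a Monday).
#' @param interruption_prob Probability that an injected non-wear bout
#'   carries a short (1-2 min) non-zero interruption.
#' @param max_bout Longest single injected non-wear bout (minutes).
#' @param mvpa_cap Upper bound of sampled MVPA counts (CPM); counts within
#'   an intensity are drawn uniformly from the intensity's interval, so
#'   classification depends only on the interval.
#' @param cutpoints See [cutpoints_evenson()].
#' @return A list of class `trace_config`.
#' @export
trace_config <- function(days = 7L, start_date = as.Date("2012-03-05"),
                         interruption_prob = 0.5, max_bout = 240L,
                         mvpa_cap = 10000L,
                         cutpoints = cutpoints_evenson()) {
  structure(as.list(environment()), class = "trace_config")
}

#' Render a 60-s epoch count trace for one participant-wave
#'
#' Emits a day-resolved count series embedding the full measurement
#' protocol: overnight zeros (23:00-06:00), injected non-wear bouts
#' (zeros, optionally with a <= 2-min non-zero interruption), and worn
#' epochs whose counts are sampled from the intensity intervals in the
#' exact proportions of the row's daily targets. Each day satisfies
#' `sed + lpa + mvpa + non-wear = 1020` (the 06:00-23:00 window), with
#' non-wear derived as the remainder; a remainder in (0, 60) cannot form a
#' bout and is an error. Worn epochs adjacent to any zero block are forced
#' non-zero so that non-wear detection recovers exactly the injected
#' bouts, making the render -> flag -> summarize round trip exact.
#'
#' @param row One-row data frame (or list) with daily targets `raw_sed`,
#'   `raw_lpa`, `raw_mvpa` (minutes, rounded to integers) plus
#'   `participant_id` and `wave_index`.
#' @param config A [trace_config()].
#' @return An [epoch_series()] at 60-s epochs spanning `config$days` days,
#'   all epochs initially flagged worn / not excluded.
#' @export
render_traces <- function(row, config = trace_config()) {
  stopifnot(inherits(config, "trace_config"))
  sed <- as.integer(round(row$raw_sed))
  lpa <- as.integer(round(row$raw_lpa))
  mvpa <- as.integer(round(row$raw_mvpa))
  if (anyNA(c(sed, lpa, mvpa)) || any(c(sed, lpa, mvpa) < 0)) {
    abort("row must carry non-negative raw_sed/raw_lpa/raw_mvpa targets",
          class = "actichange_config_error")
  }
  window <- 1020L
  nonwear <- window - (sed + lpa + mvpa)
  if (nonwear < 0L) {
    abort("targets exceed the 1020-min 06:00-23:00 window",
          class = "actichange_infeasible_error")
  }
  if (nonwear > 0L && nonwear < 60L) {
    abort("remainder of the wear window is under 60 min and cannot form a non-wear bout",
          class = "actichange_infeasible_error")
  }
  bouts <- if (nonwear == 0L) integer() else split_bouts(nonwear, config$max_bout)
  days <- lapply(seq_len(config$days), function(d) {
    render_trace_day(sed, lpa, mvpa, bouts, config)
  })
  epoch_series(unlist(days),
               start_time = as.POSIXct(paste(config$start_date, "00:00:00"),
                                       tz = "UTC"),
               epoch_length = 60L,
               participant_id = if (!is.null(row$participant_id)) row$participant_id else "SIM",
               wave_index = if (!is.null(row$wave_index)) row$wave_index else 1L)
}

split_bouts <- function(total, max_bout) {
  k <- ceiling(total / max_bout)
  base <- total %/% k
  lens <- rep(base, k)
  lens[seq_len(total - base * k)] <- base + 1L
  lens
}

# one day: 1440 counts, minute-of-day 0..1439; worn window minutes 360..1379
render_trace_day <- function(sed, lpa, mvpa, bouts, config) {
  counts <- integer(1440L)
  window_idx <- 361:1380  # 1-based positions of the 06:00-23:00 window
  k <- length(bouts)
  n_worn <- 1020L - sum(bouts)
  # place bouts with gaps of at least 3 worn epochs so bouts never merge
  min_gap <- 3L
  slack <- n_worn - min_gap * (k + 1L)
  if (k > 0L && slack < 0L) {
    abort("not enough worn time to separate the non-wear bouts",
          class = "actichange_infeasible_error")
  }
  worn_pos <- window_idx
  bout_pos <- integer(0)
  if (k > 0L) {
    extra <- if (slack > 0L) {
      tabulate(sample.int(k + 1L, slack, replace = TRUE), nbins = k + 1L)
    } else {
      integer(k + 1L)
    }
    gaps <- min_gap + extra
    cursor <- window_idx[1L] - 1L
    starts <- integer(k)
    for (b in seq_len(k)) {
      cursor <- cursor + gaps[b]
      starts[b] <- cursor + 1L
      cursor <- cursor + bouts[b]
    }
    bout_pos <- unlist(Map(seq.int, starts, starts + bouts - 1L))
    worn_pos <- setdiff(window_idx, bout_pos)
    # optional short interruption inside each bout (kept within tolerance)
    for (b in seq_len(k)) {
      if (runif(1) < config$interruption_prob && bouts[b] >= 62L) {
        len <- sample(1:2, 1L)
        at <- sample((starts[b] + 1L):(starts[b] + bouts[b] - 1L - len), 1L)
        counts[at:(at + len - 1L)] <- sample(1:100, len, replace = TRUE)
      }
    }
  }
  stopifnot(length(worn_pos) == sed + lpa + mvpa)
  cp <- config$cutpoints
  labels <- sample(rep(c("sedentary", "light", "mvpa"), c(sed, lpa, mvpa)))
  vals <- integer(length(labels))
  vals[labels == "sedentary"] <- sample(0:cp$sed_max, sum(labels == "sedentary"),
                                        replace = TRUE)
  vals[labels == "light"] <- sample((cp$sed_max + 1L):(cp$mvpa_min - 1L),
                                    sum(labels == "light"), replace = TRUE)
  vals[labels == "mvpa"] <- sample(cp$mvpa_min:config$mvpa_cap,
                                   sum(labels == "mvpa"), replace = TRUE)
  counts[worn_pos] <- vals
  # worn zero-count epochs adjacent to a zero block would be absorbed into a
  # detected bout; force them into the non-zero sedentary band instead
  zero_block <- rep(FALSE, 1442L)
  zero_block[c(1L, 1442L)] <- TRUE  # virtual overnight neighbours
  zero_block[1L + setdiff(seq_len(1440L), window_idx)] <- TRUE
  zero_block[1L + bout_pos] <- TRUE
  guard <- worn_pos[(zero_block[worn_pos] | zero_block[worn_pos + 2L]) &
                      counts[worn_pos] == 0L]
  if (length(guard) > 0L) {
    counts[guard] <- sample(1:cp$sed_max, length(guard), replace = TRUE)
  }
  counts
}

#' Write boundary-case fixture files
#'
#' Writes small deterministic CSV fixtures that exercise every protocol
#' boundary: 59- vs 60-minute zero runs, 2- vs 3-minute interruptions,
#' 599- vs 600-minute days, the intensity cut-point edges, and valid-file
#' edge cases (the last two as day-summary tables).
#'
#' @param out_dir Directory to write into (created if needed).
#' @return Invisibly, the paths written.
#' @export
make_fixture_suite <- function(out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  write_epochs <- function(name, counts, start = "2012-03-05 08:00:00") {
    ts <- as.POSIXct(start, tz = "UTC") + 60 * (seq_along(counts) - 1)
    p <- file.path(out_dir, name)
    readr::write_csv(tibble::tibble(
      timestamp = format(ts, "%Y-%m-%d %H:%M:%S"), counts = counts), p)
    paths[[name]] <<- p
  }
  nz <- rep(500L, 5L)
  write_epochs("bout_60min.csv", c(nz, rep(0L, 60L), nz))
  write_epochs("bout_59min.csv", c(nz, rep(0L, 59L), nz))
  write_epochs("interruption_2min.csv",
               c(nz, rep(0L, 30L), c(50L, 50L), rep(0L, 30L), nz))
  write_epochs("interruption_3min.csv",
               c(nz, rep(0L, 30L), c(50L, 50L, 50L), rep(0L, 30L), nz))
  write_epochs("cutpoint_edges.csv", c(0L, 100L, 101L, 2294L, 2295L))
  write_epochs("day_600min.csv", rep(50L, 600L))
  write_epochs("day_599min.csv", rep(50L, 599L))
  write_days <- function(name, dates, wear) {
    p <- file.path(out_dir, name)
    d <- as.Date(dates)
    readr::write_csv(tibble::tibble(
      participant_id = "FIX", wave_index = 1L, date = d,
      day_type = as.character(day_type_of(d)),
      wear_min = wear, sed_min = wear, lpa_min = 0L, mvpa_min = 0L,
      valid = wear >= 600L), p)
    paths[[name]] <<- p
  }
  # 2012-03-05 is a Monday
  write_days("days_valid_file_ok.csv",
             c("2012-03-05", "2012-03-06", "2012-03-10"), rep(700L, 3L))
  write_days("days_valid_file_bad.csv",
             c("2012-03-05", "2012-03-06", "2012-03-07"), rep(700L, 3L))
  invisible(paths)
}
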