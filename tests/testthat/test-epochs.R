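test_that("plain epoch CSVs parse with inferred epoch length", {
  p <- withr::local_tempfile(fileext = ".csv")
  ts <- as.POSIXct("2012-03-05 09:00:00", tz = "UTC") + 60 * (0:2)
  readr::write_csv(data.frame(timestamp = format(ts, "%Y-%m-%d %H:%M:%S"),
                              counts = c(0, 150, 3000)), p)
  es <- read_epoch_csv(p, participant_id = "A")
  expect_s3_class(es, "epoch_series")
  expect_length(es, 3L)
  expect_equal(es$epoch_length, 60L)
  expect_equal(es$counts, c(0, 150, 3000))
  expect_true(all(es$wear) && !any(es$excluded))

  p15 <- withr::local_tempfile(fileext = ".csv")
  ts15 <- as.POSIXct("2012-03-05 09:00:00", tz = "UTC") + 15 * (0:7)
  readr::write_csv(data.frame(timestamp = format(ts15, "%Y-%m-%d %H:%M:%S"),
                              counts = 1:8), p15)
  es15 <- read_epoch_csv(p15)
  expect_length(es15, 8L)
  expect_equal(es15$epoch_length, 15L)
})

test_that("ActiGraph-style header blocks are understood", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "--------- Data File Created By ActiGraph ---------",
    "Serial Number: XYZ123",
    "Start Time 09:00:00",
    "Start Date 03/05/2012",
    "Epoch Period (hh:mm:ss) 00:01:00",
    "---------------------------------------------------",
    "0", "150", "3000"
  ), p)
  es <- read_epoch_csv(p)
  expect_equal(es$counts, c(0, 150, 3000))
  expect_equal(es$epoch_length, 60L)
  expect_equal(format(es$start_time, "%Y-%m-%d %H:%M"), "2012-03-05 09:00")
})

test_that("malformed epoch CSVs are rejected with specific errors", {
  gap <- withr::local_tempfile(fileext = ".csv")
  ts <- as.POSIXct("2012-03-05 09:00:00", tz = "UTC") + 60 * c(0, 1, 4, 5)
  readr::write_csv(data.frame(timestamp = format(ts, "%Y-%m-%d %H:%M:%S"),
                              counts = c(5, 5, 7, 7)), gap)
  expect_error(read_epoch_csv(gap), class = "actichange_gap_error")
  filled <- read_epoch_csv(gap, gap_action = "zero_fill")
  expect_equal(filled$counts, c(5, 5, 0, 0, 7, 7))

  bad <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(data.frame(timestamp = format(rev(ts), "%Y-%m-%d %H:%M:%S"),
                              counts = 1:4), bad)
  expect_error(read_epoch_csv(bad), class = "actichange_format_error")

  nocounts <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(data.frame(timestamp = format(ts, "%Y-%m-%d %H:%M:%S"),
                              cpm = 1:4), nocounts)
  expect_error(read_epoch_csv(nocounts), class = "actichange_format_error")

  expect_error(epoch_series(1:4, "2012-03-05", epoch_length = 45),
               class = "actichange_epoch_error")
})

test_that("reintegration sums aligned windows and drops the partial tail", {
  es15 <- epoch_series(c(10, 20, 30, 40), "2012-03-05 09:00:00", 15)
  expect_equal(reintegrate(es15)$counts, 100)

  es60 <- series_of(c(3, 1, 4))
  expect_equal(reintegrate(es60, 60)$counts, c(3, 1, 4))

  es30 <- epoch_series(rep(5, 5), "2012-03-05 09:00:00", 30)
  out <- reintegrate(es30)
  expect_equal(out$counts, c(10, 10))

  expect_error(reintegrate(es15, 50), class = "actichange_target_error")
})

test_that("reintegration conserves counts over retained windows and realigns", {
  set.seed(42)
  for (len in c(15, 30)) {
    counts <- sample(0:500, 97, replace = TRUE)
    es <- epoch_series(counts, "2012-03-05 09:00:00", len)
    out <- reintegrate(es)
    per <- 60 / len
    kept <- length(out) * per
    expect_equal(sum(out$counts), sum(counts[seq_len(kept)]))
  }
  # start mid-minute: leading epochs before the next aligned boundary drop
  es <- epoch_series(c(1, 2, 3, 4, 5, 6), "2012-03-05 09:00:30", 15)
  out <- reintegrate(es)
  expect_equal(format(out$start_time, "%H:%M:%S"), "09:01:00")
  expect_equal(out$counts, 3 + 4 + 5 + 6)
})

test_that("overnight exclusion is half-open on [23:00, 06:00)", {
  es <- series_of(c(10, 10, 10), start = "2012-03-05 22:59:00")
  es <- flag_overnight(es)
  expect_equal(es$excluded, c(FALSE, TRUE, TRUE))  # 22:59, 23:00, 23:01

  es2 <- series_of(c(10, 10), start = "2012-03-05 05:59:00")
  expect_equal(flag_overnight(es2)$excluded, c(TRUE, FALSE))  # 05:59, 06:00

  es3 <- series_of(10, start = "2012-03-05 12:00:00")
  expect_false(flag_overnight(es3)$excluded)
})

test_that("non-wear bout boundaries behave as specified", {
  nz <- rep(500, 5)
  b60 <- detect_nonwear(series_of(c(nz, rep(0, 60), nz)))
  expect_equal(nrow(b60), 1L)
  expect_equal(b60$span_min, 60L)
  expect_equal(c(b60$start_index, b60$end_index), c(6L, 66L))

  expect_equal(nrow(detect_nonwear(series_of(c(nz, rep(0, 59), nz)))), 0L)

  b62 <- detect_nonwear(series_of(c(nz, rep(0, 30), 9, 9, rep(0, 30), nz)))
  expect_equal(nrow(b62), 1L)
  expect_equal(b62$span_min, 62L)

  b3 <- detect_nonwear(series_of(c(nz, rep(0, 30), 9, 9, 9, rep(0, 30), nz)))
  expect_equal(nrow(b3), 0L)

  # a bare 60-zero series is one bout spanning everything
  all0 <- detect_nonwear(series_of(rep(0, 60)))
  expect_equal(c(all0$start_index, all0$end_index), c(1L, 61L))

  expect_error(detect_nonwear(series_of(rep(0, 70)), min_bout = 3, tolerance = 2),
               class = "actichange_parameter_error")
})

test_that("per-bout tolerance accounting is available as an alternative", {
  # two 1-min interruptions: allowed per-interruption, also allowed per-bout
  counts <- c(rep(0, 20), 9, rep(0, 20), 9, rep(0, 20))
  expect_equal(nrow(detect_nonwear(series_of(counts))), 1L)
  expect_equal(nrow(detect_nonwear(series_of(counts),
                                   tolerance_scope = "per_bout")), 1L)
  # three 1-min interruptions: fine per-interruption, over budget per-bout
  counts3 <- c(rep(0, 16), 9, rep(0, 16), 9, rep(0, 16), 9, rep(0, 16))
  expect_equal(nrow(detect_nonwear(series_of(counts3))), 1L)
  expect_equal(nrow(detect_nonwear(series_of(counts3),
                                   tolerance_scope = "per_bout")), 0L)
})

test_that("detection matches the brute-force oracle on random series", {
  set.seed(2901)
  for (rep in 1:200) {
    counts <- random_count_series()
    got <- detect_nonwear(series_of(counts))
    want <- oracle_nonwear(counts)
    expect_equal(got$start_index, want$start_index,
                 info = paste("replicate", rep))
    expect_equal(got$end_index, want$end_index,
                 info = paste("replicate", rep))
  }
})

test_that("non-wear flagging is idempotent and bout-monotone in zeros", {
  set.seed(77)
  for (rep in 1:25) {
    counts <- random_count_series(n = 250, p_zero = 0.9)
    es1 <- flag_nonwear(series_of(counts))
    es2 <- flag_nonwear(es1)
    expect_identical(es1$wear, es2$wear)

    bouts <- attr(es1, "nonwear_bouts")
    if (nrow(bouts) == 0L) next
    b <- bouts[1L, ]
    inside <- which(counts[b$start_index:(b$end_index - 1L)] > 0)
    if (length(inside) == 0L) next
    counts2 <- counts
    counts2[b$start_index + inside[1L] - 1L] <- 0
    bouts2 <- detect_nonwear(series_of(counts2))
    covered <- any(bouts2$start_index <= b$start_index &
                     bouts2$end_index >= b$end_index)
    expect_true(covered)
  }
})

test_that("daily wear, non-wear and excluded minutes partition the day", {
  # full recorded day, always worn: 06:00-23:00 window remains
  day <- flag_overnight(series_of(rep(50, 1440), start = "2012-03-05 00:00:00"))
  wm <- wear_minutes(day)
  expect_equal(wm$wear_min, 1020)
  expect_equal(wm$excluded_min, 420)

  # fully non-worn day
  off <- series_of(rep(0, 1440), start = "2012-03-05 00:00:00")
  off <- flag_overnight(flag_nonwear(off))
  expect_equal(wear_minutes(off)$wear_min, 0)

  # one 120-min bout inside the window
  counts <- rep(50, 1440)
  counts[481:600] <- 0  # 08:00-10:00
  mid <- flag_overnight(flag_nonwear(series_of(counts, start = "2012-03-05 00:00:00")))
  wm2 <- wear_minutes(mid)
  expect_equal(wm2$wear_min, 900)
  expect_equal(wm2$nonwear_min, 120)

  # complement identity on arbitrary flagged series
  set.seed(11)
  es <- series_of(random_count_series(n = 3000, p_zero = 0.6),
                  start = "2012-03-04 17:23:00")
  es <- flag_overnight(flag_nonwear(es))
  wm3 <- wear_minutes(es)
  expect_equal(wm3$wear_min + wm3$nonwear_min + wm3$excluded_min, wm3$total_min)
  expect_equal(sum(wm3$total_min), 3000)
})
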