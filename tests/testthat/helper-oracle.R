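# Independent brute-force oracle for non-wear detection.
#
# For every zero epoch that begins a zero run, walk forward epoch by epoch,
# tracking the current run of non-zero interruptions; the furthest zero
# reached before any interruption exceeds the tolerance bounds the widest
# window starting there. Windows contained in another window are discarded
# (non-maximal), then windows shorter than the minimum bout are dropped.
# This enumerates maximal qualifying windows directly from their
# definition, independently of the run-length-merging implementation.
oracle_nonwear <- function(counts, min_bout = 60L, tolerance = 2L) {
  n <- length(counts)
  zero <- counts == 0
  cand <- list()
  for (i in which(zero)) {
    if (i > 1L && zero[i - 1L]) next  # dominated by the run's first zero
    run <- 0L
    last_zero <- i
    j <- i
    while (j <= n) {
      if (zero[j]) {
        run <- 0L
        last_zero <- j
      } else {
        run <- run + 1L
        if (run > tolerance) break
      }
      j <- j + 1L
    }
    cand[[length(cand) + 1L]] <- c(i, last_zero)
  }
  if (length(cand) == 0L) {
    return(data.frame(start_index = integer(), end_index = integer()))
  }
  m <- do.call(rbind, cand)
  maximal <- vapply(seq_len(nrow(m)), function(r) {
    !any(m[, 1L] <= m[r, 1L] & m[, 2L] >= m[r, 2L] &
           (m[, 1L] != m[r, 1L] | m[, 2L] != m[r, 2L]))
  }, logical(1))
  m <- m[maximal, , drop = FALSE]
  m <- m[m[, 2L] - m[, 1L] + 1L >= min_bout, , drop = FALSE]
  data.frame(start_index = m[, 1L], end_index = m[, 2L] + 1L)
}

random_count_series <- function(n = NULL, p_zero = NULL) {
  if (is.null(n)) n <- sample(20:300, 1L)
  if (is.null(p_zero)) p_zero <- runif(1, 0.2, 0.97)
  ifelse(runif(n) < p_zero, 0L, sample.int(3000L, n, replace = TRUE))
}

series_of <- function(counts, start = "2012-03-05 08:00:00", ...) {
  epoch_series(counts, start_time = start, epoch_length = 60, ...)
}
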