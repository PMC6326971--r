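test_that("DAM monitor files parse into readings, channel by channel", {
  tmp <- withr::local_tempfile(fileext = ".txt")

  # all-zero monitor: one reading per line, 32 zero channels
  write_dam_file(matrix(0, nrow = 3, ncol = 32), tmp)
  mon <- read_dam_monitor(tmp)
  expect_equal(nrow(mon), 3L)
  expect_equal(unname(as.matrix(mon[paste0("ch", 1:32)])),
               matrix(0, 3, 32))
  expect_s3_class(mon$datetime, "POSIXct")
  expect_true(!is.unsorted(mon$datetime, strictly = TRUE))

  # counts land on the right channel in the right order
  m <- matrix(0, nrow = 3, ncol = 32)
  m[, 5] <- c(1, 2, 3)
  write_dam_file(m, tmp)
  mon <- read_dam_monitor(tmp)
  expect_equal(mon$ch5, c(1, 2, 3))
  expect_equal(dam_channel_series(mon, 5)$counts, c(1, 2, 3))
})

test_that("malformed monitor lines are reported by line number", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  writeLines(paste(rep("0", 41), collapse = "\t"), tmp)
  expect_error(read_dam_monitor(tmp), "line 1")
  writeLines(c(paste(c("1", "01 Jan 16", "00:00:00", "1", rep("0", 38)),
                     collapse = "\t"),
               paste(c("2", "01 Jan 16", "00:01:00", "1", rep("0", 37),
                       "x"), collapse = "\t")), tmp)
  expect_error(read_dam_monitor(tmp), "line 2.*non-integer")
  expect_error(read_dam_monitor(file.path(tempdir(), "nope.txt")),
               "no such file")
})

test_that("binning sums constituent minutes and drops the remainder", {
  expect_equal(bin_activity(rep(1, 30))$counts, 30)
  # 14 days of 1-min data in 30-min bins
  expect_equal(bin_activity(rep(0:1, 14 * 24 * 30))$N, 672L)
  # trailing partial bin dropped
  b <- bin_activity(rep(1, 61))
  expect_equal(b$counts, c(30, 30))
  expect_error(bin_activity(rep(1, 60), bin_width_min = 7,
                            sampling_interval_min = 2),
               "multiple")
})

test_that("binning conserves counts up to the dropped remainder", {
  set.seed(42)
  for (len in c(120, 119, 250)) {
    x <- rpois(len, 2)
    b <- bin_activity(x, bin_width_min = 30)
    kept <- (len %/% 30) * 30
    expect_identical(sum(b$counts), as.numeric(sum(x[seq_len(kept)])))
  }
})

test_that("simulated counts round-trip through DAM write/read and binning", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  sims <- lapply(1:3, function(i) {
    simulate_fly(days = 1, seed = i)$counts
  })
  write_dam_file(do.call(cbind, sims), tmp)
  mon <- read_dam_monitor(tmp)
  for (i in 1:3) {
    back <- dam_channel_series(mon, i)$counts
    expect_identical(back, sims[[i]])
    expect_identical(bin_activity(back)$counts,
                     bin_activity(sims[[i]])$counts)
  }
})

test_that("long-format tables read back per fly", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(
    fly_id = rep(c("a", "b"), each = 60),
    line = "L1", sex = rep(c("M", "F"), each = 60),
    block = 1L, replicate = 1L,
    datetime = format(as.POSIXct("2016-01-01", tz = "UTC") + 60 * (0:59)),
    counts = rep(c(2, 3), each = 60))
  write.table(tab, tmp, sep = "\t", row.names = FALSE, quote = FALSE)
  flies <- read_activity_long(tmp)
  expect_length(flies, 2L)
  expect_equal(flies[[1]]$counts, rep(2, 60))
  expect_equal(flies[[2]]$meta$sex, "F")
})

test_that("QC drops dead flies, trims the first day, and is idempotent", {
  alive <- bin_activity(simulate_fly(days = 14, seed = 1)$counts,
                        meta = list(fly_id = "alive"))
  died <- simulate_fly(days = 14, seed = 2, death_time_hours = 13 * 24)
  dead <- bin_activity(died$counts, meta = list(fly_id = "dead"))

  qc <- qc_filter(list(alive, dead))
  expect_length(qc$retained, 1L)
  expect_equal(qc$exclusions$fly_id, "dead")
  expect_equal(qc$exclusions$reason, "dead")
  # first 24 h = 48 bins trimmed
  expect_equal(qc$retained[[1]]$N, alive$N - 48L)
  expect_equal(qc$retained[[1]]$counts, alive$counts[-(1:48)])

  # idempotent: filtering the retained set again changes nothing
  qc2 <- qc_filter(qc$retained)
  expect_equal(qc2$retained[[1]]$counts, qc$retained[[1]]$counts)
  expect_equal(nrow(qc2$exclusions), 0L)

  # all flies dead -> empty result, full report
  allq <- qc_filter(list(dead, dead))
  expect_length(allq$retained, 0L)
  expect_equal(nrow(allq$exclusions), 2L)
})
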