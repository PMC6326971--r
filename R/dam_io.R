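#' Read a Trikinetics DAM monitor file
#'
#' Parses the tab-delimited text emitted by the Drosophila Activity
#' Monitoring system: one row per sampling interval, with a reading index,
#' date, time and status code followed by bookkeeping columns and one count
#' column per channel (32 channels, one fly each). Only the layout is
#' assumed: at least 42 tab-separated fields, the last 32 of which are
#' integer beam-crossing counts.
#'
#' @param path Path to a DAM monitor text file.
#' @param n_channels Number of trailing count columns (default 32).
#'
#' @return A data frame with columns `index`, `datetime` (`POSIXct`),
#'   `status`, and `ch1` ... `ch32`.
#' @examples
#' \dontrun{
#' mon <- read_dam_monitor("Monitor1.txt")
#' fly5 <- dam_channel_series(mon, channel = 5)
#' }
#' @export
read_dam_monitor <- function(path, n_channels = 32L) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty monitor file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  min_cols <- 4L + n_channels
  counts <- matrix(NA_real_, nrow = length(lines), ncol = n_channels)
  idx <- integer(length(lines))
  status <- integer(length(lines))
  dt <- character(length(lines))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < min_cols) {
      stop(sprintf(
        "line %d: expected at least %d tab-separated columns, found %d",
        i, min_cols, length(f)))
    }
    cnt <- suppressWarnings(as.numeric(f[(length(f) - n_channels + 1L):length(f)]))
    if (anyNA(cnt) || any(cnt != round(cnt))) {
      stop(sprintf("line %d: non-integer count field", i))
    }
    counts[i, ] <- cnt
    idx[i] <- suppressWarnings(as.integer(f[1L]))
    status[i] <- suppressWarnings(as.integer(f[4L]))
    dt[i] <- paste(f[2L], f[3L])
  }
  datetime <- as.POSIXct(dt, format = "%d %b %y %H:%M:%S", tz = "UTC")
  if (anyNA(datetime)) {
    bad <- which(is.na(datetime))[1L]
    stop(sprintf("line %d: unparseable date-time '%s'", bad, dt[bad]))
  }
  if (is.unsorted(datetime, strictly = TRUE)) {
    stop("timestamps are not strictly increasing within the monitor file")
  }
  out <- data.frame(index = idx, datetime = datetime, status = status)
  cn <- paste0("ch", seq_len(n_channels))
  out[cn] <- as.data.frame(counts)
  out
}

#' Extract one channel's per-minute series from monitor readings
#'
#' @param readings Data frame from [read_dam_monitor()].
#' @param channel Channel number (1-32).
#' @param meta Metadata list merged into the result (see [activity_series()]).
#'
#' @return A list with `counts` (per-minute numeric vector), `start_time`,
#'   and `meta`, suitable for [bin_activity()].
#' @export
dam_channel_series <- function(readings, channel, meta = list()) {
  col <- paste0("ch", channel)
  if (!col %in% names(readings)) stop("no such channel: ", channel)
  meta$channel <- channel
  list(counts = readings[[col]], start_time = readings$datetime[1L],
       meta = meta)
}

#' Write counts to a DAM-style monitor file
#'
#' Emits the 42-column tab-delimited layout read by [read_dam_monitor()]
#' (index, date, time, status, six bookkeeping zeros, 32 channel counts).
#' Used by the simulators to produce round-trippable fixtures.
#'
#' @param counts Numeric matrix, one row per minute, one column per channel
#'   (at most 32; remaining channels are written as zeros).
#' @param path Output path.
#' @param start_time `POSIXct` timestamp of the first reading.
#' @export
write_dam_file <- function(counts, path,
                           start_time = as.POSIXct("2016-01-01 00:00:00",
                                                   tz = "UTC")) {
  counts <- as.matrix(counts)
  if (ncol(counts) > 32L) stop("at most 32 channels")
  full <- matrix(0, nrow = nrow(counts), ncol = 32L)
  full[, seq_len(ncol(counts))] <- counts
  times <- start_time + 60 * (seq_len(nrow(counts)) - 1L)
  lines <- paste(
    seq_len(nrow(counts)),
    format(times, "%d %b %y"),
    format(times, "%H:%M:%S"),
    1L,
    paste(rep("0", 6L), collapse = "\t"),
    apply(full, 1L, paste, collapse = "\t"),
    sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a long-format activity table
#'
#' Alternative to monitor files: a delimited table with a header and columns
#' `fly_id`, `line`, `sex`, `block`, `replicate`, `datetime`, `counts`, one
#' row per fly per sampling interval, rows of each fly in time order.
#'
#' @param path Path to the tab- or comma-delimited table.
#' @param sep Field separator (default tab).
#' @return A list of per-fly lists (`counts`, `start_time`, `meta`) in first
#'   appearance order, suitable for [bin_activity()].
#' @export
read_activity_long <- function(path, sep = "\t") {
  tab <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("fly_id", "line", "sex", "block", "replicate", "datetime",
            "counts")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("long-format table lacks columns: ", paste(missing, collapse = ", "))
  }
  ids <- unique(tab$fly_id)
  lapply(ids, function(id) {
    rows <- tab[tab$fly_id == id, , drop = FALSE]
    list(counts = as.numeric(rows$counts),
         start_time = as.POSIXct(rows$datetime[1L], tz = "UTC"),
         meta = list(fly_id = id, line = rows$line[1L], sex = rows$sex[1L],
                     block = rows$block[1L], replicate = rows$replicate[1L]))
  })
}

#' Write binned series to a long-format table
#'
#' One row per fly per bin; the inverse of the binned-table interchange
#' format used by the pipeline outputs.
#'
#' @param flies List of `"activity_series"` objects.
#' @param path Output path (tab-delimited).
#' @export
write_binned_long <- function(flies, path) {
  tabs <- lapply(flies, as.data.frame)
  utils::write.table(do.call(rbind, tabs), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
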