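#' Construct a binned activity series
#'
#' The basic container for one fly's locomotor record: beam-crossing counts
#' summed into fixed-width bins (30 min by default), together with the
#' identifying metadata (line, sex, block, replicate) used by the
#' quantitative-genetic analyses.
#'
#' @param counts Integer vector of non-negative binned counts.
#' @param bin_width_min Bin width in minutes.
#' @param start_time `POSIXct` time of the first bin's first sample, or `NULL`.
#' @param meta Named list of identifiers. Recognised entries: `fly_id`,
#'   `line`, `sex` (`"M"`/`"F"`), `block`, `replicate`, `monitor`, `channel`.
#'   Missing entries default to `NA`.
#'
#' @return An object of class `"activity_series"`: a list with elements
#'   `counts`, `bin_width_min`, `start_time`, `meta` and `N` (number of bins).
#' @seealso [bin_activity()], [fit_rhythm()]
#' @export
activity_series <- function(counts, bin_width_min = 30, start_time = NULL,
                            meta = list()) {
  counts <- as.numeric(counts)
  if (length(counts) == 0L) stop("'counts' must be non-empty")
  if (anyNA(counts) || any(counts < 0)) {
    stop("'counts' must be non-negative and free of NA")
  }
  if (!is.numeric(bin_width_min) || length(bin_width_min) != 1L ||
      bin_width_min <= 0) {
    stop("'bin_width_min' must be a single positive number")
  }
  defaults <- list(fly_id = NA_character_, line = NA_character_,
                   sex = NA_character_, block = NA_integer_,
                   replicate = NA_integer_, monitor = NA_character_,
                   channel = NA_integer_)
  meta <- utils::modifyList(defaults, as.list(meta))
  structure(
    list(counts = counts, bin_width_min = bin_width_min,
         start_time = start_time, meta = meta, N = length(counts)),
    class = "activity_series"
  )
}

#' @export
print.activity_series <- function(x, ...) {
  m <- x$meta
  cat("Binned activity series",
      if (!is.na(m$fly_id)) paste0("for fly ", m$fly_id) else "", "\n")
  cat(sprintf("  %d bins of %g min (%.1f days); total %g counts\n",
              x$N, x$bin_width_min, x$N * x$bin_width_min / 1440,
              sum(x$counts)))
  if (!is.na(m$line)) {
    cat(sprintf("  line %s, sex %s, block %s, replicate %s\n",
                m$line, m$sex, m$block, m$replicate))
  }
  invisible(x)
}

#' @export
as.data.frame.activity_series <- function(x, ...) {
  data.frame(fly_id = x$meta$fly_id, line = x$meta$line, sex = x$meta$sex,
             block = x$meta$block, replicate = x$meta$replicate,
             bin = seq_len(x$N), count = x$counts,
             stringsAsFactors = FALSE)
}

#' Sum per-minute counts into fixed-width bins
#'
#' Activity counts are summed into bins (30 min by default) before any rhythm
#' statistic is computed; binning damps the spurious high-frequency structure
#' of raw 1-min counts. A trailing partial bin is dropped, so total counts
#' are conserved up to that remainder.
#'
#' @param counts Numeric vector of per-interval counts (typically 1-min).
#' @param bin_width_min Target bin width in minutes; must be a positive
#'   multiple of `sampling_interval_min`.
#' @param sampling_interval_min Sampling interval of `counts`, in minutes.
#' @param start_time,meta Passed through to [activity_series()].
#'
#' @return An `"activity_series"` object of the binned counts.
#' @examples
#' x <- bin_activity(rep(1, 120))   # two 30-min bins of 30, plus two more
#' x$counts
#' @export
bin_activity <- function(counts, bin_width_min = 30,
                         sampling_interval_min = 1, start_time = NULL,
                         meta = list()) {
  per_bin <- bin_width_min / sampling_interval_min
  if (!isTRUE(all.equal(per_bin, round(per_bin))) || per_bin < 1) {
    stop("'bin_width_min' must be a positive multiple of the sampling interval")
  }
  per_bin <- as.integer(round(per_bin))
  counts <- as.numeric(counts)
  n_bins <- length(counts) %/% per_bin
  if (n_bins == 0L) stop("series shorter than one bin")
  kept <- counts[seq_len(n_bins * per_bin)]
  binned <- colSums(matrix(kept, nrow = per_bin))
  activity_series(binned, bin_width_min = bin_width_min,
                  start_time = start_time, meta = meta)
}

#' Quality-control filtering of a set of flies
#'
#' Applies the two standard exclusions before phenotyping: flies that did not
#' survive the recording are dropped, and the first recording day (flies
#' recovering from CO2 anaesthesia) is trimmed from every retained series.
#' A fly is scored dead when its final contiguous run of zero-count bins
#' spans at least `death_window_hours`. Trimming is recorded on the object,
#' so the filter is idempotent.
#'
#' @param flies List of `"activity_series"` objects.
#' @param death_window_hours Length of terminal inactivity, in hours, that
#'   scores a fly as dead (default 24).
#' @param trim_first_hours Hours trimmed from the start of each retained
#'   series (default 24, i.e. the first recording day).
#'
#' @return A list with `retained` (list of trimmed `"activity_series"`) and
#'   `exclusions` (data frame with columns `fly_id`, `reason`).
#' @export
qc_filter <- function(flies, death_window_hours = 24, trim_first_hours = 24) {
  stopifnot(is.list(flies))
  retained <- list()
  excl <- list()
  for (fly in flies) {
    stopifnot(inherits(fly, "activity_series"))
    bins_per_hour <- 60 / fly$bin_width_min
    death_bins <- ceiling(death_window_hours * bins_per_hour)
    run <- terminal_zero_run(fly$counts)
    if (run >= death_bins) {
      excl[[length(excl) + 1L]] <- data.frame(
        fly_id = fly$meta$fly_id, reason = "dead",
        stringsAsFactors = FALSE)
      next
    }
    if (!isTRUE(attr(fly, "qc_trimmed"))) {
      trim_bins <- ceiling(trim_first_hours * bins_per_hour)
      if (trim_bins >= fly$N) {
        excl[[length(excl) + 1L]] <- data.frame(
          fly_id = fly$meta$fly_id, reason = "too_short",
          stringsAsFactors = FALSE)
        next
      }
      fly$counts <- fly$counts[-seq_len(trim_bins)]
      fly$N <- length(fly$counts)
      if (!is.null(fly$start_time)) {
        fly$start_time <- fly$start_time + trim_bins * fly$bin_width_min * 60
      }
      attr(fly, "qc_trimmed") <- TRUE
    }
    retained[[length(retained) + 1L]] <- fly
  }
  exclusions <- if (length(excl)) {
    do.call(rbind, excl)
  } else {
    data.frame(fly_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  }
  list(retained = retained, exclusions = exclusions)
}

# length of the trailing run of zeros
terminal_zero_run <- function(x) {
  nz <- which(x > 0)
  if (length(nz) == 0L) return(length(x))
  length(x) - max(nz)
}
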