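#' Read a TriKinetics-style DAM monitor file
#'
#' Monitor files are tab-delimited with one row per 1-min reading:
#' column 1 the reading index, column 2 the date (`"D Mon YY"`), column 3 the
#' time (`"HH:MM:SS"`), column 4 a status code (1 = valid), columns 5-9
#' reserved, column 10 the light flag, and columns 11-42 the beam-break
#' counts for channels 1-32.
#'
#' Rows with status other than 1 are retained but marked invalid
#' (`valid == FALSE`); [extract_series()] zero-fills their minutes.
#'
#' @param path Path to a monitor file.
#' @return A tibble with columns `reading`, `timestamp` (POSIXct, UTC),
#'   `status`, `valid`, `light`, and `ch01` ... `ch32`.
#' @export
read_dam_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(empty_dam_readings())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  bad <- which(ncols < 42)
  if (length(bad) > 0) {
    abort(sprintf("line %d of '%s': expected >= 42 tab-delimited columns, found %d",
                  bad[1], path, ncols[bad[1]]))
  }
  m <- do.call(rbind, fields)
  ts <- parse_dam_datetime(m[, 2], m[, 3])
  if (anyNA(ts)) {
    abort(sprintf("line %d of '%s': unparseable date/time '%s %s'",
                  which(is.na(ts))[1], path, m[which(is.na(ts))[1], 2],
                  m[which(is.na(ts))[1], 3]))
  }
  if (is.unsorted(ts, strictly = TRUE)) {
    abort(sprintf("'%s': timestamps must be strictly increasing", path))
  }
  counts <- matrix(suppressWarnings(as.integer(m[, 11:42])), ncol = 32)
  if (anyNA(counts) || any(counts < 0)) {
    abort(sprintf("'%s': channel counts must be non-negative integers", path))
  }
  out <- tibble(
    reading = as.integer(m[, 1]),
    timestamp = ts,
    status = as.integer(m[, 4]),
    light = as.integer(m[, 10])
  )
  out$valid <- out$status == 1L
  colnames(counts) <- sprintf("ch%02d", 1:32)
  dplyr::bind_cols(out, as_tibble(counts))[, dam_reading_cols()]
}

dam_reading_cols <- function() {
  c("reading", "timestamp", "status", "valid", "light", sprintf("ch%02d", 1:32))
}

empty_dam_readings <- function() {
  counts <- matrix(integer(0), ncol = 32, dimnames = list(NULL, sprintf("ch%02d", 1:32)))
  dplyr::bind_cols(
    tibble(reading = integer(0),
           timestamp = as.POSIXct(character(0), tz = "UTC"),
           status = integer(0), valid = logical(0), light = integer(0)),
    as_tibble(counts)
  )
}

MONTH_ABB <- c("Jan", "Feb", "Mar", "Apr", "May", "Jun",
               "Jul", "Aug", "Sep", "Oct", "Nov", "Dec")

# locale-independent "D Mon YY" + "HH:MM:SS" parser/formatter
parse_dam_datetime <- function(date_str, time_str) {
  parts <- stringr::str_match(date_str, "^\\s*(\\d{1,2}) ([A-Za-z]{3}) (\\d{2})$")
  mon <- match(parts[, 3], MONTH_ABB)
  iso <- sprintf("20%s-%02d-%02d %s", parts[, 4], mon, as.integer(parts[, 2]), time_str)
  iso[is.na(mon) | is.na(parts[, 2])] <- NA
  as.POSIXct(iso, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
}

format_dam_datetime <- function(ts) {
  lt <- as.POSIXlt(ts, tz = "UTC")
  list(
    date = sprintf("%d %s %02d", lt$mday, MONTH_ABB[lt$mon + 1], lt$year %% 100),
    time = sprintf("%02d:%02d:%02d", lt$hour, lt$min, lt$sec)
  )
}

#' Write readings back out in the DAM monitor dialect
#'
#' Emits exactly the tab-delimited layout accepted by [read_dam_file()], so
#' canonical files round-trip byte-for-byte.
#'
#' @param readings A readings tibble as returned by [read_dam_file()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dam_file <- function(readings, path) {
  if (nrow(readings) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  if (is.unsorted(readings$timestamp, strictly = TRUE)) {
    abort("readings must be sorted by strictly increasing timestamp")
  }
  dt <- format_dam_datetime(readings$timestamp)
  counts <- as.matrix(readings[, sprintf("ch%02d", 1:32)])
  body <- apply(counts, 1, paste, collapse = "\t")
  lines <- paste(readings$reading, dt$date, dt$time, readings$status,
                 0L, 0L, 0L, 0L, 0L, readings$light, body, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Per-fly beam-break series
#'
#' A dense per-minute record of beam-break counts for one fly: bin `i`
#' (1-based) covers the minute starting at `origin + (i - 1)` minutes.
#'
#' @param fly_id Identifier.
#' @param origin POSIXct time of the first bin.
#' @param counts Non-negative integer counts, one per minute, no gaps.
#' @return A `beam_series` object.
#' @export
beam_series <- function(fly_id, origin, counts) {
  counts <- as.integer(counts)
  if (anyNA(counts) || any(counts < 0)) abort("counts must be non-negative integers")
  structure(
    list(fly_id = fly_id, origin = origin, bin_minutes = 1L, counts = counts),
    class = "beam_series"
  )
}

#' @export
print.beam_series <- function(x, ...) {
  cat(sprintf("<beam_series> fly '%s': %d min from %s, total %d beam breaks\n",
              x$fly_id, length(x$counts), format(x$origin, usetz = TRUE),
              sum(x$counts)))
  invisible(x)
}

#' @export
as_tibble.beam_series <- function(x, ...) {
  tibble(
    fly_id = x$fly_id,
    minute = seq_along(x$counts) - 1L,
    timestamp = x$origin + (seq_along(x$counts) - 1L) * 60,
    count = x$counts
  )
}

#' Extract one channel as a dense beam-break series
#'
#' Invalid-status minutes are zero-filled (the downstream sleep and death
#' logic needs a dense 1-min series) and reported via a message.
#'
#' @param readings Readings tibble from [read_dam_file()].
#' @param channel Channel number, 1-32.
#' @param window Optional POSIXct `c(start, end)`; half-open, must lie
#'   within the file span with no missing minutes.
#' @param fly_id Identifier for the resulting series.
#' @return A [beam_series()].
#' @export
extract_series <- function(readings, channel, window = NULL,
                           fly_id = sprintf("ch%02d", channel)) {
  if (!is.numeric(channel) || channel < 1 || channel > 32) {
    abort("channel must be in 1..32")
  }
  if (nrow(readings) == 0) abort("no readings")
  if (is.null(window)) {
    window <- c(readings$timestamp[1], readings$timestamp[nrow(readings)] + 60)
  }
  n_min <- round(as.numeric(difftime(window[2], window[1], units = "mins")))
  if (n_min < 1) abort("empty window")
  want <- window[1] + (seq_len(n_min) - 1L) * 60
  idx <- match(as.numeric(want), as.numeric(readings$timestamp))
  if (anyNA(idx)) {
    abort(sprintf("window has %d minute(s) with no reading (gap); use concatenate_weeks for split records",
                  sum(is.na(idx))))
  }
  counts <- readings[[sprintf("ch%02d", channel)]][idx]
  invalid <- !readings$valid[idx]
  if (any(invalid)) {
    counts[invalid] <- 0L
    rlang::inform(sprintf("extract_series: zero-filled %d invalid-status minute(s)",
                          sum(invalid)))
  }
  beam_series(fly_id, window[1], counts)
}

#' Concatenate weekly series parts into one record
#'
#' Flies are transferred to fresh food tubes each week, splitting the record
#' across monitor files. Parts must be chronological and non-overlapping;
#' gaps up to `max_gap_min` (brief transfer handling) are filled with
#' zero-count minutes.
#'
#' @param parts List of [beam_series()] in chronological order.
#' @param max_gap_min Largest tolerated gap between parts, minutes.
#' @return A single contiguous [beam_series()] with attribute
#'   `transfer_gap_bins`: 1-based indices of the zero-filled gap minutes.
#' @export
concatenate_weeks <- function(parts, max_gap_min = 120) {
  if (length(parts) == 0) abort("no parts to concatenate")
  if (length(parts) == 1) return(parts[[1]])
  origin <- parts[[1]]$origin
  ends <- vapply(parts, function(p) {
    as.numeric(difftime(p$origin, origin, units = "mins")) + length(p$counts)
  }, numeric(1))
  starts <- vapply(parts, function(p) {
    as.numeric(difftime(p$origin, origin, units = "mins"))
  }, numeric(1))
  gaps <- starts[-1] - ends[-length(ends)]
  if (any(gaps < 0)) abort("parts overlap")
  if (any(gaps > max_gap_min)) {
    abort(sprintf("gap of %.0f min exceeds transfer-gap limit (%d min); likely data loss",
                  max(gaps), max_gap_min))
  }
  total <- as.integer(ends[length(ends)])
  counts <- integer(total)
  gap_bins <- integer(0)
  filled <- logical(total)
  for (k in seq_along(parts)) {
    i0 <- as.integer(starts[k])
    counts[i0 + seq_along(parts[[k]]$counts)] <- parts[[k]]$counts
    filled[i0 + seq_along(parts[[k]]$counts)] <- TRUE
  }
  gap_bins <- which(!filled)
  if (length(gap_bins) > 0) {
    rlang::inform(sprintf("concatenate_weeks: %d transfer-gap minute(s) zero-filled",
                          length(gap_bins)))
  }
  out <- beam_series(parts[[1]]$fly_id, origin, counts)
  attr(out, "transfer_gap_bins") <- gap_bins
  out
}

#' Read a fly-metadata table
#'
#' @param path TSV with columns `fly_id`, `sex` (female/male), `treatment`
#'   (control/CCM), `monitor`, `channel` (1-32), `excluded` (logical;
#'   escaped flies, dropped from all analyses).
#' @return A tibble of the included flies plus an `excluded` column.
#' @export
read_fly_meta <- function(path) {
  meta <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            fly_id = "c", sex = "c", treatment = "c",
                            monitor = "c", channel = "i", excluded = "l"
                          ))
  if (any(meta$channel < 1 | meta$channel > 32)) abort("channel must be in 1..32")
  if (anyDuplicated(meta$fly_id)) abort("duplicate fly_id in metadata")
  meta
}
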