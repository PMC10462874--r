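# The microSD-style append-only log: text dialect, flush-on-write emitter,
# lossless parser tolerant of mid-line truncation, CSV export.
#
# Dialect (format_version 1):
#   New Titration                      <- experiment marker, one per run
#   key=value                          <- header lines (settings snapshot)
#   <t_s>\t<pH>\t<aliquots>\t<cum_volume_uL>   <- one record per tick
#   stop_reason=<reason>               <- trailing key, known only at the end
# pH is written at 3 decimals, volumes at 2; times are experiment-relative
# seconds (the device has no real-time clock). Each record line is flushed
# before the next is produced, so a file truncated by a power outage always
# parses up to the last complete record.

LOG_MARKER <- "New Titration"

#' Construct a titration log
#'
#' @param header Named list of experiment metadata (the settings snapshot,
#'   including the quantized aliquot volume needed later by the lipolysis
#'   calculation).
#' @param records A data.frame with columns `t_s`, `pH`, `aliquots`,
#'   `cum_volume_uL`, one row per sampling tick.
#' @param stop_reason One of `"user_abort"`, `"endstop_syringe_empty"`,
#'   `"stability_reached"`, `"max_duration"`, or `NA` for a log whose tail
#'   was lost.
#' @return An object of class `titration_log`.
#' @export
titration_log <- function(header = list(), records = NULL, stop_reason = NA_character_) {
  if (is.null(records)) {
    records <- data.frame(t_s = numeric(), pH = numeric(),
                          aliquots = integer(), cum_volume_uL = numeric())
  }
  need <- c("t_s", "pH", "aliquots", "cum_volume_uL")
  if (!all(need %in% names(records))) {
    stop("'records' must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  records <- records[need]
  if (is.unsorted(records$t_s, strictly = TRUE)) {
    stop("record times must be strictly increasing", call. = FALSE)
  }
  if (any(diff(records$aliquots) < 0) || any(diff(records$cum_volume_uL) < 0)) {
    stop("aliquot count and cumulative volume must be non-decreasing",
         call. = FALSE)
  }
  if (length(header) && is.null(names(header))) {
    stop("'header' must be a named list", call. = FALSE)
  }
  structure(list(header = header, records = records,
                 stop_reason = stop_reason),
            class = "titration_log")
}

fmt_header_value <- function(v) {
  if (is.numeric(v)) sprintf("%.10g", v) else as.character(v)
}

format_record_line <- function(t_s, pH, aliquots, cum_volume_uL) {
  sprintf("%.10g\t%.3f\t%d\t%.2f", t_s, pH, as.integer(aliquots),
          cum_volume_uL)
}

#' Serialize a titration log to the device text dialect
#'
#' Emits the `"New Titration"` marker, the header as `key=value` lines, one
#' tab-separated record line per tick, and the trailing `stop_reason` key.
#' When writing to a file or connection every record line is flushed before
#' the next is produced, so truncation at any point (e.g. a power outage)
#' leaves a parseable prefix.
#'
#' @param log A [titration_log()] or a list of them (appended in order, as
#'   the device appends runs to one file).
#' @param sink Optional file path or writable connection. If omitted the
#'   serialized text is returned as a single string.
#' @param append Append to an existing file (the device behaviour) rather
#'   than truncate. Default `TRUE`.
#' @return Invisibly, the serialized text as one string (also when a sink
#'   was given).
#' @export
write_log <- function(log, sink = NULL, append = TRUE) {
  logs <- if (inherits(log, "titration_log")) list(log) else log
  if (!all(vapply(logs, inherits, logical(1), "titration_log"))) {
    stop("'log' must be a titration_log or a list of them", call. = FALSE)
  }
  lines <- character(0)
  for (lg in logs) {
    lines <- c(lines, LOG_MARKER)
    for (k in names(lg$header)) {
      lines <- c(lines, paste0(k, "=", fmt_header_value(lg$header[[k]])))
    }
    r <- lg$records
    if (nrow(r)) {
      lines <- c(lines, format_record_line(r$t_s, r$pH, r$aliquots,
                                           r$cum_volume_uL))
    }
    if (!is.na(lg$stop_reason)) {
      lines <- c(lines, paste0("stop_reason=", lg$stop_reason))
    }
  }
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(sink)) {
    con <- if (is.character(sink)) {
      file(sink, if (append) "a" else "w")
    } else {
      sink
    }
    if (is.character(sink)) on.exit(close(con))
    for (ln in lines) {       # line-at-a-time with flush: the SD contract
      writeLines(ln, con)
      flush(con)
    }
  }
  invisible(text)
}

header_line_re <- "^[A-Za-z_][A-Za-z0-9_.]*="

parse_header_line <- function(line) {
  eq <- regexpr("=", line, fixed = TRUE)
  key <- substr(line, 1L, eq - 1L)
  val <- substr(line, eq + 1L, nchar(line))
  num <- suppressWarnings(as.numeric(val))
  value <- if (!is.na(num) && grepl("^[-+0-9.eE]+$", val)) num else val
  list(key = key, value = value)
}

parse_record_line <- function(line) {
  parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(parts) != 4L) return(NULL)
  vals <- suppressWarnings(as.numeric(parts))
  if (any(is.na(vals))) return(NULL)
  vals
}

#' Parse a device log file back into titration logs
#'
#' Lossless inverse of [write_log()]: splits the text on the
#' `"New Titration"` marker and rebuilds one [titration_log()] per
#' experiment. Header keys are order-insensitive. A malformed *final* line
#' (the signature of a file truncated mid-write) is discarded with a
#' warning; a malformed interior line is an error reported with its line
#' number. A file without the marker is rejected as not a log.
#'
#' @param x A file path, a single string containing the whole file, or a
#'   character vector of lines.
#' @return A list of [titration_log()] objects (possibly with zero records
#'   each).
#' @export
parse_log <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) &&
               file.exists(x)) {
    suppressWarnings(readLines(x))  # keep an unterminated final fragment
  } else if (length(x) == 1L) {
    strsplit(x, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(x)
  }
  markers <- which(lines == LOG_MARKER)
  if (!length(markers)) {
    stop("not a titration log: no '", LOG_MARKER, "' marker found",
         call. = FALSE)
  }
  if (any(nzchar(trimws(lines[seq_len(markers[1] - 1L)])))) {
    stop("not a titration log: content before the first '", LOG_MARKER,
         "' marker", call. = FALSE)
  }
  n_lines <- length(lines)
  bounds <- c(markers, n_lines + 1L)
  logs <- vector("list", length(markers))
  for (e in seq_along(markers)) {
    idx <- seq(bounds[e] + 1L, length.out = bounds[e + 1L] - bounds[e] - 1L)
    header <- list()
    stop_reason <- NA_character_
    recs <- vector("list", length(idx))
    nr <- 0L
    for (ii in idx) {
      line <- lines[ii]
      if (!nzchar(trimws(line))) next
      if (grepl(header_line_re, line)) {
        kv <- parse_header_line(line)
        if (kv$key == "stop_reason") stop_reason <- as.character(kv$value)
        else header[[kv$key]] <- kv$value
        next
      }
      rec <- parse_record_line(line)
      if (!is.null(rec)) {
        # a record on the file's very last line may be truncation damage:
        # well-formed but inconsistent with its predecessor
        if (ii == n_lines && nr >= 1L) {
          prev <- recs[[nr]]
          if (rec[1] <= prev[1] || rec[3] < prev[3] || rec[4] < prev[4]) {
            warning("discarding trailing partial record: ", dQuote(line),
                    call. = FALSE)
            next
          }
        }
        nr <- nr + 1L
        recs[[nr]] <- rec
        next
      }
      if (ii == n_lines) {
        warning("discarding trailing partial line: ", dQuote(line),
                call. = FALSE)
      } else {
        stop("malformed log line ", ii, ": ", dQuote(line), call. = FALSE)
      }
    }
    if (nr) {
      m <- do.call(rbind, recs[seq_len(nr)])
      records <- data.frame(t_s = m[, 1], pH = m[, 2],
                            aliquots = as.integer(m[, 3]),
                            cum_volume_uL = m[, 4])
    } else {
      records <- NULL
    }
    logs[[e]] <- titration_log(header, records, stop_reason)
  }
  logs
}

#' Export a log's records as CSV
#'
#' RFC-4180 CSV with columns `t_s,pH,aliquots,cum_volume_uL`, one row per
#' record; numeric fields always use `.` as the decimal separator (R fixes
#' `LC_NUMERIC` to the C locale).
#'
#' @param log A [titration_log()].
#' @param sink File path or connection.
#' @return Invisibly, the exported data.frame.
#' @export
export_csv <- function(log, sink) {
  stopifnot(inherits(log, "titration_log"))
  utils::write.csv(log$records, sink, row.names = FALSE, quote = FALSE)
  invisible(log$records)
}

#' @export
as.data.frame.titration_log <- function(x, ...) x$records

#' @export
print.titration_log <- function(x, ...) {
  n <- nrow(x$records)
  cat(sprintf("<titration_log> %d records, %d aliquots, %.2f uL dispensed, stop: %s\n",
              n,
              if (n) x$records$aliquots[n] else 0L,
              if (n) x$records$cum_volume_uL[n] else 0,
              x$stop_reason))
  if (length(x$header)) {
    cat("  header:", paste0(names(x$header), "=",
                            vapply(x$header, fmt_header_value, character(1)),
                            collapse = " "), "\n")
  }
  invisible(x)
}
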