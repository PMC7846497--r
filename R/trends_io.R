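#' @section Input dialect:
#' Google Trends "multiTimeline" exports carry an optional two-line preamble
#' (`Category: All categories` plus a blank line), then a header of the form
#' `Week,<topic>: (<area>),...`, ISO dates, and integer cells where sub-unit
#' interest is printed as `"<1"`.
#'
#' @name trends-io
#' @keywords internal
NULL

#' Construct a single attention series
#'
#' An attention series is one topic's weekly relative search interest in one
#' geographic area, on the dimensionless 0-100 scale used by Google Trends.
#'
#' @param topic free-text topic label.
#' @param dates vector of `Date`s, strictly increasing with constant 7-day
#'   spacing (the Trends week-start convention).
#' @param values numeric relative-interest values in `[0, 100]`, same length
#'   as `dates`.
#' @param area free-text area label (default `""`).
#' @return an object of class `attention_series`.
#' @export
attention_series <- function(topic, dates, values, area = "") {
  dates <- as.Date(dates)
  if (length(dates) != length(values))
    stop("attention_series: 'dates' and 'values' lengths differ (",
         length(dates), " vs ", length(values), ")")
  if (anyNA(dates) || anyNA(values))
    stop("attention_series: missing dates or values for topic '", topic, "'")
  d <- diff(as.integer(dates))
  if (any(d <= 0)) {
    i <- which(d <= 0)[1L]
    stop("attention_series: dates not strictly increasing at row ", i + 1L,
         " (", dates[i + 1L], ")")
  }
  if (any(d != 7L)) {
    i <- which(d != 7L)[1L]
    stop("attention_series: non-weekly spacing between ", dates[i], " and ",
         dates[i + 1L], " (gap of ", d[i], " days)")
  }
  if (any(values < 0 | values > 100))
    stop("attention_series: values outside [0, 100] for topic '", topic, "'")
  structure(list(topic = topic, area = area, dates = dates,
                 values = as.numeric(values)),
            class = "attention_series")
}

#' @export
print.attention_series <- function(x, ...) {
  cat("<attention_series> topic:", x$topic,
      if (nzchar(x$area)) paste0("(", x$area, ")") else "",
      "-", length(x$values), "weeks,",
      format(min(x$dates)), "to", format(max(x$dates)), "\n")
  invisible(x)
}

#' Read a Google-Trends-style multi-topic CSV
#'
#' Parses the "multiTimeline" dialect: an optional preamble, a header naming
#' one date column and one column per topic (`"<topic>: (<area>)"`), ISO
#' week-start dates, and integer or `"<1"` cells. `"<1"` is mapped to 0.5,
#' the midpoint of the censored interval, so that downstream log-odds are
#' finite.
#'
#' @param path path to the CSV file.
#' @param skip number of preamble lines to skip, or `"auto"` (default) to
#'   locate the header line automatically.
#' @param sub_unit value substituted for `"<1"` cells (default 0.5).
#' @return a named list of [attention_series], one per topic column.
#' @export
read_trends_csv <- function(path, skip = "auto", sub_unit = 0.5) {
  if (!file.exists(path)) stop("read_trends_csv: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (identical(skip, "auto")) {
    hdr <- grep("^\"?(Week|Day|Month)\"?,", lines)[1L]
    if (is.na(hdr)) stop("read_trends_csv: no header line starting with a ",
                         "date column (Week/Day/Month) found in ", path)
  } else {
    hdr <- skip + 1L
  }
  tab <- utils::read.csv(text = paste(lines[hdr:length(lines)], collapse = "\n"),
                         check.names = FALSE, colClasses = "character",
                         strip.white = TRUE)
  if (ncol(tab) < 2L)
    stop("read_trends_csv: header must name a date column and >= 1 topic ",
         "columns")
  if (nrow(tab) < 9L)
    stop("read_trends_csv: only ", nrow(tab), " data rows; at least 9 weekly ",
         "observations are needed to fit any periodic model")
  dates <- as.Date(tab[[1L]])
  if (anyNA(dates)) {
    i <- which(is.na(dates))[1L]
    stop("read_trends_csv: unparseable date '", tab[[1L]][i], "' at data row ",
         i)
  }
  if (anyDuplicated(dates)) {
    i <- which(duplicated(dates))[1L]
    stop("read_trends_csv: duplicate date ", format(dates[i]), " at data row ",
         i)
  }
  d <- diff(as.integer(dates))
  if (any(d != 7L)) {
    i <- which(d != 7L)[1L]
    stop("read_trends_csv: expected weekly spacing; gap between ",
         format(dates[i]), " and ", format(dates[i + 1L]), " at data row ",
         i + 1L)
  }
  parse_cell <- function(x, col) {
    x <- trimws(x)
    out <- suppressWarnings(as.numeric(x))
    lt1 <- x == "<1"
    out[lt1] <- sub_unit
    bad <- is.na(out) & !lt1
    if (any(bad)) {
      i <- which(bad)[1L]
      stop("read_trends_csv: non-numeric cell '", x[i], "' in column '", col,
           "' at data row ", i)
    }
    out
  }
  series <- lapply(seq.int(2L, ncol(tab)), function(j) {
    nm <- names(tab)[j]
    m <- regmatches(nm, regexec("^(.*?):\\s*\\((.*)\\)\\s*$", nm))[[1L]]
    topic <- if (length(m) == 3L) m[2L] else nm
    area <- if (length(m) == 3L) m[3L] else ""
    attention_series(topic, dates, parse_cell(tab[[j]], nm), area = area)
  })
  names(series) <- vapply(series, `[[`, "", "topic")
  series
}

#' Floor zero and sub-unit values of an attention panel
#'
#' The logit share model needs strictly positive observations (`ln 0` is the
#' alternative). Exact zeros in the input are floored before share
#' conversion; `"<1"` cells were already mapped at read time.
#'
#' @param series named list of [attention_series].
#' @param floor positive floor value (default 0.5).
#' @return the panel with every value `< floor` replaced by `floor`.
#' @export
floor_values <- function(series, floor = 0.5) {
  stopifnot(floor > 0)
  lapply(series, function(s) {
    s$values <- pmax(s$values, floor)
    s
  })
}

## shared time axis of a panel, with alignment checks
panel_dates <- function(series) {
  if (length(series) == 0L) stop("empty attention panel")
  dates <- series[[1L]]$dates
  for (s in series[-1L]) {
    if (length(s$dates) != length(dates) || any(s$dates != dates))
      stop("attention series '", s$topic, "' is not aligned with '",
           series[[1L]]$topic, "': differing time axes")
  }
  dates
}

panel_values <- function(series) {
  dates <- panel_dates(series)
  v <- vapply(series, `[[`, numeric(length(dates)), "values")
  colnames(v) <- vapply(series, `[[`, "", "topic")
  v
}

## full-precision numeric formatting so CSV round trips are lossless
fmt_num <- function(x) sprintf("%.17g", x)

#' Write an interaction report to CSV
#'
#' Flat table with one row per (time point, unordered topic pair): the role
#' label, the predator topic (predator-prey rows only), the two interaction
#' coefficient values and the system-wide interaction intensity. Numbers are
#' written at full double precision so [read_report()] round-trips losslessly.
#'
#' @param report an `interaction_report` (see [classify_system()]).
#' @param path output CSV path.
#' @export
write_report <- function(report, path) {
  if (!inherits(report, "interaction_report"))
    stop("write_report: not an interaction_report")
  if (nrow(report) == 0L) stop("write_report: report is empty")
  out <- data.frame(
    time = fmt_num(report$time),
    topic_a = report$topic_a,
    topic_b = report$topic_b,
    role = report$role,
    predator = ifelse(is.na(report$predator), "", report$predator),
    g_a = fmt_num(report$g_a),
    g_b = fmt_num(report$g_b),
    intensity = fmt_num(report$intensity),
    stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("write_report: cannot write '", path, "': ", conditionMessage(ok))
  invisible(path)
}

#' Read an interaction report written by [write_report()]
#'
#' @param path CSV path.
#' @return an `interaction_report`.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("read_report: no such file: ", path)
  tab <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("time", "topic_a", "topic_b", "role", "predator", "g_a", "g_b",
            "intensity")
  if (!all(need %in% names(tab)))
    stop("read_report: missing columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  new_interaction_report(data.frame(
    time = as.numeric(tab$time),
    topic_a = tab$topic_a,
    topic_b = tab$topic_b,
    role = tab$role,
    predator = ifelse(tab$predator == "", NA_character_, tab$predator),
    g_a = as.numeric(tab$g_a),
    g_b = as.numeric(tab$g_b),
    intensity = as.numeric(tab$intensity),
    stringsAsFactors = FALSE))
}
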