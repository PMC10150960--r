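# Internal time helpers. All diary timestamps are timezone-naive local times
# stored as POSIXct in UTC; offsets are decimal hours.

DIARY_TZ <- "UTC"
DIARY_TIME_FORMAT <- "%Y-%m-%dT%H:%M:%S"

parse_diary_time <- function(x) {
  if (inherits(x, "POSIXct")) {
    return(as.POSIXct(as.numeric(x), origin = "1970-01-01", tz = DIARY_TZ))
  }
  out <- as.POSIXct(x, format = DIARY_TIME_FORMAT, tz = DIARY_TZ)
  bad <- !is.na(x) & x != "" & is.na(out)
  if (any(bad)) {
    stop("unparseable timestamp(s): ", paste(utils::head(x[bad], 3L), collapse = ", "),
         call. = FALSE)
  }
  out
}

format_diary_time <- function(x) format(x, DIARY_TIME_FORMAT, tz = DIARY_TZ)

#' Decimal hours between two time points
#' @noRd
hours_between <- function(from, to) as.numeric(difftime(to, from, units = "hours"))

#' Time of day as decimal hours in [0, 24)
#' @noRd
time_of_day_hours <- function(ts) {
  lt <- as.POSIXlt(ts, tz = DIARY_TZ)
  lt$hour + lt$min / 60 + lt$sec / 3600
}

#' Calendar date (Date, UTC) of a diary timestamp
#' @noRd
diary_date <- function(ts) as.Date(ts, tz = DIARY_TZ)

#' TRUE on Monday--Friday
#' @noRd
is_business_day <- function(ts) {
  wd <- as.POSIXlt(ts, tz = DIARY_TZ)$wday # 0 = Sunday
  wd >= 1 & wd <= 5
}

#' Truncate timestamps to whole minutes (the diary time resolution)
#' @noRd
trunc_minute <- function(ts) {
  as.POSIXct(floor(as.numeric(ts) / 60) * 60, origin = "1970-01-01", tz = DIARY_TZ)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
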