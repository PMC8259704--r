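# Internal helpers shared across modules.

# Dimension names of a working-hour series, in the fixed order used
# everywhere: shift length (h), rest after the shift (h), start hour of day.
ws_dims <- function() c("shift_length", "rest_after", "start_hour")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Parse timestamps at minute (or second) precision. Naive local clock time:
# everything is interpreted in a fixed zone (UTC) so durations are literal
# clock differences with no DST arithmetic.
parse_timestamp <- function(x) {
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  fmts <- c(
    "%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
    "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"
  )
  todo <- !is.na(x) & nzchar(x)
  for (f in fmts) {
    if (!any(todo)) break
    p <- as.POSIXct(x[todo], format = f, tz = "UTC")
    ok <- !is.na(p)
    out[which(todo)[ok]] <- p[ok]
    todo[todo] <- !ok
  }
  out
}

format_timestamp <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

hours_between <- function(from, to) {
  as.numeric(difftime(to, from, units = "hours"))
}

# Calendar date of a timestamp under the naive-clock convention.
ts_date <- function(x) as.Date(x, tz = "UTC")

# Clock hour of day in [0, 24) with minute/second fraction.
clock_hour <- function(x) {
  lt <- as.POSIXlt(x, tz = "UTC")
  lt$hour + lt$min / 60 + lt$sec / 3600
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
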