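#' Merge back-to-back shift entries
#'
#' A payroll system may record one continuous work period as several rows.
#' Any shift starting at most one minute after the previous shift's end (per
#' employee, in start order) is absorbed into that shift, iterated to a
#' fixpoint. Shifts overlapping by more than one minute are unified into a
#' single covering interval ("truncate and merge") and counted, so no
#' recorded work time is invented or lost.
#'
#' @param records Shift records (possibly several employees), as returned
#'   by [read_shift_log()].
#' @return Merged records sorted by `(employee_id, start)`, with attributes
#'   `n_merged` (rows absorbed) and `n_overlaps` (rows that overlapped the
#'   running interval by more than one minute).
#' @export
merge_adjacent_shifts <- function(records) {
  records <- records[order(records$employee_id, records$start,
                           records$end), , drop = FALSE]
  pieces <- split(seq_len(nrow(records)), records$employee_id)
  out <- vector("list", length(pieces))
  n_merged <- 0L
  n_overlaps <- 0L
  for (i in seq_along(pieces)) {
    idx <- pieces[[i]]
    s <- as.numeric(records$start[idx])
    e <- as.numeric(records$end[idx])
    run_end <- cummax(e)
    prev_end <- c(-Inf, run_end[-length(run_end)])
    new_run <- s > prev_end + 60
    n_overlaps <- n_overlaps + sum(s < prev_end - 60)
    grp <- cumsum(new_run)
    n_merged <- n_merged + length(idx) - max(grp)
    out[[i]] <- data.frame(
      employee_id = names(pieces)[i],
      start = as.POSIXct(as.vector(tapply(s, grp, min)),
                         origin = "1970-01-01", tz = "UTC"),
      end = as.POSIXct(as.vector(tapply(e, grp, max)),
                       origin = "1970-01-01", tz = "UTC"),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_merged") <- n_merged
  attr(res, "n_overlaps") <- n_overlaps
  res
}

#' Drop unreliably short shift entries
#'
#' Removes every shift strictly shorter than `min_hours` (default 3 h);
#' such entries are administrative artefacts, not work shifts. Apply after
#' [merge_adjacent_shifts()] so that split recordings of a real shift are
#' reunited before the length test.
#'
#' @param records Merged shift records.
#' @param min_hours Minimum shift duration kept, in hours.
#' @return Filtered records with attribute `n_short_dropped`.
#' @export
drop_short_entries <- function(records, min_hours = 3) {
  dur <- hours_between(records$start, records$end)
  keep <- dur >= min_hours
  res <- records[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_short_dropped") <- sum(!keep)
  res
}

#' Longest uninterrupted stretch of one employee's shifts
#'
#' Splits an employee's shift sequence wherever consecutive shift start
#' dates differ by more than `max_gap_days` calendar days (pauses of up to
#' `max_gap_days` days are tolerated) and returns the piece spanning the
#' most calendar days (first such piece on ties).
#'
#' @param records One employee's merged, filtered shift records, sorted by
#'   start.
#' @param max_gap_days Largest tolerated difference (days) between
#'   consecutive shift start dates.
#' @return The longest piece, with attributes `span_days` (calendar days
#'   from first to last shift start, inclusive) and `n_pieces`.
#' @export
longest_valid_stretch <- function(records, max_gap_days = 4) {
  if (nrow(records) == 0) {
    attr(records, "span_days") <- 0L
    attr(records, "n_pieces") <- 0L
    return(records)
  }
  d <- ts_date(records$start)
  gap <- as.integer(diff(d))
  piece <- cumsum(c(0L, gap > max_gap_days))
  spans <- tapply(as.integer(d), piece, function(x) max(x) - min(x) + 1L)
  best <- as.integer(names(spans)[which.max(spans)])
  res <- records[piece == best, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "span_days") <- as.integer(max(spans))
  attr(res, "n_pieces") <- length(spans)
  res
}

#' Test whether a stretch represents full-time work
#'
#' Full-time work requires at least `min_annual_hours` realized work hours
#' (default 150 x 7.75 = 1162.5) in every 52-week (364-day) window fully
#' inside the stretch, the window advanced one day at a time. Hours are
#' attributed to the shift's start date.
#'
#' @param records One employee's longest valid stretch.
#' @param min_annual_hours Required hours per 52-week window.
#' @param window_days Window width in days (default 364 = 52 weeks).
#' @return `TRUE` or `FALSE`; on `FALSE` the attribute `reason` says
#'   whether the stretch was too short or which window failed first.
#' @export
full_time_mask <- function(records, min_annual_hours = 150 * 7.75,
                           window_days = 364L) {
  d <- as.integer(ts_date(records$start))
  if (nrow(records) == 0 || max(d) - min(d) + 1L < window_days) {
    out <- FALSE
    attr(out, "reason") <- sprintf("stretch spans fewer than %d days",
                                   window_days)
    return(out)
  }
  rel <- d - min(d) + 1L
  span <- max(rel)
  daily <- numeric(span)
  hours <- hours_between(records$start, records$end)
  agg <- tapply(hours, rel, sum)
  daily[as.integer(names(agg))] <- agg
  cs <- c(0, cumsum(daily))
  win <- cs[(window_days + 1):(span + 1)] - cs[1:(span - window_days + 1)]
  if (all(win >= min_annual_hours)) return(TRUE)
  out <- FALSE
  attr(out, "reason") <- sprintf(
    "window starting on day %d holds %.2f h < %.1f h",
    which(win < min_annual_hours)[1], min(win), min_annual_hours)
  out
}

#' Build a working-hour time series for one employee
#'
#' Converts cleaned shift records into the three aligned per-shift series
#' that are clustered: shift length (h), rest after the shift (h), and
#' start hour of day. With `T` shifts the series have length `T - 1`: the
#' final shift has no following shift, hence no rest period, and is
#' dropped from the series (its timestamps are retained).
#'
#' @param records One employee's cleaned shift records (>= 2 shifts),
#'   sorted by start.
#' @return An object of class `work_series`: a list with `employee_id`,
#'   `start` and `end` (`POSIXct` of all `T` shifts), and the length
#'   `T - 1` vectors `shift_length`, `rest_after`, `start_hour`, and
#'   `shift_dates` (`Date` of each series shift's start).
#' @export
build_work_series <- function(records) {
  n <- nrow(records)
  if (n < 2) {
    stopf("employee %s has %d shift(s); need at least 2 to form a series",
          records$employee_id[1] %||% "<none>", n)
  }
  id <- records$employee_id[1]
  dur <- hours_between(records$start, records$end)
  rest <- hours_between(records$end[-n], records$start[-1])
  if (any(rest <= 0)) {
    stopf("employee %s: non-positive rest after shift %d (overlap?)",
          id, which(rest <= 0)[1])
  }
  structure(
    list(employee_id = id,
         start = records$start, end = records$end,
         shift_length = dur[-n],
         rest_after = rest,
         start_hour = clock_hour(records$start)[-n],
         shift_dates = ts_date(records$start)[-n]),
    class = "work_series"
  )
}

#' @export
print.work_series <- function(x, ...) {
  cat(sprintf("<work_series> %s: %d shifts, %s to %s\n", x$employee_id,
              length(x$start), format(min(x$shift_dates)),
              format(max(x$shift_dates))))
  invisible(x)
}

ws_slice <- function(ws, series_idx, shift_idx) {
  structure(
    list(employee_id = ws$employee_id,
         start = ws$start[shift_idx], end = ws$end[shift_idx],
         shift_length = ws$shift_length[series_idx],
         rest_after = ws$rest_after[series_idx],
         start_hour = ws$start_hour[series_idx],
         shift_dates = ws$shift_dates[series_idx]),
    class = "work_series"
  )
}

#' Split a working-hour series into a past and a future half
#'
#' The first `ceiling(T/2)` series elements form the "past" (exposure
#' period), the remainder the "future" (outcome period). The split date is
#' the start date of the first future shift.
#'
#' @param ws A `work_series` with at least 2 series elements.
#' @return A list with `work_series` elements `past` and `future`, the
#'   `split_index` (last past element) and the `split_date`.
#' @export
split_half <- function(ws) {
  n <- length(ws$shift_length)
  if (n < 2) stopf("series of length %d cannot be split", n)
  p <- ceiling(n / 2)
  list(
    past = ws_slice(ws, 1:p, 1:p),
    future = ws_slice(ws, (p + 1):n, (p + 1):(n + 1)),
    split_index = p,
    split_date = ts_date(ws$start[p + 1])
  )
}

#' Clean a shift log and build the cohort of working-hour series
#'
#' Runs the full inclusion pipeline per employee: merge back-to-back
#' entries, drop sub-3-hour artefacts, restrict to the longest stretch
#' without pauses above `max_gap_days` days, require the stretch to span at
#' least `min_span_days` days, optionally require full-time work in every
#' 52-week window, and build the working-hour series.
#'
#' @param records Shift records for any number of employees.
#' @param min_span_days Minimum calendar span of the kept stretch (default
#'   3 x 365 = 1095 days; set 0 to keep everyone).
#' @param max_gap_days Largest tolerated pause, see
#'   [longest_valid_stretch()].
#' @param min_shift_hours Shortest credible shift, see
#'   [drop_short_entries()].
#' @param require_full_time If `TRUE`, apply [full_time_mask()].
#' @param min_annual_hours Threshold for [full_time_mask()].
#' @return A list with `series` (named list of `work_series` for included
#'   employees) and `provenance` (counts of records and employees dropped
#'   at each rule, plus per-employee exclusion reasons).
#' @export
prepare_cohort <- function(records, min_span_days = 1095,
                           max_gap_days = 4, min_shift_hours = 3,
                           require_full_time = TRUE,
                           min_annual_hours = 150 * 7.75) {
  n_input <- nrow(records)
  merged <- merge_adjacent_shifts(records)
  cleaned <- drop_short_entries(merged, min_hours = min_shift_hours)
  series <- list()
  reasons <- character(0)
  per_emp <- split(cleaned, cleaned$employee_id)
  for (id in names(per_emp)) {
    stretch <- longest_valid_stretch(per_emp[[id]],
                                     max_gap_days = max_gap_days)
    if (attr(stretch, "span_days") < min_span_days) {
      reasons[id] <- sprintf("span %d < %d days",
                             attr(stretch, "span_days"), min_span_days)
      next
    }
    if (require_full_time) {
      ft <- full_time_mask(stretch, min_annual_hours = min_annual_hours)
      if (!ft) {
        reasons[id] <- paste("not full-time:", attr(ft, "reason"))
        next
      }
    }
    if (nrow(stretch) < 2) {
      reasons[id] <- "fewer than 2 shifts"
      next
    }
    series[[id]] <- build_work_series(stretch)
  }
  list(
    series = series,
    provenance = list(
      n_input_records = n_input,
      n_merged = attr(merged, "n_merged"),
      n_overlaps = attr(merged, "n_overlaps"),
      n_short_dropped = attr(cleaned, "n_short_dropped"),
      n_employees_in = length(per_emp),
      n_employees_kept = length(series),
      exclusions = reasons
    )
  )
}
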