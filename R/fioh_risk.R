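#' Configuration of the shift-ergonomics risk scores
#'
#' Parameters of the three work-burden scores (each on a 0--3 scale):
#' long work spells, night-shift load over three-week windows, and quick
#' returns. The score breakpoints are reconstructed defaults -- three
#' ascending thresholds per score, a spell/window statistic scoring one
#' point per threshold reached -- and should be overridden where an
#' authoritative parameterization is available. The night window and the
#' 11-hour quick-return threshold follow common Finnish practice.
#'
#' @param quick_return_h Rest strictly below this many hours is a quick
#'   return (default 11).
#' @param night_window Clock interval `(from, to)` in hours; a shift
#'   overlapping it on any day is a night shift (default 23:00--06:00).
#' @param long_spell_breaks Ascending spell total-hour thresholds mapped
#'   to scores 1, 2, 3.
#' @param night_breaks Ascending night-shift counts per 21-day window
#'   mapped to scores 1, 2, 3.
#' @param quick_return_breaks Ascending quick-return counts per spell
#'   mapped to scores 1, 2, 3.
#' @param night_window_days Width of the rolling night-count window.
#' @return A list of class `fioh_config`.
#' @export
fioh_config <- function(quick_return_h = 11,
                        night_window = c(23, 6),
                        long_spell_breaks = c(40, 48, 54),
                        night_breaks = c(2, 4, 6),
                        quick_return_breaks = c(1, 2, 3),
                        night_window_days = 21L) {
  for (b in list(long_spell_breaks, night_breaks, quick_return_breaks)) {
    if (length(b) != 3 || is.unsorted(b, strictly = TRUE)) {
      stopf("score breakpoints must be 3 strictly ascending values")
    }
  }
  structure(list(quick_return_h = quick_return_h,
                 night_window = night_window,
                 long_spell_breaks = long_spell_breaks,
                 night_breaks = night_breaks,
                 quick_return_breaks = quick_return_breaks,
                 night_window_days = as.integer(night_window_days)),
            class = "fioh_config")
}

#' Work spells of one employee
#'
#' A work spell is a maximal run of shifts with no intervening day off (a
#' calendar date with no work; shifts crossing midnight count work on both
#' dates). Returns per-spell totals used by the long-spell and
#' quick-return scores.
#'
#' @param ws A `work_series` (all shift timestamps are used).
#' @param config A [fioh_config()].
#' @return A data frame with one row per spell: `spell`, `n_shifts`,
#'   `total_hours`, `quick_returns` (rests within the spell strictly below
#'   the quick-return threshold), and attribute `spell_id` (per shift).
#' @export
work_spells <- function(ws, config = fioh_config()) {
  n <- length(ws$start)
  start_date <- ts_date(ws$start)
  end_date <- ts_date(ws$end - 1)
  # A new spell begins when at least one full free day separates shift
  # i from shift i+1.
  new_spell <- c(TRUE,
                 as.integer(start_date[-1] - end_date[-n]) >= 2L)
  spell_id <- cumsum(new_spell)
  dur <- hours_between(ws$start, ws$end)
  rest <- hours_between(ws$end[-n], ws$start[-1])
  same_spell_rest <- spell_id[-1] == spell_id[-n]
  qr <- rest < config$quick_return_h & same_spell_rest
  spells <- data.frame(
    spell = seq_len(max(spell_id)),
    n_shifts = as.integer(tabulate(spell_id)),
    total_hours = as.numeric(tapply(dur, spell_id, sum)),
    quick_returns = vapply(seq_len(max(spell_id)), function(s) {
      sum(qr[spell_id[-n] == s])
    }, numeric(1))
  )
  attr(spells, "spell_id") <- spell_id
  spells
}

score_by_breaks <- function(v, breaks) findInterval(v, breaks)

#' Long-work-spell burden score
#'
#' Each spell's total work hours map through the configured breakpoints to
#' 0--3; the employee's score is the mean over spells.
#'
#' @param spells Output of [work_spells()].
#' @param config A [fioh_config()].
#' @return Value in `[0, 3]`.
#' @export
long_spell_score <- function(spells, config = fioh_config()) {
  if (nrow(spells) == 0) stopf("no spells")
  mean(score_by_breaks(spells$total_hours, config$long_spell_breaks))
}

#' Quick-return burden score
#'
#' Each spell's count of quick returns (rests strictly below the
#' threshold, default 11 h) maps through the breakpoints to 0--3; the
#' employee's score is the mean over spells.
#'
#' @inheritParams long_spell_score
#' @return Value in `[0, 3]`.
#' @export
quick_return_score <- function(spells, config = fioh_config()) {
  if (nrow(spells) == 0) stopf("no spells")
  mean(score_by_breaks(spells$quick_returns, config$quick_return_breaks))
}

# Does a shift starting at clock hour s (in [0, 24)) of duration L hours
# overlap the nightly window (from, to) crossing midnight (from > to)?
# End instants are exclusive: a shift ending exactly at `from` o'clock is
# not a night shift. Shifts of >= 24 h necessarily cover a night.
overlaps_night <- function(s, L, from = 23, to = 6) {
  if (from <= to) stopf("night window must cross midnight (from > to)")
  (s < to) | (s + L > from) | (L >= 24)
}

#' Night-shift burden score
#'
#' A shift is a night shift if it overlaps the configured nightly window
#' (default 23:00--06:00). Night shifts are counted in rolling 21-day
#' windows advanced one day at a time over the series span (a single
#' window if the span is shorter); each count maps through the breakpoints
#' to 0--3 and the employee's score is the mean over windows.
#'
#' @param ws A `work_series`.
#' @param config A [fioh_config()].
#' @return Value in `[0, 3]`.
#' @export
night_shift_score <- function(ws, config = fioh_config()) {
  s <- clock_hour(ws$start)
  L <- hours_between(ws$start, ws$end)
  night <- overlaps_night(s, L, config$night_window[1],
                          config$night_window[2])
  d <- as.integer(ts_date(ws$start))
  rel <- d - min(d) + 1L
  span <- max(rel)
  daily <- numeric(span)
  agg <- tapply(as.numeric(night), rel, sum)
  daily[as.integer(names(agg))] <- agg
  w <- min(config$night_window_days, span)
  cs <- c(0, cumsum(daily))
  counts <- cs[(w + 1):(span + 1)] - cs[1:(span - w + 1)]
  mean(score_by_breaks(counts, config$night_breaks))
}

#' All three shift-ergonomics risk scores of one employee
#'
#' @param ws A `work_series`.
#' @param config A [fioh_config()].
#' @return A one-row data frame: `employee_id`, `long_spell_score`,
#'   `night_shift_score`, `quick_return_score`.
#' @export
fioh_risk_scores <- function(ws, config = fioh_config()) {
  spells <- work_spells(ws, config)
  data.frame(
    employee_id = ws$employee_id,
    long_spell_score = long_spell_score(spells, config),
    night_shift_score = night_shift_score(ws, config),
    quick_return_score = quick_return_score(spells, config),
    stringsAsFactors = FALSE
  )
}

#' Risk scores for a whole cohort
#'
#' @param series Named list of `work_series`.
#' @param config A [fioh_config()].
#' @return Data frame with one row per employee.
#' @export
cohort_risk_scores <- function(series, config = fioh_config()) {
  res <- do.call(rbind, lapply(series, fioh_risk_scores, config = config))
  rownames(res) <- NULL
  res
}
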