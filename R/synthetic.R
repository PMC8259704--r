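#' Working-hour archetypes of the synthetic roster generator
#'
#' Eight stylized hospital shift-work patterns, spanning regular
#' weekday work, irregular three-shift (morning/evening/night) work with
#' and without contract interruptions, and quickly versus slowly rotating
#' morning/evening rosters distinguished mainly by how often a shift is
#' followed by less than 13 hours of rest. Each archetype carries a
#' sickness-absence rate (days/year) used by [simulate_sa()].
#'
#' @return Character vector of the eight archetype names.
#' @export
archetype_names <- function() {
  c("regular_me", "irregular_m", "irregular_men", "regular_m",
    "irregular_men_interrupted", "variable_m", "quick_rotating_me",
    "slow_rotating_me")
}

#' Parameters of one synthetic archetype
#'
#' @param name One of [archetype_names()].
#' @return List with the archetype's descriptive label, SA rate
#'   (days/year) and generator parameters.
#' @export
archetype_spec <- function(name) {
  sa_rates <- c(regular_me = 8.58, irregular_m = 11.35,
                irregular_men = 11.76, regular_m = 5.81,
                irregular_men_interrupted = 13.03, variable_m = 11.62,
                quick_rotating_me = 9.67, slow_rotating_me = 5.59)
  labels <- c(regular_me = "Regular M/E work, weekends off",
              irregular_m = "Irregular M work",
              irregular_men = "Irregular M/E/N work",
              regular_m = "Regular M work, weekends off",
              irregular_men_interrupted =
                "Irregular, interrupted M/E/N work",
              variable_m = "Variable M work, weekends off",
              quick_rotating_me =
                "Quickly rotating M/E work, non-standard weeks",
              slow_rotating_me =
                "Slowly rotating M/E work, non-standard weeks")
  if (!name %in% archetype_names()) stopf("unknown archetype %s", name)
  list(name = name, label = unname(labels[name]),
       sa_rate = unname(sa_rates[name]))
}

# Minute-scale deviation from a nominal clock time. Payroll times are
# mostly exact nominal values (ties in the series are the norm, and the
# stable tie rule makes them informative), so with probability `p_exact`
# the deviation is zero.
jit <- function(n, minutes, p_exact = 0.85) {
  stats::runif(n, -minutes, minutes) / 60 *
    (stats::runif(n) >= p_exact)
}

# Generators return data.frame(day, start_hour, length_h) with `day` a
# 0-based offset from the roster start date (a Monday). Weekday w of day d
# is d %% 7 (0 = Monday).

# Regular two-shift rotation: mornings and evenings alternate daily
# (Mon-Fri, weekends off), the phase flipping weekly so the alternation
# continues across weekends. Evenings end 21:30 and the next morning
# starts 9:00, an 11.5 h turnaround: regular, below 13 h but above the
# 11 h quick-return line.
g_regular_me <- function(days) {
  nweeks <- days %/% 7
  day <- unlist(lapply(seq_len(nweeks) - 1L, function(w) w * 7L + 0:4))
  type <- rep_len(c("M", "E"), length(day))
  n <- length(day)
  data.frame(day = day,
             start_hour = ifelse(type == "M", 9, 13.5) + jit(n, 10),
             length_h = 8 + jit(n, 10))
}

# Irregular workday pattern as alternating work runs and off runs. Off
# runs stay at 3 days or fewer so consecutive shift start dates never
# differ by more than 4 days: irregular rosters are still uninterrupted
# employment under the inclusion rules.
irregular_workdays <- function(days, work_run = 2:6, off_run = 1:3) {
  day <- integer(0)
  d <- 0L
  while (d < days) {
    w <- sample(work_run, 1)
    day <- c(day, d + seq_len(min(w, days - d)) - 1L)
    d <- d + w + sample(off_run, 1)
  }
  day
}

g_irregular_m <- function(days) {
  day <- irregular_workdays(days, work_run = 2:6, off_run = 1:3)
  n <- length(day)
  data.frame(day = day,
             start_hour = 7.7 + stats::runif(n, -1.2, 1.2),
             length_h = 8 + jit(n, 15, p_exact = 0.5))
}

g_irregular_men <- function(days, short_runs = FALSE) {
  day <- if (short_runs) {
    # interrupted pattern: shorter work runs, more frequent maximal pauses
    irregular_workdays(days, work_run = 2:4, off_run = 2:3)
  } else {
    irregular_workdays(days, work_run = 2:7, off_run = 1:3)
  }
  n <- length(day)
  # shift-type sequence with no morning directly after a night shift
  # (the night ends mid-morning, so a same-morning start cannot occur)
  type <- character(n)
  type[1] <- sample(c("M", "E", "N"), 1, prob = c(0.45, 0.30, 0.25))
  for (i in seq_len(n - 1L)) {
    type[i + 1L] <- if (type[i] == "N" && day[i + 1L] - day[i] == 1L) {
      sample(c("E", "N"), 1, prob = c(0.5, 0.5))
    } else {
      sample(c("M", "E", "N"), 1, prob = c(0.45, 0.30, 0.25))
    }
  }
  start <- ifelse(type == "M", 7 + stats::runif(n, -0.5, 1),
           ifelse(type == "E", 14 + stats::runif(n, -0.5, 1),
                  21.5 + stats::runif(n, -0.5, 0.5)))
  len <- ifelse(type == "N", stats::runif(n, 8, 12.75),
                stats::runif(n, 7.75, 10))
  data.frame(day = day, start_hour = start, length_h = len)
}

g_regular_m <- function(days) {
  nweeks <- days %/% 7
  day <- unlist(lapply(seq_len(nweeks) - 1L, function(w) w * 7L + 0:4))
  n <- length(day)
  data.frame(day = day, start_hour = 7.5 + jit(n, 5),
             length_h = 8 + jit(n, 5))
}

g_variable_m <- function(days) {
  nweeks <- days %/% 7
  day <- unlist(lapply(seq_len(nweeks) - 1L, function(w) w * 7L + 0:4))
  n <- length(day)
  data.frame(day = day, start_hour = stats::runif(n, 6, 10),
             length_h = stats::runif(n, 6, 10))
}

# Quickly rotating M/E, 4-day weeks. Evening shifts end 21:30, mornings
# start 9:00, so an evening-to-morning turnaround rests 11.5 h: "quickish"
# (< 13 h) but not a < 11 h quick return. Week patterns M,E,M,E and
# E,M,E,M contain 1 and 2 such turnarounds among 4 weekly rests; mixing
# them 0.704/0.296 targets a 32.4% overall quickish fraction.
g_quick_rotating <- function(days, p_emem = 0.296) {
  nweeks <- days %/% 7
  rows <- lapply(seq_len(nweeks) - 1L, function(w) {
    pat <- if (stats::runif(1) < p_emem) c("E", "M", "E", "M")
           else c("M", "E", "M", "E")
    data.frame(day = w * 7L + 0:3, type = pat)
  })
  df <- do.call(rbind, rows)
  n <- nrow(df)
  data.frame(day = df$day,
             start_hour = ifelse(df$type == "M", 9, 13.5) + jit(n, 6),
             length_h = 8 + jit(n, 6))
}

# Slowly rotating M/E, 5-day weeks starting Monday or Tuesday. Week
# patterns M,M,E,M,E and M,M,M,E,E contain 1 and 0 quickish turnarounds
# among 5 weekly rests; mixing them 0.724/0.276 targets a 14.48% quickish
# fraction.
g_slow_rotating <- function(days, p_mmeme = 0.724) {
  nweeks <- days %/% 7
  rows <- lapply(seq_len(nweeks) - 1L, function(w) {
    off <- sample(0:1, 1)
    pat <- if (stats::runif(1) < p_mmeme) c("M", "M", "E", "M", "E")
           else c("M", "M", "M", "E", "E")
    data.frame(day = w * 7L + off + 0:4, type = pat)
  })
  df <- do.call(rbind, rows)
  n <- nrow(df)
  data.frame(day = df$day,
             start_hour = ifelse(df$type == "M", 9, 13.5) + jit(n, 6),
             length_h = 8 + jit(n, 6))
}

#' Generate one employee's synthetic roster
#'
#' Draws a shift sequence over `days` calendar days from the archetype's
#' template. Start hours and lengths carry minute-scale jitter; proposed
#' shifts beginning less than two hours after the previous shift's end are
#' skipped so rest periods stay positive.
#'
#' @param archetype One of [archetype_names()].
#' @param days Roster span in days.
#' @param employee_id Id attached to the records.
#' @param start_date First day of the roster (a Monday keeps weekday
#'   templates aligned; default 2015-01-05).
#' @param seed Optional seed (the cohort generator seeds once for all
#'   employees instead).
#' @return Shift records (`employee_id`, `start`, `end`) sorted by start,
#'   with attribute `archetype`.
#' @export
generate_archetype_roster <- function(archetype, days,
                                      employee_id = archetype,
                                      start_date = as.Date("2015-01-05"),
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  plan <- switch(archetype,
    regular_me = g_regular_me(days),
    irregular_m = g_irregular_m(days),
    irregular_men = g_irregular_men(days),
    regular_m = g_regular_m(days),
    irregular_men_interrupted = g_irregular_men(days, short_runs = TRUE),
    variable_m = g_variable_m(days),
    quick_rotating_me = g_quick_rotating(days),
    slow_rotating_me = g_slow_rotating(days),
    stopf("unknown archetype %s", archetype)
  )
  if (nrow(plan) == 0) stopf("archetype %s produced no shifts", archetype)
  origin <- as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC")
  start <- origin + (plan$day * 24 + plan$start_hour) * 3600
  end <- start + plan$length_h * 3600
  # sequential guard: drop shifts that would start < 2 h after the
  # previous end (possible in the irregular archetypes)
  keep <- logical(nrow(plan))
  prev_end <- -Inf
  s <- as.numeric(start); e <- as.numeric(end)
  for (i in order(s)) {
    if (s[i] >= prev_end + 2 * 3600) {
      keep[i] <- TRUE
      prev_end <- e[i]
    }
  }
  res <- data.frame(employee_id = employee_id,
                    start = start[keep], end = end[keep],
                    stringsAsFactors = FALSE)
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "archetype") <- archetype
  res
}

#' Simulate sickness-absence days
#'
#' Per employee, the number of SA days is Poisson with mean
#' `rate * followup_days / 365` (capped at the follow-up length) and the
#' days are placed uniformly without replacement inside the follow-up
#' window.
#'
#' @param employees Data frame with columns `employee_id`, `first_date`
#'   (`Date`), `followup_days`, `rate` (days/year).
#' @param seed Optional seed.
#' @return SA records (`employee_id`, `date`), sorted.
#' @export
simulate_sa <- function(employees, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(employees$rate < 0)) stopf("SA rate must be nonnegative")
  rows <- lapply(seq_len(nrow(employees)), function(i) {
    T <- employees$followup_days[i]
    n <- min(stats::rpois(1, employees$rate[i] * T / 365), T)
    if (n == 0) return(NULL)
    data.frame(employee_id = employees$employee_id[i],
               date = employees$first_date[i] +
                 sort(sample.int(T, n) - 1L),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    return(data.frame(employee_id = character(0),
                      date = as.Date(character(0))))
  }
  res <- res[order(res$employee_id, res$date), , drop = FALSE]
  rownames(res) <- NULL
  res
}

inject_noise <- function(shifts, dup_rate, junk_rate, split_rate) {
  n <- nrow(shifts)
  injected <- list(duplicates = 0L, junk = 0L, splits = 0L)
  # back-to-back splits: replace a shift by two rows meeting at an
  # interior point (the merge rule must reunite them)
  n_split <- round(split_rate * n)
  if (n_split > 0) {
    idx <- sample.int(n, n_split)
    f <- stats::runif(n_split, 0.3, 0.7)
    mid <- shifts$start[idx] +
      f * as.numeric(shifts$end[idx] - shifts$start[idx],
                     units = "secs")
    first <- shifts[idx, , drop = FALSE]; first$end <- mid
    second <- shifts[idx, , drop = FALSE]; second$start <- mid
    shifts <- rbind(shifts[-idx, , drop = FALSE], first, second)
    injected$splits <- n_split
  }
  # junk (< 3 h) entries at noon of work-free days between shifts
  n_junk <- round(junk_rate * n)
  if (n_junk > 0) {
    junk <- list()
    for (id in unique(shifts$employee_id)) {
      d <- sort(unique(ts_date(shifts$start[shifts$employee_id == id])))
      gaps <- which(diff(d) >= 3)
      if (!length(gaps)) next
      free <- d[gaps] + 2 # strictly inside the gap
      take <- utils::head(free, max(1, n_junk %/%
                                      length(unique(shifts$employee_id))))
      js <- as.POSIXct(paste(take, "12:00:00"), tz = "UTC") +
        stats::runif(length(take), 0, 3600)
      junk[[id]] <- data.frame(employee_id = id, start = js,
                               end = js + stats::runif(length(take),
                                                       0.5, 2.8) * 3600,
                               stringsAsFactors = FALSE)
    }
    junk <- do.call(rbind, junk)
    if (!is.null(junk)) {
      shifts <- rbind(shifts, junk)
      injected$junk <- nrow(junk)
    }
  }
  n_dup <- round(dup_rate * nrow(shifts))
  if (n_dup > 0) {
    shifts <- rbind(shifts, shifts[sample.int(nrow(shifts), n_dup), ,
                                   drop = FALSE])
    injected$duplicates <- n_dup
  }
  attr(shifts, "injected") <- injected
  shifts
}

#' Generate a synthetic cohort
#'
#' Produces shift records for `n` employees per archetype over a common
#' span, optionally corrupted with cleanable noise (duplicate rows,
#' sub-3-hour junk entries on free days, and shifts split into
#' back-to-back pieces), plus demographics, Poisson sickness-absence days
#' at archetype-specific rates, and the ground-truth archetype labels.
#' All randomness flows from one seeded generator, so a fixed seed
#' reproduces the cohort exactly.
#'
#' @param archetypes Named integer vector: employees per archetype (names
#'   from [archetype_names()]).
#' @param days Roster span per employee in days.
#' @param seed Integer seed fixing the whole output stream.
#' @param noise List with `dup_rate`, `junk_rate`, `split_rate` (fractions
#'   of shift rows; all 0 disables noise).
#' @param start_date First roster day.
#' @param sa Simulate SA records (`TRUE` by default).
#' @return List with `shifts`, `sa`, `labels` (named archetype vector),
#'   `demographics` (`employee_id`, `woman`, `age`), `injected` noise
#'   counts and the call parameters.
#' @export
generate_cohort <- function(archetypes, days = 560, seed = 1,
                            noise = list(dup_rate = 0, junk_rate = 0,
                                         split_rate = 0),
                            start_date = as.Date("2015-01-05"),
                            sa = TRUE) {
  stopifnot(all(names(archetypes) %in% archetype_names()))
  set.seed(seed)
  archetypes <- archetypes[archetypes > 0]
  shifts <- list()
  labels <- character(0)
  for (a in names(archetypes)) {
    for (i in seq_len(archetypes[[a]])) {
      id <- sprintf("%s_%03d", a, i)
      shifts[[id]] <- generate_archetype_roster(a, days, employee_id = id,
                                                start_date = start_date)
      labels[id] <- a
    }
  }
  shifts <- do.call(rbind, shifts)
  rownames(shifts) <- NULL
  shifts <- inject_noise(shifts,
                         dup_rate = noise$dup_rate %||% 0,
                         junk_rate = noise$junk_rate %||% 0,
                         split_rate = noise$split_rate %||% 0)
  injected <- attr(shifts, "injected")
  attr(shifts, "injected") <- NULL
  ids <- names(labels)
  demographics <- data.frame(
    employee_id = ids,
    woman = as.integer(stats::runif(length(ids)) < 0.916),
    age = pmin(pmax(round(stats::rnorm(length(ids), 39.4, 10)), 18), 70),
    stringsAsFactors = FALSE
  )
  sa_rec <- NULL
  if (sa) {
    emp <- do.call(rbind, lapply(ids, function(id) {
      rows <- shifts$employee_id == id
      data.frame(employee_id = id,
                 first_date = min(ts_date(shifts$start[rows])),
                 followup_days = as.integer(
                   max(ts_date(shifts$end[rows])) -
                     min(ts_date(shifts$start[rows]))) + 1L,
                 rate = archetype_spec(labels[id])$sa_rate,
                 stringsAsFactors = FALSE)
    }))
    sa_rec <- simulate_sa(emp)
  }
  shifts <- shifts[order(shifts$employee_id, shifts$start), , drop = FALSE]
  rownames(shifts) <- NULL
  list(shifts = shifts, sa = sa_rec, labels = labels,
       demographics = demographics, injected = injected,
       params = list(archetypes = archetypes, days = days, seed = seed,
                     noise = noise, start_date = start_date))
}
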