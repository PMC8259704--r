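# Shared fixtures and independent oracles for the test suite.

# Build a shift-record data frame from timestamp strings.
shift_df <- function(id, start, end) {
  data.frame(employee_id = id,
             start = as.POSIXct(start, tz = "UTC"),
             end = as.POSIXct(end, tz = "UTC"),
             stringsAsFactors = FALSE)
}

# Regular Mon-Fri roster: `weeks` weeks of `len_h`-hour shifts starting at
# `start_hour` o'clock, beginning on a Monday.
weekday_roster <- function(id, weeks, start_hour = 8, len_h = 8,
                           start_date = as.Date("2015-01-05")) {
  day <- unlist(lapply(seq_len(weeks) - 1L, function(w) w * 7L + 0:4))
  origin <- as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC")
  start <- origin + (day * 24 + start_hour) * 3600
  data.frame(employee_id = id, start = start,
             end = start + len_h * 3600, stringsAsFactors = FALSE)
}

# Independent codebook oracle: selection-sort ranks (earliest index wins
# ties), explicit window loop, environment-based counting. Shares no code
# with build_codebook.
naive_codebook_counts <- function(x, m, t) {
  counts <- new.env(parent = emptyenv())
  n_win <- length(x) - (m - 1) * t
  for (j in seq_len(n_win)) {
    w <- x[j + (0:(m - 1)) * t]
    remaining <- seq_len(m)
    perm <- integer(m)
    for (k in seq_len(m)) {
      i <- remaining[which(w[remaining] == min(w[remaining]))[1]]
      perm[k] <- i - 1L
      remaining <- remaining[remaining != i]
    }
    key <- paste(perm, collapse = ",")
    counts[[key]] <- (if (is.null(counts[[key]])) 0 else counts[[key]]) + 1
  }
  out <- unlist(as.list(counts))
  out[order(names(out))]
}

# Independent Poisson IRLS fitter (log link, offset), Newton scoring from
# zero start.
irls_poisson <- function(X, y, offset, tol = 1e-12, maxit = 200) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta) + offset
    mu <- exp(eta)
    z <- eta - offset + (y - mu) / mu
    fit <- solve(crossprod(X, X * mu), crossprod(X, mu * z))
    if (max(abs(fit - beta)) < tol) {
      beta <- drop(fit)
      break
    }
    beta <- drop(fit)
  }
  beta
}

# Point-mass codebook on a single codeword key.
point_codebook <- function(key, m, total = 10) {
  new_codebook(stats::setNames(total, key), total = total, m = m, t = 1L)
}

# Standard three-archetype recovery cohort used by the clustering and
# assignment checks.
recovery_cohort <- function(seed, n_per = 20, days = 560) {
  generate_cohort(c(regular_me = n_per, regular_m = n_per,
                    irregular_men_interrupted = n_per),
                  days = days, seed = seed,
                  noise = list(dup_rate = 0, junk_rate = 0.02,
                               split_rate = 0.02), sa = FALSE)
}

prep_series <- function(coh) {
  prepare_cohort(coh$shifts, min_span_days = 0, require_full_time = FALSE)
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
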