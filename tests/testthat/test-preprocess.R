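test_that("back-to-back shifts merge to a fixpoint and overlaps are unified", {
  rec <- shift_df("a", c("2015-01-05 07:00", "2015-01-05 15:00"),
                  c("2015-01-05 15:00", "2015-01-05 21:00"))
  m <- merge_adjacent_shifts(rec)
  expect_equal(nrow(m), 1)
  expect_equal(as.numeric(difftime(m$end, m$start, units = "hours")), 14)

  # a 60-minute gap exceeds the 1-minute rule: kept separate
  rec2 <- shift_df("a", c("2015-01-05 07:00", "2015-01-05 16:00"),
                   c("2015-01-05 15:00", "2015-01-05 21:00"))
  expect_equal(nrow(merge_adjacent_shifts(rec2)), 2)

  # three chained pieces collapse to the brute-force interval union
  rec3 <- shift_df("a",
                   c("2015-01-05 07:00", "2015-01-05 11:00",
                     "2015-01-05 15:00"),
                   c("2015-01-05 11:00", "2015-01-05 15:00",
                     "2015-01-05 21:00"))
  m3 <- merge_adjacent_shifts(rec3)
  expect_equal(nrow(m3), 1)
  expect_equal(m3$start, min(rec3$start))
  expect_equal(m3$end, max(rec3$end))
  expect_equal(attr(m3, "n_merged"), 2L)

  # >1-minute overlap is unified and counted
  rec4 <- shift_df("a", c("2015-01-05 07:00", "2015-01-05 14:00"),
                   c("2015-01-05 15:00", "2015-01-05 21:00"))
  m4 <- merge_adjacent_shifts(rec4)
  expect_equal(nrow(m4), 1)
  expect_equal(attr(m4, "n_overlaps"), 1L)
  expect_equal(as.numeric(difftime(m4$end, m4$start, units = "hours")), 14)
})

test_that("sub-3-hour entries are dropped with a strict boundary", {
  rec <- shift_df("a",
                  c("2015-01-05 08:00", "2015-01-06 08:00",
                    "2015-01-07 08:00"),
                  c("2015-01-05 10:54", "2015-01-06 11:00",
                    "2015-01-07 16:00"))
  kept <- drop_short_entries(rec) # 2.9 h, 3.0 h, 8 h
  expect_equal(nrow(kept), 2)
  expect_equal(attr(kept, "n_short_dropped"), 1)
  expect_equal(kept$start[1], rec$start[2]) # exactly 3 h is kept

  allshort <- shift_df("a", "2015-01-05 08:00", "2015-01-05 09:00")
  expect_equal(nrow(drop_short_entries(allshort)), 0)
})

test_that("stretch selection splits at >4-day start-date gaps", {
  # gap of exactly 4 days: no split
  rec <- shift_df("a", c("2015-01-05 08:00", "2015-01-09 08:00"),
                  c("2015-01-05 16:00", "2015-01-09 16:00"))
  s <- longest_valid_stretch(rec)
  expect_equal(nrow(s), 2)
  expect_equal(attr(s, "n_pieces"), 1L)

  # gap of 5 days: split
  rec2 <- shift_df("a", c("2015-01-05 08:00", "2015-01-10 08:00"),
                   c("2015-01-05 16:00", "2015-01-10 16:00"))
  s2 <- longest_valid_stretch(rec2)
  expect_equal(attr(s2, "n_pieces"), 2L)
  expect_equal(nrow(s2), 1)

  # 4 years with a 10-day interruption after year 2: longest piece wins,
  # brute-force enumeration of the pieces as the oracle
  r1 <- weekday_roster("a", 100, start_date = as.Date("2015-01-05"))
  r2 <- weekday_roster("a", 112,
                       start_date = as.Date("2015-01-05") + 100 * 7 + 10)
  both <- rbind(r1, r2)
  gaps <- as.integer(diff(as.Date(both$start)))
  pieces <- split(seq_len(nrow(both)), cumsum(c(0L, gaps > 4)))
  spans <- vapply(pieces, function(i) {
    as.integer(diff(range(as.Date(both$start)[i]))) + 1L
  }, integer(1))
  s3 <- longest_valid_stretch(both)
  expect_equal(nrow(s3), max(lengths(pieces)))
  expect_equal(attr(s3, "span_days"), max(spans))
  expect_equal(s3$start[1], r2$start[1])
  # the winning 112-week piece spans under 3 years: employee excluded
  expect_lt(attr(s3, "span_days"), 1095)
})

test_that("full-time rule checks every sliding 52-week window", {
  # 5 x 7.75 h per week = 2015 h per any 364-day window
  rec <- weekday_roster("a", 120, len_h = 7.75)
  expect_true(full_time_mask(rec))

  # an empty 52-week window inside an otherwise dense record fails
  r1 <- weekday_roster("a", 60)
  r2 <- weekday_roster("a", 60, start_date = as.Date("2015-01-05") +
                         60 * 7 + 370)
  ft <- full_time_mask(rbind(r1, r2))
  expect_false(ft)
  expect_match(attr(ft, "reason"), "window")

  # stretches shorter than 364 days fail with a reason
  short <- weekday_roster("a", 14)
  ft2 <- full_time_mask(short)
  expect_false(ft2)
  expect_match(attr(ft2, "reason"), "fewer")
})

test_that("work-series construction yields aligned length/rest/start triples", {
  rec <- shift_df("a", c("2015-01-05 07:30", "2015-01-06 07:30"),
                  c("2015-01-05 15:30", "2015-01-06 15:30"))
  ws <- build_work_series(rec)
  expect_equal(length(ws$shift_length), 1) # final shift dropped
  expect_equal(ws$shift_length, 8)
  expect_equal(ws$rest_after, 16)
  expect_equal(ws$start_hour, 7.5)

  rec2 <- shift_df("a", c("2015-01-05 21:15", "2015-01-06 21:15"),
                   c("2015-01-06 07:15", "2015-01-07 07:15"))
  expect_equal(build_work_series(rec2)$start_hour, 21.25)

  expect_error(build_work_series(rec[1, ]), "at least 2")
})

test_that("the past/future split uses the ceiling rule and partitions exactly", {
  rec <- weekday_roster("a", 3)[1:11, ] # series length 10
  ws <- build_work_series(rec)
  h <- split_half(ws)
  expect_equal(length(h$past$shift_length), 5)
  expect_equal(length(h$future$shift_length), 5)

  rec2 <- weekday_roster("a", 3)[1:12, ] # series length 11
  ws2 <- build_work_series(rec2)
  h2 <- split_half(ws2)
  expect_equal(length(h2$past$shift_length), 6)
  expect_equal(length(h2$future$shift_length), 5)
  expect_equal(h2$split_date, as.Date(ws2$start[7]))
  # concatenation reproduces the original series
  for (d in c("shift_length", "rest_after", "start_hour")) {
    expect_equal(c(h2$past[[d]], h2$future[[d]]), ws2[[d]])
  }
})

test_that("cleaning is idempotent and conserves record counts", {
  set.seed(31)
  coh <- generate_cohort(c(irregular_men = 3, regular_me = 2), days = 200,
                         seed = 31, sa = FALSE,
                         noise = list(dup_rate = 0, junk_rate = 0.03,
                                      split_rate = 0.03))
  once <- drop_short_entries(merge_adjacent_shifts(coh$shifts))
  twice <- drop_short_entries(merge_adjacent_shifts(once))
  expect_equal(nrow(once), nrow(twice))
  expect_equal(once$start, twice$start)
  expect_equal(once$end, twice$end)

  # counts conserve: kept + merged + dropped = input rows
  merged <- merge_adjacent_shifts(coh$shifts)
  cleaned <- drop_short_entries(merged)
  expect_equal(nrow(cleaned) + attr(merged, "n_merged") +
                 attr(cleaned, "n_short_dropped"), nrow(coh$shifts))

  # every emitted series satisfies the type invariants
  prep <- prep_series(coh)
  for (ws in prep$series) {
    n <- length(ws$shift_length)
    expect_equal(length(ws$rest_after), n)
    expect_equal(length(ws$start_hour), n)
    expect_equal(length(ws$shift_dates), n)
    expect_true(all(ws$shift_length > 0))
    expect_true(all(ws$rest_after > 0))
    expect_true(all(ws$start_hour >= 0 & ws$start_hour < 24))
  }
})
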