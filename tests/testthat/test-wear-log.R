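test_that("log CSV parsing preserves components and missingness", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("date,wake,on,off,bed",
               "2012-03-01,6:30 AM,7:00 AM,9:30 PM,10:30 PM",
               "2012-03-02,6:30 AM,7:00,9:30 PM,10:30 PM",
               ",6:30 AM,7:00 AM,9:30 PM,10:30 PM",
               "2012-03-04,,,,"), f)
  lg <- read_log(f, "S1")
  expect_equal(n_log_days <- nrow(lg$days), 4)
  d <- lg$days
  expect_equal(d$on_hour[1], 7L)
  expect_equal(d$on_mer[1], "AM")
  expect_true(is.na(d$on_mer[2]))     # "7:00" keeps time, loses meridiem
  expect_equal(d$on_hour[2], 7L)
  expect_true(is.na(d$date[3]))
  expect_true(all(is.na(d[4, c("on_hour", "off_hour", "wake_hour", "bed_hour")])))

  cc <- log_completeness(lg)
  expect_equal(cc$missing_date, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(cc$missing_time, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(cc$missing_meridiem, c(FALSE, TRUE, FALSE, FALSE))

  # round trip through write_log
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_log(lg, f2)
  lg2 <- read_log(f2, "S1")
  expect_identical(lg2$days, lg$days)

  writeLines(c("date,wake,on,off,bed",
               "2012-03-01,6:30 AM,25:99 AM,9:30 PM,10:30 PM"), f)
  expect_error(read_log(f), "row 1, field 'on'")
  writeLines(c("date,wake,on,off,bed",
               "2012-03-01,6:30 AM,7 oclock,9:30 PM,10:30 PM"), f)
  expect_error(read_log(f), "unparseable time token")
})

test_that("missingness tabulation counts per day index", {
  complete_day <- log_day(date = "2012-03-01", wake = c(6, 30, "AM"),
                          on = c(7, 0, "AM"), off = c(9, 30, "PM"),
                          bed = c(10, 30, "PM"))
  logs <- c(
    replicate(80, monitor_log("a", complete_day), simplify = FALSE),
    replicate(20, {
      d <- complete_day
      d$on_mer <- NA_character_
      monitor_log("b", d)
    }, simplify = FALSE)
  )
  tab <- tabulate_missingness(logs)
  expect_equal(tab$n_logs, 100)
  expect_equal(tab$meridiem, 20)
  expect_equal(tab$meridiem_pct, 20)
  expect_equal(tab$date, 0)
  expect_equal(tab$time, 0)

  tab0 <- tabulate_missingness(logs[1:80])
  expect_true(all(tab0[, c("date", "time", "meridiem")] == 0))
})

test_that("meridiem imputation applies default windows, ordering and audit", {
  # rule 2 forced by wake: on "7:30" with wake 6:30 AM -> AM
  lg <- make_log(log_day("2012-03-01", wake = c(6, 30, "AM"), on = c(7, 30, NA),
                         off = c(9, 30, "PM"), bed = c(10, 30, "PM")))
  out <- impute_meridiem(lg)
  expect_equal(out$log$days$on_mer, "AM")
  expect_equal(nrow(out$audit), 1)

  # off "9:00" with bed 10:30 PM -> PM (default window also agrees)
  lg <- make_log(log_day("2012-03-01", wake = c(6, 30, "AM"), on = c(7, 0, "AM"),
                         off = c(9, 0, NA), bed = c(10, 30, "PM")))
  expect_equal(impute_meridiem(lg)$log$days$off_mer, "PM")

  # on "12:15" (outside default window), wake 11:00 AM, bed 11:00 PM:
  # only PM satisfies on >= wake
  lg <- make_log(log_day("2012-03-01", wake = c(11, 0, "AM"), on = c(12, 15, NA),
                         off = c(9, 0, "PM"), bed = c(11, 0, "PM")))
  out <- impute_meridiem(lg)
  expect_equal(out$log$days$on_mer, "PM")
  expect_equal(out$audit$rule, "ordering")

  # off at hour 12 defaults to AM (midnight), bed window default PM
  lg <- make_log(log_day("2012-03-01", off = c(12, 5, NA), bed = c(10, 0, NA)))
  out <- impute_meridiem(lg)
  expect_equal(out$log$days$off_mer, "AM")
  expect_equal(out$log$days$bed_mer, "PM")

  # contradiction: no meridiem puts off within (on, bed]; hour 2 is outside
  # the default windows so the ordering rule must decide - and cannot
  lg <- make_log(log_day("2012-03-01", on = c(3, 0, "PM"), off = c(2, 0, NA),
                         bed = c(1, 0, "AM")))
  out <- impute_meridiem(lg)
  expect_true(is.na(out$log$days$off_mer))
  expect_true("contradiction" %in% out$audit$rule)

  # never overwrites a recorded meridiem; ambiguous stays missing
  lg <- make_log(log_day("2012-03-01", wake = c(2, 0, "AM"), on = c(3, 0, NA),
                         off = c(4, 30, "PM"), bed = c(11, 0, "PM")))
  out <- impute_meridiem(lg)
  expect_true(is.na(out$log$days$on_mer))  # hour 3 outside window, both orders fit
  # determinism and idempotence
  again <- impute_meridiem(out$log)
  expect_identical(again$log$days, out$log$days)
})

test_that("detailed-log mask covers [on, off) on complete days only", {
  es <- flat_series(2880, a1 = 10)  # two days from 2012-03-01T00:00
  lg <- make_log(
    log_day("2012-03-01", wake = c(6, 30, "AM"), on = c(7, 0, "AM"),
            off = c(9, 0, "PM"), bed = c(10, 30, "PM")),
    log_day("2012-03-02", wake = c(6, 30, "AM"), on = c(7, 0, NA),
            off = c(9, 0, "PM"), bed = c(10, 30, "PM")))
  # leave day 2 meridiem unresolved on purpose (no imputation called)
  m <- detailed_log_mask(lg, es)
  byday <- wear_minutes(m, es, by = "calendar_day")
  expect_equal(unname(byday), c(840, 0))  # 14 h on day 1, nothing on day 2
  expect_equal(attr(m, "dropped_days"), 2L)
  # wear epochs are exactly [on, off): first worn epoch starts 07:00, last 20:59
  expect_equal(range(which(as.logical(m))), c(7 * 60 + 1, 21 * 60))

  # series not overlapping any log date -> all-false with a warning
  es_far <- flat_series(1440, a1 = 10, start = "2013-01-01T00:00:00")
  expect_warning(m2 <- detailed_log_mask(lg, es_far), "not covered")
  expect_equal(sum(m2), 0)

  # off <= on contributes nothing and is flagged
  lg3 <- make_log(log_day("2012-03-01", on = c(9, 0, "PM"), off = c(7, 0, "AM")))
  m3 <- detailed_log_mask(lg3, es)
  expect_equal(sum(m3), 0)
  expect_equal(attr(m3, "dropped_days"), 1L)
})

test_that("limited-log restriction forces non-log dates to non-wear", {
  # 9 days of continuous wear-like counts; log lists only 7 dates
  es <- flat_series(9 * 1440, a1 = 500)
  alg <- troiano_nonwear(axis_counts(es, "vertical"))
  expect_equal(sum(alg), 9 * 1440)  # algorithm sees wear everywhere
  days <- as.Date("2012-03-02") + 0:6
  rows <- lapply(days, function(d)
    log_day(format(d), on = c(7, 0, "AM"), off = c(9, 0, "PM")))
  lg <- do.call(make_log, rows)
  m <- limited_log_restrict(alg, lg, es)
  expect_equal(unname(wear_minutes(m, es, by = "calendar_day")),
               c(0, rep(1440, 7), 0))
  expect_equal(attr(m, "method"), "limited_log_troiano")

  # never increases wear; idempotent
  expect_lte(sum(m), sum(alg))
  expect_identical(as.logical(limited_log_restrict(m, lg, es)), as.logical(m))

  # log dates covering all mask dates leave the mask unchanged
  rows9 <- lapply(as.Date("2012-03-01") + 0:8, function(d)
    log_day(format(d), on = c(7, 0, "AM"), off = c(9, 0, "PM")))
  lg9 <- do.call(make_log, rows9)
  expect_identical(as.logical(limited_log_restrict(alg, lg9, es)),
                   as.logical(alg))

  # empty date intersection -> all-false mask
  far_rows <- lapply(as.Date("2013-06-01") + 0:2, function(d)
    log_day(format(d), on = c(7, 0, "AM"), off = c(9, 0, "PM")))
  expect_equal(sum(limited_log_restrict(alg, do.call(make_log, far_rows), es)), 0)

  # a log with no usable dates is a refusal
  lg_none <- make_log(log_day(NA, on = c(7, 0, "AM"), off = c(9, 0, "PM")))
  expect_error(limited_log_restrict(alg, lg_none, es), "no usable dates")
})
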