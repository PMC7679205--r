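test_that("event log parsing handles both dialects and canonicalizes", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "2021-03-01 08:00:00.000000 M001 ON Sleep",
    "2021-03-01 08:00:01.500000 M005 on ",
    "2021-03-01 08:00:03.250000 M001 OFF Sleep"), f)
  suppressMessages(log <- read_event_log(f, .schema))
  expect_equal(nrow(log), 3L)
  expect_equal(log$state, c("ON", "ON", "OFF"))
  expect_equal(log$activity, c("Sleep", NA, "Sleep"))
  expect_true(!is.unsorted(as.numeric(log$timestamp)))

  # empty file is an empty log, not an error
  writeLines(character(), f)
  suppressMessages(expect_equal(nrow(read_event_log(f, .schema)), 0L))

  # CSV dialect
  writeLines(c("timestamp,sensor_id,sensor_type,state,activity",
               "2021-03-01 02:00:00.000000,M001,PIR,ON,Sleep"), f)
  suppressMessages(log <- read_event_log(f, .schema))
  expect_equal(log$activity, "Sleep")
  expect_equal(log$sensor_type, "PIR")
})

test_that("malformed lines and unknown sensors are rejected by line", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("2021-03-01 08:00:00.0 M001 ON",
               "not a line"), f)
  expect_error(suppressMessages(read_event_log(f, .schema)),
               "line 2")
  writeLines("2021-03-01 08:00:00.0 MX99 ON", f)
  expect_error(suppressMessages(read_event_log(f, .schema)),
               "schema error.*MX99")
  writeLines("2021-03-01 08:00:00.0 M001 MAYBE", f)
  expect_error(suppressMessages(read_event_log(f, .schema)),
               "state")
})

test_that("write/read round-trip preserves every field", {
  log <- mk_log(c(2.0001, 2.5, 23.999), c("bed", "toilet", "hallway"),
                c("ON", "ON", "OFF"),
                activity = c("Sleep", "Bed-Toilet Transition", NA))
  for (fmt in c("text", "csv")) {
    f <- withr::local_tempfile()
    write_event_log(log, f, format = fmt)
    suppressMessages(back <- read_event_log(f, .schema))
    expect_equal(as.numeric(back$timestamp), as.numeric(log$timestamp),
                 tolerance = 1e-6)
    expect_equal(back$sensor_id, log$sensor_id)
    expect_equal(back$state, log$state)
    expect_equal(back$activity, log$activity)
  }
})

test_that("day segmentation conserves events and emits gap days", {
  # midnight boundary is half-open
  log <- mk_log(c(23 + 59 / 60 + 59.5 / 3600, 24.0), c("bed", "bed"))
  segs <- segment_days(log)
  expect_length(segs, 2L)
  expect_equal(vapply(segs, function(s) nrow(s$events), 1L), c(1L, 1L))

  # 7 days of events: conservation against a brute-force calendar walk
  set.seed(4)
  hrs <- sort(runif(200, 0, 7 * 24))
  log <- mk_log(hrs, sample(c("bed", "kitchen", "hallway"), 200, TRUE))
  segs <- segment_days(log)
  expect_length(segs, 7L)
  expect_equal(sum(vapply(segs, function(s) nrow(s$events), 1L)), 200L)
  walk <- table(factor(as.Date(log$timestamp, tz = "UTC"),
                       levels = as.character(vapply(segs, function(s)
                         as.character(s$date), ""))))
  expect_equal(unname(vapply(segs, function(s) nrow(s$events), 1L)),
               as.integer(walk))

  # a day with no events still yields an (empty) segment
  log <- mk_log(c(1, 49), c("bed", "bed"))  # day 1 and day 3
  segs <- segment_days(log)
  expect_length(segs, 3L)
  expect_equal(nrow(segs[[2]]$events), 0L)

  # unsorted input is rejected
  bad <- mk_log(c(5, 1), c("bed", "bed"))
  bad <- bad[c(1, 2), ]
  bad$timestamp <- rev(bad$timestamp)
  expect_error(segment_days(bad), "ordering error")
})

test_that("day labeling follows the overlap rule and balances classes", {
  days <- lapply(seq(as.Date("2021-03-01"), as.Date("2021-03-31"), "day"),
                 empty_day, label = "unlabeled")
  days <- lapply(days, function(d) { d$participant_id <- "P001"; d })
  pe <- data.frame(participant_id = "P001",
                   start = as.POSIXct("2021-03-03 12:00:00", tz = "UTC"),
                   end = as.POSIXct("2021-03-04 06:00:00", tz = "UTC"),
                   type = "acute", stringsAsFactors = FALSE)
  nw <- data.frame(participant_id = "P001",
                   start = as.Date("2021-03-15"),
                   end = as.Date("2021-03-21"))
  out <- label_days(days, pe, nw)
  lab <- vapply(out, function(d) d$label, "")
  expect_equal(which(lab == "pain"), c(3L, 4L))
  # balance: 2 pain days -> exactly 2 pain-free days, nearest in time
  expect_equal(sum(lab == "pain_free"), 2L)
  expect_equal(which(lab == "pain_free"), c(15L, 16L))
  # matched controls inherit the event id
  expect_equal(out[[15]]$event_id, out[[3]]$event_id)

  # idempotence
  out2 <- label_days(out, pe, nw)
  expect_equal(vapply(out2, function(d) d$label, ""), lab)

  # no pain events -> no pain-free days retained
  out0 <- label_days(days, pe[0, ], nw)
  expect_equal(sum(vapply(out0, function(d) d$label, "") != "unlabeled"), 0L)

  # a pain event overlapping a declared normal week is inconsistent
  nw_bad <- data.frame(participant_id = "P001",
                       start = as.Date("2021-03-01"),
                       end = as.Date("2021-03-07"))
  expect_error(label_days(days, pe, nw_bad), "consistency error")
})

test_that("nearest-in-time pain-free selection matches a brute-force oracle", {
  days <- lapply(seq(as.Date("2021-03-01"), as.Date("2021-04-14"), "day"),
                 empty_day)
  pe <- data.frame(participant_id = "P001",
                   start = as.POSIXct("2021-03-05 00:00:00", tz = "UTC"),
                   end = as.POSIXct("2021-03-13 00:00:00", tz = "UTC"),
                   type = "flare", stringsAsFactors = FALSE)
  # 21 candidate normal days, 8 pain days
  nw <- data.frame(participant_id = "P001",
                   start = as.Date(c("2021-03-22", "2021-03-29",
                                     "2021-04-05")),
                   end = as.Date(c("2021-03-28", "2021-04-04",
                                   "2021-04-11")))
  out <- label_days(days, pe, nw)
  lab <- vapply(out, function(d) d$label, "")
  expect_equal(sum(lab == "pain"), 8L)
  expect_equal(sum(lab == "pain_free"), 8L)
  # oracle: enumerate candidates, rank by distance to nearest pain day
  dates <- as.Date(vapply(out, function(d) as.character(d$date), ""))
  pain_dates <- dates[lab == "pain"]
  cand <- dates[dates >= as.Date("2021-03-22") &
                  dates <= as.Date("2021-04-11")]
  dist <- vapply(cand, function(d)
    min(abs(as.numeric(d - pain_dates))), 0)
  oracle <- sort(cand[order(dist, cand)][1:8])
  expect_equal(sort(dates[lab == "pain_free"]), oracle)
})

test_that("schema round-trips through YAML and JSON", {
  for (ext in c(".yaml", ".json")) {
    f <- withr::local_tempfile(fileext = ext)
    write_home_schema(.schema, f)
    back <- read_home_schema(f)
    expect_equal(back$sensors$sensor_id, .schema$sensors$sensor_id)
    expect_equal(back$locations, .schema$locations)
    expect_equal(back$activities, .schema$activities)
    expect_equal(back$sensors$x, .schema$sensors$x)
  }
  expect_length(.schema$locations, 36L)
  expect_length(.schema$activities, 13L)
})
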