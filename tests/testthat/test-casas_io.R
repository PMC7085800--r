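test_that("annotated and bare event lines parse into the right fields", {
  ev <- parse_events(c(
    "2010-11-04 05:40:51.303739 M004 ON Bed_to_Toilet begin",
    "2010-11-04 05:40:52.342105 M005 OFF"
  ))
  expect_equal(nrow(ev), 2)
  expect_equal(ev$date[1], as.Date("2010-11-04"))
  expect_equal(ev$time[1], "05:40:51.303739")
  expect_equal(ev$sensor, c("M004", "M005"))
  expect_equal(ev$status, c("ON", "OFF"))
  expect_equal(ev$activity, c("Bed_to_Toilet", NA))
  expect_equal(ev$marker, c("begin", NA))
  expect_equal(ev$line, 1:2)
})

test_that("empty input gives an empty event collection", {
  expect_equal(nrow(parse_events(character())), 0)
  expect_equal(nrow(parse_events("")), 0)
})

test_that("tabs and mixed whitespace delimit fields", {
  ev <- parse_events("2010-11-04\t05:40:51.303739  M004\tON")
  expect_equal(ev$sensor, "M004")
})

test_that("malformed lines are rejected with their line number", {
  expect_error(parse_events(c("2010-11-04 05:40:51 M004 ON",
                              "2010-11-04 05:40:52 M005")),
               "line 2")
  expect_error(parse_events("04/11/2010 05:40:51 M004 ON"), "date")
  expect_error(parse_events("2010-11-04 29:40:51 M004 ON"), "time")
  expect_error(parse_events("2010-11-04 05:40:51 M004 ON Sleep middle"),
               "marker")
})

test_that("sensor-prefix exclusion drops temperature events", {
  ev <- parse_events(c("2010-11-04 05:40:51 T001 21.5",
                       "2010-11-04 05:40:52 M004 ON"),
                     exclude_prefix = "T")
  expect_equal(ev$sensor, "M004")
})

test_that("the overlapping worked example segments into two instances", {
  acts <- segment_activities(table1_fixture())
  expect_equal(acts$label, c("Bed_to_Toilet", "Sleep"))
  expect_equal(acts$bt, c(5L, 5L))
  expect_equal(acts$et, c(5L, 5L))
  # every event from begin through end inclusive, shared span contributing
  # to both instances
  expect_equal(acts$sq[[1]],
               c("M004", "M005", "M007", "M001", "M004", "M004", "M007",
                 "M007"))
  expect_equal(acts$sq[[2]],
               c("M004", "M004", "M007", "M007", "M006", "M007", "M005",
                 "M004"))
})

test_that("a minimal begin/end pair yields one instance over its events", {
  ev <- parse_events(c("2010-11-04 10:00:00 M001 ON Nap begin",
                       "2010-11-04 10:30:00 M001 OFF Nap end"))
  acts <- segment_activities(ev)
  expect_equal(nrow(acts), 1)
  expect_equal(acts$sq[[1]], c("M001", "M001"))
  expect_equal(acts$bt, 10L)
})

test_that("nested activities match a brute-force span-membership oracle", {
  lines <- c(
    "2010-01-01 08:00:00 M001 ON Outer begin",
    "2010-01-01 08:01:00 M002 ON Middle begin",
    "2010-01-01 08:02:00 M003 ON Inner begin",
    "2010-01-01 08:03:00 M004 ON",
    "2010-01-01 08:04:00 M005 OFF Inner end",
    "2010-01-01 08:05:00 M006 ON",
    "2010-01-01 08:06:00 M007 OFF Middle end",
    "2010-01-01 08:07:00 M008 ON",
    "2010-01-01 08:08:00 M009 OFF Outer end"
  )
  ev <- parse_events(lines)
  acts <- segment_activities(ev)
  spans <- oracle_spans(ev)
  expect_equal(nrow(acts), length(spans))
  for (sp in spans) {
    i <- which(acts$label == sp$label)
    expect_equal(acts$sq[[i]], ev$sensor[sp$from:sp$to])
  }
  # conservation: every event inside a span is in at least one instance,
  # and an event outside all spans is in none
  covered <- unique(unlist(lapply(spans, function(s) s$from:s$to)))
  all_used <- unlist(lapply(acts$sq, identity))
  expect_setequal(sort(unique(all_used)), sort(unique(ev$sensor[covered])))
})

test_that("stray end markers and unclosed activities are skipped loudly", {
  ev <- parse_events(c("2010-01-01 08:00:00 M001 ON Ghost end",
                       "2010-01-01 08:01:00 M002 ON Open begin"))
  expect_warning(expect_warning(acts <- segment_activities(ev),
                                "no open instance"),
                 "still open")
  expect_equal(nrow(acts), 0)
})

test_that("write then parse is the identity on fixtures and random data", {
  fix <- table1_fixture()
  rt <- parse_events(write_events(fix))
  expect_equal(rt, fix)

  expect_length(write_events(empty <- parse_events(character())), 0)

  sim <- generate_events(default_scenario(days = 30, seed = 11))
  expect_gt(nrow(sim$events), 1000)
  rt2 <- parse_events(write_events(sim$events))
  for (col in c("date", "time", "sensor", "status", "activity", "marker")) {
    expect_equal(rt2[[col]], sim$events[[col]], label = col)
  }
})

test_that("out-of-order timestamps are reported", {
  expect_warning(parse_events(c("2010-01-01 09:00:00 M001 ON",
                                "2010-01-01 08:00:00 M002 ON")),
                 "non-decreasing")
})
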