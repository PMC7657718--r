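test_that("rolling statistics match hand-computed windows", {
  out <- rolling_window_features(1:5, w = 3)
  expect_equal(out$sum, c(6, 9, 12))
  expect_equal(out$mean, c(2, 3, 4))
  expect_equal(out$min, c(1, 2, 3))
  expect_equal(out$max, c(3, 4, 5))
  expect_equal(out$sd, c(1, 1, 1))
  expect_equal(out$index, 3:5)  # aligned to each window's last point
})

test_that("w = 1 reproduces the series and leaves sd undefined", {
  x <- c(2.5, -1, 7)
  out <- rolling_window_features(x, w = 1)
  expect_equal(out$sum, x)
  expect_equal(out$mean, x)
  expect_equal(out$min, x)
  expect_equal(out$max, x)
  expect_true(all(is.na(out$sd)))
})

test_that("rolling features of a constant series are constant with sd 0", {
  out <- rolling_window_features(rep(5, 3), w = 3)
  expect_equal(out$sum, 15)
  expect_equal(out$mean, 5)
  expect_equal(out$sd, 0)
})

test_that("rolling output length is max(0, n - w + 1) and w < 1 errors", {
  expect_equal(nrow(rolling_window_features(1:10, w = 4)), 7L)
  expect_equal(nrow(rolling_window_features(1:3, w = 5)), 0L)
  expect_error(rolling_window_features(1:3, w = 0), "positive")
  # missing entries are skipped before windowing by default
  out <- rolling_window_features(c(1, NA, 2, 3), w = 3)
  expect_equal(out$sum, 6)
})

test_that("interaction terms are elementwise products with missing propagation", {
  dt <- data.frame(a = c(1, 2, NA), b = c(3, 4, 5), z = c("p", "q", "r"))
  out <- interaction_terms(dt, list(c("a", "b")))
  expect_equal(out$a_x_b, c(3, 8, NA))
  out2 <- interaction_terms(dt, list(c("a", "a")))
  expect_equal(out2$a_x_a, c(1, 4, NA))  # self-pair is the square
  expect_error(interaction_terms(dt, list(c("a", "z"))), "numeric")
})

test_that("all-pairs interactions add p(p-1)/2 columns", {
  dt <- data.frame(a = 1:4, b = 5:8, c = 9:12, d = 13:16)
  out <- interaction_terms(dt, "all")
  expect_equal(ncol(out) - ncol(dt), choose(4, 2))
})

test_that("event indicators flag days with at least one event", {
  raw <- raw_touchpoints(
    tp("u1", 0, "mood", 1),
    tp("u1", 3, "login", 1, "system", time = "08:00:00"),
    tp("u1", 3, "login", 1, "system", time = "12:00:00"),
    tp("u1", 5, "mood", 2))
  log <- parse_touchpoints(raw)
  ind <- event_indicator(log, "login")
  expect_equal(ind$indicator, c(0, 0, 0, 1, 0, 0))  # days 0..5
  expect_equal(sum(ind$indicator), 1)               # two logins, one day
  expect_error(event_indicator(log, "nonsense"), "unknown event")
})

test_that("days since last contact counts gaps and resets on contact", {
  raw <- raw_touchpoints(
    tp("u1", 1, "mood", 1), tp("u1", 4, "mood", 2))
  log <- parse_touchpoints(raw)
  g <- days_since_last_contact(log)
  # grid runs day 1..4: contact day 1 -> 0, then 1, 2, reset to 0
  expect_equal(g$gap_days, c(0, 1, 2, 0))
  expect_true(all(g$gap_days >= 0))
})

test_that("days before the first contact are missing", {
  raw <- raw_touchpoints(tp("u1", 2, "mood", 1), tp("u1", 4, "mood", 1))
  log <- parse_touchpoints(raw)
  span <- data.frame(user_id = "u1", start = as.Date("2020-01-01"),
                     end = as.Date("2020-01-05"))
  g <- days_since_last_contact(log, span = span)
  expect_equal(g$gap_days, c(NA, NA, 0, 1, 0))
})

test_that("completion latencies and their running mean follow the schedule", {
  raw <- raw_touchpoints(
    tp("u1", 0, "core_available_0", 1, "system"),
    tp("u1", 3, "core_completed_0", 1, "system"),
    tp("u1", 10, "core_available_1", 1, "system"),
    tp("u1", 15, "core_completed_1", 1, "system"),
    tp("u1", 22, "core_available_2", 1, "system"))
  lat <- completion_latency(core_schedule(parse_touchpoints(raw)))
  expect_equal(lat$latency_days, c(3, 5, NA))
  expect_equal(lat$running_avg, c(3, 4, 4))  # mean of 3 and 5 after core 1
})

test_that("completion before availability is an error", {
  raw <- raw_touchpoints(
    tp("u1", 5, "core_available_0", 1, "system"),
    tp("u1", 2, "core_completed_0", 1, "system"))
  expect_error(core_schedule(parse_touchpoints(raw)), "precedes")
})

test_that("clock parsing and shortest signed differences behave", {
  expect_equal(parse_clock(c("06:30", "23:45")), c(390, 1425))
  expect_message(bad <- parse_clock(c("06:30", "25:00", "oops")),
                 "malformed")
  expect_equal(is.na(bad), c(FALSE, TRUE, TRUE))
  expect_equal(clock_diff_min(390, 420), 30)    # 06:30 -> 07:00
  expect_equal(clock_diff_min(1425, 15), 30)    # 23:45 -> 00:15 crosses midnight
  expect_equal(clock_diff_min(15, 1425), -30)
})

test_that("catalog features compute flags, differences and trends", {
  raw <- do.call(raw_touchpoints, c(
    list(tp("u1", 0, "core_available_0", 1, "system"),
         tp("u1", 2, "core_completed_0", 1, "system"),
         tp("u1", 9, "core_available_1", 1, "system"),
         tp("u1", 12, "core_completed_1", 1, "system"),
         tp("u1", 19, "core_available_2", 1, "system"),
         tp("u1", 21, "core_completed_2", 1, "system")),
    # diary: bedtime 23:00, arise 07:00 -> exactly an 8-hour window
    lapply(0:2, function(d) tp("u1", d, "bedtime", "23:00")),
    lapply(0:2, function(d) tp("u1", d, "arise_time", "07:00")),
    lapply(0:2, function(d) tp("u1", d, "awake_time", "06:30")),
    # per-core sleep durations 7.5, 7.0, 6.5 -> decreasing twice
    list(tp("u1", 0, "sleep_duration_h", 7.5),
         tp("u1", 10, "sleep_duration_h", 7.0),
         tp("u1", 20, "sleep_duration_h", 6.5))))
  log <- parse_touchpoints(raw)
  ut <- user_level_aggregate(
    aggregate_within_window(assign_windows(log)))
  cat_entries <- Filter(function(e) e$name %in%
                          c("sleep_window_5or8h", "awake_to_arise_min",
                            "sleep_duration_decreasing", "latency_core_0",
                            "latency_core_1", "latency_core_avg"),
                        default_feature_catalog())
  out <- apply_feature_catalog(ut, log, catalog = cat_entries)
  expect_equal(out$sleep_window_5or8h, 3)       # all three diary days flag
  expect_equal(out$awake_to_arise_min, 30)
  expect_equal(out$sleep_duration_decreasing, 2)
  expect_equal(out$latency_core_0, 2)
  expect_equal(out$latency_core_1, 3)
  expect_equal(out$latency_core_avg, mean(c(2, 3, 2)))
  expect_true(all(cat_entries_names <- vapply(cat_entries, `[[`, "", "name")
                  %in% attr(out, "protected_features")))
})

test_that("a catalog feature with no base variable is all-missing with warning", {
  raw <- raw_touchpoints(tp("u1", 0, "mood", 1))
  log <- parse_touchpoints(raw)
  ut <- user_level_aggregate(
    aggregate_within_window(assign_windows(log)))
  entry <- Filter(function(e) e$name == "awake_to_arise_min",
                  default_feature_catalog())
  w <- capture_warnings(out <- apply_feature_catalog(ut, log, catalog = entry))
  expect_true(any(grepl("all-missing", w)))
  expect_true(all(is.na(out$awake_to_arise_min)))
})
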