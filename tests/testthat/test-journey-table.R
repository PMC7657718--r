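windowed <- function(raw, w = 1) {
  assign_windows(parse_touchpoints(raw), window_days = w)
}

test_that("within-window aggregation applies the per-type defaults", {
  raw <- raw_touchpoints(
    tp("u1", 0, "mood", 2, time = "08:00:00"),
    tp("u1", 0, "mood", 4, time = "12:00:00"),
    tp("u1", 0, "login", 1, "system", time = "08:00:00"),
    tp("u1", 0, "login", 1, "system", time = "09:00:00"),
    tp("u1", 0, "login", 1, "system", time = "10:00:00"),
    tp("u1", 0, "color", "yes", time = "08:00:00"),
    tp("u1", 0, "color", "yes", time = "09:00:00"),
    tp("u1", 0, "color", "no", time = "10:00:00"))
  jt <- aggregate_within_window(windowed(raw))
  expect_equal(jt$mood, 3.0)
  expect_equal(jt$login, 3)
  expect_equal(jt$color, "yes")
})

test_that("mode ties break toward the earliest observed value", {
  raw <- raw_touchpoints(
    tp("u1", 0, "color", "b", time = "08:00:00"),
    tp("u1", 0, "color", "a", time = "09:00:00"),
    tp("u1", 0, "color", "a", time = "10:00:00"),
    tp("u1", 0, "color", "b", time = "11:00:00"))
  jt <- aggregate_within_window(windowed(raw))
  expect_equal(jt$color, "b")
})

test_that("sum-aggregated events conserve the raw event count", {
  sim <- small_cohort()
  w <- assign_windows(sim$log, window_days = 7)
  jt <- aggregate_within_window(w)
  for (ev in c("login", "email_sent")) {
    expect_equal(sum(jt[[ev]], na.rm = TRUE),
                 nrow(sim$log[variable == ev]))
  }
})

test_that("duplicating touchpoints doubles sums but fixes means and modes", {
  raw <- raw_touchpoints(
    tp("u1", 0, "mood", 2), tp("u1", 0, "mood", 4),
    tp("u1", 0, "login", 1, "system"),
    tp("u1", 0, "color", "a"), tp("u1", 0, "color", "b"))
  log1 <- windowed(raw)
  log2 <- windowed(rbind(raw, raw))
  jt1 <- aggregate_within_window(log1)
  jt2 <- aggregate_within_window(log2)
  expect_equal(jt2$mood, jt1$mood)
  expect_equal(jt2$color, jt1$color)
  expect_equal(jt2$login, 2 * jt1$login)
})

test_that("carry_forward fills gaps until the next occurrence only", {
  # ISI observed in windows 2 and 6; 3-5 take the window-2 value,
  # 0-1 stay missing
  raw <- do.call(raw_touchpoints, c(
    lapply(0:6, function(d) tp("u1", d, "mood", d)),
    list(tp("u1", 2, "isi", 15), tp("u1", 6, "isi", 11))))
  log <- windowed(raw)
  specs <- default_specs(log, carry_forward_variables = "isi")
  jt <- carry_forward(aggregate_within_window(log, specs))
  expect_equal(jt$isi, c(NA, NA, 15, 15, 15, 15, 11))
})

test_that("carry_forward is idempotent and leaves complete columns alone", {
  raw <- do.call(raw_touchpoints, c(
    lapply(0:4, function(d) tp("u1", d, "mood", d)),
    list(tp("u1", 1, "isi", 9))))
  log <- windowed(raw)
  specs <- default_specs(log, carry_forward_variables = c("isi", "mood"))
  jt1 <- carry_forward(aggregate_within_window(log, specs))
  jt2 <- carry_forward(jt1)
  expect_equal(as.data.frame(jt2), as.data.frame(jt1))
  expect_equal(jt1$mood, 0:4)  # complete column unchanged
})

test_that("all-missing columns stay missing under carry_forward", {
  raw <- raw_touchpoints(tp("u1", 0, "mood", 1), tp("u2", 0, "isi", 3))
  log <- windowed(raw)
  specs <- default_specs(log, carry_forward_variables = "isi")
  jt <- carry_forward(aggregate_within_window(log, specs))
  expect_true(is.na(jt[user_id == "u1", isi]))
})

test_that("single-level and all-missing categorical columns are removed", {
  raw <- raw_touchpoints(
    tp("u1", 0, "constant", "no"), tp("u2", 0, "constant", "no"),
    tp("u1", 0, "varying", "no"), tp("u2", 0, "varying", "yes"))
  jt <- aggregate_within_window(windowed(raw))
  out <- drop_constant_categoricals(jt)
  expect_false("constant" %in% names(out))
  expect_true("varying" %in% names(out))
  expect_equal(attr(out, "dropped_constant"), "constant")

  # a categorical column observed for no user counts as single-level
  jt2 <- data.table::copy(jt)
  jt2[, ghost := NA_character_]
  data.table::setattr(jt2, "var_types",
                      c(attr(jt, "var_types"), ghost = "categorical"))
  out2 <- drop_constant_categoricals(jt2)
  expect_false("ghost" %in% names(out2))
})

test_that("user-level aggregation follows the per-variable rules", {
  raw <- raw_touchpoints(
    tp("u1", 0, "login", 1, "system"), tp("u1", 2, "login", 1, "system"),
    tp("u1", 3, "login", 1, "system"),
    tp("u1", 0, "diary", 4), tp("u1", 2, "diary", 6),
    tp("u1", 0, "latency", 3), tp("u1", 3, "latency", 5))
  log <- windowed(raw)
  specs <- rbind(
    variable_spec("login", "event", user_agg = "sum"),
    variable_spec("diary", "numeric", user_agg = "mean"),
    variable_spec("latency", "numeric", user_agg = "last"))
  ut <- user_level_aggregate(aggregate_within_window(log, specs))
  expect_equal(ut$login, 3)     # daily indicator [1,0,1,1] summed
  expect_equal(ut$diary, 5.0)
  expect_equal(ut$latency, 5)   # last observation
})

test_that("cutoff windows restrict users and attach labels", {
  raw <- raw_touchpoints(
    tp("u1", 0, "mood", 1), tp("u1", 5, "mood", 9),
    tp("u2", 0, "mood", 2))
  jt <- aggregate_within_window(windowed(raw))
  labels <- data.frame(user_id = c("u1", "u2"), y = c(1, 0))
  expect_message(
    ut <- user_level_aggregate(jt, labels = labels,
                               cutoff_windows = c(u1 = 2L)),
    "excluded")
  expect_equal(ut$user_id, "u1")
  expect_equal(ut$mood, 1)  # window 5 excluded by the cutoff
  expect_equal(ut$y, 1L)
})

test_that("eligible cohort size is non-increasing across core cutoffs", {
  sim <- small_cohort()
  sched <- core_schedule(sim$log)
  ns <- vapply(0:5, function(cc) {
    nrow(sched[core == cc & !is.na(completed_date)])
  }, numeric(1))
  expect_true(all(diff(ns) <= 0))
})
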