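make_ut <- function(df, protected = character()) {
  dt <- data.table::as.data.table(df)
  data.table::setattr(dt, "protected_features", protected)
  data.table::setattr(dt, "class", c("user_table", "data.table", "data.frame"))
  dt
}

test_that("missingness fractions are per-column missing-row shares", {
  ut <- make_ut(data.frame(user_id = sprintf("u%02d", 1:10),
                           a = c(rep(NA, 2), rnorm(8)),
                           b = rnorm(10),
                           c = rep(NA_real_, 10)))
  frac <- missingness_fraction(ut)
  expect_equal(unname(frac[c("a", "b", "c")]), c(0.2, 0, 1))
})

test_that("deletion uses a strict threshold and spares protected features", {
  ut <- make_ut(data.frame(user_id = sprintf("u%02d", 1:10),
                           at_20 = c(rep(NA, 2), rnorm(8)),
                           at_50 = c(rep(NA, 5), rnorm(5)),
                           full = rnorm(10),
                           hand = c(rep(NA, 5), rnorm(5))),
                protected = "hand")
  # fraction 0.20: dropped at tau = 0.15 but kept at tau = 0.20
  expect_false("at_20" %in% names(delete_by_missingness(ut, 0.15)))
  expect_true("at_20" %in% names(delete_by_missingness(ut, 0.20)))
  # protected feature survives any threshold
  out <- delete_by_missingness(ut, 0.05)
  expect_true("hand" %in% names(out))
  expect_false("at_50" %in% names(out))
  report <- attr(out, "deletion_report")
  expect_equal(report[report$feature == "hand", ]$action, "kept_protected")
  # tau = 1 keeps everything
  expect_equal(ncol(delete_by_missingness(ut, 1)), ncol(ut))
})

test_that("retained feature sets nest as the threshold grows", {
  set.seed(7)
  n <- 40
  df <- data.frame(user_id = sprintf("u%03d", 1:n))
  for (j in 1:25) {
    x <- rnorm(n)
    x[sample(n, rbinom(1, n, runif(1, 0, 0.3)))] <- NA
    df[[paste0("f", j)]] <- x
  }
  ut <- make_ut(df)
  kept <- lapply(c(0.05, 0.10, 0.15, 0.20),
                 function(tau) names(delete_by_missingness(ut, tau)))
  for (i in 1:3) expect_true(all(kept[[i]] %in% kept[[i + 1]]))
})

test_that("median/mode imputation fills without touching observed cells", {
  ut <- make_ut(data.frame(user_id = sprintf("u%02d", 1:4),
                           num = c(1, 2, 100, NA),
                           cat = c("a", "a", "b", NA),
                           stringsAsFactors = FALSE))
  out <- impute_simple(ut)
  expect_equal(out$num, c(1, 2, 100, 2))  # median of {1, 2, 100}
  expect_equal(out$cat, c("a", "a", "b", "a"))
  expect_equal(out$num[1:3], ut$num[1:3])
  # idempotent; complete tables unchanged
  expect_equal(as.data.frame(impute_simple(out)), as.data.frame(out))
  expect_error(impute_simple(make_ut(data.frame(user_id = "u1",
                                                bad = NA_real_))),
               "bad")
})

test_that("knn with k = 1 copies an exact duplicate row's value", {
  ut <- make_ut(data.frame(user_id = sprintf("u%02d", 1:4),
                           a = c(1, 1, 5, 9),
                           b = c(2, 2, 7, 3),
                           c = c(3.5, NA, 1, 0)))
  out <- impute_knn(ut, k = 1)
  expect_equal(out$c[2], 3.5)  # row 1 is the zero-distance neighbour
  expect_false(anyNA(out))
})

test_that("knn imputation matches a brute-force distance oracle", {
  df <- data.frame(user_id = c("u1", "u2", "u3"),
                   a = c(0, 0.1, 10),
                   b = c(1, 1.2, -5),
                   c = c(NA, 4, 8))
  ut <- make_ut(df)
  # oracle: standardized Manhattan distance averaged over co-observed dims
  z <- scale(df[, c("a", "b")])
  d12 <- mean(abs(z[1, ] - z[2, ]))
  d13 <- mean(abs(z[1, ] - z[3, ]))
  expect_true(d12 < d13)  # so rows 2 and 3 are the 2 nearest, in that order
  out <- impute_knn(ut, k = 2)
  expect_equal(out$c[1], mean(c(4, 8)))
})

test_that("knn never alters observed cells and leaves no missingness", {
  sim <- small_cohort()
  ut <- suppressWarnings(build_core_dataset(sim$log, sim$labels, core = 1))
  ut <- delete_by_missingness(ut, 0.2)
  keep <- names(which(missingness_fraction(ut) < 1))
  ut <- ut[, c("user_id", keep, "y"), with = FALSE]
  data.table::setattr(ut, "class", c("user_table", "data.table", "data.frame"))
  out <- impute_knn(ut, k = 5)
  expect_false(anyNA(out[, keep, with = FALSE]))
  for (cl in keep) {
    obs <- !is.na(ut[[cl]])
    expect_equal(out[[cl]][obs], ut[[cl]][obs])
  }
})

test_that("rows with no co-observed dimensions are maximally distant", {
  D <- mixed_distance(data.frame(a = c(1, NA), b = c(NA, 2)))
  expect_equal(D[1, 2], Inf)
  D2 <- mixed_distance(data.frame(a = c(1, 2, 3), b = c("x", "x", "y")))
  expect_true(isSymmetric(D2))
  expect_equal(diag(D2), rep(0, 3))
})
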