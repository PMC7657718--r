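# shared fixtures, built in code

# raw touchpoint rows ready for parse_touchpoints()
raw_touchpoints <- function(...) {
  rows <- list(...)
  data.frame(
    user_id = vapply(rows, `[[`, character(1), 1L),
    timestamp = vapply(rows, `[[`, character(1), 2L),
    variable = vapply(rows, `[[`, character(1), 3L),
    value = vapply(rows, `[[`, character(1), 4L),
    source = vapply(rows, function(r) if (length(r) >= 5L) r[[5L]] else "self_report",
                    character(1)),
    stringsAsFactors = FALSE)
}

tp <- function(user, day, variable, value, source = "self_report",
               time = "08:00:00") {
  c(user, paste0(format(as.Date("2020-01-01") + day), "T", time),
    variable, as.character(value), source)
}

# a small deterministic simulated cohort, cached across test files
small_cohort <- local({
  cache <- new.env(parent = emptyenv())
  function(n_users = 60, seed = 42, scenario = NULL) {
    key <- paste(n_users, seed, scenario %||% "plain", sep = "_")
    if (is.null(cache[[key]])) {
      params <- if (is.null(scenario)) {
        journeydrop::cohort_params(n_users = n_users, seed = seed)
      } else {
        journeydrop::scenario_params(scenario, n_users = n_users, seed = seed,
                                     calibration_n = 2000L)
      }
      cache[[key]] <- journeydrop::simulate_cohort(params)
    }
    cache[[key]]
  }
})

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force AUC over all positive-negative pairs (independent oracle)
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# separable fixture: one feature tracks the label up to tiny noise
separable_table <- function(n = 60, seed = 1) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  dt <- data.table::data.table(
    user_id = sprintf("u%03d", seq_len(n)),
    signal = y + rnorm(n, 0, 0.01),
    noise = rnorm(n),
    y = y)
  data.table::setattr(dt, "class",
                      c("user_table", "data.table", "data.frame"))
  dt
}
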