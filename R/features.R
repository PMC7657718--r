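#' Rolling time-window aggregate features
#'
#' Slides a window of `w` consecutive observations along an ordered
#' numeric series and computes, per window position, the requested
#' statistics. Output is aligned to the last observation of each
#' window, giving `max(0, n - w + 1)` rows. The standard deviation
#' uses the sample (n-1) denominator and is therefore reported missing
#' at `w = 1`.
#'
#' @param series Ordered numeric vector (one value per time step).
#' @param w Window length in consecutive observations (>= 1).
#' @param stats Subset of `c("sum", "mean", "min", "max", "sd")`.
#' @param na_action `"skip"` drops missing entries before windowing;
#'   `"keep"` lets a missing entry make its windows missing.
#' @return A data.table with `index` (position of the window's last
#'   observation in the series used) and one column per statistic.
#' @export
rolling_window_features <- function(series, w,
                                    stats = c("sum", "mean", "min", "max", "sd"),
                                    na_action = c("skip", "keep")) {
  na_action <- match.arg(na_action)
  stats <- match.arg(stats, several.ok = TRUE)
  if (!is.numeric(w) || w < 1) stop("w must be a positive integer")
  w <- as.integer(w)
  x <- as.numeric(series)
  if (na_action == "skip") x <- x[!is.na(x)]
  n <- length(x)
  if (n < w) {
    out <- data.table::data.table(index = integer(0))
    for (s in stats) out[, (s) := numeric(0)]
    return(out[])
  }
  windows <- embed(x, w)  # row i = x[(i+w-1):i]
  out <- data.table::data.table(index = seq.int(w, n))
  fns <- list(sum = function(m) rowSums(m),
              mean = function(m) rowMeans(m),
              min = function(m) apply(m, 1L, min),
              max = function(m) apply(m, 1L, max),
              sd = function(m) {
                if (w == 1L) rep(NA_real_, nrow(m)) else apply(m, 1L, sd)
              })
  for (s in stats) out[, (s) := fns[[s]](windows)]
  out[]
}

#' Pairwise interaction terms
#'
#' Adds, for each requested pair of numeric features, a new column
#' named `a_x_b` holding their elementwise product. Missing values
#' propagate.
#'
#' @param table A `user_table` (or any data.frame of features).
#' @param pairs A list of length-2 character vectors naming feature
#'   pairs, or `"all"` for every unordered pair of numeric features.
#' @return The table with the interaction columns appended.
#' @export
interaction_terms <- function(table, pairs) {
  dt <- data.table::copy(as.data.table(table))
  num_cols <- names(dt)[vapply(dt, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, "y")
  if (identical(pairs, "all")) {
    if (length(num_cols) < 2L) return(dt[])
    cmb <- utils::combn(num_cols, 2L)
    pairs <- lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
  }
  for (p in pairs) {
    if (length(p) != 2L) stop("each pair must have exactly two feature names")
    absent <- setdiff(p, names(dt))
    if (length(absent)) stop("unknown feature(s): ", paste(absent, collapse = ", "))
    not_num <- p[!p %in% num_cols & !vapply(p, function(cl) is.numeric(dt[[cl]]), logical(1))]
    if (length(not_num)) {
      stop("interaction terms require numeric features; '",
           not_num[1L], "' is not numeric")
    }
    dt[, (paste0(p[1L], "_x_", p[2L])) := dt[[p[1L]]] * dt[[p[2L]]]]
  }
  dt[]
}

#' Daily event indicator
#'
#' For each user and calendar day of their observation span, 1 when at
#' least one event of the given type occurred that day, else 0.
#'
#' @param log A `touchpoint_log`.
#' @param event_type Name of an event variable present in the log.
#' @param span Optional data.frame `user_id`, `start`, `end` (Dates)
#'   giving each user's day grid; defaults to first-to-last touchpoint.
#' @return A data.table `user_id`, `date`, `indicator`.
#' @export
event_indicator <- function(log, event_type, span = NULL) {
  dt <- as.data.table(log)
  known_events <- unique(dt[value_type == "event", variable])
  if (!event_type %in% known_events) {
    stop("unknown event type: ", event_type)
  }
  span <- user_span(dt, span)
  ev <- unique(dt[variable == event_type, .(user_id, date)])
  grid <- span[, .(date = seq(start, end, by = "day")), by = user_id]
  ev[, indicator := 1L]
  out <- merge(grid, ev, by = c("user_id", "date"), all.x = TRUE)
  out[is.na(indicator), indicator := 0L]
  out[]
}

user_span <- function(dt, span = NULL) {
  if (is.null(span)) {
    span <- dt[, .(start = min(date), end = max(date)), by = user_id]
  } else {
    span <- data.table::as.data.table(span)
    span[, `:=`(user_id = as.character(user_id),
                start = as.Date(start), end = as.Date(end))]
  }
  span
}

#' Days since the last contact
#'
#' For each user and day of their span, the number of whole days
#' elapsed since the most recent interaction on or before that day
#' (0 on contact days). Days before the first contact are missing.
#'
#' @param log A `touchpoint_log`.
#' @param sources Which touchpoint sources count as contact.
#' @param span Optional per-user day grid as in [event_indicator()].
#' @return A data.table `user_id`, `date`, `gap_days`.
#' @export
days_since_last_contact <- function(log,
                                    sources = c("self_report", "system"),
                                    span = NULL) {
  dt <- as.data.table(log)
  span <- user_span(dt, span)
  contacts <- unique(dt[source %in% sources, .(user_id, date)])
  grid <- span[, .(date = seq(start, end, by = "day")), by = user_id]
  data.table::setkey(contacts, user_id, date)
  grid[, gap_days := {
    cd <- contacts[user_id == .BY$user_id, date]
    out <- rep(NA_real_, .N)
    if (length(cd)) {
      idx <- findInterval(date, cd)
      ok <- idx > 0L
      out[ok] <- as.numeric(date[ok] - cd[idx[ok]])
    }
    out
  }, by = user_id]
  grid[]
}

#' Extract the core schedule from an event log
#'
#' Cores are sequential content modules released at intervals; their
#' availability and completion are recorded as event touchpoints named
#' `core_available_<c>` and `core_completed_<c>`. Returns one row per
#' (user, core) with availability date, completion date (NA when the
#' core was never completed) and completion latency in whole days.
#'
#' @param log A `touchpoint_log`.
#' @return A data.table `user_id`, `core`, `available_date`,
#'   `completed_date`, `latency_days`.
#' @export
core_schedule <- function(log) {
  dt <- as.data.table(log)
  avail <- dt[grepl("^core_available_[0-9]+$", variable),
              .(available_date = min(date)),
              by = .(user_id, core = as.integer(sub("^core_available_", "", variable)))]
  compl <- dt[grepl("^core_completed_[0-9]+$", variable),
              .(completed_date = min(date)),
              by = .(user_id, core = as.integer(sub("^core_completed_", "", variable)))]
  out <- merge(avail, compl, by = c("user_id", "core"), all = TRUE)
  if (any(!is.na(out$completed_date) & !is.na(out$available_date) &
          out$completed_date < out$available_date)) {
    stop("core completion precedes availability")
  }
  out[, latency_days := as.numeric(completed_date - available_date)]
  data.table::setorder(out, user_id, core)
  out[]
}

#' Per-core completion latencies and running average
#'
#' For each user and core, days from availability to completion, plus
#' the running mean latency over the cores available so far. An
#' incomplete core has missing latency and does not enter the running
#' mean.
#'
#' @param schedule Output of [core_schedule()].
#' @return A data.table `user_id`, `core`, `latency_days`,
#'   `running_avg`.
#' @export
completion_latency <- function(schedule) {
  dt <- data.table::copy(as.data.table(schedule))
  data.table::setorder(dt, user_id, core)
  dt[, running_avg := {
    obs <- !is.na(latency_days)
    cs <- cumsum(ifelse(obs, latency_days, 0))
    cn <- cumsum(obs)
    ifelse(cn > 0, cs / cn, NA_real_)
  }, by = user_id]
  dt[, .(user_id, core, latency_days, running_avg)]
}

#' Parse clock strings to minutes since midnight
#' @param x Character `"HH:MM"` values; malformed entries become `NA`
#'   (their count is reported via a message).
#' @return Numeric minutes in `[0, 1440)`.
#' @export
parse_clock <- function(x) {
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))
  out <- vapply(m, function(g) {
    if (length(g) != 3L) return(NA_real_)
    h <- as.numeric(g[2L]); mi <- as.numeric(g[3L])
    if (h > 23 || mi > 59) return(NA_real_)
    h * 60 + mi
  }, numeric(1))
  n_bad <- sum(is.na(out) & !is.na(x))
  if (n_bad > 0) message(n_bad, " malformed clock value(s) set to missing")
  out
}

#' Shortest signed clock difference in minutes
#'
#' Difference `to - from` between two times of day, taken across
#' midnight when that is shorter; the result lies in (-720, 720].
#' @param from,to Minutes since midnight.
#' @return Signed minutes.
#' @export
clock_diff_min <- function(from, to) {
  d <- (to - from) %% 1440
  ifelse(d > 720, d - 1440, d)
}

#' The default handcrafted / theory-driven feature catalog
#'
#' Catalog of derived features computed from raw touchpoints rather
#' than present in them: engagement indicators (daily login, email,
#' trigger, nap, alcohol flags, later sum-aggregated per user), gap
#' features (days since last contact), per-core completion latencies
#' and their running average, clock-difference features (awake to
#' arise; preferred vs actual arise and bedtime), threshold flags
#' (sleep window of 5 or 8 hours; preferred arise after 8 AM during
#' core 2), a core-to-core sleep-duration-decrease trend flag, the
#' count of diary-free days, and study-specific entries (homework in
#' core 2, precipitating-factor flags) that no-op when their base
#' variables are absent. Catalog features are protected from
#' missingness-threshold deletion.
#'
#' @return A list of catalog entries (name, kind, params, user_agg,
#'   description).
#' @export
default_feature_catalog <- function() {
  entry <- function(name, kind, params, user_agg, description) {
    list(name = name, kind = kind, params = params,
         user_agg = user_agg, description = description)
  }
  c(
    lapply(c(login = "login", email = "email_sent", trigger = "trigger_event",
             nap = "nap", alcohol = "alcohol"), function(ev) {
      entry(paste0(ev, "_day_count"), "event_indicator",
            list(event = ev), "sum",
            paste0("days with at least one '", ev, "' event (user sum)"))
    }),
    list(
      entry("days_since_last_contact", "gap_days", list(), "sum",
            "daily days-since-last-interaction, summed per user"),
      entry("latency_core_avg", "completion_latency_avg", list(), "last",
            "running mean days to complete a core over cores available so far"),
      entry("awake_to_arise_min", "difference",
            list(from = "awake_time", to = "arise_time", unit = "min"), "mean",
            "minutes between waking and getting out of bed"),
      entry("pref_vs_actual_arise_min", "difference",
            list(from = "preferred_arise_time", to = "arise_time", unit = "min"),
            "mean", "preferred vs actual arise time, minutes"),
      entry("pref_vs_actual_arise_ampm", "difference",
            list(from = "preferred_arise_time", to = "arise_time", unit = "ampm"),
            "mean", "preferred and actual arise time on same side of noon"),
      entry("pref_vs_actual_bedtime_min", "difference",
            list(from = "preferred_bedtime", to = "bedtime", unit = "min"),
            "mean", "preferred vs actual bedtime, minutes"),
      entry("sleep_window_5or8h", "threshold_flag",
            list(flag = "sleep_window"), "sum",
            "1 when the bed-to-arise window rounds to 5 or 8 hours"),
      entry("arise_after_8am_core2", "threshold_flag",
            list(flag = "arise_after_8am_core2"), "last",
            "preferred arise time later than 8 AM during core 2"),
      entry("pref_arise_diff_core2_core3", "threshold_flag",
            list(flag = "pref_arise_diff_core2_core3"), "last",
            "preferred arise time change from core 2 to core 3, minutes"),
      entry("sleep_duration_decreasing", "trend_flag",
            list(variable = "sleep_duration_h"), "sum",
            "1 per core-to-core decrease in mean sleep duration"),
      entry("days_no_diary", "no_diary_days",
            list(diary_variable = "sleep_duration_h"), "last",
            "days with no completed diary in the analysis period"),
      entry("homework_core2_done", "event_indicator_last",
            list(event = "homework_core2"), "last",
            "participant finished the homework of core 2"),
      entry("precip_major_life_event", "level_flag",
            list(variable = "precipitating_factor", level = "major_life_event"),
            "last", "precipitating factor includes a major life event"),
      entry("precip_health_psych", "level_flag",
            list(variable = "precipitating_factor", level = "health_psychological"),
            "last", "precipitating factor includes health/psychological")
    ),
    lapply(0:5, function(cc) {
      entry(paste0("latency_core_", cc), "completion_latency",
            list(core = cc), "last",
            paste0("days to complete core ", cc))
    })
  )
}

catalog_feature_names <- function(catalog = default_feature_catalog()) {
  vapply(catalog, `[[`, character(1), "name")
}

#' Apply the handcrafted feature catalog to a user feature table
#'
#' Computes every catalog feature from the raw log and joins the
#' resulting user-level columns onto the table. A catalog entry whose
#' base variables are absent from the log yields an all-missing column
#' with a warning rather than an error. The added columns are recorded
#' as protected (exempt from missingness-threshold deletion).
#'
#' @param table A `user_table` (one row per user).
#' @param log The `touchpoint_log` the table was built from (already
#'   truncated to the analysis period, if any).
#' @param catalog A feature catalog; [default_feature_catalog()].
#' @param schedule Optional precomputed [core_schedule()].
#' @param span Optional per-user analysis span (`user_id`, `start`,
#'   `end`); defaults to each user's first-to-last touchpoint.
#' @return The table with catalog columns appended;
#'   `attr(, "protected_features")` lists them.
#' @export
apply_feature_catalog <- function(table, log,
                                  catalog = default_feature_catalog(),
                                  schedule = NULL, span = NULL) {
  dt <- data.table::copy(as.data.table(table))
  log <- as.data.table(log)
  users <- dt$user_id
  if (is.null(schedule)) schedule <- core_schedule(log)
  span <- user_span(log, span)
  lat <- if (nrow(schedule)) completion_latency(schedule) else NULL

  col_for <- function(e) {
    vals <- switch(
      e$kind,
      event_indicator = {
        if (!e$params$event %in% log$variable) return(NULL)
        ind <- event_indicator(log, e$params$event, span)
        agg <- ind[, .(v = sum(indicator)), by = user_id]
        setNames(agg$v, agg$user_id)
      },
      event_indicator_last = {
        if (!e$params$event %in% log$variable) return(NULL)
        ind <- unique(log[variable == e$params$event, .(user_id)])
        out <- setNames(rep(0, length(users)), users)
        out[ind$user_id] <- 1
        out
      },
      gap_days = {
        g <- days_since_last_contact(log, span = span)
        agg <- g[, .(v = sum(gap_days, na.rm = TRUE)), by = user_id]
        setNames(agg$v, agg$user_id)
      },
      completion_latency = {
        if (is.null(lat)) return(NULL)
        ll <- lat[core == e$params$core & !is.na(latency_days)]
        setNames(ll$latency_days, ll$user_id)
      },
      completion_latency_avg = {
        if (is.null(lat)) return(NULL)
        ll <- lat[!is.na(running_avg), .(v = running_avg[.N]), by = user_id]
        setNames(ll$v, ll$user_id)
      },
      difference = clock_difference_feature(log, e$params),
      threshold_flag = threshold_flag_feature(log, e$params, schedule),
      trend_flag = trend_flag_feature(log, e$params, schedule),
      no_diary_days = {
        v <- e$params$diary_variable
        if (!v %in% log$variable) return(NULL)
        grid <- span[, .(n_days = as.numeric(end - start) + 1), by = user_id]
        diaries <- unique(log[variable == v, .(user_id, date)])[, .(n_diary = .N), by = user_id]
        m <- merge(grid, diaries, by = "user_id", all.x = TRUE)
        m[is.na(n_diary), n_diary := 0L]
        setNames(m$n_days - m$n_diary, m$user_id)
      },
      level_flag = {
        v <- e$params$variable
        if (!v %in% log$variable) return(NULL)
        obs <- log[variable == v, .(v = as.integer(any(value_chr == e$params$level))),
                   by = user_id]
        setNames(obs$v, obs$user_id)
      },
      stop("unknown catalog feature kind: ", e$kind)
    )
    vals
  }

  added <- character()
  for (e in catalog) {
    vals <- col_for(e)
    if (is.null(vals)) {
      warning("catalog feature '", e$name,
              "' has no base variable in the log; column is all-missing")
      dt[, (e$name) := NA_real_]
    } else {
      dt[, (e$name) := as.numeric(vals[users])]
    }
    added <- c(added, e$name)
  }
  data.table::setattr(dt, "var_types", attr(table, "var_types"))
  data.table::setattr(dt, "protected_features",
                      union(attr(table, "protected_features"), added))
  data.table::setattr(dt, "class", c("user_table", "data.table", "data.frame"))
  dt[]
}

# daily clock-difference features, averaged per user at the window level
clock_difference_feature <- function(log, params) {
  need <- c(params$from, params$to)
  if (!all(need %in% log$variable)) return(NULL)
  a <- log[variable == params$from, .(user_id, date, from = parse_clock(value_chr))]
  b <- log[variable == params$to, .(user_id, date, to = parse_clock(value_chr))]
  # questionnaire-style 'preferred' values apply forward in time
  if (nrow(a) && nrow(b) && length(unique(a$date)) < length(unique(b$date))) {
    data.table::setkey(a, user_id, date)
    m <- a[b, on = .(user_id, date), roll = TRUE]
  } else {
    m <- merge(a, b, by = c("user_id", "date"))
  }
  m <- m[!is.na(from) & !is.na(to)]
  if (!nrow(m)) return(NULL)
  if (identical(params$unit, "ampm")) {
    m[, d := as.integer((from < 720) == (to < 720))]
  } else {
    m[, d := clock_diff_min(from, to)]
  }
  agg <- m[, .(v = mean(d)), by = user_id]
  setNames(agg$v, agg$user_id)
}

threshold_flag_feature <- function(log, params, schedule) {
  if (params$flag == "sleep_window") {
    if (!all(c("bedtime", "arise_time") %in% log$variable)) return(NULL)
    bt <- log[variable == "bedtime", .(user_id, date, bt = parse_clock(value_chr))]
    ar <- log[variable == "arise_time", .(user_id, date, ar = parse_clock(value_chr))]
    m <- merge(bt, ar, by = c("user_id", "date"))
    m <- m[!is.na(bt) & !is.na(ar)]
    if (!nrow(m)) return(NULL)
    m[, win_h := ((ar - bt) %% 1440) / 60]
    m[, flag := as.integer(round(win_h) %in% c(5, 8))]
    agg <- m[, .(v = sum(flag)), by = user_id]
    return(setNames(agg$v, agg$user_id))
  }
  if (params$flag == "arise_after_8am_core2") {
    v <- "preferred_arise_time"
    if (!v %in% log$variable || !nrow(schedule)) return(NULL)
    pref <- core_window_values(log, schedule, v, core_index = 2)
    if (is.null(pref)) return(NULL)
    agg <- pref[, .(v = as.integer(parse_clock(value_chr[.N]) > 480)), by = user_id]
    agg <- agg[!is.na(v)]
    return(setNames(agg$v, agg$user_id))
  }
  if (params$flag == "pref_arise_diff_core2_core3") {
    v <- "preferred_arise_time"
    if (!v %in% log$variable || !nrow(schedule)) return(NULL)
    p2 <- core_window_values(log, schedule, v, core_index = 2)
    p3 <- core_window_values(log, schedule, v, core_index = 3)
    if (is.null(p2) || is.null(p3)) return(NULL)
    a2 <- p2[, .(v2 = parse_clock(value_chr[.N])), by = user_id]
    a3 <- p3[, .(v3 = parse_clock(value_chr[.N])), by = user_id]
    m <- merge(a2, a3, by = "user_id")
    m <- m[!is.na(v2) & !is.na(v3)]
    if (!nrow(m)) return(NULL)
    return(setNames(clock_diff_min(m$v2, m$v3), m$user_id))
  }
  NULL
}

# values of a variable observed while a given core was the newest available
core_window_values <- function(log, schedule, variable_name, core_index) {
  sc <- as.data.table(schedule)[core == core_index & !is.na(available_date)]
  if (!nrow(sc)) return(NULL)
  obs <- log[variable == variable_name, .(user_id, date, value_chr)]
  m <- merge(obs, sc[, .(user_id, available_date, completed_date)], by = "user_id")
  upper <- m$completed_date
  upper[is.na(upper)] <- as.Date("9999-12-31")
  m <- m[date >= available_date & date <= upper]
  if (!nrow(m)) return(NULL)
  data.table::setorder(m, user_id, date)
  m[, .(user_id, date, value_chr)]
}

trend_flag_feature <- function(log, params, schedule) {
  v <- params$variable
  if (!v %in% log$variable || !nrow(schedule)) return(NULL)
  sc <- as.data.table(schedule)[!is.na(available_date)]
  obs <- log[variable == v & !is.na(value_num), .(user_id, date, value_num)]
  if (!nrow(obs)) return(NULL)
  m <- merge(obs, sc[, .(user_id, core, available_date)],
             by = "user_id", allow.cartesian = TRUE)
  m <- m[date >= available_date]
  m <- m[, .SD[core == max(core)], by = .(user_id, date)]
  percore <- m[, .(mu = mean(value_num)), by = .(user_id, core)]
  data.table::setorder(percore, user_id, core)
  agg <- percore[, .(v = if (.N < 2) 0L else sum(diff(mu) < 0)), by = user_id]
  setNames(agg$v, agg$user_id)
}
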