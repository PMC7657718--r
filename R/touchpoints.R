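#' Parse long-format touchpoint records
#'
#' Reads raw touchpoint records — one row per user, timestamp and
#' variable — and returns a validated, time-sorted touchpoint log.
#' Each variable is assigned a single value type: `numeric` when every
#' observed value parses as a number, `event` for point events that
#' carry an implicit value of 1, and `categorical` otherwise. A
#' variable whose values are all clock strings (`"HH:MM"`) is typed
#' numeric and carried as minutes since midnight; the raw string stays
#' available in `value_chr`. A variable mixing numeric and non-numeric
#' values is a hard error, since no single aggregation rule would
#' apply to it.
#'
#' @param x A file path to a delimited text file with header
#'   `user_id,timestamp,variable,value,source`, or a data.frame with
#'   those columns. Timestamps must be ISO-8601 dates or date-times;
#'   rows with unparseable timestamps are dropped with a warning.
#' @param value_types Optional named character vector overriding the
#'   inferred value type (`"numeric"`, `"categorical"`, `"event"`) for
#'   specific variables.
#' @param event_variables Optional character vector of variable names
#'   to treat as events regardless of their values. Without it, a
#'   variable whose observed values are all `"1"` (or empty) is
#'   inferred to be an event.
#' @return A `touchpoint_log`: a [data.table::data.table] with columns
#'   `user_id`, `timestamp` (POSIXct, UTC), `date` (Date), `variable`,
#'   `value_chr`, `value_num`, `value_type`, `source`, sorted by user,
#'   time and variable.
#' @export
parse_touchpoints <- function(x, value_types = NULL, event_variables = NULL) {
  if (is.character(x) && length(x) == 1L) {
    dt <- data.table::fread(x, colClasses = "character", na.strings = c("", "NA"))
  } else {
    dt <- data.table::as.data.table(x)
  }
  required <- c("user_id", "timestamp", "variable", "value", "source")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols)) {
    stop("touchpoint input lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  dt <- dt[, required, with = FALSE]
  dt[, user_id := as.character(user_id)]
  dt[, variable := as.character(variable)]
  dt[, source := as.character(source)]
  dt[, value := as.character(value)]

  ts <- parse_iso_time(dt$timestamp)
  bad <- is.na(ts) & !is.na(dt$timestamp)
  if (any(bad)) {
    warning(sum(bad), " row(s) dropped: unparseable timestamp")
  }
  keep <- !is.na(ts)
  dt <- dt[keep]
  dt[, timestamp := ts[keep]]
  dt[, date := as.Date(timestamp, tz = "UTC")]

  bad_source <- !dt$source %in% c("self_report", "system")
  if (any(bad_source)) {
    stop("unknown source value(s): ",
         paste(unique(dt$source[bad_source]), collapse = ", "))
  }

  types <- infer_value_types(dt, value_types, event_variables)
  dt[, value_type := types[variable]]
  dt[, value_chr := trimws(value)]
  dt[value_type == "event", value_chr := "1"]
  suppressWarnings(dt[, value_num := ifelse(value_type == "categorical",
                                            NA_real_, as.numeric(value_chr))])
  # clock-valued variables carry numeric minutes-since-midnight
  clock_vars <- names(types)[types == "numeric"]
  clock_vars <- clock_vars[vapply(clock_vars, function(v) {
    vv <- dt[variable == v & !is.na(value_chr), value_chr]
    length(vv) > 0L && all(grepl("^[0-9]{1,2}:[0-9]{2}$", vv))
  }, logical(1))]
  if (length(clock_vars)) {
    dt[variable %in% clock_vars,
       value_num := suppressMessages(parse_clock(value_chr))]
  }
  dt[, value := NULL]
  data.table::setorder(dt, user_id, timestamp, variable)
  data.table::setcolorder(dt, c("user_id", "timestamp", "date", "variable",
                                "value_chr", "value_num", "value_type", "source"))
  data.table::setattr(dt, "class", c("touchpoint_log", class(dt)))
  dt[]
}

# element-wise ISO-8601 parsing: later formats only fill what earlier,
# more specific ones could not parse
parse_iso_time <- function(x) {
  fmts <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
            "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d")
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                    tz = "UTC")
  for (f in fmts) {
    todo <- which(is.na(out) & !is.na(x))
    if (!length(todo)) break
    p <- as.POSIXct(strptime(x[todo], f, tz = "UTC"), tz = "UTC")
    out[todo[!is.na(p)]] <- p[!is.na(p)]
  }
  out
}

infer_value_types <- function(dt, value_types = NULL, event_variables = NULL) {
  vars <- unique(dt$variable)
  vals <- dt[!is.na(value) & trimws(value) != "",
             .(value = trimws(value)), by = variable]
  types <- setNames(rep("categorical", length(vars)), vars)
  for (v in vars) {
    vv <- vals[variable == v, value]
    if (v %in% event_variables) {
      types[[v]] <- "event"
      next
    }
    if (!length(vv) || all(vv == "1")) {
      types[[v]] <- "event"
      next
    }
    if (all(grepl("^[0-9]{1,2}:[0-9]{2}$", vv))) {
      types[[v]] <- "numeric"  # clock values become minutes since midnight
      next
    }
    num <- suppressWarnings(as.numeric(vv))
    if (all(!is.na(num))) {
      types[[v]] <- "numeric"
    } else if (any(!is.na(num))) {
      stop("variable '", v, "' mixes numeric and categorical values")
    }
  }
  if (!is.null(value_types)) {
    unknown <- setdiff(names(value_types), vars)
    types[intersect(names(value_types), vars)] <-
      value_types[intersect(names(value_types), vars)]
  }
  types
}

#' Variable aggregation specifications
#'
#' A `VariableSpec` ties a variable to its within-window and user-level
#' aggregation rules and to the flags driving carry-forward filling and
#' protection from missingness-threshold deletion.
#'
#' @param name Variable name.
#' @param value_type `"numeric"`, `"categorical"` or `"event"`.
#' @param within_window_agg One of `"mean"`, `"mode"`, `"sum"`,
#'   `"last"`, `"max"`, `"min"`. `mode` is only valid for categorical
#'   variables; `sum` only for numeric or event variables.
#' @param user_agg One of `"mean"`, `"mode"`, `"sum"`, `"last"`.
#' @param carry_forward Fill missing windows with the last observed
#'   value (questionnaire-style variables)?
#' @param protected Exempt from missingness-threshold deletion?
#' @return A one-row data.table; bind several with `rbind()`.
#' @export
variable_spec <- function(name, value_type,
                          within_window_agg = NULL, user_agg = NULL,
                          carry_forward = FALSE, protected = FALSE) {
  stopifnot(value_type %in% c("numeric", "categorical", "event"))
  if (is.null(within_window_agg)) {
    within_window_agg <- switch(value_type, numeric = "mean",
                                categorical = "mode", event = "sum")
  }
  if (is.null(user_agg)) {
    user_agg <- switch(value_type, numeric = "mean",
                       categorical = "mode", event = "sum")
  }
  check_agg(within_window_agg, value_type,
            c("mean", "mode", "sum", "last", "max", "min"), name)
  check_agg(user_agg, value_type, c("mean", "mode", "sum", "last"), name)
  data.table::data.table(name = name, value_type = value_type,
                         within_window_agg = within_window_agg,
                         user_agg = user_agg,
                         carry_forward = carry_forward,
                         protected = protected)
}

check_agg <- function(agg, value_type, allowed, name) {
  if (!agg %in% allowed) {
    stop("invalid aggregation '", agg, "' for variable '", name, "'")
  }
  if (agg == "mode" && value_type != "categorical") {
    stop("mode aggregation is only valid for categorical variables ('",
         name, "')")
  }
  if (agg == "sum" && value_type == "categorical") {
    stop("sum aggregation is not valid for categorical variables ('",
         name, "')")
  }
  invisible(TRUE)
}

#' Default variable specs for a touchpoint log
#'
#' Numeric variables aggregate by mean, categorical by mode, events by
#' sum, at both the window and the user level.
#'
#' @param log A `touchpoint_log`.
#' @param carry_forward_variables Variables (typically questionnaires
#'   administered once per core) whose values are carried forward until
#'   the next occurrence; their user-level aggregation stays the
#'   type default.
#' @return A data.table of specs, one row per variable in the log.
#' @export
default_specs <- function(log, carry_forward_variables = character()) {
  info <- unique(as.data.table(log)[, .(variable, value_type)])
  specs <- data.table::rbindlist(lapply(seq_len(nrow(info)), function(i) {
    variable_spec(info$variable[i], info$value_type[i],
                  carry_forward = info$variable[i] %in% carry_forward_variables)
  }))
  specs
}

#' Assign time-window indices to touchpoints
#'
#' Tags every touchpoint with the index of the half-open window
#' `[origin + i*w, origin + (i+1)*w)` (in whole days) containing its
#' calendar date. The default origin is each user's first touchpoint
#' date; a fixed calendar origin shared by all users is available.
#'
#' @param log A `touchpoint_log`.
#' @param window_days Window length `w` in days (positive integer).
#' @param origin `"first_touchpoint"` (per user) or `"fixed"`.
#' @param origin_date Required when `origin = "fixed"`; a `Date`.
#' @return The log with `window_index` and `origin_date` columns and
#'   attributes `window_days` and `origin`.
#' @export
assign_windows <- function(log, window_days = 1L,
                           origin = c("first_touchpoint", "fixed"),
                           origin_date = NULL) {
  origin <- match.arg(origin)
  if (!is.numeric(window_days) || window_days < 1) {
    stop("window_days must be a positive integer")
  }
  window_days <- as.integer(window_days)
  dt <- data.table::copy(as.data.table(log))
  if (origin == "first_touchpoint") {
    dt[, origin_date := min(date), by = user_id]
  } else {
    if (is.null(origin_date)) stop("origin_date required for fixed origin")
    od <- as.Date(origin_date)
    if (any(dt$date < od)) {
      stop("touchpoint(s) precede the fixed origin date")
    }
    dt[, origin_date := od]
  }
  dt[, window_index := as.integer(floor(as.numeric(date - origin_date) / window_days))]
  data.table::setattr(dt, "window_days", window_days)
  data.table::setattr(dt, "origin", origin)
  data.table::setattr(dt, "class", c("touchpoint_log", "data.table", "data.frame"))
  dt[]
}

#' Most frequent value, ties broken by earliest observation
#' @param x A vector, ordered by observation time.
#' @return The modal value, or `NA` when all values are missing.
#' @export
mode_first <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA)
  ux <- unique(x)  # preserves first-occurrence order
  ux[which.max(tabulate(match(x, ux)))]
}

agg_numeric <- function(x, agg) {
  switch(agg,
         mean = mean(x), sum = sum(x), max = max(x), min = min(x),
         last = x[length(x)],
         stop("unsupported numeric aggregation: ", agg))
}
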