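#' Aggregate touchpoints within time windows (long-to-wide transform)
#'
#' Collapses a windowed touchpoint log to one row per (user, window)
#' with one column per variable, applying each variable's
#' within-window aggregation: by default the mean for numeric
#' variables, the mode for categorical variables (ties broken by the
#' earliest observed value in the window) and the count for events.
#' Only (user, window) pairs with at least one touchpoint are
#' materialised; windows with no touchpoint for a variable hold an
#' explicit `NA`.
#'
#' @param log A windowed `touchpoint_log` (see [assign_windows()]).
#' @param specs Variable specs ([variable_spec()]); defaults per type.
#' @return A `journey_table`: a data.table keyed by
#'   `(user_id, window_index)` with one column per variable and
#'   attributes `var_types`, `specs`, `window_days`, `origin`.
#' @export
aggregate_within_window <- function(log, specs = NULL) {
  dt <- as.data.table(log)
  if (!"window_index" %in% names(dt)) {
    stop("log has no window_index; call assign_windows() first")
  }
  if (is.null(specs)) specs <- default_specs(dt)
  missing_spec <- setdiff(unique(dt$variable), specs$name)
  if (length(missing_spec)) {
    stop("no VariableSpec for variable(s): ",
         paste(missing_spec, collapse = ", "))
  }
  dt <- dt[order(user_id, window_index, variable, timestamp)]

  agg_map <- setNames(specs$within_window_agg, specs$name)
  type_map <- setNames(specs$value_type, specs$name)

  cat_vars <- specs$name[specs$value_type == "categorical"]
  num_vars <- specs$name[specs$value_type != "categorical"]

  base <- unique(dt[, .(user_id, window_index)])
  data.table::setkey(base, user_id, window_index)

  wide <- base
  if (length(num_vars)) {
    num_long <- dt[variable %in% num_vars,
                   .(val = agg_numeric(value_num, agg_map[[variable[1L]]])),
                   by = .(user_id, window_index, variable)]
    num_wide <- data.table::dcast(num_long, user_id + window_index ~ variable,
                                  value.var = "val")
    wide <- merge(wide, num_wide, by = c("user_id", "window_index"),
                  all.x = TRUE)
  }
  if (length(cat_vars)) {
    cat_long <- dt[variable %in% cat_vars,
                   .(val = {
                     agg <- agg_map[[variable[1L]]]
                     if (agg == "mode") as.character(mode_first(value_chr))
                     else if (agg == "last") value_chr[.N]
                     else stop("unsupported categorical aggregation: ", agg)
                   }),
                   by = .(user_id, window_index, variable)]
    cat_wide <- data.table::dcast(cat_long, user_id + window_index ~ variable,
                                  value.var = "val")
    wide <- merge(wide, cat_wide, by = c("user_id", "window_index"),
                  all.x = TRUE)
  }
  data.table::setorder(wide, user_id, window_index)
  data.table::setattr(wide, "var_types", type_map)
  data.table::setattr(wide, "specs", specs)
  data.table::setattr(wide, "window_days", attr(log, "window_days"))
  data.table::setattr(wide, "origin", attr(log, "origin"))
  data.table::setattr(wide, "class", c("journey_table", "data.table", "data.frame"))
  wide[]
}

#' Densify a journey table to a full per-user window grid
#'
#' Adds rows for every window index from 0 to each user's maximum
#' (or to `max_window` if given), so that rolling-window features see
#' an unbroken grid.
#'
#' @param table A `journey_table`.
#' @param max_window Optional named integer vector (per user) of the
#'   last window index to materialise.
#' @return A `journey_table` with a complete window grid per user.
#' @export
densify_journey <- function(table, max_window = NULL) {
  dt <- as.data.table(table)
  grid <- dt[, .(window_index = 0:max(window_index)), by = user_id]
  if (!is.null(max_window)) {
    ext <- data.table::rbindlist(lapply(names(max_window), function(u) {
      data.table::data.table(user_id = u,
                             window_index = 0:max_window[[u]])
    }))
    grid <- unique(rbind(grid[user_id %in% names(max_window) == FALSE], ext))
  }
  out <- merge(grid, dt, by = c("user_id", "window_index"), all.x = TRUE)
  data.table::setorder(out, user_id, window_index)
  restore_journey_attrs(out, table)
}

restore_journey_attrs <- function(new, old) {
  for (a in c("var_types", "specs", "window_days", "origin")) {
    data.table::setattr(new, a, attr(old, a))
  }
  data.table::setattr(new, "class", c("journey_table", "data.table", "data.frame"))
  new[]
}

locf <- function(x) {
  ok <- !is.na(x)
  if (!any(ok)) return(x)
  idx <- cummax(ifelse(ok, seq_along(x), 0L))
  out <- x
  fill <- idx > 0L
  out[fill] <- x[idx[fill]]
  out
}

#' Carry observations forward across windows
#'
#' For questionnaire-style variables administered intermittently,
#' fills each user's missing cells with the most recent observed value
#' (last observation carried forward). Cells before a user's first
#' observation remain missing. Idempotent.
#'
#' @param table A `journey_table`.
#' @param features Column names to fill; defaults to the variables
#'   flagged `carry_forward` in the table's specs.
#' @return The filled `journey_table`.
#' @export
carry_forward <- function(table, features = NULL) {
  specs <- attr(table, "specs")
  if (is.null(features)) {
    features <- if (!is.null(specs)) specs$name[specs$carry_forward] else character()
  }
  features <- intersect(features, names(table))
  dt <- data.table::copy(as.data.table(table))
  if (length(features)) {
    data.table::setorder(dt, user_id, window_index)
    dt[, (features) := lapply(.SD, locf), by = user_id, .SDcols = features]
  }
  restore_journey_attrs(dt, table)
}

#' Remove single-level categorical columns
#'
#' Categorical columns with at most one distinct observed level carry
#' no information for classification and are removed. An all-missing
#' categorical column counts as single-level.
#'
#' @param table A `journey_table` or user feature table.
#' @return The table without constant categorical columns; the removed
#'   names are in `attr(, "dropped_constant")`.
#' @export
drop_constant_categoricals <- function(table) {
  var_types <- attr(table, "var_types")
  dt <- data.table::copy(as.data.table(table))
  cat_cols <- if (!is.null(var_types)) {
    intersect(names(var_types)[var_types == "categorical"], names(dt))
  } else {
    names(dt)[vapply(dt, is.character, logical(1))]
  }
  dropped <- cat_cols[vapply(cat_cols, function(cl) {
    length(unique(dt[[cl]][!is.na(dt[[cl]])])) <= 1L
  }, logical(1))]
  if (length(dropped)) dt[, (dropped) := NULL]
  out <- restore_journey_attrs(dt, table)
  data.table::setattr(out, "dropped_constant", dropped)
  out
}

#' Aggregate a journey table to one row per user
#'
#' Collapses each user's windows to a single feature row using each
#' variable's user-level aggregation (Sum / Last / Mean / Mode).
#' Optionally restricts each user to windows at or below a per-user
#' cutoff — the timepoint-specific analyses only use data up to the
#' core in question — and excludes users without any window before
#' their cutoff.
#'
#' @param table A `journey_table`.
#' @param specs Variable specs; defaults to the table's specs. Columns
#'   without a spec aggregate by mean (numeric) or mode (categorical).
#' @param labels Optional data.frame `user_id`, `y` with the binary
#'   dropout outcome (1 = dropout, 0 = completer).
#' @param cutoff_windows Optional named integer vector: last window
#'   index to include per user. Users absent from it are excluded.
#' @return A `user_table`: one row per user, feature columns, and `y`
#'   when labels are given; attribute `var_types` records column types.
#' @export
user_level_aggregate <- function(table, specs = NULL, labels = NULL,
                                 cutoff_windows = NULL) {
  dt <- as.data.table(table)
  if (is.null(specs)) specs <- attr(table, "specs")
  var_types <- attr(table, "var_types")
  if (!is.null(cutoff_windows)) {
    n_before <- length(unique(dt$user_id))
    dt <- dt[user_id %in% names(cutoff_windows)]
    dt <- dt[window_index <= cutoff_windows[user_id]]
    n_after <- length(unique(dt$user_id))
    if (n_after < n_before) {
      message(n_before - n_after,
              " user(s) excluded: no window before cutoff")
    }
  }
  data.table::setorder(dt, user_id, window_index)
  feat_cols <- setdiff(names(dt), c("user_id", "window_index"))

  agg_for <- function(cl) {
    if (!is.null(specs) && cl %in% specs$name) {
      specs$user_agg[match(cl, specs$name)]
    } else if (is.character(dt[[cl]])) "mode" else "mean"
  }
  aggs <- vapply(feat_cols, agg_for, character(1))

  out <- dt[, {
    vals <- lapply(feat_cols, function(cl) {
      x <- .SD[[cl]]
      obs <- x[!is.na(x)]
      a <- aggs[[cl]]
      if (a == "mode") {
        as.character(mode_first(x))
      } else if (!length(obs)) {
        if (is.character(x)) NA_character_ else NA_real_
      } else {
        switch(a,
               mean = mean(obs), sum = sum(obs), last = obs[length(obs)],
               stop("unsupported user aggregation: ", a))
      }
    })
    setNames(vals, feat_cols)
  }, by = user_id, .SDcols = feat_cols]

  if (!is.null(labels)) {
    lab <- data.table::as.data.table(labels)[, .(user_id = as.character(user_id),
                                                 y = as.integer(y))]
    out <- merge(out, lab, by = "user_id", all.x = TRUE)
  }
  data.table::setattr(out, "var_types",
                      if (!is.null(var_types)) var_types[intersect(names(var_types), names(out))])
  data.table::setattr(out, "class", c("user_table", "data.table", "data.frame"))
  out[]
}
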