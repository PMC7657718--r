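#' Per-feature missingness fractions
#'
#' @param table A `user_table` or `journey_table`; key columns
#'   (`user_id`, `window_index`, `y`) are ignored.
#' @return Named numeric vector of the fraction of missing rows per
#'   feature column.
#' @export
missingness_fraction <- function(table) {
  dt <- as.data.table(table)
  cols <- setdiff(names(dt), c("user_id", "window_index", "y"))
  vapply(setNames(cols, cols), function(cl) mean(is.na(dt[[cl]])), numeric(1))
}

#' Delete features by missingness threshold
#'
#' Drops every feature whose fraction of missing values is strictly
#' greater than `tau`, except protected features (the handcrafted,
#' theory-driven catalog columns, which are kept on clinical grounds
#' regardless of their missingness).
#'
#' @param table A `user_table`.
#' @param tau Missingness threshold in `[0, 1]`; the study grid is
#'   0.05, 0.10, 0.15, 0.20.
#' @param protected Character vector of protected feature names;
#'   defaults to `attr(table, "protected_features")`.
#' @return The reduced table. `attr(, "deletion_report")` is a
#'   data.table (`feature`, `fraction`, `action`) covering every
#'   feature column.
#' @export
delete_by_missingness <- function(table, tau, protected = NULL) {
  stopifnot(is.numeric(tau), tau >= 0, tau <= 1)
  if (is.null(protected)) protected <- attr(table, "protected_features")
  frac <- missingness_fraction(table)
  report <- data.table::data.table(feature = names(frac), fraction = unname(frac))
  report[, action := ifelse(feature %in% protected, "kept_protected",
                            ifelse(fraction > tau, "dropped", "kept"))]
  dt <- data.table::copy(as.data.table(table))
  drop <- report[action == "dropped", feature]
  if (length(drop)) dt[, (drop) := NULL]
  keep_attrs_user_table(dt, table)
  data.table::setattr(dt, "deletion_report", report[])
  dt[]
}

keep_attrs_user_table <- function(new, old) {
  vt <- attr(old, "var_types")
  data.table::setattr(new, "var_types",
                      if (!is.null(vt)) vt[intersect(names(vt), names(new))])
  data.table::setattr(new, "protected_features",
                      intersect(attr(old, "protected_features"), names(new)))
  data.table::setattr(new, "class", c("user_table", "data.table", "data.frame"))
  invisible(new)
}

feature_columns <- function(dt) setdiff(names(dt), c("user_id", "window_index", "y"))

#' Median / mode imputation
#'
#' Fills each missing numeric cell with the column median and each
#' missing categorical cell with the column mode (ties broken by the
#' earliest observed level). Observed cells are never altered.
#'
#' @param table A `user_table`.
#' @return The completed table.
#' @export
impute_simple <- function(table) {
  dt <- data.table::copy(as.data.table(table))
  for (cl in feature_columns(dt)) {
    x <- dt[[cl]]
    if (!anyNA(x)) next
    if (all(is.na(x))) stop("cannot impute all-missing column '", cl, "'")
    fill <- if (is.numeric(x)) median(x, na.rm = TRUE) else mode_first(x)
    data.table::set(dt, which(is.na(x)), cl, fill)
  }
  keep_attrs_user_table(dt, table)
  dt[]
}

#' Mixed-type pairwise distances for KNN imputation
#'
#' Gower-style dissimilarity: numeric dimensions contribute the
#' absolute difference of z-scores, categorical dimensions a 0/1
#' mismatch; each pair is averaged over the dimensions observed in
#' both rows. Pairs with no co-observed dimension get infinite
#' distance.
#'
#' @param dt A data.frame of feature columns (numeric or character).
#' @return An n-by-n symmetric distance matrix.
#' @export
mixed_distance <- function(dt) {
  dt <- as.data.table(dt)
  n <- nrow(dt)
  S <- matrix(0, n, n)
  C <- matrix(0, n, n)
  for (cl in names(dt)) {
    x <- dt[[cl]]
    obs <- !is.na(x)
    if (!any(obs)) next
    if (is.numeric(x)) {
      s <- sd(x, na.rm = TRUE)
      z <- if (is.na(s) || s == 0) rep(0, n) else (x - mean(x, na.rm = TRUE)) / s
      z[!obs] <- 0
      D <- abs(outer(z, z, "-"))
    } else {
      xi <- match(x, unique(x[obs]))
      xi[!obs] <- 0L
      D <- outer(xi, xi, "!=") * 1
    }
    O <- outer(obs, obs, "&")
    S <- S + D * O
    C <- C + O
  }
  out <- ifelse(C > 0, S / C, Inf)
  diag(out) <- 0
  out
}

#' K-nearest-neighbour imputation for mixed-type tables
#'
#' For each missing cell, finds the `k` nearest rows (by
#' [mixed_distance()], ties broken by row order) among rows where the
#' cell's column is observed, and imputes the unweighted mean of their
#' values (numeric) or their mode (categorical, ties by nearest
#' neighbour first). When no candidate neighbour has the column
#' observed, the cell falls back to median/mode imputation (logged).
#'
#' @param table A `user_table` with at least `k + 1` rows.
#' @param k Number of neighbours (default 5).
#' @return The completed table.
#' @export
impute_knn <- function(table, k = 5L) {
  dt <- data.table::copy(as.data.table(table))
  cols <- feature_columns(dt)
  n <- nrow(dt)
  if (n < k + 1) stop("impute_knn needs at least k + 1 rows")
  all_missing <- cols[vapply(cols, function(cl) all(is.na(dt[[cl]])), logical(1))]
  if (length(all_missing)) {
    stop("cannot impute all-missing column '", all_missing[1L], "'")
  }
  D <- mixed_distance(dt[, cols, with = FALSE])
  n_fallback <- 0L
  for (cl in cols) {
    x <- dt[[cl]]
    miss <- which(is.na(x))
    if (!length(miss)) next
    donors <- which(!is.na(x))
    for (i in miss) {
      d <- D[i, donors]
      usable <- donors[is.finite(d)]
      if (!length(usable)) {
        n_fallback <- n_fallback + 1L
        fill <- if (is.numeric(x)) median(x, na.rm = TRUE) else mode_first(x)
      } else {
        ord <- usable[order(D[i, usable], usable)]  # ties by row order
        nb <- head(ord, k)
        fill <- if (is.numeric(x)) mean(x[nb]) else mode_first(x[nb])
      }
      data.table::set(dt, i, cl, fill)
    }
  }
  if (n_fallback > 0L) {
    message(n_fallback,
            " cell(s) had no usable neighbour; median/mode fallback used")
  }
  keep_attrs_user_table(dt, table)
  dt[]
}

#' Apply an imputation method by name
#' @param table A `user_table`.
#' @param method `"median_mode"` or `"knn"`.
#' @param knn_k Neighbour count for KNN (default 5).
#' @return The completed table.
#' @export
impute <- function(table, method = c("median_mode", "knn"), knn_k = 5L) {
  method <- match.arg(method)
  switch(method,
         median_mode = impute_simple(table),
         knn = impute_knn(table, k = knn_k))
}
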