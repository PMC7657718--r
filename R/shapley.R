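#' Shapley-value attribution for a single prediction
#'
#' Interventional Shapley values: a feature's attribution is its
#' average marginal effect on the model score when introduced into a
#' coalition, with absent features replaced by values from a
#' background sample. Exact mode enumerates all `2^m` coalitions
#' (feasible for `m <= 12` features); sampled mode averages marginal
#' contributions along random feature orderings, pairing each ordering
#' with a background row so that local accuracy — attributions plus
#' base value equal the model score — holds exactly in both modes.
#'
#' @param f Score function: takes a data.frame of rows, returns a
#'   numeric score per row (larger = more dropout-like).
#' @param instance One-row data.frame (or coercible) to explain.
#' @param background Data.frame of background rows defining the
#'   reference distribution (e.g. training rows).
#' @param mode `"auto"` picks exact when `m <= 12`, else sampled.
#' @param n_perm Number of sampled orderings (sampled mode).
#' @param seed Integer seed for the sampled orderings.
#' @return A `jd_attribution`: list with `phi` (named per-feature
#'   values), `base_value`, `score`, `instance`, `mode`.
#' @export
shapley_values <- function(f, instance, background,
                           mode = c("auto", "exact", "sampled"),
                           n_perm = 200L, seed = 1L) {
  mode <- match.arg(mode)
  instance <- as.data.table(as.data.frame(instance))[1L]
  background <- as.data.table(as.data.frame(background))
  if (!nrow(background)) stop("background sample is empty")
  feats <- names(instance)
  if (!identical(sort(feats), sort(names(background)))) {
    stop("instance and background must share the same feature columns")
  }
  background <- background[, feats, with = FALSE]
  m <- length(feats)
  if (mode == "auto") mode <- if (m <= 12L) "exact" else "sampled"
  if (mode == "exact" && m > 12L) {
    stop("exact mode enumerates 2^m coalitions; use sampled mode for m > 12")
  }
  res <- if (mode == "exact") {
    shapley_exact(f, instance, background, feats)
  } else {
    shapley_sampled(f, instance, background, feats, n_perm, seed)
  }
  structure(list(phi = res$phi, base_value = res$base,
                 score = res$score, instance = instance, mode = mode),
            class = "jd_attribution")
}

# rows = background with coalition columns replaced by instance values
coalition_rows <- function(instance, background, members) {
  out <- data.table::copy(background)
  for (cl in members) data.table::set(out, j = cl, value = instance[[cl]])
  out
}

shapley_exact <- function(f, instance, background, feats) {
  m <- length(feats)
  n_sets <- 2L^m
  # v(S) = mean over background rows of f(background with S from instance)
  v <- numeric(n_sets)
  for (s in 0:(n_sets - 1L)) {
    members <- feats[bitwAnd(s, bitwShiftL(1L, seq_len(m) - 1L)) > 0L]
    v[s + 1L] <- mean(f(coalition_rows(instance, background, members)))
  }
  fact <- factorial(0:m)
  phi <- setNames(numeric(m), feats)
  for (i in seq_len(m)) {
    bit <- bitwShiftL(1L, i - 1L)
    for (s in 0:(n_sets - 1L)) {
      if (bitwAnd(s, bit) > 0L) next
      size <- sum(bitwAnd(s, bitwShiftL(1L, seq_len(m) - 1L)) > 0L)
      w <- fact[size + 1L] * fact[m - size] / fact[m + 1L]
      phi[i] <- phi[i] + w * (v[s + bit + 1L] - v[s + 1L])
    }
  }
  list(phi = phi, base = v[1L], score = v[n_sets])
}

shapley_sampled <- function(f, instance, background, feats, n_perm, seed) {
  m <- length(feats)
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  bg_idx <- rep_len(sample.int(nrow(background)), n_perm)
  phi <- setNames(numeric(m), feats)
  # batch all evaluations: per ordering, m+1 states from empty to full
  states <- vector("list", n_perm * (m + 1L))
  orders <- vector("list", n_perm)
  pos <- 1L
  for (j in seq_len(n_perm)) {
    ord <- sample.int(m)
    orders[[j]] <- ord
    row <- background[bg_idx[j]]
    states[[pos]] <- data.table::copy(row); pos <- pos + 1L
    for (i in ord) {
      data.table::set(row, j = feats[i], value = instance[[feats[i]]])
      states[[pos]] <- data.table::copy(row); pos <- pos + 1L
    }
  }
  scores <- f(data.table::rbindlist(states))
  base_scores <- numeric(n_perm)
  for (j in seq_len(n_perm)) {
    off <- (j - 1L) * (m + 1L)
    base_scores[j] <- scores[off + 1L]
    deltas <- diff(scores[off + seq_len(m + 1L)])
    phi[orders[[j]]] <- phi[orders[[j]]] + deltas
  }
  phi <- phi / n_perm
  list(phi = phi, base = mean(base_scores),
       score = mean(base_scores) + sum(phi))
}

#' Shapley attributions for many instances
#'
#' @param f Score function as in [shapley_values()].
#' @param instances Data.frame of instances to explain (rows).
#' @param background Background sample.
#' @param ... Passed to [shapley_values()] (`mode`, `n_perm`, `seed`).
#' @return A list with `phi` (instances-by-features matrix),
#'   `base_values`, and `values` (the explained feature values).
#' @export
shapley_matrix <- function(f, instances, background, ...) {
  instances <- as.data.table(as.data.frame(instances))
  res <- lapply(seq_len(nrow(instances)), function(i) {
    shapley_values(f, instances[i], background, ...)
  })
  phi <- do.call(rbind, lapply(res, `[[`, "phi"))
  rownames(phi) <- NULL
  list(phi = phi,
       base_values = vapply(res, `[[`, numeric(1), "base_value"),
       values = instances)
}

#' Rank features by mean absolute Shapley value
#'
#' @param phi Instances-by-features attribution matrix (as from
#'   [shapley_matrix()]).
#' @param values Optional data.frame of the explained instances'
#'   feature values, for dependence (value, phi) pairs.
#' @param top_k How many features to return (default 5, as in per-core
#'   importance summaries).
#' @return A list: `ranking` (data.table `feature`, `mean_abs_phi`,
#'   descending), `top` (top_k names), `dependence` (long data.table
#'   `feature`, `value`, `phi` for the top features, when `values`
#'   given).
#' @export
importance_summary <- function(phi, values = NULL, top_k = 5L) {
  stopifnot(is.matrix(phi))
  ranking <- data.table::data.table(feature = colnames(phi),
                                    mean_abs_phi = colMeans(abs(phi)))
  data.table::setorder(ranking, -mean_abs_phi)
  top <- head(ranking$feature, top_k)
  dependence <- NULL
  if (!is.null(values)) {
    values <- as.data.table(as.data.frame(values))
    dependence <- data.table::rbindlist(lapply(top, function(ft) {
      data.table::data.table(feature = ft,
                             value = values[[ft]],
                             phi = phi[, ft])
    }))
  }
  list(ranking = ranking[], top = top, dependence = dependence)
}
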