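#' Classifier specification
#'
#' The four classifier families of the selection grid: L1- and
#' L2-regularised logistic regression, support vector machines, and
#' gradient-boosted trees. Every family exposes the same contract —
#' fit on a numeric design matrix and return a real-valued score per
#' row where larger means more dropout-like (probabilities for the
#' boosted trees, linear predictors for logistic regression, decision
#' margins for the SVM; AUC is rank-based, so calibration is not
#' needed).
#'
#' @param kind One of `"logreg_l1"`, `"logreg_l2"`, `"svm"`, `"gbt"`.
#' @param params Named list of hyperparameters: `lambda` for logistic
#'   regression; `cost`, `kernel` (and optional `gamma`) for the SVM;
#'   `nrounds`, `max_depth`, `eta` for the boosted trees. Missing
#'   entries take the first value of the default grid.
#' @return An object of class `jd_model_spec`.
#' @export
model_spec <- function(kind = c("logreg_l1", "logreg_l2", "svm", "gbt"),
                       params = list()) {
  kind <- match.arg(kind)
  defaults <- default_grid(kind)[[1L]]
  structure(list(kind = kind, params = modifyList(defaults, params)),
            class = "jd_model_spec")
}

#' Default hyperparameter grids
#'
#' Logistic regression searches a log-spaced regularisation path; the
#' SVM a penalty-by-kernel grid; the boosted trees tree count, depth
#' and learning rate.
#'
#' @param kind Model family as in [model_spec()].
#' @return A list of named parameter lists (grid points, in order).
#' @export
default_grid <- function(kind = c("logreg_l1", "logreg_l2", "svm", "gbt")) {
  kind <- match.arg(kind)
  switch(kind,
         logreg_l1 = ,
         logreg_l2 = lapply(10^seq(-4, 1, length.out = 6),
                            function(l) list(lambda = l)),
         svm = {
           g <- expand.grid(cost = c(0.1, 1, 10),
                            kernel = c("linear", "radial"),
                            stringsAsFactors = FALSE)
           lapply(seq_len(nrow(g)), function(i) as.list(g[i, ]))
         },
         gbt = {
           g <- expand.grid(nrounds = c(100, 300, 500),
                            max_depth = c(2, 3, 4),
                            eta = c(0.05, 0.1))
           lapply(seq_len(nrow(g)), function(i) as.list(g[i, ]))
         })
}

# accept a grid as a list of parameter lists or as a data.frame of
# settings (one row per grid point, e.g. from a JSON/YAML config)
as_param_grid <- function(grid) {
  if (is.null(grid) || !is.data.frame(grid)) return(grid)
  lapply(seq_len(nrow(grid)), function(i) as.list(grid[i, , drop = FALSE]))
}

# build a one-hot encoder with categorical levels fixed on the given
# (training) data; unseen levels later map to all-zero indicators
make_encoder <- function(train) {
  train <- as.data.table(train)
  cols <- setdiff(names(train), c("user_id", "y"))
  level_map <- lapply(setNames(cols, cols), function(cl) {
    if (is.character(train[[cl]]) || is.factor(train[[cl]])) {
      unique(as.character(train[[cl]][!is.na(train[[cl]])]))
    } else NULL
  })
  enc_col <- function(dt, cl, levels) {
    x <- dt[[cl]]
    if (is.null(levels)) {
      matrix(as.numeric(x), ncol = 1, dimnames = list(NULL, cl))
    } else {
      m <- vapply(levels, function(lv) as.numeric(!is.na(x) & x == lv),
                  numeric(nrow(dt)))
      if (!is.matrix(m)) m <- matrix(m, nrow = nrow(dt))
      colnames(m) <- paste0(cl, "=", levels)
      m
    }
  }
  function(dt) {
    dt <- as.data.table(dt)
    do.call(cbind, lapply(cols, function(cl) enc_col(dt, cl, level_map[[cl]])))
  }
}

# encode train/test with the encoder fit on train only (no leakage)
encode_design <- function(train, test = NULL) {
  enc <- make_encoder(train)
  list(train = enc(train),
       test = if (!is.null(test)) enc(test) else NULL,
       encoder = enc)
}

standardize_fit <- function(X) {
  mu <- colMeans(X)
  s <- apply(X, 2L, sd)
  s[!is.finite(s) | s == 0] <- 1
  list(center = mu, scale = s)
}

standardize_apply <- function(X, st) {
  sweep(sweep(X, 2L, st$center, "-"), 2L, st$scale, "/")
}

fit_model <- function(spec, X, y) {
  stopifnot(inherits(spec, "jd_model_spec"))
  y <- as.integer(y)
  kind <- spec$kind
  p <- spec$params
  if (kind %in% c("logreg_l1", "logreg_l2", "svm")) {
    st <- standardize_fit(X)
    Xs <- standardize_apply(X, st)
  }
  fit <- switch(
    kind,
    logreg_l1 = ,
    logreg_l2 = {
      alpha <- if (kind == "logreg_l1") 1 else 0
      Xg <- if (ncol(Xs) < 2L) cbind(Xs, `.pad` = 0) else Xs
      glmnet::glmnet(Xg, y, family = "binomial", alpha = alpha,
                     lambda = p$lambda, standardize = FALSE)
    },
    svm = {
      args <- list(x = Xs, y = factor(y, levels = c(0, 1)),
                   kernel = p$kernel, cost = p$cost, scale = FALSE)
      if (!is.null(p$gamma)) args$gamma <- p$gamma
      do.call(e1071::svm, args)
    },
    gbt = {
      dm <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
      xgboost::xgb.train(params = list(objective = "binary:logistic",
                                       max_depth = p$max_depth, eta = p$eta,
                                       nthread = 1),
                         data = dm, nrounds = p$nrounds, verbose = 0)
    })
  structure(list(kind = kind, fit = fit,
                 standardize = if (exists("st", inherits = FALSE)) st else NULL,
                 n_features = ncol(X)),
            class = "jd_model_fit")
}

predict_score <- function(object, X) {
  stopifnot(inherits(object, "jd_model_fit"))
  switch(
    object$kind,
    logreg_l1 = ,
    logreg_l2 = {
      Xs <- standardize_apply(X, object$standardize)
      if (ncol(Xs) < 2L) Xs <- cbind(Xs, `.pad` = 0)
      as.numeric(predict(object$fit, Xs, type = "link"))
    },
    svm = {
      Xs <- standardize_apply(X, object$standardize)
      pr <- predict(object$fit, Xs, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # the margin is positive for the class named first in the column label
      flip <- startsWith(colnames(dv)[1L], "0/")
      as.numeric(dv[, 1L]) * if (flip) -1 else 1
    },
    gbt = as.numeric(predict(object$fit, xgboost::xgb.DMatrix(X, nthread = 1)))
  )
}

#' Cross-validation configuration
#'
#' @param k_folds Number of folds (default 10).
#' @param stratified Preserve class proportions per fold (default)?
#' @param seed Integer seed driving fold assignment.
#' @return A `jd_cv_config` list.
#' @export
cv_config <- function(k_folds = 10L, stratified = TRUE, seed = 1L) {
  structure(list(k_folds = as.integer(k_folds), stratified = stratified,
                 seed = as.integer(seed)),
            class = "jd_cv_config")
}

#' Stratified fold assignment
#'
#' Assigns each instance to one of `k` folds so that, within each
#' class, fold counts differ by at most one.
#'
#' @param y 0/1 labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @param stratified Stratify on `y`? Plain shuffled folds otherwise.
#' @return Integer fold ids in `1:k`, one per instance.
#' @export
stratified_folds <- function(y, k, seed = 1L, stratified = TRUE) {
  n <- length(y)
  stopifnot(k >= 2L, n >= k)
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  folds <- integer(n)
  if (stratified) {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    folds <- rep_len(seq_len(k), n)[sample.int(n)]
  }
  folds
}

# evaluate under a private RNG state; returns a restore function
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Cross-validated fitting and out-of-fold scoring
#'
#' Stratified k-fold cross-validation of a single model
#' configuration: every row is scored exactly once by a model that
#' never saw it, categorical encodings and standardisation are fit on
#' the training folds only, and per-fold AUCs are returned alongside
#' the pooled out-of-fold score vector. A fold holding a single class
#' yields a missing fold AUC (with a warning); the mean is over the
#' defined folds.
#'
#' @param spec A [model_spec()].
#' @param table A `user_table` with label column `y`.
#' @param cv A [cv_config()].
#' @return A list: `fold_auc`, `mean_auc`, `oof_scores` (aligned to
#'   the table rows), `folds`, `y`.
#' @export
fit_predict_cv <- function(spec, table, cv = cv_config()) {
  dt <- as.data.table(table)
  if (!"y" %in% names(dt)) stop("table has no label column 'y'")
  y <- as.integer(dt$y)
  if (length(unique(y)) < 2L) stop("need both classes to cross-validate")
  if (nrow(dt) < cv$k_folds) stop("fewer rows than folds")
  folds <- stratified_folds(y, cv$k_folds, seed = cv$seed,
                            stratified = cv$stratified)
  oof <- rep(NA_real_, nrow(dt))
  fold_auc <- rep(NA_real_, cv$k_folds)
  for (f in seq_len(cv$k_folds)) {
    tr <- folds != f
    enc <- encode_design(dt[tr], dt[!tr])
    rng <- local_rng(cv$seed + f)  # learners with internal randomness
    fit <- fit_model(spec, enc$train, y[tr])
    rng()
    sc <- predict_score(fit, enc$test)
    oof[!tr] <- sc
    if (length(unique(y[!tr])) < 2L) {
      warning("fold ", f, " holds a single class; fold AUC undefined")
    } else {
      fold_auc[f] <- roc_auc(sc, y[!tr])$auc
    }
  }
  list(fold_auc = fold_auc,
       mean_auc = mean(fold_auc, na.rm = TRUE),
       oof_scores = oof, folds = folds, y = y)
}

#' Grid search by mean cross-validated AUC
#'
#' Evaluates every hyperparameter setting of a family with
#' [fit_predict_cv()] and returns the setting with the highest mean
#' fold AUC; ties go to the earliest grid entry.
#'
#' @param kind Model family.
#' @param grid List of parameter lists; `default_grid(kind)` if `NULL`.
#' @param table A labelled `user_table`.
#' @param cv A [cv_config()].
#' @return A list: `best_params`, `best_auc`, `results` (data.table of
#'   all settings with their mean AUC, in grid order).
#' @export
grid_search <- function(kind, grid = NULL, table, cv = cv_config()) {
  if (is.null(grid)) grid <- default_grid(kind)
  grid <- as_param_grid(grid)
  if (!length(grid)) stop("empty hyperparameter grid")
  aucs <- vapply(grid, function(p) {
    fit_predict_cv(model_spec(kind, p), table, cv)$mean_auc
  }, numeric(1))
  best <- which.max(aucs)  # first maximum wins
  results <- data.table::data.table(
    setting = vapply(grid, function(p) {
      paste(names(p), unlist(p), sep = "=", collapse = ",")
    }, character(1)),
    mean_auc = aucs)
  list(best_params = grid[[best]], best_auc = aucs[best], results = results)
}
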