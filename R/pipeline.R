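#' Default analysis configuration
#'
#' One list controlling the whole pipeline: the long-to-wide window
#' size, the questionnaire variables carried forward, the missingness
#' policy, the classifier family and its search grid, the
#' cross-validation setup, which core analyses to run, and the
#' attribution settings. The defaults mirror the configuration that
#' performed best in the motivating study: boosted trees, 15%
#' missingness threshold, KNN imputation (k = 5), stratified 10-fold
#' cross-validation.
#'
#' @param ... Named overrides, merged recursively into the defaults
#'   (e.g. `model = list(kind = "logreg_l2")`).
#' @return A configuration list.
#' @export
default_config <- function(...) {
  cfg <- list(
    window_days = 1L,
    origin = "first_touchpoint",
    questionnaire_variables = c("isi", "preferred_arise_time",
                                "preferred_bedtime", "age",
                                "gender", "precipitating_factor"),
    missingness = list(threshold = 0.15, imputation = "knn", knn_k = 5L),
    model = list(kind = "gbt", grid = NULL, tune = TRUE),
    cv = list(k_folds = 10L, stratified = TRUE, seed = 1L),
    n_cores = 7L,
    cores = NULL,  # default: 0 .. n_cores - 2
    attribution = list(enabled = TRUE, top_k = 5L, mode = "sampled",
                       n_perm = 60L, background_n = 100L,
                       explain_n = 200L, seed = 1L)
  )
  overrides <- list(...)
  if (length(overrides)) cfg <- modifyList(cfg, overrides)
  cfg
}

#' Assemble the per-user feature table for one core analysis
#'
#' The timepoint-specific dataset: users eligible at core `core`
#' (those who completed it), their touchpoints truncated at that
#' core's completion date, transformed long-to-wide, questionnaires
#' carried forward, constant categoricals dropped, aggregated to one
#' row per user, and augmented with the handcrafted feature catalog.
#' Missingness handling is left to [prepare_model_table()] so that the
#' deletion/imputation policy can vary per configuration-grid cell.
#'
#' @param log A `touchpoint_log`.
#' @param labels data.frame `user_id`, `y`.
#' @param core Core index (0-based) defining eligibility and cutoff.
#' @param config A [default_config()] list.
#' @param catalog Feature catalog ([default_feature_catalog()]).
#' @return A labelled `user_table` with protected catalog columns.
#' @export
build_core_dataset <- function(log, labels, core, config = default_config(),
                               catalog = default_feature_catalog()) {
  log <- as.data.table(log)
  core_idx <- core
  schedule <- core_schedule(log)
  eligible <- schedule[core == core_idx & !is.na(completed_date),
                       .(user_id, cutoff = completed_date)]
  if (!nrow(eligible)) stop("no user completed core ", core)
  trunc <- merge(log, eligible, by = "user_id")
  trunc <- trunc[date <= cutoff]
  data.table::setattr(trunc, "class",
                      c("touchpoint_log", "data.table", "data.frame"))

  windowed <- assign_windows(trunc, window_days = config$window_days,
                             origin = config$origin,
                             origin_date = config$origin_date)
  specs <- default_specs(windowed,
                         carry_forward_variables = config$questionnaire_variables)
  jt <- aggregate_within_window(windowed, specs)
  jt <- carry_forward(jt)
  jt <- drop_constant_categoricals(jt)
  ut <- user_level_aggregate(jt, labels = labels)

  sched_trunc <- core_schedule(trunc)
  span <- trunc[, .(start = min(date)), by = user_id]
  span <- merge(span, eligible, by = "user_id")
  data.table::setnames(span, "cutoff", "end")
  ut <- apply_feature_catalog(ut, trunc, catalog = catalog,
                              schedule = sched_trunc, span = span)
  ut
}

#' Apply the missingness policy and return a model-ready table
#'
#' Deletes features above the missingness threshold (protected
#' catalog features exempt), removes features with no observed value
#' at this timepoint (nothing can be learned or imputed from them),
#' and imputes the rest.
#'
#' @param table A labelled `user_table`.
#' @param threshold Missingness threshold tau.
#' @param imputation `"median_mode"` or `"knn"`.
#' @param knn_k Neighbour count for KNN imputation.
#' @return A complete `user_table`.
#' @export
prepare_model_table <- function(table, threshold = 0.15,
                                imputation = "median_mode", knn_k = 5L) {
  dt <- delete_by_missingness(table, tau = threshold)
  report <- attr(dt, "deletion_report")
  all_missing <- names(which(missingness_fraction(dt) == 1))
  if (length(all_missing)) {
    dt2 <- data.table::copy(as.data.table(dt))
    dt2[, (all_missing) := NULL]
    keep_attrs_user_table(dt2, dt)
    dt <- dt2
  }
  out <- impute(dt, method = imputation, knn_k = knn_k)
  data.table::setattr(out, "deletion_report", report)
  out
}

#' Run the per-core dropout analyses
#'
#' For each core in `config$cores` (default 0 to `n_cores - 2`):
#' restrict the cohort to users who completed that core and their data
#' to the core's completion date, build features, apply the
#' missingness policy, select hyperparameters, cross-validate, and
#' evaluate ROC/AUC and precision-recall on the pooled out-of-fold
#' scores; optionally attribute the refitted model's predictions to
#' features with Shapley values. Cores with fewer eligible users than
#' folds, or a single outcome class, are skipped with a warning.
#'
#' @param log A `touchpoint_log`.
#' @param labels data.frame `user_id`, `y` (1 = dropout).
#' @param config A [default_config()] list.
#' @param catalog Feature catalog.
#' @return A list of per-core results plus `summary`, a data.table
#'   with one row per analysed core (`core`, `n`, `n_dropout`, `auc`,
#'   `pr_auc`, `pr_baseline`, `best_setting`).
#' @export
run_core_analyses <- function(log, labels, config = default_config(),
                              catalog = default_feature_catalog()) {
  cores <- config$cores
  if (is.null(cores)) cores <- 0:(config$n_cores - 2L)
  results <- list()
  for (cc in cores) {
    res <- tryCatch(
      run_core_analysis(log, labels, cc, config, catalog),
      jd_skip = function(e) {
        warning("core ", cc, " skipped: ", conditionMessage(e))
        NULL
      })
    if (!is.null(res)) results[[paste0("core_", cc)]] <- res
  }
  summary <- data.table::rbindlist(lapply(results, function(r) {
    data.table::data.table(core = r$core, n = r$n, n_dropout = r$n_dropout,
                           auc = r$auc, pr_auc = r$pr_auc,
                           pr_baseline = r$pr_baseline,
                           best_setting = r$best_setting)
  }))
  list(results = results, summary = summary)
}

skip_analysis <- function(msg) {
  stop(structure(class = c("jd_skip", "condition"),
                 list(message = msg, call = NULL)))
}

run_core_analysis <- function(log, labels, core, config, catalog) {
  ut <- build_core_dataset(log, labels, core, config, catalog)
  cv <- cv_config(config$cv$k_folds, config$cv$stratified, config$cv$seed)
  if (nrow(ut) < cv$k_folds) {
    skip_analysis(sprintf("only %d eligible users (fewer than %d folds)",
                          nrow(ut), cv$k_folds))
  }
  if (length(unique(ut$y)) < 2L) skip_analysis("a single outcome class")
  ut <- prepare_model_table(ut, threshold = config$missingness$threshold,
                            imputation = config$missingness$imputation,
                            knn_k = config$missingness$knn_k)
  kind <- config$model$kind
  if (isTRUE(config$model$tune)) {
    gs <- grid_search(kind, config$model$grid, ut, cv)
    best <- gs$best_params
  } else {
    grid <- as_param_grid(config$model$grid)
    best <- if (!is.null(grid)) grid[[1L]] else default_grid(kind)[[1L]]
    gs <- NULL
  }
  cvres <- fit_predict_cv(model_spec(kind, best), ut, cv)
  roc <- roc_auc(cvres$oof_scores, cvres$y)
  pr <- pr_auc(cvres$oof_scores, cvres$y)

  attribution <- NULL
  if (isTRUE(config$attribution$enabled)) {
    attribution <- attribute_model(kind, best, ut, config$attribution, cv$seed)
  }
  list(core = core, n = nrow(ut), n_dropout = sum(ut$y == 1L),
       auc = roc$auc, pr_auc = pr$pr_auc, pr_baseline = pr$baseline,
       roc = roc$roc, pr_points = pr$points,
       fold_auc = cvres$fold_auc, oof_scores = cvres$oof_scores,
       best_params = best,
       best_setting = paste(names(best), unlist(best), sep = "=", collapse = ","),
       grid_results = if (!is.null(gs)) gs$results else NULL,
       table = ut, attribution = attribution)
}

# fit the selected configuration on the full analysis table and
# explain its predictions against a background sample
attribute_model <- function(kind, params, ut, acfg, seed) {
  dt <- as.data.table(ut)
  enc <- make_encoder(dt)
  rng <- local_rng(seed)
  fit <- fit_model(model_spec(kind, params), enc(dt), dt$y)
  rng()
  f <- function(rows) predict_score(fit, enc(rows))
  feat <- dt[, setdiff(names(dt), c("user_id", "y")), with = FALSE]

  rng <- local_rng(acfg$seed %||% 1L)
  bg_idx <- sample.int(nrow(feat), min(acfg$background_n, nrow(feat)))
  ex_idx <- sample.int(nrow(feat), min(acfg$explain_n, nrow(feat)))
  rng()
  sm <- shapley_matrix(f, feat[ex_idx], feat[bg_idx],
                       mode = acfg$mode, n_perm = acfg$n_perm,
                       seed = acfg$seed %||% 1L)
  imp <- importance_summary(sm$phi, values = sm$values, top_k = acfg$top_k)
  list(phi = sm$phi, base_values = sm$base_values,
       explained = dt$user_id[ex_idx],
       ranking = imp$ranking, top = imp$top, dependence = imp$dependence)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Model-by-imputation-by-threshold configuration grid
#'
#' Evaluates every combination of classifier family, imputation
#' method and missingness threshold by its mean cross-validated AUC
#' across the per-core analyses, reproducing the heat-map style model
#' selection. Feature tables are built once per core and shared
#' across cells.
#'
#' @param log A `touchpoint_log`.
#' @param labels data.frame `user_id`, `y`.
#' @param models Character vector of model families.
#' @param imputations Character vector of imputation methods.
#' @param thresholds Numeric vector of missingness thresholds.
#' @param config Base configuration ([default_config()]); its `model`
#'   and `missingness` entries are overridden cell by cell.
#' @param grids Optional named list (per model kind) of hyperparameter
#'   grids; `NULL` uses [default_grid()].
#' @return A list: `cells` (data.table `model`, `imputation`,
#'   `threshold`, `mean_auc`, `n_analyses`), `best` (the argmax row).
#' @export
config_grid <- function(log, labels,
                        models = c("logreg_l1", "logreg_l2", "svm", "gbt"),
                        imputations = c("median_mode", "knn"),
                        thresholds = c(0.05, 0.10, 0.15, 0.20),
                        config = default_config(), grids = NULL) {
  cores <- config$cores
  if (is.null(cores)) cores <- 0:(config$n_cores - 2L)
  cv <- cv_config(config$cv$k_folds, config$cv$stratified, config$cv$seed)
  datasets <- lapply(cores, function(cc) {
    tryCatch(build_core_dataset(log, labels, cc, config), error = function(e) NULL)
  })
  keep <- !vapply(datasets, is.null, logical(1))
  datasets <- datasets[keep]
  cells <- data.table::CJ(model = models, imputation = imputations,
                          threshold = thresholds, sorted = FALSE)
  cells[, mean_auc := NA_real_]
  cells[, n_analyses := 0L]
  for (ti in unique(cells$threshold)) for (im in unique(cells$imputation)) {
    prepared <- lapply(datasets, function(d) {
      if (nrow(d) < cv$k_folds || length(unique(d$y)) < 2L) return(NULL)
      prepare_model_table(d, threshold = ti, imputation = im,
                          knn_k = config$missingness$knn_k)
    })
    prepared <- prepared[!vapply(prepared, is.null, logical(1))]
    for (mk in models) {
      aucs <- vapply(prepared, function(tab) {
        grid_search(mk, grids[[mk]], tab, cv)$best_auc
      }, numeric(1))
      row <- cells$model == mk & cells$imputation == im & cells$threshold == ti
      cells[row, `:=`(mean_auc = mean(aucs), n_analyses = length(aucs))]
    }
  }
  best <- cells[which.max(mean_auc)]
  list(cells = cells[], best = best)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the whole process on one log: long-to-wide
#' transformation and feature engineering, missingness handling,
#' per-core cross-validated modeling, evaluation and Shapley
#' attribution, and (optionally) the model-selection configuration
#' grid. Any stage failure aborts with a stage-labelled message.
#'
#' @param log A `touchpoint_log` or path to a touchpoint CSV.
#' @param labels data.frame `user_id`, `y` or path to a labels CSV.
#' @param config A [default_config()] list.
#' @param grid_axes Optional list with `models`, `imputations`,
#'   `thresholds` (and optionally `grids`) to also run [config_grid()].
#' @param out_dir Optional directory for artifact files (report JSON,
#'   per-core summary CSV, grid CSV, attribution CSVs).
#' @return A `jd_run_report`: config echo, per-core summary and
#'   results, grid cells and best cell (when requested), top features
#'   per core, seed and package version.
#' @export
run_pipeline <- function(log, labels, config = default_config(),
                         grid_axes = NULL, out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  log <- stage("ingest", {
    if (is.character(log)) log <- parse_touchpoints(log)
    if (!nrow(log)) stop("empty touchpoint log")
    log
  })
  labels <- stage("ingest", {
    if (is.character(labels)) labels <- data.table::fread(labels)
    data.table::as.data.table(labels)[, .(user_id = as.character(user_id),
                                          y = as.integer(y))]
  })
  analyses <- stage("core_analyses", run_core_analyses(log, labels, config))
  grid <- if (!is.null(grid_axes)) {
    stage("config_grid", do.call(config_grid, c(list(log = log, labels = labels,
                                                     config = config),
                                                grid_axes)))
  } else NULL

  report <- structure(list(
    config = config,
    summary = analyses$summary,
    results = analyses$results,
    grid = grid$cells, best_cell = grid$best,
    top_features = lapply(analyses$results, function(r) {
      if (!is.null(r$attribution)) r$attribution$top else NULL
    }),
    seed = config$cv$seed,
    package_version = as.character(utils::packageVersion("journeydrop"))
  ), class = "jd_run_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character()
  add <- function(p) manifest <<- c(manifest, p)
  summary_csv <- file.path(out_dir, "core_summary.csv")
  data.table::fwrite(report$summary, summary_csv); add(summary_csv)
  if (!is.null(report$grid)) {
    grid_csv <- file.path(out_dir, "config_grid.csv")
    data.table::fwrite(report$grid, grid_csv); add(grid_csv)
  }
  for (nm in names(report$results)) {
    r <- report$results[[nm]]
    roc_csv <- file.path(out_dir, paste0(nm, "_roc.csv"))
    data.table::fwrite(r$roc, roc_csv); add(roc_csv)
    if (!is.null(r$attribution)) {
      phi_csv <- file.path(out_dir, paste0(nm, "_shap.csv"))
      phi <- data.table::as.data.table(r$attribution$phi)
      phi[, user_id := r$attribution$explained]
      data.table::fwrite(phi, phi_csv); add(phi_csv)
    }
  }
  json_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(list(
    summary = report$summary,
    best_cell = report$best_cell,
    top_features = report$top_features,
    seed = report$seed,
    package_version = report$package_version,
    manifest = c(manifest, json_path)
  ), json_path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(json_path)
}

#' @export
print.jd_run_report <- function(x, ...) {
  cat("journeydrop run report (package ", x$package_version, ")\n", sep = "")
  cat("Per-core analyses:\n")
  print(x$summary)
  if (!is.null(x$best_cell) && nrow(x$best_cell)) {
    cat("Best configuration: ", x$best_cell$model, " / ",
        x$best_cell$imputation, " / tau=", x$best_cell$threshold,
        " (mean AUC ", round(x$best_cell$mean_auc, 3), ")\n", sep = "")
  }
  invisible(x)
}
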