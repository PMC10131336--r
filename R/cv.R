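#' Configuration of a model-comparison run
#'
#' @param models subset of `c("R", "B", "RO")`: the conventional GBLUP
#'   regression classifier, the probit threshold classifier, and the
#'   cutoff-rescaled regression classifier.
#' @param threshold a [threshold_spec()] defining the top-line threshold
#'   (default: training-set quantile at `tau = 0.8`).
#' @param outer_k outer CV folds (evaluation; default 5).
#' @param inner_k inner CV folds (cutoff tuning for B/RO; default 10).
#' @param seed integer seed governing all randomness of the run.
#' @param mcmc an [mcmc_config()] for the Bayesian fits.
#' @param gblup_mode `"gibbs"` or `"blup_deterministic"` for the regression
#'   fits (R/RO). The probit fits are always Gibbs-sampled.
#' @param aggregate_B cutoff aggregation for model B
#'   (default `"mean_of_cutoffs"`: probabilities share a common scale).
#' @param aggregate_RO cutoff aggregation for model RO (default
#'   `"mean_of_levels"`: fitted-value scales shift between inner fits and
#'   the refit, so quantile levels transfer better than raw cutoffs).
#' @param stratify_inner stratify inner folds on the binarized label.
#' @param min_obs minimum observed phenotypes per fit (see [fit_gblup()]).
#' @return an object of class `run_config`.
#' @export
run_config <- function(models = c("R", "B", "RO"),
                       threshold = threshold_spec(),
                       outer_k = 5, inner_k = 10, seed = 1,
                       mcmc = mcmc_config(),
                       gblup_mode = c("gibbs", "blup_deterministic"),
                       aggregate_B = "mean_of_cutoffs",
                       aggregate_RO = "mean_of_levels",
                       stratify_inner = TRUE, min_obs = 20) {
  models <- match.arg(models, c("R", "B", "RO"), several.ok = TRUE)
  gblup_mode <- match.arg(gblup_mode)
  stopifnot(inherits(threshold, "threshold_spec"), outer_k >= 2,
            inner_k >= 2)
  structure(list(models = models, threshold = threshold,
                 outer_k = as.integer(outer_k),
                 inner_k = as.integer(inner_k), seed = as.integer(seed),
                 mcmc = mcmc, gblup_mode = gblup_mode,
                 aggregate_B = aggregate_B, aggregate_RO = aggregate_RO,
                 stratify_inner = stratify_inner, min_obs = min_obs),
            class = "run_config")
}

#' Build a nested cross-validation fold plan
#'
#' Outer folds are a seeded random partition with sizes differing by at most
#' one. Within each outer-training set, inner folds are stratified on the
#' supplied binary labels (so scarce positives spread across folds); if any
#' stratum is smaller than `inner_k` the plan falls back to unstratified
#' assignment with a warning.
#'
#' @param n number of lines.
#' @param outer_k,inner_k fold counts.
#' @param seed integer seed.
#' @param labels optional 0/1 vector of length `n` for inner stratification.
#' @return an object of class `fold_plan`: `outer` (fold id per line) and
#'   `inner` (per outer fold, a length-`n` vector with inner fold ids on the
#'   training lines and `NA` on the test lines).
#' @export
make_folds <- function(n, outer_k = 5, inner_k = 10, seed = 1,
                       labels = NULL) {
  if (n < outer_k * 2)
    stop("need at least ", outer_k * 2, " lines for ", outer_k,
         " outer folds", call. = FALSE)
  if (!is.null(labels)) stopifnot(length(labels) == n)
  set.seed(seed)
  outer <- sample(rep_len(seq_len(outer_k), n))
  inner <- vector("list", outer_k)
  stratified <- logical(outer_k)
  for (f in seq_len(outer_k)) {
    tr <- which(outer != f)
    assign_f <- rep(NA_integer_, n)
    strat <- !is.null(labels) &&
      all(table(labels[tr]) >= inner_k) && length(unique(labels[tr])) == 2
    if (!is.null(labels) && !strat)
      warning("outer fold ", f, ": a label stratum is smaller than inner_k;",
              " inner folds unstratified")
    if (strat) {
      for (lv in unique(labels[tr])) {
        idx <- tr[labels[tr] == lv]
        assign_f[idx] <- sample(rep_len(seq_len(inner_k), length(idx)))
      }
    } else {
      assign_f[tr] <- sample(rep_len(seq_len(inner_k), length(tr)))
    }
    inner[[f]] <- assign_f
    stratified[f] <- strat
  }
  structure(list(n = n, outer_k = outer_k, inner_k = inner_k, seed = seed,
                 outer = outer, inner = inner, stratified = stratified),
            class = "fold_plan")
}

subset_kinship <- function(K, ids)
  kinship_matrix(unclass(K)[ids, ids, drop = FALSE], check = FALSE)

# deterministic sub-seed per (fold, model, inner fold), < 2^31
derive_seed <- function(base, fold, model_idx, inner = 0L)
  (as.integer(base) %% 100000L) * 10000L + fold * 1000L +
    model_idx * 100L + inner

with_seed_cfg <- function(cfg, seed) { cfg$seed <- seed; cfg }

# one regression fit per outer fold, shared by models R and RO
fit_fold_gblup <- function(yv, K, train_ids, test_ids, config, seed) {
  Ksub <- subset_kinship(K, c(train_ids, test_ids))
  ytr <- yv[train_ids]
  if (config$gblup_mode == "gibbs")
    fit_gblup(ytr, Ksub, cfg = with_seed_cfg(config$mcmc, seed),
              mode = "gibbs", min_obs = config$min_obs)
  else
    fit_gblup(ytr, Ksub, mode = "blup_deterministic",
              min_obs = config$min_obs)
}

# inner tuning loop shared by B (probit probabilities) and RO (continuous
# GBLUP predictions): returns a list of optimal_cutoff or NULL per fold
tune_inner <- function(yv, K, train_ids, inner_assign, ids, Y_tau, config,
                       fold, model_idx, probit) {
  per_fold <- vector("list", config$inner_k)
  for (j in seq_len(config$inner_k)) {
    val_ids <- ids[which(inner_assign == j)]
    itr_ids <- setdiff(train_ids, val_ids)
    val_obs <- binarize(yv[val_ids], Y_tau, op = ">=")
    if (length(unique(val_obs$labels)) < 2) next  # skipped, stays NULL
    sj <- derive_seed(config$seed, fold, model_idx, j)
    scores <- tryCatch({
      Ksub <- subset_kinship(K, c(itr_ids, val_ids))
      if (probit) {
        itr_lab <- binarize(yv[itr_ids], Y_tau, op = ">=")
        fit <- fit_tgblup(stats::setNames(itr_lab$labels, itr_ids), Ksub,
                          cfg = with_seed_cfg(config$mcmc, sj))
        predict_tgblup_proba(fit, val_ids)
      } else {
        fit <- if (config$gblup_mode == "gibbs")
          fit_gblup(yv[itr_ids], Ksub,
                    cfg = with_seed_cfg(config$mcmc, sj),
                    mode = "gibbs", min_obs = config$min_obs)
        else fit_gblup(yv[itr_ids], Ksub, mode = "blup_deterministic",
                       min_obs = config$min_obs)
        predict_gblup(fit, val_ids)
      }
    }, error = function(e) NULL)
    if (is.null(scores)) next
    per_fold[[j]] <- tryCatch(optimal_cutoff(scores, val_obs),
                              error = function(e) NULL)
  }
  per_fold
}

#' Run the full model comparison under nested cross-validation
#'
#' For every outer fold the top-line threshold `Y_tau` is re-resolved on
#' that fold's training responses (check-based thresholds are resolved once,
#' since checks are fold-independent), observed test labels are binarized at
#' `Y_tau` (inclusive `>=`), and each requested model produces predicted
#' labels on the held-out test lines (strict `>` at its cutoff):
#' \describe{
#'   \item{R}{fit GBLUP on the training lines, classify test predictions at
#'     the nominal `Y_tau`.}
#'   \item{B}{binarize the training responses, tune the probability cutoff
#'     `tau0` by inner CV on probit-model validation probabilities
#'     (minimizing `(sensitivity - specificity)^2`), refit on the full
#'     outer-training set, classify test probabilities at `tau0`.}
#'   \item{RO}{tune on continuous GBLUP validation predictions instead,
#'     aggregate the tuned quantile levels, resolve the continuous cutoff
#'     `Y_tau0` on the refit model's fitted training values, and classify
#'     test predictions at `Y_tau0`. The refit is shared with model R, so R
#'     and RO differ only in the cutoff.}
#' }
#'
#' @param K a [kinship_matrix()] over all lines.
#' @param y phenotypes: [phenotype_table()] or named vector covering the
#'   lines of `K` (no `NA`).
#' @param config a [run_config()].
#' @param checks optional numeric check values for check-based thresholds
#'   (defaults to the phenotypes of `check_ids` when `y` is a
#'   [phenotype_table()]).
#' @return an object of class `gs_result`: `per_fold` (per model, per outer
#'   fold: cutoffs, scores, predicted/observed labels, confusion, metrics),
#'   `summary`/`re` comparison tables, `plan`, `config`, `provenance`.
#' @export
gs_run <- function(K, y, config = run_config(), checks = NULL) {
  stopifnot(inherits(K, "kinship_matrix"), inherits(config, "run_config"))
  if (inherits(y, "phenotype_table") && is.null(checks) &&
      length(y$check_ids))
    checks <- pheno_values(y)[y$check_ids]
  yv <- align_response(y, K)
  if (anyNA(yv))
    stop("phenotypes must cover every line of K for a CV run", call. = FALSE)
  ids <- rownames(K)
  n <- length(ids)

  spec <- config$threshold
  check_based <- spec$kind %in% c("check_mean", "check_max")
  global_spec <- if (check_based || spec$kind == "fixed")
    resolve_threshold(yv, spec, checks) else NULL

  # stratification labels from the global threshold (fold composition only)
  strat_spec <- if (is.null(global_spec)) resolve_threshold(yv, spec)
                else global_spec
  glab <- binarize(yv, strat_spec, op = ">=")
  plan <- make_folds(n, config$outer_k, config$inner_k, config$seed,
                     labels = if (config$stratify_inner) glab$labels)

  model_idx <- stats::setNames(seq_along(c("R", "B", "RO")),
                               c("R", "B", "RO"))
  per_fold <- stats::setNames(
    lapply(config$models, function(m) vector("list", config$outer_k)),
    config$models)

  for (f in seq_len(config$outer_k)) {
    test_ids <- ids[plan$outer == f]
    train_ids <- ids[plan$outer != f]
    spec_f <- if (is.null(global_spec))
      resolve_threshold(yv[train_ids], spec) else global_spec
    Y_tau <- spec_f$value
    obs_test <- binarize(yv[test_ids], Y_tau, op = ">=")

    shared_fit <- NULL
    if (any(c("R", "RO") %in% config$models)) {
      shared_fit <- fit_fold_gblup(yv, K, train_ids, test_ids, config,
                                   derive_seed(config$seed, f, 1L))
      yhat_test <- predict_gblup(shared_fit, test_ids)
    }

    if ("R" %in% config$models) {
      pred <- classify(yhat_test, Y_tau)
      cm <- confusion(obs_test, pred)
      per_fold$R[[f]] <- list(
        fold = f, threshold = spec_f, cutoff = Y_tau, scores = yhat_test,
        predicted = pred, observed = obs_test, confusion = cm,
        metrics = metrics(cm), train_ids = train_ids, test_ids = test_ids)
    }

    if ("RO" %in% config$models) {
      inner <- tune_inner(yv, K, train_ids, plan$inner[[f]], ids, Y_tau,
                          config, f, model_idx["RO"], probit = FALSE)
      res <- tryCatch({
        agg <- aggregate_cutoffs(inner, strategy = config$aggregate_RO)
        Y_tau0 <- if (config$aggregate_RO == "mean_of_levels")
          resolve_continuous_cutoff(agg$level,
                                    predict_gblup(shared_fit, train_ids))
        else agg$value
        pred <- classify(yhat_test, Y_tau0)
        cm <- confusion(obs_test, pred)
        list(fold = f, threshold = spec_f, cutoff = Y_tau0, tuned = agg,
             scores = yhat_test, predicted = pred, observed = obs_test,
             confusion = cm, metrics = metrics(cm), train_ids = train_ids,
             test_ids = test_ids)
      }, error = function(e) list(fold = f, error = conditionMessage(e)))
      per_fold$RO[[f]] <- res
    }

    if ("B" %in% config$models) {
      res <- tryCatch({
        tr_lab <- binarize(yv[train_ids], Y_tau, op = ">=")
        if (length(unique(tr_lab$labels)) < 2)
          stop("single-class outer-training labels")
        inner <- tune_inner(yv, K, train_ids, plan$inner[[f]], ids, Y_tau,
                            config, f, model_idx["B"], probit = TRUE)
        agg <- aggregate_cutoffs(inner, strategy = config$aggregate_B)
        tau0 <- agg$value
        Ksub <- subset_kinship(K, c(train_ids, test_ids))
        refit <- fit_tgblup(stats::setNames(tr_lab$labels, train_ids), Ksub,
                            cfg = with_seed_cfg(
                              config$mcmc,
                              derive_seed(config$seed, f, model_idx["B"])))
        p_test <- predict_tgblup_proba(refit, test_ids)
        pred <- classify(p_test, tau0)
        cm <- confusion(obs_test, pred)
        list(fold = f, threshold = spec_f, cutoff = tau0, tuned = agg,
             scores = p_test, predicted = pred, observed = obs_test,
             confusion = cm, metrics = metrics(cm), train_ids = train_ids,
             test_ids = test_ids)
      }, error = function(e) list(fold = f, error = conditionMessage(e)))
      per_fold$B[[f]] <- res
    }
  }

  usable <- lapply(per_fold, function(folds)
    Filter(function(x) is.null(x$error), folds))
  summ <- if (all(vapply(usable, length, integer(1)) >= 2))
    summarize_folds(lapply(config$models, function(m)
      lapply(usable[[m]], `[[`, "metrics")), config$models)
  else NULL

  structure(list(per_fold = per_fold, summary = summ$summary,
                 re = summ$re, plan = plan, config = config,
                 provenance = list(
                   seed = config$seed, n_lines = n,
                   package_version =
                     as.character(utils::packageVersion("toplineGS")))),
            class = "gs_result")
}

#' @export
print.gs_result <- function(x, ...) {
  cat(sprintf("gs_result: models %s, %d lines, %d outer x %d inner folds\n",
              paste(x$config$models, collapse = "/"), x$plan$n,
              x$plan$outer_k, x$plan$inner_k))
  if (!is.null(x$summary)) print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Run a single model through the outer-fold pipeline
#'
#' Convenience wrappers around [gs_run()] restricted to one model.
#'
#' @param data list with elements `K` (kinship) and `y` (phenotypes).
#' @param config a [run_config()]; its `models` field is overridden.
#' @return the per-fold result list for that model.
#' @export
run_model_R <- function(data, config = run_config()) {
  config$models <- "R"
  gs_run(data$K, data$y, config)$per_fold$R
}

#' @rdname run_model_R
#' @export
run_model_B <- function(data, config = run_config()) {
  config$models <- "B"
  gs_run(data$K, data$y, config)$per_fold$B
}

#' @rdname run_model_R
#' @export
run_model_RO <- function(data, config = run_config()) {
  config$models <- "RO"
  gs_run(data$K, data$y, config)$per_fold$RO
}

#' Comparison tables from a finished run
#'
#' @param result a `gs_result`.
#' @return list with `summary` (metric, model, mean, SE, LL, UL) and `re`
#'   (pairwise relative efficiencies and percent advantages) data frames.
#' @export
compare_models <- function(result) {
  stopifnot(inherits(result, "gs_result"))
  if (is.null(result$summary))
    stop("run has no summarizable folds", call. = FALSE)
  list(summary = result$summary, re = result$re)
}

#' Write the comparison table to CSV
#'
#' Columns mirror the appendix-table layout: metric, model, mean, SE,
#' LL and UL (t-based interval over folds), fold counts. A companion RE
#' block is appended below a blank line when `include_re = TRUE`.
#'
#' @param result a `gs_result`.
#' @param path output CSV path.
#' @param include_re append the pairwise relative-efficiency table.
#' @export
write_metrics_csv <- function(result, path, include_re = TRUE) {
  stopifnot(inherits(result, "gs_result"))
  data.table::fwrite(result$summary, path)
  if (include_re && !is.null(result$re)) {
    cat("\n", file = path, append = TRUE)
    data.table::fwrite(result$re, path, append = TRUE, col.names = TRUE)
  }
  invisible(path)
}

#' Write per-line predictions to CSV
#'
#' One row per line, outer fold and model: score (continuous prediction or
#' probability), predicted and observed label, and the cutoff applied.
#'
#' @param result a `gs_result`.
#' @param path output CSV path.
#' @export
write_predictions_csv <- function(result, path) {
  stopifnot(inherits(result, "gs_result"))
  rows <- list()
  for (m in names(result$per_fold)) for (r in result$per_fold[[m]]) {
    if (!is.null(r$error)) next
    rows[[length(rows) + 1]] <- data.frame(
      line_id = r$predicted$line_ids, fold = r$fold, model = m,
      score = unname(r$scores), cutoff = r$cutoff,
      predicted = r$predicted$labels, observed = r$observed$labels)
  }
  data.table::fwrite(do.call(rbind, rows), path)
  invisible(path)
}
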