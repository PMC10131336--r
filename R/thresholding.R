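#' Specify a top-line selection threshold
#'
#' The threshold `Y_tau` that splits lines into top (positive class) and
#' not-top can be a training-set quantile (default `tau = 0.8`), the mean or
#' maximum of check-line performance, or a fixed value.
#'
#' @param kind `"quantile"`, `"check_mean"`, `"check_max"` or `"fixed"`.
#' @param tau quantile level in (0, 1); required when `kind = "quantile"`.
#' @param value resolved threshold in trait units (required for `"fixed"`,
#'   filled in by [resolve_threshold()] otherwise).
#' @return an object of class `threshold_spec`.
#' @export
threshold_spec <- function(kind = c("quantile", "check_mean", "check_max",
                                    "fixed"),
                           tau = if (kind == "quantile") 0.8 else NULL,
                           value = NULL) {
  kind <- match.arg(kind)
  if (kind == "quantile") {
    if (is.null(tau) || !is.finite(tau) || tau <= 0 || tau >= 1)
      stop("`tau` must lie strictly in (0, 1)", call. = FALSE)
  } else tau <- NULL
  if (kind == "fixed" && (is.null(value) || !is.finite(value)))
    stop("`fixed` threshold needs a finite `value`", call. = FALSE)
  structure(list(kind = kind, tau = tau, value = value),
            class = "threshold_spec")
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf("threshold_spec: %s%s%s\n", x$kind,
              if (!is.null(x$tau)) sprintf(" (tau=%g)", x$tau) else "",
              if (!is.null(x$value)) sprintf(" -> Y_tau=%g", x$value)
              else " (unresolved)"))
  invisible(x)
}

#' Resolve a threshold specification on training data
#'
#' Quantile thresholds use the linear-interpolation empirical quantile
#' (type 7, the default convention of this environment); check-based
#' thresholds take the mean or max of the check values.
#'
#' @param y numeric training responses (quantile kinds).
#' @param spec a [threshold_spec()].
#' @param checks numeric check-line values (check kinds).
#' @return the spec with `value` filled in.
#' @export
resolve_threshold <- function(y = NULL, spec = threshold_spec(),
                              checks = NULL) {
  stopifnot(inherits(spec, "threshold_spec"))
  spec$value <- switch(spec$kind,
    quantile = {
      y <- y[!is.na(y)]
      if (!length(y)) stop("empty training response", call. = FALSE)
      unname(stats::quantile(y, spec$tau, type = 7))
    },
    check_mean = {
      if (!length(checks)) stop("no check values supplied", call. = FALSE)
      mean(checks, na.rm = TRUE)
    },
    check_max = {
      if (!length(checks)) stop("no check values supplied", call. = FALSE)
      max(checks, na.rm = TRUE)
    },
    fixed = spec$value)
  if (!is.finite(spec$value))
    stop("resolved threshold is not finite", call. = FALSE)
  spec
}

#' Binary top-line labels
#'
#' @param line_ids character ids.
#' @param labels integer 0/1 vector (1 = top line), same length.
#' @return an object of class `binary_labels`.
#' @export
binary_labels <- function(line_ids, labels) {
  line_ids <- as.character(line_ids)
  labels <- as.integer(labels)
  if (length(labels) != length(line_ids))
    stop("ids and labels lengths differ", call. = FALSE)
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be 0/1", call. = FALSE)
  structure(list(line_ids = line_ids, labels = labels),
            class = "binary_labels")
}

#' @export
print.binary_labels <- function(x, ...) {
  cat(sprintf("binary_labels: %d lines, %d top (1), %d not top (0)\n",
              length(x$labels), sum(x$labels == 1), sum(x$labels == 0)))
  invisible(x)
}

#' Binarize observed trait values at a threshold
#'
#' Observed lines at or above the threshold are labelled 1 (top line); the
#' boundary is inclusive for observed labels (`>=`), in contrast to
#' [classify()] which uses strict `>` for predicted scores.
#'
#' @param y named numeric trait values (or a [phenotype_table()]).
#' @param threshold a resolved [threshold_spec()] or a single number.
#' @param op boundary operator for the positive class, `">="` (default) or
#'   `">"`.
#' @return a [binary_labels()].
#' @export
binarize <- function(y, threshold, op = c(">=", ">")) {
  op <- match.arg(op)
  if (inherits(y, "phenotype_table")) y <- pheno_values(y)
  value <- if (inherits(threshold, "threshold_spec")) {
    if (is.null(threshold$value))
      stop("threshold is unresolved; call resolve_threshold() first",
           call. = FALSE)
    threshold$value
  } else threshold
  lab <- if (op == ">=") as.integer(y >= value) else as.integer(y > value)
  binary_labels(if (is.null(names(y))) seq_along(y) else names(y), lab)
}

#' Classify prediction scores at a cutoff
#'
#' Predicted scores strictly above the cutoff are labelled top line (1);
#' exact ties go to class 0 (strict `>`), in contrast to [binarize()].
#'
#' @param scores named numeric predictions or probabilities.
#' @param cutoff finite numeric cutoff.
#' @param op boundary operator, `">"` (default) or `">="`.
#' @return a [binary_labels()].
#' @export
classify <- function(scores, cutoff, op = c(">", ">=")) {
  op <- match.arg(op)
  if (!is.finite(cutoff)) stop("cutoff must be finite", call. = FALSE)
  lab <- if (op == ">") as.integer(scores > cutoff)
         else as.integer(scores >= cutoff)
  binary_labels(if (is.null(names(scores))) seq_along(scores)
                else names(scores), lab)
}

#' Tune the decision cutoff to balance sensitivity and specificity
#'
#' Scans candidate cutoffs (midpoints between consecutive distinct sorted
#' scores, plus one candidate below the minimum and one above the maximum)
#' and returns the one minimizing the squared difference between sensitivity
#' and specificity of `classify(scores, c)`. Ties are broken toward the
#' smallest candidate, which favors sensitivity.
#'
#' @param scores validation scores (probabilities or continuous predictions).
#' @param labels observed validation labels: a [binary_labels()] or 0/1
#'   vector aligned with `scores`. Both classes must be present.
#' @return an object of class `optimal_cutoff`: `value` (the cutoff),
#'   `level` (fraction of scores at or below the cutoff), `objective`
#'   (achieved `(sens - spec)^2`), `sensitivity`, `specificity`.
#' @export
optimal_cutoff <- function(scores, labels) {
  if (inherits(labels, "binary_labels")) labels <- labels$labels
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2)
    stop("validation labels are single-class; fold must be skipped",
         call. = FALSE)
  s <- sort(unique(scores))
  gap <- if (length(s) > 1) min(diff(s)) else 1
  cand <- c(s[1] - gap, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
            s[length(s)] + gap)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  obj <- vapply(cand, function(cc) {
    pred <- scores > cc
    sens <- sum(pred & labels == 1) / n_pos
    spec <- sum(!pred & labels == 0) / n_neg
    (sens - spec)^2
  }, numeric(1))
  # ties (within floating-point noise) go to the smallest candidate,
  # which favors sensitivity
  best <- cand[obj <= min(obj) + 1e-12][1]
  pred <- scores > best
  sens <- sum(pred & labels == 1) / n_pos
  spec <- sum(!pred & labels == 0) / n_neg
  structure(list(value = best, level = mean(scores <= best),
                 objective = min(obj), sensitivity = sens,
                 specificity = spec), class = "optimal_cutoff")
}

#' @export
print.optimal_cutoff <- function(x, ...) {
  cat(sprintf(
    "optimal_cutoff: value=%.4g (level %.3f), sens=%.3f spec=%.3f obj=%.2g\n",
    x$value, x$level, x$sensitivity, x$specificity, x$objective))
  invisible(x)
}

#' Aggregate per-fold tuned cutoffs
#'
#' Folds that failed (e.g. single-class validation labels) are passed as
#' `NULL` and excluded; their count is recorded. `"mean_of_cutoffs"`
#' (default for the probit classifier, whose probabilities share a common
#' scale) averages the cutoff values; `"mean_of_levels"` (default for the
#' rescaled-regression route, whose fitted-value scale shifts between inner
#' fits and the refit) averages the quantile levels, to be re-resolved on
#' refit fitted values via [resolve_continuous_cutoff()].
#'
#' @param per_fold list of `optimal_cutoff` objects (or `NULL` for skipped
#'   folds).
#' @param strategy `"mean_of_cutoffs"` or `"mean_of_levels"`.
#' @return an `optimal_cutoff` with the aggregated `value`/`level`, mean
#'   objective, the per-fold list, and `n_skipped`.
#' @export
aggregate_cutoffs <- function(per_fold, strategy = c("mean_of_cutoffs",
                                                     "mean_of_levels")) {
  strategy <- match.arg(strategy)
  ok <- Filter(Negate(is.null), per_fold)
  if (!length(ok)) stop("no usable inner folds", call. = FALSE)
  out <- structure(list(
    value = mean(vapply(ok, `[[`, numeric(1), "value")),
    level = mean(vapply(ok, `[[`, numeric(1), "level")),
    objective = mean(vapply(ok, `[[`, numeric(1), "objective")),
    sensitivity = NA_real_, specificity = NA_real_,
    strategy = strategy, per_fold = ok,
    n_skipped = length(per_fold) - length(ok)), class = "optimal_cutoff")
  out
}

#' Resolve a tuned quantile level into a continuous-scale cutoff
#'
#' `Y_tau0` is the type-7 empirical quantile of the refit model's fitted
#' training values at the tuned level `tau0`. It is resolved on training
#' fitted values only, never on test predictions, keeping the decision rule
#' test-independent.
#'
#' @param level tuned level `tau0` in (0, 1).
#' @param refit_predictions fitted values of the refit model on its training
#'   lines.
#' @return the continuous cutoff `Y_tau0`.
#' @export
resolve_continuous_cutoff <- function(level, refit_predictions) {
  if (!is.finite(level) || level <= 0 || level >= 1)
    stop("`level` must lie strictly in (0, 1)", call. = FALSE)
  refit_predictions <- refit_predictions[!is.na(refit_predictions)]
  if (!length(refit_predictions))
    stop("empty refit predictions", call. = FALSE)
  unname(stats::quantile(refit_predictions, level, type = 7))
}

#' Rescale predictions so the nominal threshold becomes the tuned one
#'
#' The adjusted prediction is `Y*_i = Y_i * (Y_tau / Y_tau0)`. When both
#' thresholds are positive, `classify(Y*, Y_tau)` is identical to
#' `classify(Y, Y_tau0)`, so the familiar nominal threshold can be kept
#' while effectively applying the tuned one.
#'
#' @param y_hat numeric predictions.
#' @param Y_tau nominal threshold.
#' @param Y_tau0 tuned threshold (nonzero).
#' @return adjusted predictions, same names as `y_hat`.
#' @export
adjust_predictions <- function(y_hat, Y_tau, Y_tau0) {
  if (!is.finite(Y_tau0) || Y_tau0 == 0)
    stop("`Y_tau0` must be finite and nonzero", call. = FALSE)
  if (sign(Y_tau) != sign(Y_tau0))
    warning("Y_tau and Y_tau0 differ in sign: the classification ",
            "equivalence with the rescaled rule does not hold")
  y_hat * (Y_tau / Y_tau0)
}
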