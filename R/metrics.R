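#' Confusion matrix for binary top-line classification
#'
#' The positive class is 1 (top line).
#'
#' @param observed observed labels: [binary_labels()] or 0/1 vector.
#' @param predicted predicted labels, same ids/length.
#' @return an object of class `confusion_matrix` with counts `TP`, `TN`,
#'   `FP`, `FN` and total `N`.
#' @export
confusion <- function(observed, predicted) {
  oid <- NULL
  if (inherits(observed, "binary_labels")) {
    oid <- observed$line_ids; observed <- observed$labels
  }
  pid <- NULL
  if (inherits(predicted, "binary_labels")) {
    pid <- predicted$line_ids; predicted <- predicted$labels
  }
  if (length(observed) != length(predicted))
    stop("observed and predicted lengths differ", call. = FALSE)
  if (!is.null(oid) && !is.null(pid) && !identical(oid, pid))
    stop("observed and predicted line ids differ (align first)",
         call. = FALSE)
  stopifnot(all(observed %in% 0:1), all(predicted %in% 0:1))
  structure(list(
    TP = sum(observed == 1 & predicted == 1),
    TN = sum(observed == 0 & predicted == 0),
    FP = sum(observed == 0 & predicted == 1),
    FN = sum(observed == 1 & predicted == 0),
    N = length(observed)), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("confusion_matrix (N=%d): TP=%d FN=%d FP=%d TN=%d\n",
              x$N, x$TP, x$FN, x$FP, x$TN))
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Computes sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision
#' `TP/(TP+FP)`, F1 (harmonic mean of precision and sensitivity), and
#' Cohen's kappa `(P0 - Pe)/(1 - Pe)` with `P0 = (TP+TN)/N` and
#' `Pe = (TP+FN)/N * (TP+FP)/N + (FP+TN)/N * (FN+TN)/N`. Any metric whose
#' denominator is zero is `NA`, not 0 — e.g. precision (hence F1) when no
#' positives are predicted, or kappa when `Pe = 1`.
#'
#' @param cm a [confusion()] result.
#' @return an object of class `metric_set`: `sensitivity`, `specificity`,
#'   `precision`, `f1`, `kappa`, `p0`, `pe`.
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$N == 0) stop("empty confusion matrix", call. = FALSE)
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- div(cm$TP, cm$TP + cm$FN)
  spec <- div(cm$TN, cm$TN + cm$FP)
  prec <- div(cm$TP, cm$TP + cm$FP)
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_
        else 2 * prec * sens / (prec + sens)
  p0 <- (cm$TP + cm$TN) / cm$N
  pe <- (cm$TP + cm$FN) / cm$N * (cm$TP + cm$FP) / cm$N +
        (cm$FP + cm$TN) / cm$N * (cm$FN + cm$TN) / cm$N
  kappa <- if (pe == 1) NA_real_ else (p0 - pe) / (1 - pe)
  structure(list(sensitivity = sens, specificity = spec, precision = prec,
                 f1 = f1, kappa = kappa, p0 = p0, pe = pe),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf(
    "metric_set: sens=%.3f spec=%.3f prec=%.3f F1=%.3f kappa=%.3f\n",
    x$sensitivity, x$specificity, x$precision, x$f1, x$kappa))
  invisible(x)
}

#' Relative efficiency of one model's metric over another's
#'
#' `RE = metric_y / metric_z`; `RE > 1` favors model y, `RE < 1` model z,
#' `RE = 1` means both are equally efficient.
#'
#' @param metric_y metric of the numerator model.
#' @param metric_z metric of the denominator model.
#' @return the ratio, or `NA` (with a message) when the denominator is zero
#'   or either input is `NA`.
#' @export
relative_efficiency <- function(metric_y, metric_z) {
  if (is.na(metric_y) || is.na(metric_z)) {
    message("relative efficiency undefined: NA metric input")
    return(NA_real_)
  }
  if (metric_z == 0) {
    message("relative efficiency undefined: zero denominator metric")
    return(NA_real_)
  }
  metric_y / metric_z
}

#' Percent advantage of the better model over the worse
#'
#' `100 * (1 - worse/better)`: the share of the better model's metric that
#' the worse model fails to reach. This is the convention used when naming
#' the better model first (e.g. "model R outperformed model B by 43.9%"
#' for specificities 0.970 vs 0.544).
#'
#' @param better metric of the better model (must be positive).
#' @param worse metric of the worse model.
#' @return percentage on the 0-100 scale.
#' @export
percent_advantage <- function(better, worse) {
  if (is.na(better) || !is.finite(better) || better <= 0)
    stop("`better` must be a positive finite metric", call. = FALSE)
  100 * (1 - worse / better)
}

#' Summarize per-fold metrics into a comparison table
#'
#' For each metric and model: the mean over folds ignoring `NA` (with the
#' `NA` count reported), the standard error `sd/sqrt(#non-NA)`, and
#' t-distribution interval bounds `mean -/+ t(0.975, df) * SE`. Relative
#' efficiencies are computed on the fold-mean metrics for every ordered
#' model pair.
#'
#' @param per_fold either a list of lists of `metric_set` (one list per
#'   model, folds within) or, for a single model, a list of `metric_set`.
#' @param models character model labels (e.g. `c("R", "B", "RO")`).
#' @param conf confidence level for the interval (default 0.95).
#' @return list with `summary` (data.frame: metric, model, mean, SE, LL, UL,
#'   n_folds, n_na) and `re` (data.frame: metric, model_y, model_z, RE,
#'   percent_advantage).
#' @export
summarize_folds <- function(per_fold, models, conf = 0.95) {
  if (length(models) == 1 && inherits(per_fold[[1]], "metric_set"))
    per_fold <- list(per_fold)
  stopifnot(length(per_fold) == length(models))
  metric_names <- c("sensitivity", "specificity", "precision", "f1", "kappa")
  rows <- list()
  means <- list()
  for (m in seq_along(models)) {
    folds <- per_fold[[m]]
    if (length(folds) < 2)
      stop("need at least 2 folds per model", call. = FALSE)
    for (met in metric_names) {
      v <- vapply(folds, function(f) f[[met]], numeric(1))
      ok <- v[!is.na(v)]
      if (length(ok) == 0) {
        mu <- se <- ll <- ul <- NA_real_
      } else {
        mu <- mean(ok)
        se <- if (length(ok) > 1) stats::sd(ok) / sqrt(length(ok)) else 0
        tq <- if (length(ok) > 1)
          stats::qt(1 - (1 - conf) / 2, df = length(ok) - 1) else NA_real_
        ll <- mu - tq * se
        ul <- mu + tq * se
      }
      rows[[length(rows) + 1]] <- data.frame(
        metric = met, model = models[m], mean = mu, SE = se, LL = ll,
        UL = ul, n_folds = length(v), n_na = sum(is.na(v)))
      means[[paste(met, models[m])]] <- mu
    }
  }
  re_rows <- list()
  for (met in metric_names) {
    for (y in models) for (z in setdiff(models, y)) {
      my <- means[[paste(met, y)]]
      mz <- means[[paste(met, z)]]
      re <- if (is.na(my) || is.na(mz) || mz == 0) NA_real_ else my / mz
      pa <- if (!is.na(my) && !is.na(mz) && my > 0) 100 * (1 - mz / my)
            else NA_real_
      re_rows[[length(re_rows) + 1]] <- data.frame(
        metric = met, model_y = y, model_z = z, RE = re,
        percent_advantage = pa)
    }
  }
  list(summary = do.call(rbind, rows), re = do.call(rbind, re_rows))
}
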