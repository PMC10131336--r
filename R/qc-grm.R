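#' Quality-filter markers on MAF, missingness and heterozygosity
#'
#' A marker is retained when its minor allele frequency is at least
#' `maf_min`, its missing fraction is below `max_missing`, and its
#' heterozygote fraction is below `max_het`. MAF is computed from the
#' non-missing dosages as `p = mean(dosage)/2`, `MAF = min(p, 1 - p)`;
#' heterozygosity is the fraction of non-missing calls equal to 1. The
#' heterozygosity filter only applies to raw diploid calls; for matrices
#' already imputed to real values it is skipped with a warning.
#'
#' @param M a [marker_matrix()].
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param max_missing maximum tolerated missing fraction (default 0.50,
#'   exclusive).
#' @param max_het maximum tolerated heterozygosity (default 0.05, exclusive).
#' @return list with the filtered `markers` and a `report` of class
#'   `marker_qc_report` (counts in/out and per-filter removal counts).
#' @export
filter_markers <- function(M, maf_min = 0.05, max_missing = 0.50,
                           max_het = 0.05) {
  stopifnot(inherits(M, "marker_matrix"))
  for (th in c(maf_min, max_missing, max_het))
    if (!is.finite(th) || th < 0 || th > 1)
      stop("QC thresholds must lie in [0, 1]", call. = FALSE)
  X <- unclass(M)
  n_obs <- colSums(!is.na(X))
  p <- colMeans(X, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[n_obs == 0] <- 0
  miss_frac <- colMeans(is.na(X))
  imputed <- isTRUE(attr(M, "imputed"))
  if (imputed) {
    warning("heterozygosity filter skipped: matrix holds imputed ",
            "real-valued dosages")
    het_frac <- rep(0, ncol(X))
  } else {
    het_frac <- colSums(X == 1, na.rm = TRUE) / pmax(n_obs, 1)
  }
  fail_maf <- maf < maf_min
  fail_miss <- miss_frac >= max_missing
  fail_het <- het_frac >= max_het
  keep <- !(fail_maf | fail_miss | fail_het)
  if (!any(keep))
    stop("all markers removed by QC; relax maf_min/max_missing/max_het",
         call. = FALSE)
  report <- structure(list(
    n_markers_in = ncol(X), n_markers_out = sum(keep),
    removed_maf = sum(fail_maf), removed_missing = sum(fail_miss),
    removed_het = sum(fail_het), removed_total = sum(!keep),
    thresholds = c(maf_min = maf_min, max_missing = max_missing,
                   max_het = max_het),
    het_filter_applied = !imputed), class = "marker_qc_report")
  list(markers = marker_matrix(X[, keep, drop = FALSE], imputed = imputed),
       report = report)
}

#' @export
print.marker_qc_report <- function(x, ...) {
  cat(sprintf(
    paste0("marker QC: %d -> %d markers (removed %d: maf %d, missing %d,",
           " het %d%s)\n"),
    x$n_markers_in, x$n_markers_out, x$removed_total, x$removed_maf,
    x$removed_missing, x$removed_het,
    if (x$het_filter_applied) "" else " [het filter skipped]"))
  invisible(x)
}

#' Replace missing dosages by the marker mean
#'
#' Each missing cell is replaced by the non-missing mean of its marker
#' column (a real value). This is deliberately simple preprocessing; users
#' wanting LD-aware imputation should pre-impute externally.
#'
#' @param M a [marker_matrix()].
#' @return a [marker_matrix()] without missing values, flagged as imputed.
#' @export
impute_missing_mean <- function(M) {
  stopifnot(inherits(M, "marker_matrix"))
  X <- unclass(M)
  if (!anyNA(X)) return(M)
  n_obs <- colSums(!is.na(X))
  if (any(n_obs == 0))
    stop("fully-missing marker(s): ",
         paste(utils::head(colnames(X)[n_obs == 0], 5), collapse = ", "),
         " (filter first)", call. = FALSE)
  mu <- colMeans(X, na.rm = TRUE)
  idx <- which(is.na(X), arr.ind = TRUE)
  X[idx] <- mu[idx[, 2]]
  marker_matrix(X, imputed = TRUE)
}

#' VanRaden genomic relationship matrix
#'
#' With per-marker allele frequency `p_k = mean(dosage_k)/2` and
#' column-centered dosages `W = dosages - 2 p_k`, returns
#' `G = W W' / (2 * sum(p_k (1 - p_k)))`.
#'
#' @param M a [marker_matrix()] with no missing values (impute first).
#' @return a [kinship_matrix()].
#' @export
compute_grm <- function(M) {
  stopifnot(inherits(M, "marker_matrix"))
  X <- unclass(M)
  if (anyNA(X))
    stop("missing dosages: run impute_missing_mean() first", call. = FALSE)
  if (ncol(X) < 1) stop("need at least one marker", call. = FALSE)
  p <- colMeans(X) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    stop("all markers monomorphic: VanRaden denominator is zero",
         call. = FALSE)
  W <- sweep(X, 2, 2 * p)
  G <- tcrossprod(W) / denom
  G <- (G + t(G)) / 2
  kinship_matrix(G, check = FALSE)
}
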