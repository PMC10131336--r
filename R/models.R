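#' MCMC settings for the Bayesian samplers
#'
#' Defaults mirror common practice for Gibbs-sampled whole-genome regression:
#' 6,000 iterations, 1,000 burn-in, thinning 5, scaled-inverse-chi-square
#' variance priors with 5 degrees of freedom and scales matched to the sample
#' variance split evenly between genomic and residual components
#' (`r2 = 0.5`).
#'
#' @param n_iter total Gibbs iterations.
#' @param burn_in discarded iterations (`burn_in < n_iter`).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed integer RNG seed, or `NULL` to use the current RNG state.
#' @param df0 prior degrees of freedom for both variance components.
#' @param r2 prior fraction of phenotypic variance assigned to the genomic
#'   component when setting prior scales.
#' @return an object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 6000, burn_in = 1000, thin = 5, seed = NULL,
                        df0 = 5, r2 = 0.5) {
  stopifnot(n_iter >= 1, burn_in >= 0, burn_in < n_iter, thin >= 1,
            df0 > 0, r2 > 0, r2 < 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = seed, df0 = df0, r2 = r2),
            class = "mcmc_config")
}

# Align a phenotype input (phenotype_table or named vector, NA = masked test
# line) to the kinship ids; lines in K absent from y are treated as masked.
align_response <- function(y, K) {
  ids <- rownames(K)
  yv <- if (inherits(y, "phenotype_table")) pheno_values(y) else y
  if (is.null(names(yv)))
    stop("`y` must be a phenotype_table or a named vector", call. = FALSE)
  unknown <- setdiff(names(yv), ids)
  if (length(unknown))
    stop("phenotyped line(s) missing from K: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  out <- stats::setNames(rep(NA_real_, length(ids)), ids)
  out[names(yv)] <- yv
  out
}

# Eigendecomposition of K with a PSD check; small negative eigenvalues are
# clamped to zero, anything worse errors.
eigen_kinship <- function(K) {
  e <- eigen(unclass(K), symmetric = TRUE)
  mx <- max(abs(e$values), 1)
  if (min(e$values) < -1e-6 * mx)
    stop("K is not positive semidefinite beyond jitter tolerance",
         call. = FALSE)
  e$values[e$values < 0] <- 0
  e
}

#' Fit the GBLUP regression model
#'
#' The model is `Y_i = mu + g_i + e_i` with `g ~ N(0, sigma_g^2 G)` and
#' independent residuals. Two fitting modes are provided:
#' \describe{
#'   \item{`gibbs`}{full Bayesian fit. G is eigendecomposed once and the
#'     sampler draws `(mu, g, sigma^2, sigma_g^2)`; phenotypes of masked
#'     (test) lines are imputed each sweep from their conditional normal, so
#'     test lines obtain genomic values inside one joint model.}
#'   \item{`blup_deterministic`}{REML estimation of the variance components
#'     by 1-D profile likelihood over `lambda = sigma^2/sigma_g^2` on the
#'     eigenspectrum of the observed block, followed by the closed-form BLUP
#'     `g_all = G[, obs] (G[obs, obs] + lambda I)^-1 (y_obs - mu)`. This is
#'     the exact conditional posterior mean of the Gibbs model at the REML
#'     variance estimates, and is fast and deterministic.}
#' }
#'
#' @param y phenotypes: a [phenotype_table()] or a named numeric vector.
#'   `NA` (or absence from `y`) masks a line as unobserved; masked lines
#'   still receive genomic predictions.
#' @param K a [kinship_matrix()] covering all lines (training and test).
#' @param cfg an [mcmc_config()] (used in `gibbs` mode).
#' @param mode `"gibbs"` or `"blup_deterministic"`.
#' @param lambda optional fixed variance ratio `sigma^2/sigma_g^2` for
#'   `blup_deterministic`; `NULL` estimates it by REML.
#' @param keep_draws keep per-line posterior draws (gibbs mode; memory!).
#' @param min_obs minimum number of observed phenotypes (default 20).
#' @return an object of class `gblup_fit` with elements `mu`, `g_hat`
#'   (named, all lines), `sigma2_e`, `sigma2_g`, `h2_draws` (gibbs),
#'   `train_ids`, `all_ids`, `mode`, `mcmc_meta`.
#' @export
fit_gblup <- function(y, K, cfg = mcmc_config(),
                      mode = c("gibbs", "blup_deterministic"), lambda = NULL,
                      keep_draws = FALSE, min_obs = 20) {
  mode <- match.arg(mode)
  stopifnot(inherits(K, "kinship_matrix"))
  yv <- align_response(y, K)
  obs <- which(!is.na(yv))
  if (length(obs) < min_obs)
    stop("need at least ", min_obs, " observed phenotypes (got ",
         length(obs), ")", call. = FALSE)
  ids <- rownames(K)

  if (mode == "blup_deterministic")
    return(fit_gblup_reml(yv, K, lambda))

  e <- eigen_kinship(K)
  vy <- stats::var(yv[obs])
  S0e <- vy * (1 - cfg$r2)
  S0g <- vy * cfg$r2 / mean(diag(K))
  yinit <- yv
  yinit[-obs] <- mean(yv[obs])
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  res <- gblup_gibbs_cpp(yinit, miss = setdiff(seq_along(yv), obs) - 1L,
                         U = e$vectors, d = e$values,
                         n_iter = cfg$n_iter, burn_in = cfg$burn_in,
                         thin = cfg$thin, df0 = cfg$df0, S0e = S0e,
                         S0g = S0g, update_var = TRUE,
                         s2e_init = S0e, s2g_init = S0g,
                         keep_draws = keep_draws)
  out <- list(mu = res$mu,
              g_hat = stats::setNames(as.numeric(res$g_mean), ids),
              g_mc_var = stats::setNames(as.numeric(res$g_var), ids),
              sigma2_e = mean(res$s2e_draws),
              sigma2_g = mean(res$s2g_draws),
              h2_draws = res$s2g_draws * mean(diag(K)) /
                (res$s2g_draws * mean(diag(K)) + res$s2e_draws),
              n_keep = res$n_keep,
              train_ids = ids[obs], all_ids = ids, mode = "gibbs",
              mcmc_meta = cfg)
  if (keep_draws) out$g_draws <- res$g_draws
  structure(out, class = "gblup_fit")
}

# REML via profile likelihood over lambda on the eigenspectrum of G_obs.
fit_gblup_reml <- function(yv, K, lambda = NULL) {
  ids <- rownames(K)
  obs <- which(!is.na(yv))
  Gobs <- unclass(K)[obs, obs, drop = FALSE]
  e <- eigen(Gobs, symmetric = TRUE)
  mx <- max(abs(e$values), 1)
  if (min(e$values) < -1e-6 * mx)
    stop("K is not positive semidefinite beyond jitter tolerance",
         call. = FALSE)
  d <- pmax(e$values, 0)
  n <- length(obs)
  ys <- crossprod(e$vectors, yv[obs])          # rotated response
  xs <- crossprod(e$vectors, rep(1, n))        # rotated intercept column

  prof <- function(log_lambda) {
    lam <- exp(log_lambda)
    w <- 1 / (d + lam)
    xwx <- sum(w * xs^2)
    bhat <- sum(w * xs * ys) / xwx
    r <- ys - xs * bhat
    s2g <- sum(w * r^2) / (n - 1)
    # restricted log-likelihood up to a constant
    -0.5 * ((n - 1) * log(s2g) - sum(log(w)) + log(xwx) + (n - 1))
  }
  if (is.null(lambda)) {
    opt <- stats::optimize(prof, interval = c(-12, 12), maximum = TRUE,
                           tol = 1e-8)
    lambda <- exp(opt$maximum)
  }
  w <- 1 / (d + lambda)
  xwx <- sum(w * xs^2)
  mu <- sum(w * xs * ys) / xwx
  r <- ys - xs * mu
  s2g <- sum(w * r^2) / (n - 1)
  s2e <- lambda * s2g
  # g_all = G[, obs] (G_obs + lambda I)^-1 (y_obs - mu)
  alpha <- e$vectors %*% (w * r)
  g_all <- as.numeric(unclass(K)[, obs, drop = FALSE] %*% alpha)
  structure(list(mu = mu, g_hat = stats::setNames(g_all, ids),
                 sigma2_e = s2e, sigma2_g = s2g, lambda = lambda,
                 train_ids = ids[obs], all_ids = ids,
                 mode = "blup_deterministic", mcmc_meta = NULL),
            class = "gblup_fit")
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat(sprintf(
    "gblup_fit (%s): %d train / %d total lines, s2_g=%.4g, s2_e=%.4g\n",
    x$mode, length(x$train_ids), length(x$all_ids), x$sigma2_g, x$sigma2_e))
  invisible(x)
}

#' Continuous GBLUP predictions
#'
#' @param fit a `gblup_fit`.
#' @param ids line ids to predict (must be known to the fit).
#' @return named numeric vector `mu + g_hat[ids]`.
#' @export
predict_gblup <- function(fit, ids = fit$all_ids) {
  stopifnot(inherits(fit, "gblup_fit"))
  unknown <- setdiff(ids, fit$all_ids)
  if (length(unknown))
    stop("unknown line id(s): ", paste(utils::head(unknown, 5),
                                       collapse = ", "), call. = FALSE)
  fit$mu + fit$g_hat[ids]
}

#' Fit the Bayesian probit threshold (liability) model
#'
#' Binary class membership (1 = top line) is modelled as
#' `P(Y_b = 1 | g) = Phi(beta0 + g)`, arising from a latent liability
#' `l = beta0 + g + e` with `e ~ N(0, 1)` and class 1 exactly when `l > 0`.
#' `g ~ N(0, sigma_g^2 G)` as in the regression model; `beta0` has a flat
#' prior. Fitting uses Gibbs sampling with truncated-normal data
#' augmentation of the liabilities, updating `g` in the eigenbasis of G.
#'
#' @param yb binary labels: named 0/1 vector (or a `binary_labels` object),
#'   `NA`/absent lines masked as test lines. Both classes must be present
#'   among the observed labels.
#' @param K a [kinship_matrix()] covering all lines.
#' @param cfg an [mcmc_config()]. The prior scale for `sigma_g^2` is 1 on
#'   the liability scale.
#' @param keep_draws keep per-line posterior draws of `g`.
#' @return an object of class `tgblup_fit` with `beta0`, `beta0_draws`,
#'   `g_hat`, `proba` (posterior mean of `Phi(beta0 + g)` per line),
#'   `train_ids`, `all_ids`, `mcmc_meta`.
#' @export
fit_tgblup <- function(yb, K, cfg = mcmc_config(), keep_draws = FALSE) {
  stopifnot(inherits(K, "kinship_matrix"))
  if (inherits(yb, "binary_labels"))
    yb <- stats::setNames(yb$labels, yb$line_ids)
  yv <- align_response(yb, K)
  obs <- which(!is.na(yv))
  if (!all(yv[obs] %in% c(0, 1)))
    stop("labels must be 0/1", call. = FALSE)
  if (length(unique(yv[obs])) < 2)
    stop("degenerate binarization: observed labels are single-class ",
         "- raise tau or check the threshold", call. = FALSE)
  ids <- rownames(K)
  e <- eigen_kinship(K)
  ybi <- as.integer(yv)   # NA_integer_ for masked
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  res <- tgblup_gibbs_cpp(ybi, U = e$vectors, d = e$values,
                          n_iter = cfg$n_iter, burn_in = cfg$burn_in,
                          thin = cfg$thin, df0 = cfg$df0, S0g = 1,
                          keep_draws = keep_draws)
  out <- list(beta0 = res$beta0, beta0_draws = as.numeric(res$beta0_draws),
              g_hat = stats::setNames(as.numeric(res$g_mean), ids),
              proba = stats::setNames(as.numeric(res$phi_mean), ids),
              sigma2_g = mean(res$s2g_draws), n_keep = res$n_keep,
              train_ids = ids[obs], all_ids = ids, mcmc_meta = cfg)
  if (keep_draws) out$g_draws <- res$g_draws
  structure(out, class = "tgblup_fit")
}

#' @export
print.tgblup_fit <- function(x, ...) {
  cat(sprintf(
    "tgblup_fit: %d train / %d total lines, beta0=%.3f, s2_g=%.4g\n",
    length(x$train_ids), length(x$all_ids), x$beta0, x$sigma2_g))
  invisible(x)
}

#' Predicted class-1 probabilities from a probit threshold fit
#'
#' @param fit a `tgblup_fit`.
#' @param ids line ids to predict.
#' @param proba_mode `"posterior_mean_of_phi"` (default; the posterior
#'   predictive probability, averaging `Phi(beta0 + g)` over retained draws)
#'   or `"phi_of_posterior_mean"` (plug-in at the posterior means).
#' @return named numeric vector of probabilities in `[0, 1]`.
#' @export
predict_tgblup_proba <- function(fit, ids = fit$all_ids,
                                 proba_mode = c("posterior_mean_of_phi",
                                                "phi_of_posterior_mean")) {
  stopifnot(inherits(fit, "tgblup_fit"))
  proba_mode <- match.arg(proba_mode)
  unknown <- setdiff(ids, fit$all_ids)
  if (length(unknown))
    stop("unknown line id(s): ", paste(utils::head(unknown, 5),
                                       collapse = ", "), call. = FALSE)
  if (proba_mode == "posterior_mean_of_phi") fit$proba[ids]
  else stats::setNames(stats::pnorm(fit$beta0 + fit$g_hat[ids]), ids)
}

#' Serialize a model fit to JSON
#'
#' Writes scalars plus the per-line posterior-summary table in a plain JSON
#' layout (ids, g_hat, and probabilities where applicable).
#'
#' @param fit a `gblup_fit` or `tgblup_fit`.
#' @param path output path.
#' @export
write_fit_json <- function(fit, path) {
  x <- unclass(fit)
  x$g_draws <- NULL
  x$mcmc_meta <- if (!is.null(x$mcmc_meta)) unclass(x$mcmc_meta)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
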