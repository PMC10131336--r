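test_that("deterministic BLUP equals the closed-form ridge solve", {
  # fixed lambda: exact oracle equivalence on random instances up to n = 30
  for (seed in 1:8) {
    set.seed(300 + seed)
    n <- sample(10:30, 1)
    M <- random_marker_matrix(n + 5, 80, seed = 300 + seed)
    K <- compute_grm(M)
    y_all <- rnorm(n + 5, 10, 2)
    names(y_all) <- rownames(K)
    obs <- seq_len(n)
    lam <- runif(1, 0.2, 5)
    fit <- fit_gblup(y_all[obs], K, mode = "blup_deterministic",
                     lambda = lam, min_obs = 5)
    oracle <- blup_closed_form(unclass(K), y_all[obs], obs, lam)
    expect_equal(unname(fit$g_hat), oracle$g, tolerance = 1e-8)
    expect_equal(fit$mu, oracle$mu, tolerance = 1e-8)
  }
})

test_that("REML-estimated lambda also reproduces its own closed form", {
  fx <- fixture6()
  fit <- fit_gblup(fx$y, fx$K, mode = "blup_deterministic", min_obs = 5)
  oracle <- blup_closed_form(unclass(fx$K), fx$y, 1:6, fit$lambda)
  expect_equal(unname(fit$g_hat), oracle$g, tolerance = 1e-8)
  expect_gt(fit$sigma2_e, 0)
  expect_gte(fit$sigma2_g, 0)
})

test_that("constant response gives no genomic signal", {
  set.seed(1)
  I30 <- diag(30)
  dimnames(I30) <- list(paste0("L", 1:30), paste0("L", 1:30))
  K <- kinship_matrix(I30, check = FALSE)
  y <- setNames(rep(5, 30) + rnorm(30, 0, 1e-8), rownames(K))
  fit <- fit_gblup(y, K, mode = "blup_deterministic")
  expect_equal(fit$mu, 5, tolerance = 1e-4)
  expect_lt(max(abs(fit$g_hat)), 1e-4)
})

test_that("gblup predictions are mu + g and reject unknown ids", {
  fx <- fixture6()
  fit <- fit_gblup(fx$y, fx$K, mode = "blup_deterministic", min_obs = 5)
  expect_equal(predict_gblup(fit, "L3"),
               setNames(fit$mu + fit$g_hat["L3"], "L3"))
  expect_error(predict_gblup(fit, "nope"), "unknown line id")
})

test_that("identical kinship rows give identical held-out predictions", {
  set.seed(11)
  X <- matrix(rbinom(8 * 60, 2, 0.5), 8, 60)
  X <- rbind(X, X[8, ]) # line 9 duplicates line 8
  rownames(X) <- paste0("L", 1:9)
  colnames(X) <- paste0("M", 1:60)
  K <- compute_grm(marker_matrix(X))
  y <- setNames(rnorm(7, 10), paste0("L", 1:7))
  fit <- fit_gblup(y, K, mode = "blup_deterministic", min_obs = 5)
  p <- predict_gblup(fit, c("L8", "L9"))
  expect_equal(unname(p[1]), unname(p[2]), tolerance = 1e-10)
})

test_that("Gibbs GBLUP with fixed variances converges to the BLUP mean", {
  fx <- sim_small(n = 100, p = 250, seed = 21)
  y <- pheno_values(fx$pheno)
  det <- fit_gblup(y, fx$K, mode = "blup_deterministic")
  lam <- det$lambda
  # run the sampler at the REML variances, no variance updates
  e <- eigen(unclass(fx$K), symmetric = TRUE)
  e$values[e$values < 0] <- 0
  set.seed(99)
  res <- toplineGS:::gblup_gibbs_cpp(
    y, miss = integer(0), U = e$vectors, d = e$values,
    n_iter = 4000, burn_in = 1000, thin = 2, df0 = 5,
    S0e = det$sigma2_e, S0g = det$sigma2_g, update_var = FALSE,
    s2e_init = det$sigma2_e, s2g_init = det$sigma2_g, keep_draws = FALSE)
  mc_se <- sqrt(res$g_var / res$n_keep)
  # allow generous autocorrelation inflation: 3 SE with an ESS fudge of 5
  diff <- abs(as.numeric(res$g_mean) - unname(det$g_hat))
  expect_gt(mean(diff <= 3 * sqrt(5) * mc_se + 1e-3), 0.95)
})

test_that("gibbs fits are seed-reproducible bit-identically", {
  fx <- sim_small(n = 80, p = 200, seed = 23)
  y <- pheno_values(fx$pheno)
  cfg <- mcmc_config(n_iter = 600, burn_in = 100, thin = 2, seed = 5)
  f1 <- fit_gblup(y[1:60], fx$K, cfg = cfg, min_obs = 10)
  f2 <- fit_gblup(y[1:60], fx$K, cfg = cfg, min_obs = 10)
  expect_identical(f1$g_hat, f2$g_hat)
  expect_identical(f1$sigma2_g, f2$sigma2_g)
  lb <- binarize(y, resolve_threshold(y, threshold_spec(tau = 0.7)))
  yb <- setNames(lb$labels, lb$line_ids)[1:60]
  t1 <- fit_tgblup(yb, fx$K, cfg = cfg)
  t2 <- fit_tgblup(yb, fx$K, cfg = cfg)
  expect_identical(t1$proba, t2$proba)
})

test_that("masked phenotypes are required to be few enough and K PSD", {
  fx <- fixture6()
  expect_error(fit_gblup(fx$y, fx$K, mode = "blup_deterministic"),
               "at least 20 observed")
  bad <- unclass(fx$K)
  bad[1, 2] <- bad[1, 2] + 5 # break PSD hard
  bad[2, 1] <- bad[1, 2]
  Kb <- kinship_matrix(bad, check = FALSE)
  expect_error(fit_gblup(fx$y, Kb, mode = "blup_deterministic",
                         min_obs = 5), "positive semidefinite")
})

test_that("probit threshold model rejects degenerate labels", {
  fx <- sim_small(n = 60, p = 100, seed = 29)
  ids <- rownames(fx$K)
  expect_error(fit_tgblup(setNames(rep(1, 40), ids[1:40]), fx$K),
               "single-class")
  expect_error(fit_tgblup(setNames(rep(0, 40), ids[1:40]), fx$K),
               "degenerate")
})

test_that("probit probabilities respect range, Phi(0), and monotonicity", {
  fx <- sim_small(n = 100, p = 250, h2 = 0.8, seed = 33)
  y <- pheno_values(fx$pheno)
  lb <- binarize(y, resolve_threshold(y, threshold_spec()))
  yb <- setNames(lb$labels, lb$line_ids)
  fit <- fit_tgblup(yb[1:80], fx$K,
                    cfg = mcmc_config(n_iter = 1500, burn_in = 300,
                                      thin = 2, seed = 3),
                    keep_draws = TRUE)
  p <- predict_tgblup_proba(fit)
  expect_true(all(p >= 0 & p <= 1))
  # eta = 0 for every draw -> probability exactly 0.5
  expect_equal(mean(pnorm(0)), 0.5)
  # order preservation: if g_i >= g_j in every draw, then P_i >= P_j
  gd <- fit$g_draws
  i <- which.max(fit$g_hat); j <- which.min(fit$g_hat)
  if (all(gd[, i] >= gd[, j])) expect_gte(p[i], p[j])
  # both probability modes exposed and broadly agree in ordering
  p2 <- predict_tgblup_proba(fit, proba_mode = "phi_of_posterior_mean")
  expect_gt(cor(p, p2, method = "spearman"), 0.95)
  expect_error(predict_tgblup_proba(fit, "ghost"), "unknown line id")
})

test_that("probit probabilities are permutation-equivariant", {
  fx <- sim_small(n = 60, p = 150, seed = 41)
  y <- pheno_values(fx$pheno)
  lb <- binarize(y, resolve_threshold(y, threshold_spec(tau = 0.7)))
  yb <- setNames(lb$labels, lb$line_ids)[1:50]
  cfg <- mcmc_config(n_iter = 800, burn_in = 200, thin = 2, seed = 17)
  fit <- fit_tgblup(yb, fx$K, cfg = cfg)
  # permute line order in K (and labels); probabilities follow the ids
  set.seed(1); perm <- sample(rownames(fx$K))
  Kp <- kinship_matrix(unclass(fx$K)[perm, perm], check = FALSE)
  fitp <- fit_tgblup(yb, Kp, cfg = cfg)
  expect_gt(cor(fit$proba[perm], fitp$proba[perm]), 0.9)
})

test_that("null labels on identity kinship give probabilities near prevalence", {
  set.seed(55)
  n <- 120
  In <- diag(n)
  dimnames(In) <- list(paste0("L", 1:n), paste0("L", 1:n))
  K <- kinship_matrix(In, check = FALSE)
  yb <- setNames(rep(c(0, 1), n / 2), rownames(K)) # balanced, independent
  fit <- fit_tgblup(yb, K, cfg = mcmc_config(n_iter = 1500, burn_in = 300,
                                             thin = 2, seed = 8))
  expect_lt(abs(mean(fit$proba) - 0.5), 0.1)
})

test_that("fit serialization writes valid JSON", {
  fx <- fixture6()
  fit <- fit_gblup(fx$y, fx$K, mode = "blup_deterministic", min_obs = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, path)
  x <- jsonlite::read_json(path)
  expect_equal(length(x$g_hat), 6)
  expect_equal(x$mode, "blup_deterministic")
})
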