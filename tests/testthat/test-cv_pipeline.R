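# fast settings shared across pipeline tests
fast_cfg <- function(..., seed = 2,
                     mcmc = mcmc_config(n_iter = 800, burn_in = 200,
                                        thin = 2)) {
  run_config(..., seed = seed, gblup_mode = "blup_deterministic",
             mcmc = mcmc, min_obs = 10)
}

test_that("fold plans partition lines and are seed-reproducible", {
  labels <- rbinom(100, 1, 0.2)
  p1 <- make_folds(100, outer_k = 5, inner_k = 10, seed = 7,
                   labels = labels)
  p2 <- make_folds(100, outer_k = 5, inner_k = 10, seed = 7,
                   labels = labels)
  expect_identical(p1, p2)
  expect_equal(as.vector(table(p1$outer)), rep(20, 5))
  for (f in 1:5) {
    tr <- which(p1$outer != f)
    inner <- p1$inner[[f]]
    expect_true(all(is.na(inner[p1$outer == f])))   # no test lines inside
    expect_setequal(which(!is.na(inner)), tr)       # inner covers training
    expect_equal(sort(unique(inner[tr])), 1:10)
  }
  expect_error(make_folds(8, outer_k = 5), "at least")
})

test_that("inner folds are stratified when strata allow, else warn", {
  set.seed(3)
  labels <- rbinom(200, 1, 0.3)
  p <- make_folds(200, 5, 10, seed = 1, labels = labels)
  expect_true(all(p$stratified))
  for (f in 1:5) {
    tr <- which(p$outer != f)
    pos_per_fold <- table(p$inner[[f]][tr][labels[tr] == 1])
    expect_lte(diff(range(pos_per_fold)), 1)
  }
  # scarce positives: fall back with warning
  rare <- c(rep(1, 5), rep(0, 95))
  w <- capture_warnings(pr <- make_folds(100, 5, 10, seed = 1,
                                         labels = rare))
  expect_true(all(grepl("unstratified", w)))
  expect_false(any(pr$stratified))
})

test_that("model R matches an independently scripted straight-line run", {
  fx <- sim_small(n = 90, p = 200, h2 = 0.8, seed = 51)
  y <- pheno_values(fx$pheno)
  cfg <- fast_cfg(models = "R", outer_k = 3, inner_k = 4, seed = 9)
  res <- gs_run(fx$K, fx$pheno, cfg)

  # independent script: same plan, fit -> predict -> threshold -> count
  glab <- as.integer(y >= quantile(y, 0.8, type = 7))
  plan <- make_folds(length(y), 3, 4, seed = 9, labels = glab)
  for (f in 1:3) {
    ids <- rownames(fx$K)
    te <- ids[plan$outer == f]; tr <- ids[plan$outer != f]
    Y_tau <- unname(quantile(y[tr], 0.8, type = 7))
    fit <- fit_gblup(y[tr], subset_k <- kinship_matrix(
      unclass(fx$K)[c(tr, te), c(tr, te)], check = FALSE), min_obs = 10,
      mode = "blup_deterministic")
    pred <- as.integer((fit$mu + fit$g_hat[te]) > Y_tau)
    obs <- as.integer(y[te] >= Y_tau)
    bf <- metrics_bruteforce(obs, pred)
    got <- res$per_fold$R[[f]]
    expect_equal(got$threshold$value, Y_tau)
    expect_equal(got$metrics$specificity, bf$specificity)
    expect_equal(got$metrics$sensitivity, bf$sensitivity)
    expect_equal(c(TP = got$confusion$TP, TN = got$confusion$TN,
                   FP = got$confusion$FP, FN = got$confusion$FN),
                 bf$counts)
  }
})

test_that("no test-set leakage: test ids never touch fitting or tuning", {
  fx <- sim_small(n = 80, p = 150, seed = 53)
  res <- gs_run(fx$K, fx$pheno,
                fast_cfg(models = c("R", "RO"), outer_k = 4, inner_k = 3,
                         seed = 4))
  for (m in c("R", "RO")) for (r in res$per_fold[[m]]) {
    expect_length(intersect(r$test_ids, r$train_ids), 0)
    expect_setequal(c(r$test_ids, r$train_ids), rownames(fx$K))
  }
  # thresholds differ across folds since training subsets differ
  thr <- vapply(res$per_fold$R, function(r) r$threshold$value, numeric(1))
  expect_gt(length(unique(thr)), 1)
})

test_that("RO shares the refit with R and equals the rescaling identity", {
  fx <- sim_small(n = 90, p = 200, h2 = 0.8, seed = 55)
  res <- gs_run(fx$K, fx$pheno,
                fast_cfg(models = c("R", "RO"), outer_k = 3, inner_k = 4,
                         seed = 6))
  for (f in 1:3) {
    rR <- res$per_fold$R[[f]]; rRO <- res$per_fold$RO[[f]]
    expect_null(rRO$error)
    # continuous predictions bit-identical between R and RO
    expect_identical(rR$scores, rRO$scores)
    # classify(adjusted, Y_tau) == classify(raw, Y_tau0) for positive cuts
    expect_gt(rRO$cutoff, 0)
    adj <- adjust_predictions(rRO$scores, rR$cutoff, rRO$cutoff)
    expect_identical(classify(adj, rR$cutoff)$labels, rRO$predicted$labels)
    # tuned cutoff is below the nominal quantile threshold (shrinkage)
    expect_lte(rRO$cutoff, rR$cutoff)
  }
})

test_that("single-class outer training labels produce a recorded fold error", {
  fx <- sim_small(n = 60, p = 100, seed = 57)
  y <- pheno_values(fx$pheno)
  cfg <- fast_cfg(models = "B", outer_k = 3, inner_k = 3, seed = 2,
                  threshold = threshold_spec("fixed",
                                             value = max(y) + 1))
  res <- suppressWarnings(gs_run(fx$K, fx$pheno, cfg))
  errs <- vapply(res$per_fold$B, function(r) !is.null(r$error), logical(1))
  expect_true(all(errs))
  expect_match(res$per_fold$B[[1]]$error, "single-class")
})

test_that("identical config and seed give byte-identical output CSVs", {
  fx <- sim_small(n = 70, p = 150, seed = 59)
  cfg <- fast_cfg(models = c("R", "B", "RO"), outer_k = 3, inner_k = 3,
                  seed = 11,
                  mcmc = mcmc_config(n_iter = 400, burn_in = 100, thin = 2))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_metrics_csv(gs_run(fx$K, fx$pheno, cfg), f1)
  write_predictions_csv(gs_run(fx$K, fx$pheno, cfg), p2)
  r2 <- gs_run(fx$K, fx$pheno, cfg)
  write_metrics_csv(r2, f2)
  write_predictions_csv(r2, p1)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(p1), readLines(p2))
})

test_that("single-model wrappers agree with the joint run", {
  fx <- sim_small(n = 70, p = 150, h2 = 0.8, seed = 61)
  cfg <- fast_cfg(models = "R", outer_k = 3, inner_k = 3, seed = 5)
  solo <- run_model_R(list(K = fx$K, y = fx$pheno), cfg)
  joint <- gs_run(fx$K, fx$pheno, cfg)$per_fold$R
  expect_equal(vapply(solo, function(r) r$metrics$kappa, numeric(1)),
               vapply(joint, function(r) r$metrics$kappa, numeric(1)))
})

test_that("check-based thresholds resolve once and drive the whole run", {
  fx <- sim_small(n = 80, p = 150, seed = 63, n_checks = 4)
  checks <- pheno_values(fx$pheno)[fx$pheno$check_ids]
  res <- gs_run(fx$K, fx$pheno,
                fast_cfg(models = "R", outer_k = 3, inner_k = 3, seed = 3,
                         threshold = threshold_spec("check_mean")))
  thr <- vapply(res$per_fold$R, function(r) r$threshold$value, numeric(1))
  expect_true(all(thr == mean(checks)))
})

test_that("comparison tables and compare_models expose RE per model pair", {
  fx <- sim_small(n = 80, p = 200, h2 = 0.8, seed = 65)
  res <- gs_run(fx$K, fx$pheno,
                fast_cfg(models = c("R", "RO"), outer_k = 3, inner_k = 4,
                         seed = 8))
  cmp <- compare_models(res)
  expect_setequal(unique(cmp$summary$model), c("R", "RO"))
  re_row <- cmp$re[cmp$re$metric == "sensitivity" &
                     cmp$re$model_y == "RO" & cmp$re$model_z == "R", ]
  sens <- setNames(cmp$summary$mean[cmp$summary$metric == "sensitivity"],
                   cmp$summary$model[cmp$summary$metric == "sensitivity"])
  if (sens["R"] > 0)
    expect_equal(re_row$RE, unname(sens["RO"] / sens["R"]))
})
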