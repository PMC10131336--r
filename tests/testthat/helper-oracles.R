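# Independent oracles and small fixture builders used across the suite.
# Each oracle is a deliberately naive re-implementation kept separate from
# the package's code path.

# build a marker_matrix from a plain matrix with auto ids
mm <- function(X, imputed = FALSE) {
  if (is.null(rownames(X))) rownames(X) <- paste0("L", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- paste0("M", seq_len(ncol(X)))
  marker_matrix(X, imputed = imputed)
}

random_marker_matrix <- function(n, p, seed, missing_rate = 0) {
  set.seed(seed)
  freq <- runif(p, 0.1, 0.9)
  X <- vapply(freq, function(q) rbinom(n, 2, q), numeric(n))
  if (missing_rate > 0) X[runif(length(X)) < missing_rate] <- NA_real_
  mm(X)
}

# VanRaden GRM by explicit double loop
grm_bruteforce <- function(X) {
  p <- colMeans(X) / 2
  W <- sweep(X, 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  n <- nrow(X)
  G <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    G[i, j] <- sum(W[i, ] * W[j, ]) / denom
  G
}

# metrics recomputed directly from label vectors, no confusion() involved
metrics_bruteforce <- function(obs, pred) {
  tp <- sum(obs == 1 & pred == 1); tn <- sum(obs == 0 & pred == 0)
  fp <- sum(obs == 0 & pred == 1); fn <- sum(obs == 1 & pred == 0)
  n <- length(obs)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_
        else 2 * prec * sens / (prec + sens)
  p0 <- (tp + tn) / n
  pe <- (tp + fn) / n * (tp + fp) / n + (fp + tn) / n * (fn + tn) / n
  kap <- if (pe == 1) NA_real_ else (p0 - pe) / (1 - pe)
  list(sensitivity = sens, specificity = spec, precision = prec, f1 = f1,
       kappa = kap, counts = c(TP = tp, TN = tn, FP = fp, FN = fn))
}

# exhaustive cutoff search over the same candidate set, scanned naively
cutoff_bruteforce <- function(scores, labels) {
  s <- sort(unique(scores))
  gap <- if (length(s) > 1) min(diff(s)) else 1
  cand <- c(s[1] - gap, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
            s[length(s)] + gap)
  best <- Inf; best_c <- NA
  for (cc in cand) {
    pred <- as.integer(scores > cc)
    m <- metrics_bruteforce(labels, pred)
    o <- (m$sensitivity - m$specificity)^2
    if (o < best - 1e-12) { best <- o; best_c <- cc }
  }
  list(value = best_c, objective = best)
}

# closed-form generalized ridge/BLUP solve at fixed lambda via dense algebra
blup_closed_form <- function(G, y_obs, obs_idx, lambda) {
  Gobs <- G[obs_idx, obs_idx]
  V <- Gobs + lambda * diag(length(obs_idx))
  Vi <- solve(V)
  one <- rep(1, length(obs_idx))
  mu <- as.numeric((t(one) %*% Vi %*% y_obs) / (t(one) %*% Vi %*% one))
  g <- as.numeric(G[, obs_idx] %*% Vi %*% (y_obs - mu))
  list(mu = mu, g = g)
}

# small deterministic GBLUP fixture: 6 lines, fixed G and y
fixture6 <- function() {
  set.seed(42)
  X <- matrix(rbinom(6 * 40, 2, 0.4), 6, 40,
              dimnames = list(paste0("L", 1:6), paste0("M", 1:40)))
  K <- compute_grm(mm(X))
  y <- setNames(c(8.1, 9.5, 10.2, 11.3, 9.9, 12.0), rownames(K))
  list(K = K, y = y)
}

sim_small <- function(n = 120, p = 300, h2 = 0.5, seed = 7, ...) {
  cfg <- sim_config(n_lines = n, n_markers = p, h2 = h2, seed = seed, ...)
  b <- make_benchmark(cfg)
  M <- impute_missing_mean(b$markers)
  list(K = compute_grm(M), pheno = b$pheno, truth = b$truth, cfg = cfg,
       markers = b$markers)
}
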