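#' Configuration for the synthetic genotype/phenotype simulator
#'
#' Defaults emulate the shape of an elite-yield-trial wheat panel: 500 lines
#' by 1,000 biallelic GBS-style markers with minor allele frequency at least
#' 0.05, an additive polygenic trait at heritability 0.5, and roughly 20% of
#' lines in the top class at the `tau = 0.8` quantile threshold.
#'
#' @param n_lines number of lines.
#' @param n_markers number of biallelic markers.
#' @param maf_range allele-frequency band (subset of (0, 0.5]) from which
#'   per-marker minor allele frequencies are drawn uniformly.
#' @param inbreeding inbreeding coefficient F in [0, 1]: each genotype is
#'   homozygous (dosage 0 or 2) with probability F and a Hardy-Weinberg
#'   Binomial(2, p) draw otherwise. The default 0.95 emulates inbred wheat
#'   breeding lines, whose residual heterozygosity is what makes a 5%
#'   heterozygosity QC filter sensible; set `inbreeding = 0` for an
#'   outbred Hardy-Weinberg population.
#' @param n_qtl number of causal markers (must be >= 1 unless `h2 = 0`).
#' @param h2 narrow-sense heritability target in [0, 1].
#' @param tau quantile defining the true top-line set.
#' @param n_checks number of check lines (simulated near a high quantile to
#'   exercise check-based thresholds).
#' @param check_quantile phenotype quantile the checks sit near.
#' @param missing_rate fraction of genotype cells masked as missing.
#' @param seed integer seed; all simulator output is reproducible from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_lines = 500, n_markers = 1000,
                       maf_range = c(0.05, 0.5), inbreeding = 0.95,
                       n_qtl = 100, h2 = 0.5,
                       tau = 0.8, n_checks = 0, check_quantile = 0.9,
                       missing_rate = 0, seed = 1) {
  stopifnot(n_lines >= 2, n_markers >= 1, n_qtl <= n_markers,
            h2 >= 0, h2 <= 1, tau > 0, tau < 1,
            inbreeding >= 0, inbreeding <= 1,
            missing_rate >= 0, missing_rate < 1)
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must be an increasing pair within (0, 0.5]",
         call. = FALSE)
  if (h2 > 0 && n_qtl < 1)
    stop("a heritable trait needs at least one causal marker (n_qtl >= 1)",
         call. = FALSE)
  structure(list(n_lines = as.integer(n_lines),
                 n_markers = as.integer(n_markers), maf_range = maf_range,
                 inbreeding = inbreeding,
                 n_qtl = as.integer(n_qtl), h2 = h2, tau = tau,
                 n_checks = as.integer(n_checks),
                 check_quantile = check_quantile,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate biallelic marker dosages
#'
#' Per marker, a minor allele frequency is drawn uniformly from
#' `maf_range` and randomly assigned to either allele; per line, the
#' genotype is homozygous `2 * Bernoulli(p)` with probability `inbreeding`
#' and a Hardy-Weinberg `Binomial(2, p)` draw otherwise (no LD). Missing
#' cells are masked at `missing_rate`.
#'
#' @param cfg a [sim_config()].
#' @return a [marker_matrix()].
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  maf <- stats::runif(cfg$n_markers, cfg$maf_range[1], cfg$maf_range[2])
  flip <- stats::runif(cfg$n_markers) < 0.5
  p <- ifelse(flip, 1 - maf, maf)   # ALT-allele frequency
  X <- vapply(p, function(pk) {
    hw <- stats::rbinom(cfg$n_lines, 2, pk)
    hom <- 2 * stats::rbinom(cfg$n_lines, 1, pk)
    ifelse(stats::runif(cfg$n_lines) < cfg$inbreeding, hom, hw)
  }, numeric(cfg$n_lines))
  dimnames(X) <- list(sprintf("L%04d", seq_len(cfg$n_lines)),
                      sprintf("M%05d", seq_len(cfg$n_markers)))
  if (cfg$missing_rate > 0) {
    mask <- stats::runif(length(X)) < cfg$missing_rate
    X[mask] <- NA_real_
  }
  marker_matrix(X)
}

#' Simulate an additive polygenic trait with known ground truth
#'
#' `n_qtl` causal markers receive independent standard-normal effects; the
#' true genetic value is the centered causal score, and residual variance is
#' set to `var(g) * (1 - h2) / h2` so the realized heritability matches the
#' target (at `h2 = 0` the genetic score contributes nothing and the
#' residual variance is 1). The phenotype is `10 + g + e`: the positive
#' intercept keeps quantile thresholds positive, the regime in which the
#' prediction-rescaling identity holds. Check lines, when requested, are
#' the lines nearest the `check_quantile` of the phenotype.
#'
#' @param M a [marker_matrix()] without missing values.
#' @param cfg a [sim_config()].
#' @return list with `pheno` (a [phenotype_table()]) and `truth` (causal
#'   ids and effects, `g_true`, realized h2, and the true top-line set at
#'   the configured `tau`).
#' @export
simulate_phenotypes <- function(M, cfg) {
  stopifnot(inherits(M, "marker_matrix"), inherits(cfg, "sim_config"))
  X <- unclass(M)
  if (anyNA(X)) stop("impute genotypes before simulating phenotypes",
                     call. = FALSE)
  set.seed(cfg$seed + 1L)
  n <- nrow(X)
  if (cfg$h2 > 0) {
    causal <- sort(sample.int(ncol(X), cfg$n_qtl))
    beta <- stats::rnorm(cfg$n_qtl)
    g <- as.numeric(X[, causal, drop = FALSE] %*% beta)
    g <- g - mean(g)
    vg <- stats::var(g)
    if (vg == 0)
      stop("causal markers are monomorphic; increase n_qtl or maf floor",
           call. = FALSE)
    ve <- if (cfg$h2 == 1) 0 else vg * (1 - cfg$h2) / cfg$h2
    y <- 10 + g + stats::rnorm(n, 0, sqrt(ve))
  } else {
    causal <- integer(0)
    beta <- numeric(0)
    g <- as.numeric(scale(stats::rnorm(n), scale = FALSE)) * 0
    y <- 10 + stats::rnorm(n, 0, 1)
  }
  names(y) <- rownames(X)
  names(g) <- rownames(X)
  check_ids <- character()
  if (cfg$n_checks > 0) {
    target <- stats::quantile(y, cfg$check_quantile, type = 7)
    check_ids <- names(sort(abs(y - target))[seq_len(cfg$n_checks)])
  }
  Y_tau <- unname(stats::quantile(y, cfg$tau, type = 7))
  truth <- list(causal_ids = colnames(X)[causal], effects = beta,
                g_true = g,
                realized_h2 = if (cfg$h2 > 0) stats::var(g) / stats::var(y)
                              else 0,
                tau = cfg$tau, Y_tau = Y_tau,
                top_ids = names(y)[y >= Y_tau])
  list(pheno = phenotype_table(rownames(X), y, trait_name = "sim_trait",
                               check_ids = check_ids),
       truth = truth)
}

#' Generate and write a complete benchmark bundle
#'
#' Simulates genotypes and phenotypes, optionally writes them in the
#' package's standard file formats (genotypes/phenotypes CSV, truth and
#' config JSON), and returns the in-memory objects.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory, or `NULL` to skip writing.
#' @return list with `markers`, `pheno`, `truth`, `cfg` and (when written)
#'   `paths`.
#' @export
make_benchmark <- function(cfg = sim_config(), dir = NULL) {
  M <- simulate_genotypes(cfg)
  Mi <- impute_missing_mean(M)
  sim <- simulate_phenotypes(Mi, cfg)
  out <- list(markers = M, pheno = sim$pheno, truth = sim$truth, cfg = cfg)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    geno_path <- file.path(dir, "genotypes.csv")
    dt <- data.table::data.table(line_id = rownames(M))
    dt <- cbind(dt, data.table::as.data.table(unclass(M)))
    data.table::fwrite(dt, geno_path)
    pheno_path <- file.path(dir, "phenotypes.csv")
    data.table::fwrite(data.table::data.table(
      line_id = sim$pheno$line_ids, sim_trait = sim$pheno$values),
      pheno_path)
    truth_path <- file.path(dir, "truth.json")
    jsonlite::write_json(sim$truth, truth_path, auto_unbox = TRUE,
                         digits = NA)
    cfg_path <- file.path(dir, "config.json")
    jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE,
                         digits = NA)
    out$paths <- c(genotypes = geno_path, phenotypes = pheno_path,
                   truth = truth_path, config = cfg_path)
  }
  out
}
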