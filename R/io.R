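#' Read a marker dosage matrix from delimited text or VCF
#'
#' The delimited dialect is lines in rows and markers in columns: a header
#' row of marker ids and a first column of line ids. Missing calls may be
#' coded `NA`, empty, or `-9`. VCF input (v4.x, via the VariantAnnotation
#' package) converts biallelic genotype calls to ALT-allele dosage 0/1/2;
#' multi-allelic sites are skipped with a warning.
#'
#' @param path path to the genotype file.
#' @param format `"auto"` (by extension), `"delimited"` or `"vcf"`.
#' @param expected_line_ids optional character vector of known line ids; used
#'   to detect transposed delimited input (markers in rows), which is
#'   rejected with an explanatory error rather than silently transposed.
#' @return a [marker_matrix()].
#' @export
read_marker_matrix <- function(path, format = c("auto", "delimited", "vcf"),
                               expected_line_ids = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "delimited"
  if (format == "vcf") return(read_marker_vcf(path))

  dt <- data.table::fread(path, header = TRUE, na.strings = c("NA", "", "-9"),
                          data.table = FALSE)
  if (ncol(dt) < 2) stop("delimited genotype file needs an id column plus ",
                         "at least one marker column", call. = FALSE)
  ids <- as.character(dt[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicated line id(s) in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  mk <- colnames(dt)[-1]
  M <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(M)) {
    bad <- which(is.na(suppressWarnings(as.numeric(M))) & !is.na(M))
    rc <- arrayInd(bad[1], dim(M))
    stop(sprintf("non-numeric dosage '%s' at line '%s', marker '%s'",
                 M[bad[1]], ids[rc[1]], mk[rc[2]]), call. = FALSE)
  }
  dimnames(M) <- list(ids, mk)
  if (!is.null(expected_line_ids)) {
    row_hits <- mean(ids %in% expected_line_ids)
    col_hits <- mean(mk %in% expected_line_ids)
    if (col_hits > row_hits && col_hits > 0.5)
      stop("genotype file appears transposed (line ids found in the header ",
           "row): expected lines in rows and markers in columns",
           call. = FALSE)
  }
  marker_matrix(M)
}

# biallelic GT -> ALT dosage via VariantAnnotation; multi-allelic sites skipped
read_marker_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("reading VCF requires the VariantAnnotation package", call. = FALSE)
  vcf <- VariantAnnotation::readVcf(path)
  alt <- VariantAnnotation::alt(vcf)
  multi <- S4Vectors::elementNROWS(alt) != 1
  if (any(multi)) {
    warning(sum(multi), " multi-allelic site(s) skipped")
    vcf <- vcf[!multi]
  }
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field", call. = FALSE)
  dose <- function(x) {
    if (is.na(x) || x %in% c(".", "./.", ".|.")) return(NA_real_)
    al <- strsplit(x, "[/|]")[[1]]
    if (any(al == ".")) return(NA_real_)
    sum(al != "0")
  }
  M <- t(apply(gt, c(1, 2), dose)) # -> lines x markers
  dimnames(M) <- list(colnames(gt), rownames(gt))
  marker_matrix(M)
}

#' Read a phenotype table from delimited text
#'
#' First column: line ids; remaining columns: traits. `trait` selects the
#' column (default: the first trait column).
#'
#' @param path path to the delimited file.
#' @param trait trait column name; `NULL` uses the first non-id column.
#' @param check_ids optional character vector of check-line ids.
#' @return a [phenotype_table()].
#' @export
read_phenotype_table <- function(path, trait = NULL, check_ids = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, header = TRUE, na.strings = c("NA", ""),
                          data.table = FALSE)
  if (ncol(dt) < 2) stop("phenotype file needs an id column plus at least ",
                         "one trait column", call. = FALSE)
  if (is.null(trait)) trait <- colnames(dt)[2]
  if (!trait %in% colnames(dt))
    stop("trait '", trait, "' not found; available: ",
         paste(colnames(dt)[-1], collapse = ", "), call. = FALSE)
  phenotype_table(as.character(dt[[1]]), as.numeric(dt[[trait]]),
                  trait_name = trait,
                  check_ids = intersect(check_ids, as.character(dt[[1]])))
}

#' Restrict genotypes and phenotypes to their common lines
#'
#' Both objects are subset and reordered to the intersection of their line
#' ids, stable in marker-matrix order. Dropped ids are reported via
#' `message()`.
#'
#' @param M a [marker_matrix()].
#' @param P a [phenotype_table()].
#' @return list with elements `markers` and `pheno`.
#' @export
align_data <- function(M, P) {
  common <- intersect(rownames(M), P$line_ids)
  if (!length(common))
    stop("no line ids in common between genotypes and phenotypes",
         call. = FALSE)
  drop_m <- setdiff(rownames(M), common)
  drop_p <- setdiff(P$line_ids, common)
  if (length(drop_m))
    message(length(drop_m), " genotyped line(s) without phenotype dropped")
  if (length(drop_p))
    message(length(drop_p), " phenotyped line(s) without genotype dropped")
  keep <- rownames(M)[rownames(M) %in% common] # stable marker-matrix order
  M2 <- marker_matrix(unclass(M)[keep, , drop = FALSE],
                      imputed = isTRUE(attr(M, "imputed")))
  idx <- match(keep, P$line_ids)
  P2 <- phenotype_table(keep, P$values[idx], trait_name = P$trait_name,
                        check_ids = intersect(P$check_ids, keep))
  list(markers = M2, pheno = P2)
}
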