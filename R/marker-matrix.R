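#' Construct a marker dosage matrix
#'
#' A `marker_matrix` is a numeric matrix of allele dosages with lines in rows
#' and biallelic markers in columns. Row names are line identifiers, column
#' names are marker identifiers, and missing calls are `NA`. Raw matrices
#' carry integer dosages in \{0, 1, 2\} (count of the alternate allele);
#' after [impute_missing_mean()] entries may be real-valued and the matrix is
#' flagged as imputed.
#'
#' @param dosages numeric matrix, lines x markers, with unique row and column
#'   names; `NA` marks missing calls.
#' @param imputed logical; `TRUE` relaxes the \{0,1,2\} entry check for
#'   matrices whose missing cells have already been replaced by real values.
#' @return an object of class `marker_matrix`.
#' @export
marker_matrix <- function(dosages, imputed = FALSE) {
  if (!is.matrix(dosages) || !is.numeric(dosages))
    stop("`dosages` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(dosages)) || is.null(colnames(dosages)))
    stop("`dosages` needs line ids as rownames and marker ids as colnames",
         call. = FALSE)
  dup <- rownames(dosages)[duplicated(rownames(dosages))]
  if (length(dup))
    stop("duplicated line id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  dup <- colnames(dosages)[duplicated(colnames(dosages))]
  if (length(dup))
    stop("duplicated marker id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  if (!imputed) {
    bad <- which(!(dosages %in% c(0, 1, 2) | is.na(dosages)))
    if (length(bad)) {
      rc <- arrayInd(bad[1], dim(dosages))
      stop(sprintf(
        "dosage not in {0,1,2,NA}: value %s at line '%s', marker '%s'",
        format(dosages[bad[1]]), rownames(dosages)[rc[1]],
        colnames(dosages)[rc[2]]), call. = FALSE)
    }
  }
  structure(dosages, class = c("marker_matrix", class(dosages)),
            imputed = imputed)
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("marker_matrix: %d lines x %d markers (%d missing%s)\n",
              nrow(x), ncol(x), sum(is.na(x)),
              if (isTRUE(attr(x, "imputed"))) ", imputed" else ""))
  invisible(x)
}

#' Line identifiers of a genomic object
#' @param x a `marker_matrix`, `phenotype_table` or `kinship_matrix`.
#' @return character vector of line ids, in object order.
#' @export
line_ids <- function(x) UseMethod("line_ids")
#' @export
line_ids.marker_matrix <- function(x) rownames(x)
#' @export
line_ids.kinship_matrix <- function(x) rownames(x)
#' @export
line_ids.phenotype_table <- function(x) x$line_ids

#' Construct a phenotype table
#'
#' Holds one continuous trait value per line (e.g. grain-yield BLUEs across
#' environments), plus an optional set of check-line ids used for check-based
#' selection thresholds.
#'
#' @param line_ids character vector of unique line identifiers.
#' @param values numeric trait values, one per line; `NA` allowed.
#' @param trait_name trait label, e.g. `"GY"`.
#' @param check_ids optional subset of `line_ids` flagged as checks.
#' @return an object of class `phenotype_table`.
#' @export
phenotype_table <- function(line_ids, values, trait_name = "trait",
                            check_ids = character()) {
  line_ids <- as.character(line_ids)
  if (anyDuplicated(line_ids))
    stop("duplicated line id(s): ",
         paste(unique(line_ids[duplicated(line_ids)]), collapse = ", "),
         call. = FALSE)
  if (length(values) != length(line_ids))
    stop("`values` and `line_ids` lengths differ", call. = FALSE)
  check_ids <- as.character(check_ids)
  if (!all(check_ids %in% line_ids))
    stop("check_ids not among line_ids: ",
         paste(setdiff(check_ids, line_ids), collapse = ", "), call. = FALSE)
  structure(list(line_ids = line_ids, values = as.numeric(values),
                 trait_name = trait_name, check_ids = check_ids),
            class = "phenotype_table")
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat(sprintf("phenotype_table: trait '%s', %d lines (%d NA, %d checks)\n",
              x$trait_name, length(x$line_ids), sum(is.na(x$values)),
              length(x$check_ids)))
  invisible(x)
}

#' Named vector of phenotype values
#' @param P a `phenotype_table`.
#' @return numeric vector named by line id.
#' @export
pheno_values <- function(P) stats::setNames(P$values, P$line_ids)

#' Construct a kinship (genomic relationship) matrix
#'
#' @param G symmetric numeric matrix with line ids as dimnames.
#' @param check logical; verify symmetry (tolerance 1e-10) and positive
#'   semidefiniteness up to `-1e-8 * max(eigenvalue)`.
#' @return an object of class `kinship_matrix`.
#' @export
kinship_matrix <- function(G, check = TRUE) {
  if (!is.matrix(G) || !is.numeric(G) || nrow(G) != ncol(G))
    stop("`G` must be a square numeric matrix", call. = FALSE)
  if (is.null(rownames(G)))
    stop("`G` needs line ids as dimnames", call. = FALSE)
  if (check) {
    if (max(abs(G - t(G))) >= 1e-10)
      stop("`G` is not symmetric within 1e-10", call. = FALSE)
    ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1))
      stop("`G` is not positive semidefinite (min eigenvalue ",
           format(min(ev)), ")", call. = FALSE)
  }
  colnames(G) <- rownames(G)
  structure(G, class = c("kinship_matrix", class(G)))
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("kinship_matrix: %d lines, mean diagonal %.3f\n",
              nrow(x), mean(diag(x))))
  invisible(x)
}

#' Write a kinship matrix to CSV
#'
#' Line ids appear as both the header row and the first column.
#' @param K a `kinship_matrix`.
#' @param path output file path.
#' @export
write_kinship_csv <- function(K, path) {
  dt <- data.table::data.table(line_id = rownames(K))
  dt <- cbind(dt, data.table::as.data.table(unclass(K)))
  data.table::fwrite(dt, path)
  invisible(path)
}
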