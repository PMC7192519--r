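#' Validate a signed LD correlation matrix
#'
#' An LD matrix holds signed genotype correlations `r` between SNPs, with
#' the sign convention that `r` refers to the same effect alleles as the
#' `beta` estimates it will be used with. Validation enforces symmetry, a
#' unit diagonal, entries in `[-1, 1]` and SNP ids on both dimensions.
#'
#' @param r square numeric matrix of signed correlations.
#' @param snp SNP ids for the rows/columns; defaults to `rownames(r)`.
#' @param tol numeric tolerance for the symmetry/diagonal/range checks.
#' @return The validated matrix with `snp` as both dimnames.
#' @export
ld_matrix <- function(r, snp = rownames(r), tol = 1e-6) {
  if (!is.matrix(r) || !is.numeric(r) || nrow(r) != ncol(r))
    stopf("LD must be a square numeric matrix")
  if (is.null(snp)) stopf("LD matrix requires SNP ids (rownames or 'snp')")
  snp <- as.character(snp)
  if (length(snp) != nrow(r)) stopf("'snp' length must match LD dimension")
  if (anyDuplicated(snp)) stopf("duplicate SNP ids in LD matrix")
  if (any(!is.finite(r))) stopf("LD matrix contains non-finite values")
  if (max(abs(r - t(r))) > tol) stopf("LD matrix is not symmetric")
  if (max(abs(diag(r) - 1)) > tol) stopf("LD matrix diagonal must be 1")
  if (max(abs(r)) > 1 + tol) stopf("LD correlations must lie in [-1, 1]")
  dimnames(r) <- list(snp, snp)
  r
}

#' Read a signed LD matrix from a delimited file
#'
#' Expects a whitespace/tab-delimited square matrix whose first row and
#' first column are SNP ids and whose entries are signed correlations.
#'
#' @param path path to the file.
#' @inheritParams ld_matrix
#' @return A validated LD matrix (see [ld_matrix()]).
#' @export
read_ld_matrix <- function(path, tol = 1e-6) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tab <- utils::read.table(path, header = TRUE, sep = "", row.names = 1,
                           check.names = FALSE)
  ld_matrix(as.matrix(tab), tol = tol)
}

#' Write an LD matrix in the format read by [read_ld_matrix()]
#'
#' @param r validated LD matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(r, path) {
  utils::write.table(data.frame(snp = rownames(r), r, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# r^2 between a set of SNPs and all SNPs, as a matrix [n x length(ids)]
r2_with <- function(ld, ids) {
  miss <- setdiff(ids, colnames(ld))
  if (length(miss))
    stopf("SNP id(s) absent from LD matrix: %s", paste(miss, collapse = ", "))
  ld[, ids, drop = FALSE]^2
}
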