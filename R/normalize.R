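#' Quantile normalization of an expression matrix
#'
#' Forces every sample (column) to share one common distribution: each
#' column's sorted values are replaced by the across-sample mean quantile
#' vector, with ties within a column receiving the mean of their quantile
#' values.  Delegates to [limma::normalizeQuantiles()], the standard
#' implementation for microarray intensity data; values are assumed to be
#' on the log2 scale.
#'
#' @param matrix Numeric gene-by-sample matrix (>= 2 samples; a one-sample
#'   matrix is returned unchanged with a warning).
#' @return The normalized matrix, same dimnames; after normalization all
#'   columns contain the same multiset of values.
#' @examples
#' m <- cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
#' quantile_normalize(m)  # both columns become 2.5, 3.5, 4.5
#' @export
quantile_normalize <- function(matrix) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (any(!is.finite(matrix))) stop("expression values must be finite")
  if (ncol(matrix) < 2L) {
    warning("quantile normalization needs >= 2 samples; returning input")
    return(matrix)
  }
  out <- limma::normalizeQuantiles(matrix, ties = TRUE)
  dimnames(out) <- dimnames(matrix)
  out
}
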