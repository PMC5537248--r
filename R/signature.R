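# Extraction of stably expressed signature genes: coefficient-of-variation
# filtering of the candidate genes contributed by diversity-correlated
# pathways.

#' Select stably expressed genes by coefficient of variation
#'
#' For each candidate gene the coefficient of variation
#' CV = sd / mean is computed across samples (on the normalized log2-scale
#' values used throughout) and a gene is selected when
#' `log2(CV) < cutoff`.  Genes with zero variance (CV = 0, log2 -> -Inf)
#' are always selected.  The default cutoff of -5.5 corresponds to
#' CV < 2^-5.5, about 0.022.  Selection is monotone in the cutoff and
#' independent of gene order.
#'
#' @param matrix Numeric gene-by-sample expression matrix (>= 3 samples).
#' @param candidate_genes Genes to consider; must be rows of `matrix` and
#'   have strictly positive mean on the analysis scale.
#' @param cutoff log2(CV) selection threshold (default -5.5).
#' @return List of class `signature_result` with `table` (data.frame
#'   `gene`, `mean`, `sd`, `cv`, `log2_cv`, `selected`, sorted by
#'   `log2_cv`), `selected` (character vector) and `cutoff`.
#' @export
gene_cv_selection <- function(matrix, candidate_genes, cutoff = -5.5) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (ncol(matrix) < 3L) stop("need at least 3 samples")
  missing <- setdiff(candidate_genes, rownames(matrix))
  if (length(missing)) {
    stop("candidate gene(s) absent from matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  x <- matrix[candidate_genes, , drop = FALSE]
  mu <- rowMeans(x)
  if (any(mu <= 0)) {
    stop("CV undefined for gene(s) with non-positive mean: ",
         paste(utils::head(candidate_genes[mu <= 0], 5L), collapse = ", "))
  }
  s <- apply(x, 1L, sd)
  cv <- s / mu
  log2_cv <- ifelse(cv > 0, log2(cv), -Inf)
  tab <- data.frame(gene = candidate_genes, mean = mu, sd = s, cv = cv,
                    log2_cv = log2_cv, selected = log2_cv < cutoff,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$log2_cv, tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, selected = tab$gene[tab$selected],
                 cutoff = cutoff),
            class = "signature_result")
}

#' @export
print.signature_result <- function(x, ...) {
  cat(sprintf("signature_result: %d of %d candidate genes below log2(CV) cutoff %.2f\n",
              length(x$selected), nrow(x$table), x$cutoff))
  invisible(x)
}

#' Knee of a sorted log2(CV) curve
#'
#' Helper for choosing a CV cutoff on a new dataset: sorts the log2(CV)
#' values ascending and returns the value at the point of maximum
#' perpendicular distance to the chord joining the curve's endpoints
#' (a standard knee/inflection heuristic).
#'
#' @param log2_cv Numeric vector of log2(CV) values (finite entries used).
#' @return The log2(CV) value at the knee.
#' @export
find_cv_knee <- function(log2_cv) {
  v <- sort(log2_cv[is.finite(log2_cv)])
  n <- length(v)
  if (n < 3L) stop("need at least 3 finite values")
  x <- seq_len(n)
  dx <- n - 1
  dy <- v[n] - v[1L]
  # distance from each point to the chord (x1,v1)-(xn,vn)
  d <- abs(dy * (x - 1) - dx * (v - v[1L])) / sqrt(dx^2 + dy^2)
  v[which.max(d)]
}
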