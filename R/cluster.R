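#' Two-cluster patient stratification over signature genes
#'
#' Unsupervised hierarchical clustering of patients by their signature-
#' gene expression pattern: genes are z-scored across patients, patient
#' distance is 1 - Pearson correlation (the prevailing convention for
#' expression heatmaps; Euclidean available), linkage is average (Ward
#' available), and the dendrogram is cut into `k` groups.  Cluster labels
#' are relabeled deterministically: cluster 1 is the larger group (ties
#' broken by the alphabetically first member), so labels do not depend on
#' input column order.
#'
#' @param matrix Numeric signature-gene by patient expression matrix
#'   (>= 2 genes, >= k patients).
#' @param k Number of clusters (default 2).
#' @param distance `"correlation"` (1 - Pearson) or `"euclidean"`.
#' @param linkage Agglomeration method for [stats::hclust()]
#'   (default `"average"`).
#' @return Named integer vector of cluster labels in `1:k`, one per
#'   patient.
#' @export
cluster_patients <- function(matrix, k = 2,
                             distance = c("correlation", "euclidean"),
                             linkage = "average") {
  distance <- match.arg(distance)
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (nrow(matrix) < 2L) stop("need at least 2 signature genes")
  if (ncol(matrix) < k) stop("fewer patients than clusters")
  if (is.null(colnames(matrix))) {
    colnames(matrix) <- paste0("P", seq_len(ncol(matrix)))
  }
  s <- apply(matrix, 1L, sd)
  z <- (matrix - rowMeans(matrix)) / ifelse(s > 0, s, 1)
  d <- if (distance == "correlation") {
    as.dist(1 - cor(z))
  } else {
    dist(t(z))
  }
  hc <- hclust(d, method = linkage)
  raw <- cutree(hc, k = k)
  # deterministic relabeling: larger cluster first, ties by first member
  sizes <- table(raw)
  first_member <- vapply(names(sizes), function(g) {
    min(names(raw)[raw == as.integer(g)])
  }, character(1))
  new_order <- order(-as.integer(sizes), first_member)
  relabel <- integer(k)
  relabel[as.integer(names(sizes))[new_order]] <- seq_len(k)
  out <- relabel[raw]
  names(out) <- names(raw)
  out
}
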