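# Single-sample pathway activity scores: a rank-based random walk over
# Gaussian-kernel-smoothed expression statistics, in the style of gene set
# variation analysis for continuous (microarray) data.

#' Kernel density statistic per gene and sample
#'
#' For gene i in sample j the statistic is the Gaussian-kernel estimate of
#' the gene's expression CDF evaluated at sample j:
#' `z_ij = (1/n) * sum_k pnorm((x_ij - x_ik) / h_i)` with per-gene
#' bandwidth `h_i = s_i / 4` (`s_i` the gene's across-sample standard
#' deviation).  A constant gene takes the degenerate value 0.5 in every
#' sample.  Within a gene the statistic is strictly increasing in
#' expression and invariant to strictly increasing affine rescaling.
#'
#' @param matrix Numeric gene-by-sample expression matrix (>= 3 samples).
#' @return Matrix of statistics, same dimensions and dimnames.
#' @export
gene_density_statistic <- function(matrix) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  n <- ncol(matrix)
  if (n < 3L) stop("need at least 3 samples")
  z <- matrix(0.5, nrow(matrix), ncol(matrix), dimnames = dimnames(matrix))
  s <- apply(matrix, 1L, sd)
  for (i in which(s > 0)) {
    x <- matrix[i, ]
    z[i, ] <- rowMeans(pnorm(outer(x, x, "-") / (s[i] / 4)))
  }
  z
}

#' Single-sample gene-set variation scores
#'
#' Scores each gene set in each sample by a symmetric-rank random walk:
#' per sample, genes are ranked by decreasing kernel density statistic
#' (ties broken by gene name) and assigned the symmetric rank weight
#' `w = |p/2 - rank|`.  Walking down the ranked list, in-set genes add
#' `w^tau / sum(in-set w^tau)` and out-of-set genes subtract
#' `1 / (p - m)` (`p` genes in the universe, `m` mapped set genes).  The
#' score is the maximum positive deviation plus the minimum negative
#' deviation of the walk (the max-difference convention), positive when
#' the set concentrates at the top of the sample's ranking.
#'
#' @param matrix Numeric gene-by-sample expression matrix (>= 3 samples).
#' @param sets Named list of gene identifier vectors
#'   (a `gene_set_collection`).
#' @param min_set_size Sets with fewer mapped genes are skipped with a
#'   warning (default 5).
#' @param tau Rank-weight exponent (default 1).
#' @return Numeric matrix of scores, kept sets in rows, samples in
#'   columns, with attribute `n_mapped` (mapped genes per kept set).
#' @export
gsva_scores <- function(matrix, sets, min_set_size = 5, tau = 1) {
  stopifnot(is.matrix(matrix), is.list(sets), !is.null(names(sets)))
  genes <- rownames(matrix)
  p <- length(genes)
  z <- gene_density_statistic(matrix)
  # per-sample position of every gene in the decreasing ranking
  pos <- apply(z, 2L, function(col) {
    ord <- order(-col, genes)
    position <- integer(p)
    position[ord] <- seq_len(p)
    position
  })
  rownames(pos) <- genes
  rw <- abs(p / 2 - seq_len(p))^tau     # weight at each ranked position
  mapped <- lapply(sets, function(g) intersect(unique(g), genes))
  sizes <- lengths(mapped)
  skip <- sizes < min_set_size
  if (any(skip)) {
    warning(sum(skip), " gene set(s) with fewer than ", min_set_size,
            " mapped genes skipped: ",
            paste(names(sets)[skip], collapse = ", "))
  }
  if (any(sizes[!skip] >= p)) {
    stop("a gene set equals the whole gene universe; ",
         "the out-of-set decrement is undefined")
  }
  keep <- names(sets)[!skip]
  scores <- matrix(NA_real_, length(keep), ncol(matrix),
                   dimnames = list(keep, colnames(matrix)))
  for (nm in keep) {
    m <- sizes[[nm]]
    rows <- match(mapped[[nm]], genes)
    dec <- 1 / (p - m)
    for (j in seq_len(ncol(matrix))) {
      at <- pos[rows, j]
      step <- rep(-dec, p)
      step[at] <- rw[at] / sum(rw[at])
      walk <- cumsum(step)
      scores[nm, j] <- max(0, max(walk)) + min(0, min(walk))
    }
  }
  attr(scores, "n_mapped") <- sizes[keep]
  scores
}

#' Screen pathway scores against repertoire diversity
#'
#' Correlates every gene set's per-sample activity score with the
#' per-sample Shannon diversity (Spearman, two-sided p) and flags sets
#' whose rho exceeds the threshold.  Thresholding uses rho only; p-values
#' are reported for context.  Results are sorted by decreasing rho.
#'
#' @param scores Gene-set by sample score matrix from [gsva_scores()].
#' @param diversities Named numeric vector of per-sample Shannon indices;
#'   names must match the score columns (any order).
#' @param threshold Pass when rho is strictly greater (default 0.75).
#' @return A data.frame of class `screen_result` with columns `term`,
#'   `rho`, `p_value`, `pass`.
#' @export
diversity_pathway_screen <- function(scores, diversities,
                                     threshold = 0.75) {
  stopifnot(is.matrix(scores))
  if (is.null(names(diversities)) ||
      !setequal(names(diversities), colnames(scores)) ||
      length(diversities) != ncol(scores)) {
    stop("diversity sample ids must match the score columns")
  }
  d <- diversities[colnames(scores)]
  res <- lapply(rownames(scores), function(nm) {
    ct <- spearman_correlation(scores[nm, ], d)
    data.frame(term = nm, rho = ct$rho, p_value = ct$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$pass <- out$rho > threshold
  out <- out[order(-out$rho, out$term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("screen_result", "data.frame")
  attr(out, "threshold") <- threshold
  out
}

#' Format a screen result as a report table
#'
#' Renders the screen in the conventional report layout: term, R
#' (two decimals) and p-value, with p-values below 0.01 shown as
#' `"<0.01"` and others to two decimals.
#'
#' @param screen A `screen_result` from [diversity_pathway_screen()].
#' @param passing_only Keep only sets above the threshold (default TRUE).
#' @return A character data.frame with columns `Term`, `R`, `p-value`.
#' @export
format_screen_report <- function(screen, passing_only = TRUE) {
  stopifnot(inherits(screen, "screen_result"))
  df <- as.data.frame(screen)
  if (passing_only) df <- df[df$pass, , drop = FALSE]
  data.frame(
    Term = df$term,
    R = sprintf("%.2f", df$rho),
    `p-value` = ifelse(df$p_value < 0.01, "<0.01",
                       sprintf("%.2f", df$p_value)),
    check.names = FALSE, stringsAsFactors = FALSE
  )
}
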