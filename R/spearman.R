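#' Spearman rank correlation with exact small-sample p-value
#'
#' Computes Spearman's rho as the Pearson correlation of midranks.  For
#' n <= 10 without ties the two-sided p-value is exact: the full
#' permutation null distribution of the rank statistic is enumerated once
#' per sample size (in compiled code) and cached for the session.  With
#' ties, or for n > 10, the t approximation
#' t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 degrees of freedom is
#' used.
#'
#' @param x,y Paired numeric vectors (n >= 3, neither constant).
#' @return List with `rho`, `p_value`, `n` and `method` (`"exact"` or
#'   `"t-approximation"`).
#' @examples
#' spearman_correlation(1:5, c(2, 1, 4, 3, 5))
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  n <- length(x)
  if (n < 3L) stop("need n >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("inputs must be finite")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop("rho is undefined for a constant vector")
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- cor(rx, ry)
  has_ties <- anyDuplicated(rx) > 0L || anyDuplicated(ry) > 0L
  if (n <= 10L && !has_ties) {
    p <- .spearman_exact_p(rho, n)
    method <- "exact"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * pt(-abs(tstat), df = n - 2)
    }
    method <- "t-approximation"
  }
  list(rho = rho, p_value = min(1, p), n = n, method = method)
}

# exact two-sided p from the cached permutation null of T = sum(i * pi(i));
# rho is linear in T: rho = (T - c) / v with c = n(n+1)^2/4, v = (n^3-n)/12
.spearman_exact_p <- function(rho, n) {
  key <- as.character(n)
  tab <- .tilscape_cache[[paste0("spearman_", key)]]
  if (is.null(tab)) {
    tab <- spearman_null_T(n)
    .tilscape_cache[[paste0("spearman_", key)]] <- tab
  }
  centre <- n * (n + 1)^2 / 4
  scale <- (n^3 - n) / 12
  tvals <- seq(tab$t_min, tab$t_max)
  dev <- abs(tvals - centre)
  sum(tab$counts[dev >= abs(rho) * scale - 1e-9]) / sum(tab$counts)
}
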