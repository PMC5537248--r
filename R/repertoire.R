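# Repertoire statistics over clonotype tables: diversity, frequency
# spectrum, TOP-N expanded-clone analyses, pairwise overlap matrices,
# shared clones, and the rank-based sample-comparison tests.

.check_tables <- function(tables, min_n = 2L) {
  if (!is.list(tables) || length(tables) < min_n) {
    stop("need a list of at least ", min_n, " clonotype tables")
  }
  ok <- vapply(tables, inherits, logical(1), "clonotype_table")
  if (!all(ok)) stop("all inputs must be clonotype_table objects")
  if (any(vapply(tables, nrow, integer(1)) == 0L)) {
    stop("empty clonotype table in input")
  }
  ids <- vapply(tables, attr, character(1), "sample_id")
  if (is.null(names(tables))) names(tables) <- ids
  tables
}

# the n most expanded clonotypes; ties broken by (count desc, cdr3_nt,
# v_segment) so the selection is deterministic
.top_order <- function(table) {
  order(-table$count, table$cdr3_nt, table$v_segment)
}

#' Shannon-Wiener diversity of a repertoire
#'
#' Computes the Shannon-Wiener diversity index
#' H = -sum(p_i * log(p_i)) over clonotype frequencies, in nats
#' (natural logarithm, unnormalized).  Zero-frequency records contribute
#' nothing.  Higher values indicate a more even, more diverse repertoire;
#' H is bounded by log(richness).
#'
#' @param table A [clonotype_table] with at least one clonotype.
#' @return A list with `sample_id`, `shannon_di` (nats) and `richness`
#'   (number of unique clonotypes).
#' @examples
#' tab <- clonotype_table(data.frame(
#'   cdr3_nt = c("TGTA", "TGTC", "TGTG", "TGTT"), cdr3_aa = "CASF",
#'   v_segment = "TRBV1", d_segment = "", j_segment = "TRBJ1",
#'   count = c(1, 1, 1, 1)))
#' shannon_diversity(tab)$shannon_di  # log(4)
#' @export
shannon_diversity <- function(table) {
  stopifnot(inherits(table, "clonotype_table"))
  if (nrow(table) == 0L) stop("diversity is undefined for an empty table")
  p <- table$frequency
  p <- p[p > 0]
  list(sample_id = attr(table, "sample_id"),
       shannon_di = -sum(p * log(p)),
       richness = nrow(table))
}

#' Clone-frequency spectrum
#'
#' Proportion of unique clonotypes falling into each frequency class.
#' Bins are the half-open intervals `(bin_edges[i], bin_edges[i + 1]]`;
#' the default edges split at 1e-5, 1e-4, 1e-3 and 1e-2.
#'
#' @param table A [clonotype_table].
#' @param bin_edges Strictly increasing numeric vector of bin edges whose
#'   range must cover every observed frequency.
#' @return Named numeric vector of per-bin proportions summing to 1.
#' @export
frequency_spectrum <- function(table,
                               bin_edges = c(0, 1e-5, 1e-4, 1e-3, 1e-2, 1)) {
  stopifnot(inherits(table, "clonotype_table"))
  if (nrow(table) == 0L) stop("frequency spectrum of an empty table")
  if (length(bin_edges) < 2L || any(diff(bin_edges) <= 0)) {
    stop("bin edges must be strictly increasing")
  }
  f <- table$frequency
  if (any(f <= bin_edges[1L]) || any(f > bin_edges[length(bin_edges)])) {
    stop("bin edges do not cover all observed frequencies")
  }
  bins <- cut(f, breaks = bin_edges, right = TRUE)
  prop <- as.numeric(table(bins)) / length(f)
  names(prop) <- levels(bins)
  prop
}

#' TOP-N most expanded clonotypes
#'
#' Returns the `n` highest-count clonotypes of a sample (all of them when
#' fewer than `n` exist).  Ties are broken by higher count, then
#' lexicographic CDR3 nucleotide sequence, then V segment, so the
#' selection is deterministic.
#'
#' @param table A [clonotype_table].
#' @param n Number of clones to return (>= 1).
#' @return A `clonotype_table` restricted to the TOP-N, in rank order.
#' @export
top_clones <- function(table, n = 250) {
  stopifnot(inherits(table, "clonotype_table"), n >= 1)
  ord <- .top_order(table)
  idx <- ord[seq_len(min(n, nrow(table)))]
  out <- table[idx, , drop = FALSE]
  attributes(out)[c("sample_id", "total_count", "key_by")] <-
    attributes(table)[c("sample_id", "total_count", "key_by")]
  class(out) <- class(table)
  out
}

#' Cumulative frequency of the most expanded clones
#'
#' Entry k is the summed frequency of the k most expanded clonotypes, for
#' k = 1 .. min(n, richness); the curve is non-decreasing and bounded by 1.
#'
#' @inheritParams top_clones
#' @return Numeric vector of cumulative frequencies.
#' @export
cumulative_top_frequency <- function(table, n = 250) {
  stopifnot(inherits(table, "clonotype_table"), n >= 1)
  ord <- .top_order(table)
  cumsum(table$frequency[ord][seq_len(min(n, nrow(table)))])
}

.overlap_matrix <- function(values, ids, mode) {
  dimnames(values) <- list(ids, ids)
  structure(values, class = c("overlap_matrix", class(values)),
            mode_label = mode)
}

#' Pairwise TOP-N overlap between samples
#'
#' For every pair of samples, the percentage of shared clonotypes among
#' their TOP-N expanded-clone lists:
#' `100 * |topn(A) n topn(B)| / min(n, |topn(A)|, |topn(B)|)`.
#' The denominator adapts when a sample holds fewer than `n` clones so
#' shallow samples remain comparable.  The matrix is symmetric with a
#' diagonal of 100.
#'
#' @param tables List of at least two [clonotype_table]s.
#' @param n TOP-N size (default 250).
#' @return An `overlap_matrix` (percent, mode `"topn_topn"`).
#' @export
pairwise_topn_overlap <- function(tables, n = 250) {
  tables <- .check_tables(tables)
  tops <- lapply(tables, function(tb) top_clones(tb, n)$key)
  k <- length(tops)
  m <- matrix(100, k, k)
  for (i in seq_len(k - 1L)) {
    for (j in seq((i + 1L), k)) {
      denom <- min(n, length(tops[[i]]), length(tops[[j]]))
      ov <- 100 * length(intersect(tops[[i]], tops[[j]])) / denom
      m[i, j] <- m[j, i] <- ov
    }
  }
  .overlap_matrix(m, names(tables), "topn_topn")
}

#' TOP-N versus full-repertoire overlap
#'
#' Cell (A, B) is the percentage of sample A's TOP-N clonotypes found
#' anywhere in sample B's entire repertoire.  The matrix is asymmetric;
#' row A profiles where A's expanded clones re-occur.
#'
#' @inheritParams pairwise_topn_overlap
#' @return An `overlap_matrix` (percent, mode `"topn_full"`).
#' @export
topn_vs_full_overlap <- function(tables, n = 250) {
  tables <- .check_tables(tables)
  tops <- lapply(tables, function(tb) top_clones(tb, n)$key)
  full <- lapply(tables, function(tb) tb$key)
  k <- length(tops)
  m <- matrix(100, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j) m[i, j] <- 100 * mean(tops[[i]] %in% full[[j]])
    }
  }
  .overlap_matrix(m, names(tables), "topn_full")
}

#' Pooled tumor TOP-N detectability in peripheral blood
#'
#' Pools the TOP-N expanded clonotypes over all tumor samples and asks how
#' many of these tumor-related clones circulate: how many are detectable
#' anywhere in the blood repertoire, what fraction of the pooled set that
#' is, and how large a share of the blood repertoire they occupy, both as
#' a percentage of the blood's unique-clone count and as their summed
#' frequency mass in blood.
#'
#' @param tumor_tables List of tumor [clonotype_table]s.
#' @param blood_table Peripheral-blood [clonotype_table].
#' @param n TOP-N size (default 250).
#' @return List with `pooled_unique`, `detected`, `detected_pct`,
#'   `share_of_blood_clone_count_pct`, `share_of_blood_frequency_mass_pct`.
#' @export
pooled_topn_blood_stats <- function(tumor_tables, blood_table, n = 250) {
  tumor_tables <- .check_tables(tumor_tables, min_n = 1L)
  stopifnot(inherits(blood_table, "clonotype_table"))
  pooled <- unique(unlist(lapply(tumor_tables,
                                 function(tb) top_clones(tb, n)$key),
                          use.names = FALSE))
  if (!length(pooled)) stop("pooled TOP-N set is empty")
  hit <- pooled %in% blood_table$key
  detected <- sum(hit)
  freq_mass <- sum(blood_table$frequency[blood_table$key %in%
                                           pooled[hit]])
  list(pooled_unique = length(pooled),
       detected = detected,
       detected_pct = 100 * detected / length(pooled),
       share_of_blood_clone_count_pct = 100 * detected / nrow(blood_table),
       share_of_blood_frequency_mass_pct = 100 * freq_mass)
}

#' Clonotypes shared by every sample
#'
#' Intersects the clonotype key sets of all samples and returns the shared
#' (public) clones ranked by abundance, with per-sample frequencies
#' attached.  Abundance across samples is summarized as the mean frequency
#' by default; `rank_by = "max"` ranks by the maximum frequency instead.
#'
#' @param tables List of at least two [clonotype_table]s.
#' @param rank_by `"mean"` or `"max"` per-sample frequency aggregation.
#' @return A data.frame with `key`, `cdr3_nt`, `cdr3_aa`, `v_segment`,
#'   `j_segment`, one frequency column per sample, and `rank_stat`; sorted
#'   by decreasing `rank_stat`.  Zero rows when nothing is shared.
#' @export
common_clones <- function(tables, rank_by = c("mean", "max")) {
  rank_by <- match.arg(rank_by)
  tables <- .check_tables(tables)
  shared <- Reduce(intersect, lapply(tables, function(tb) tb$key))
  ids <- names(tables)
  first <- tables[[1L]]
  sel <- first[match(shared, first$key),
               c("key", "cdr3_nt", "cdr3_aa", "v_segment", "j_segment"),
               drop = FALSE]
  freqs <- matrix(NA_real_, nrow = length(shared), ncol = length(tables),
                  dimnames = list(NULL, ids))
  for (j in seq_along(tables)) {
    freqs[, j] <- tables[[j]]$frequency[match(shared, tables[[j]]$key)]
  }
  out <- cbind(as.data.frame(sel, stringsAsFactors = FALSE),
               as.data.frame(freqs, check.names = FALSE))
  out$rank_stat <- if (length(shared)) {
    if (rank_by == "mean") rowMeans(freqs) else apply(freqs, 1L, max)
  } else numeric(0)
  out <- out[order(-out$rank_stat, out$key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Kruskal-Wallis test for sample-wise overlap differences
#'
#' Tests whether samples differ in how strongly they overlap with the
#' rest: group g collects sample g's off-diagonal values of the overlap
#' matrix (rows by default; columns profile how often other samples'
#' expanded clones land in g for the asymmetric TOP-N versus full-repertoire
#' matrix), compared by the Kruskal-Wallis rank test with the asymptotic
#' chi-square p-value.
#'
#' @param matrix An `overlap_matrix` with at least three samples.
#' @param margin `"row"` or `"column"` grouping.
#' @return List with `statistic` (H), `p_value`, `df`.
#' @export
overlap_difference_test <- function(matrix, margin = c("row", "column")) {
  margin <- match.arg(margin)
  stopifnot(inherits(matrix, "overlap_matrix"))
  k <- nrow(matrix)
  if (k < 3L) stop("need at least 3 samples")
  if (margin == "column") matrix <- t(matrix)
  groups <- lapply(seq_len(k), function(i) matrix[i, -i])
  if (any(lengths(groups) < 2L)) stop("each group needs >= 2 values")
  if (sd(unlist(groups)) == 0) {           # fully tied: no rank variance
    return(list(statistic = 0, p_value = 1, df = k - 1L))
  }
  kt <- kruskal.test(groups)
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter))
}

#' Wilcoxon rank-sum test between two sample groups
#'
#' Two-sided rank-sum comparison of a statistic (e.g. Shannon diversity)
#' between two groups of samples.  For combined n <= 10 the p-value is
#' computed by exact enumeration of all group assignments on midranks
#' (so ties are handled and identical groups give p = 1); for larger n the
#' normal approximation of [stats::wilcox.test()] is used.
#'
#' @param values Numeric vector of per-sample statistics.
#' @param labels Grouping vector with exactly two levels, each non-empty.
#' @return List with `statistic` (rank-sum W of the first group),
#'   `p_value`, and `method`.
#' @export
diversity_group_test <- function(values, labels) {
  stopifnot(length(values) == length(labels))
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L || any(tabulate(labels) == 0L)) {
    stop("need exactly two non-empty groups")
  }
  n <- length(values)
  n1 <- sum(labels == levels(labels)[1L])
  r <- rank(values)
  w_obs <- sum(r[labels == levels(labels)[1L]])
  e_w <- n1 * (n + 1) / 2
  if (n <= 10L) {
    combos <- combn(n, n1)
    w_all <- colSums(matrix(r[combos], nrow = n1))
    p <- mean(abs(w_all - e_w) >= abs(w_obs - e_w) - 1e-9)
    method <- "exact enumeration"
  } else {
    wt <- suppressWarnings(
      wilcox.test(values[labels == levels(labels)[1L]],
                  values[labels == levels(labels)[2L]],
                  exact = FALSE, correct = TRUE))
    p <- wt$p.value
    method <- "normal approximation"
  }
  list(statistic = w_obs, p_value = p, method = method)
}
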