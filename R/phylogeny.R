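# Somatic mutation filtering cascade, mutation classification across tumor
# masses, and germline-rooted maximum parsimony reconstruction over binary
# presence/absence profiles with mutation-count branch lengths.

# annotation classes counted as protein-altering
.protein_altering <- c(
  "missense", "nonsynonymous", "nonsynonymous_snv", "nonsense", "stopgain",
  "stoploss", "frameshift", "frameshift_insertion", "frameshift_deletion",
  "frameshift_substitution", "nonframeshift_insertion",
  "nonframeshift_deletion", "nonframeshift_substitution", "splicing",
  "splice_site"
)

#' Filter candidate somatic variant calls
#'
#' Applies the post-calling filter cascade: a call is retained only when
#' (1) the germline sample has at least `germline_min_depth` reads,
#' (2) the germline sample has zero non-reference reads,
#' (3) the annotated effect is protein-altering (missense, nonsense /
#' stopgain, stoploss, frameshift and non-frameshift indels, canonical
#' splice), and (4) no other candidate call lies within
#' `cluster_window_bp` on the same contig (multi-variant clusters are
#' treated as alignment artifacts and all members removed).  Every
#' rejected call carries the full set of failed-rule reasons, and the
#' retained set is independent of input row order.
#'
#' @param variants A `variant_table` from [read_variant_table()] (or a
#'   data.frame with the same columns).
#' @param config An [analysis_config()]; `germline_min_depth` and
#'   `cluster_window_bp` are used.
#' @return List with `retained` (variant rows passing all rules) and
#'   `rejected` (variant rows plus a `reason` column of semicolon-joined
#'   failed rules among `germline_coverage`, `germline_contamination`,
#'   `effect`, `cluster`).
#' @export
filter_variants <- function(variants, config = analysis_config()) {
  df <- as.data.frame(variants)
  needed <- c("chrom", "pos", "effect", "germline_depth", "germline_alt")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("variant calls missing column(s): ",
         paste(missing, collapse = ", "))
  }
  n <- nrow(df)
  reasons <- vector("list", n)
  fail <- function(idx, why) {
    for (i in idx) reasons[[i]] <<- c(reasons[[i]], why)
  }
  fail(which(df$germline_depth < config$germline_min_depth),
       "germline_coverage")
  fail(which(df$germline_alt > 0), "germline_contamination")
  eff <- gsub("[^a-z]", "_", tolower(df$effect))
  fail(which(!eff %in% .protein_altering), "effect")
  # cluster rule: any two candidate calls within the window on one contig
  # invalidate each other
  for (chr in unique(df$chrom)) {
    idx <- which(df$chrom == chr)
    if (length(idx) < 2L) next
    pos <- df$pos[idx]
    ord <- order(pos)
    close_next <- diff(pos[ord]) <= config$cluster_window_bp
    clustered <- logical(length(idx))
    clustered[ord][c(close_next, FALSE) | c(FALSE, close_next)] <- TRUE
    fail(idx[clustered], "cluster")
  }
  bad <- lengths(reasons) > 0L
  rejected <- df[bad, , drop = FALSE]
  if (nrow(rejected)) {
    rejected$reason <- vapply(reasons[bad], paste, character(1),
                              collapse = ";")
  } else {
    rejected$reason <- character(0)
  }
  rownames(rejected) <- NULL
  retained <- df[!bad, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained, rejected = rejected)
}

#' Binary mutation presence/absence matrix
#'
#' Converts a (filtered) variant table into the mutation-by-sample binary
#' matrix used for classification and tree building.  A mutation is
#' present in a sample when at least `min_alt_reads` non-reference reads
#' support it.  Mutation identifiers combine gene and genomic change.
#'
#' @param variants Variant data.frame with `<sample>_alt` columns.
#' @param samples Sample identifiers; defaults to the `samples` attribute.
#' @param min_alt_reads Minimum supporting reads for presence (default 1).
#' @return Integer 0/1 matrix, mutations in rows, samples in columns.
#' @export
mutation_matrix <- function(variants, samples = attr(variants, "samples"),
                            min_alt_reads = 1) {
  df <- as.data.frame(variants)
  if (is.null(samples)) stop("sample identifiers are required")
  cols <- paste0(samples, "_alt")
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("missing per-sample columns: ", paste(missing, collapse = ", "))
  }
  m <- vapply(cols, function(cn) as.integer(df[[cn]] >= min_alt_reads),
              integer(nrow(df)))
  m <- matrix(m, nrow = nrow(df), dimnames = list(
    paste(df$gene, df$chrom, df$pos, paste0(df$ref, ">", df$alt),
          sep = "_"),
    samples))
  m[rowSums(m) > 0L, , drop = FALSE]
}

#' Classify mutations as shared, mass-specific or region-unique
#'
#' Labels each mutation by its distribution over tumor masses: `shared`
#' (present in at least one sample of every mass), `mass_specific`
#' (present in two or more samples of exactly one mass), or
#' `region_unique` (present in exactly one sample).  With more than two
#' masses, a mutation spanning several but not all masses is labeled
#' `multi_mass`.
#'
#' @param matrix Binary mutation-by-sample matrix (no all-absent rows).
#' @param mass_of_sample Named character vector mapping every sample
#'   column to its tumor mass; at least two masses.
#' @return List with `labels` (per-mutation character vector) and
#'   `counts` (named integer vector per class, zero-count classes kept).
#' @export
classify_mutations <- function(matrix, mass_of_sample) {
  stopifnot(is.matrix(matrix))
  samples <- colnames(matrix)
  if (is.null(samples)) stop("mutation matrix must have sample names")
  if (!all(samples %in% names(mass_of_sample))) {
    stop("unassigned sample(s): ",
         paste(setdiff(samples, names(mass_of_sample)), collapse = ", "))
  }
  if (!all(matrix %in% c(0L, 1L))) stop("matrix must be binary")
  if (any(rowSums(matrix) == 0L)) stop("all-absent mutation row")
  mass <- mass_of_sample[samples]
  all_masses <- unique(mass)
  if (length(all_masses) < 2L) stop("need at least two tumor masses")
  labels <- apply(matrix, 1L, function(row) {
    present <- samples[row == 1L]
    masses <- unique(mass[present])
    if (length(present) == 1L) "region_unique"
    else if (length(masses) == length(all_masses)) "shared"
    else if (length(masses) == 1L) "mass_specific"
    else "multi_mass"
  })
  classes <- c("shared", "mass_specific", "region_unique", "multi_mass")
  counts <- setNames(integer(length(classes)), classes)
  tab <- table(labels)
  counts[names(tab)] <- as.integer(tab)
  if (length(all_masses) == 2L) counts <- counts[classes[1:3]]
  list(labels = unname(labels), counts = counts)
}

## ---- Fitch parsimony internals -------------------------------------------
## Trees during the search are nested lists: a leaf is a sample name, an
## internal node a list of two children.  The germline (all-absent) state
## roots the tree; its join with the ingroup is scored directly.

# leaf state sets: h1[i] TRUE iff mutation i may be present
.leaf_sets <- function(matrix) {
  sets <- lapply(colnames(matrix), function(s) {
    h1 <- matrix[, s] == 1L
    list(h0 = !h1, h1 = h1)
  })
  names(sets) <- colnames(matrix)
  sets
}

# Fitch first pass over a nested-list subtree; returns state sets and the
# number of changes inside the subtree
.fitch_rec <- function(node, leaf_sets) {
  if (is.character(node)) {
    s <- leaf_sets[[node]]
    return(list(h0 = s$h0, h1 = s$h1, changes = 0L))
  }
  a <- .fitch_rec(node[[1L]], leaf_sets)
  b <- .fitch_rec(node[[2L]], leaf_sets)
  i0 <- a$h0 & b$h0
  i1 <- a$h1 & b$h1
  nonempty <- i0 | i1
  list(h0 = ifelse(nonempty, i0, a$h0 | b$h0),
       h1 = ifelse(nonempty, i1, a$h1 | b$h1),
       changes = a$changes + b$changes + sum(!nonempty))
}

# total Fitch length of ingroup subtree joined to the all-absent germline
.fitch_score_rooted <- function(top, leaf_sets) {
  f <- .fitch_rec(top, leaf_sets)
  f$changes + sum(!f$h0)
}

# canonical topology string (children sorted) for deterministic tie-breaks
.canon <- function(node) {
  if (is.character(node)) return(node)
  kids <- sort(c(.canon(node[[1L]]), .canon(node[[2L]])))
  paste0("(", kids[1L], ",", kids[2L], ")")
}

# all ways to insert leaf `x` into an edge of `node` (including its stem)
.insertions <- function(node, x) {
  out <- list(list(node, x))
  if (!is.character(node)) {
    for (left in .insertions(node[[1L]], x)) {
      out[[length(out) + 1L]] <- list(left, node[[2L]])
    }
    for (right in .insertions(node[[2L]], x)) {
      out[[length(out) + 1L]] <- list(node[[1L]], right)
    }
  }
  out
}

#' Fitch parsimony length of a fixed topology
#'
#' Counts the minimum number of binary character changes (Fitch small
#' parsimony) a rooted binary topology requires to explain a mutation
#' matrix, with an implicit all-absent germline leaf at the root.  This is
#' the scoring oracle behind [build_parsimony_tree()].
#'
#' @param topology Either a nested list (leaf = sample name, internal
#'   node = list of two children) describing the ingroup, a Newick string,
#'   or an `ape::phylo`; Newick/phylo input may include a `germline` tip,
#'   which is removed before scoring.  Polytomies are not supported.
#' @param matrix Binary mutation-by-sample matrix; column names must
#'   match the topology's leaves exactly.
#' @return Integer: total state changes over all mutations.
#' @export
fitch_length <- function(topology, matrix) {
  stopifnot(is.matrix(matrix))
  if (!all(matrix %in% c(0L, 1L))) stop("matrix must be binary")
  top <- .as_ingroup(topology)
  leaves <- .tree_leaves(top)
  if (anyDuplicated(leaves) ||
      !setequal(leaves, colnames(matrix)) ||
      length(leaves) != ncol(matrix)) {
    stop("topology leaves do not match matrix samples")
  }
  .fitch_score_rooted(top, .leaf_sets(matrix))
}

.tree_leaves <- function(node) {
  if (is.character(node)) return(node)
  c(.tree_leaves(node[[1L]]), .tree_leaves(node[[2L]]))
}

# coerce newick / phylo / nested list into the internal ingroup form
.as_ingroup <- function(topology) {
  if (is.character(topology) && length(topology) == 1L &&
      grepl("(", topology, fixed = TRUE)) {
    topology <- ape::read.tree(text = topology)
  }
  if (inherits(topology, "phylo")) {
    if ("germline" %in% topology$tip.label) {
      if (length(topology$tip.label) < 3L) {
        stop("cannot drop germline from a two-leaf tree")
      }
      topology <- ape::drop.tip(topology, "germline")
    }
    return(.phylo_to_nested(topology))
  }
  if (is.list(topology) || is.character(topology)) return(topology)
  stop("unsupported topology representation")
}

.phylo_to_nested <- function(phy) {
  ntip <- length(phy$tip.label)
  children <- split(phy$edge[, 2L], phy$edge[, 1L])
  build <- function(node) {
    if (node <= ntip) return(phy$tip.label[node])
    kids <- children[[as.character(node)]]
    if (length(kids) == 1L) return(build(kids))        # collapse root stub
    if (length(kids) != 2L) stop("polytomies are not supported")
    list(build(kids[1L]), build(kids[2L]))
  }
  build(ntip + 1L)
}

#' Germline-rooted maximum parsimony tree of tumor samples
#'
#' Searches all rooted topologies over the tumor samples (branch-and-bound
#' over stepwise leaf insertion, exact for up to 12 samples) for the tree
#' minimizing the Fitch parsimony length of the binary mutation matrix,
#' rooted at an implicit all-absent germline leaf.  Among equally
#' parsimonious topologies the one with the lexicographically smallest
#' canonical Newick string is returned, so the result is deterministic.
#' Branch lengths are integer mutation counts from a most-parsimonious
#' state reconstruction in which an ambiguous node inherits its parent's
#' state (changes are placed as late, i.e. as far from the root, as
#' possible); the germline pendant edge has length zero and trunk changes
#' sit on the ingroup stem.  Samples without any detected mutation are
#' dropped before the search.
#'
#' @param matrix Binary mutation-by-sample matrix (2-12 samples after
#'   dropping mutation-free ones).
#' @return List with `tree` (an `ape::phylo` rooted at `germline`, edge
#'   lengths = mutation counts), `newick` (the same tree as a string),
#'   `score` (total parsimony length), and `dropped_samples`.
#' @export
build_parsimony_tree <- function(matrix) {
  stopifnot(is.matrix(matrix))
  if (!all(matrix %in% c(0L, 1L))) stop("matrix must be binary")
  storage.mode(matrix) <- "integer"
  empty <- colSums(matrix) == 0L
  dropped <- colnames(matrix)[empty]
  if (any(empty)) {
    warning("dropping sample(s) without detected mutations: ",
            paste(dropped, collapse = ", "))
    matrix <- matrix[, !empty, drop = FALSE]
  }
  if (any(rowSums(matrix) == 0L)) {
    warning("dropping all-absent mutation rows")
    matrix <- matrix[rowSums(matrix) > 0L, , drop = FALSE]
  }
  k <- ncol(matrix)
  if (k < 1L) stop("no samples with mutations")
  if (k > 12L) {
    stop("exact search supports at most 12 samples; ",
         "a heuristic mode is not implemented")
  }
  leaf_sets <- .leaf_sets(matrix)
  # insertion order: most mutated first tightens the bound early
  ord <- colnames(matrix)[order(-colSums(matrix), colnames(matrix))]
  best <- new.env(parent = emptyenv())
  best$score <- Inf
  best$trees <- list()
  search <- function(tree, remaining) {
    sc <- .fitch_score_rooted(tree, leaf_sets)
    if (sc > best$score) return(invisible())
    if (!length(remaining)) {
      if (sc < best$score) {
        best$score <- sc
        best$trees <- list(tree)
      } else {
        best$trees[[length(best$trees) + 1L]] <- tree
      }
      return(invisible())
    }
    for (cand in .insertions(tree, remaining[1L])) {
      search(cand, remaining[-1L])
    }
  }
  search(ord[1L], ord[-1L])
  canon_strings <- vapply(best$trees, .canon, character(1))
  top <- best$trees[[order(canon_strings)[1L]]]
  res <- .assign_branch_lengths(top, leaf_sets, nrow(matrix))
  newick <- sprintf("(germline:0,%s);", res$newick)
  tree <- ape::read.tree(text = newick)
  list(tree = tree, newick = newick, score = best$score,
       dropped_samples = dropped)
}

# preorder most-parsimonious state assignment (parent state kept when the
# Fitch set is ambiguous) and Newick construction with integer lengths
.assign_branch_lengths <- function(top, leaf_sets, n_char) {
  annotate <- function(node) {
    if (is.character(node)) {
      s <- leaf_sets[[node]]
      return(list(label = node, h0 = s$h0, h1 = s$h1, leaf = TRUE))
    }
    a <- annotate(node[[1L]])
    b <- annotate(node[[2L]])
    i0 <- a$h0 & b$h0
    i1 <- a$h1 & b$h1
    nonempty <- i0 | i1
    list(children = list(a, b), leaf = FALSE,
         h0 = ifelse(nonempty, i0, a$h0 | b$h0),
         h1 = ifelse(nonempty, i1, a$h1 | b$h1))
  }
  ann <- annotate(top)
  root_state <- rep(FALSE, n_char)          # germline: all mutations absent
  descend <- function(node, parent_state) {
    ambiguous <- node$h0 & node$h1
    state <- ifelse(ambiguous, parent_state, node$h1)
    len <- sum(state != parent_state)
    if (node$leaf) {
      return(list(newick = sprintf("%s:%d", node$label, len)))
    }
    a <- descend(node$children[[1L]], state)
    b <- descend(node$children[[2L]], state)
    list(newick = sprintf("(%s,%s):%d", a$newick, b$newick, len))
  }
  descend(ann, root_state)
}

#' Spearman correlation between repertoire diversity and mutation burden
#'
#' Rank correlation between per-sample Shannon diversity and the number of
#' detected nonsynonymous mutations, with an exact permutation p-value for
#' n <= 10 (see [spearman_correlation()]).
#'
#' @param diversities Numeric vector of per-sample Shannon indices.
#' @param mutation_counts Numeric vector of per-sample mutation counts,
#'   same length and order (n >= 4).
#' @return List with `rho` and `p_value`.
#' @export
diversity_mutation_correlation <- function(diversities, mutation_counts) {
  if (length(diversities) != length(mutation_counts) ||
      length(diversities) < 4L) {
    stop("need paired vectors of length >= 4")
  }
  spearman_correlation(diversities, mutation_counts)
}
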