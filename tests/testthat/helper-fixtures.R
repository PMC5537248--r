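# Fixture builders and independent brute-force oracles used across tests.

# clonotype table with given counts; clone identities derived from `ids`
make_table <- function(counts, ids = NULL, sample_id = "s") {
  if (is.null(ids)) ids <- seq_along(counts)
  nt <- if (length(counts)) paste0("TGT", sprintf("%04d", ids)) else
    character(0)
  aa <- if (length(counts)) paste0("CA", sprintf("%04d", ids)) else
    character(0)
  clonotype_table(data.frame(
    cdr3_nt = nt, cdr3_aa = aa,
    v_segment = rep("TRBV1", length(counts)),
    d_segment = rep("", length(counts)),
    j_segment = rep("TRBJ1-1", length(counts)),
    count = counts, stringsAsFactors = FALSE),
    sample_id = sample_id)
}

random_table <- function(n_clones, sample_id = "s", id_pool = 10 * n_clones) {
  make_table(counts = sample(1:50, n_clones, replace = TRUE),
             ids = sample.int(id_pool, n_clones),
             sample_id = sample_id)
}

# --- independent oracles -------------------------------------------------

oracle_shannon <- function(freqs) {
  h <- 0
  for (p in freqs) if (p > 0) h <- h - p * log(p)
  h
}

oracle_spearman_rho <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# exact two-sided Spearman permutation p by full enumeration (small n)
oracle_spearman_exact_p <- function(x, y) {
  n <- length(x)
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  rho_obs <- oracle_spearman_rho(x, y)
  all_p <- perms(seq_len(n))
  rhos <- vapply(all_p, function(pm) oracle_spearman_rho(seq_len(n), pm),
                 numeric(1))
  mean(abs(rhos) >= abs(rho_obs) - 1e-9)
}

# all rooted binary topologies (nested lists) over a leaf set, grown by
# sequential insertion into every edge (independent of the package search)
all_topologies <- function(leaves) {
  grow <- function(trees, leaf) {
    out <- list()
    for (tr in trees) {
      for (ins in insert_everywhere(tr, leaf)) {
        out[[length(out) + 1L]] <- ins
      }
    }
    out
  }
  insert_everywhere <- function(node, leaf) {
    res <- list(list(node, leaf))
    if (!is.character(node)) {
      for (l in insert_everywhere(node[[1L]], leaf)) {
        res[[length(res) + 1L]] <- list(l, node[[2L]])
      }
      for (r in insert_everywhere(node[[2L]], leaf)) {
        res[[length(res) + 1L]] <- list(node[[1L]], r)
      }
    }
    res
  }
  trees <- list(leaves[1L])
  for (lf in leaves[-1L]) trees <- grow(trees, lf)
  trees
}

random_topology <- function(leaves) {
  tr <- leaves[1L]
  for (lf in leaves[-1L]) {
    all_ins <- all_insertions(tr, lf)
    tr <- all_ins[[sample.int(length(all_ins), 1L)]]
  }
  tr
}

all_insertions <- function(node, leaf) {
  res <- list(list(node, leaf))
  if (!is.character(node)) {
    for (l in all_insertions(node[[1L]], leaf)) {
      res[[length(res) + 1L]] <- list(l, node[[2L]])
    }
    for (r in all_insertions(node[[2L]], leaf)) {
      res[[length(res) + 1L]] <- list(node[[1L]], r)
    }
  }
  res
}

topology_leaves <- function(node) {
  if (is.character(node)) return(node)
  c(topology_leaves(node[[1L]]), topology_leaves(node[[2L]]))
}

# brute-force small parsimony: minimum changes over all internal-state
# assignments, germline (all-0) joined at the root; exponential but exact
oracle_parsimony_length <- function(topology, matrix) {
  leaves <- topology_leaves(topology)
  count_nodes <- function(node) {
    if (is.character(node)) return(0L)
    1L + count_nodes(node[[1L]]) + count_nodes(node[[2L]])
  }
  n_int <- count_nodes(topology)
  total <- 0L
  for (ch in seq_len(nrow(matrix))) {
    states <- matrix[ch, leaves]
    best <- Inf
    for (mask in 0:(2^n_int - 1L)) {
      assign_idx <- 0L
      cost <- function(node, parent_state) {
        if (is.character(node)) {
          return(as.integer(states[[node]] != parent_state))
        }
        assign_idx <<- assign_idx + 1L
        st <- bitwAnd(bitwShiftR(mask, assign_idx - 1L), 1L)
        as.integer(st != parent_state) +
          cost(node[[1L]], st) + cost(node[[2L]], st)
      }
      best <- min(best, cost(topology, 0L))
    }
    total <- total + best
  }
  total
}

# two-group log-rank chi-square tabulated by hand from first principles
oracle_logrank_chisq <- function(time, event, group) {
  group <- as.integer(as.factor(group))
  ev_times <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1L)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group == 1L)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) {
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  o_minus_e^2 / v
}
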