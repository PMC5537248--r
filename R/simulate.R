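# Seeded synthetic-data generators emulating the structure of the study's
# inputs: right-skewed clone-frequency repertoires with tunable sharing, a
# planted branching mutation phylogeny, expression with pathway-structured
# signal tied to repertoire diversity, and a two-class survival cohort.
# Every generator is a pure function of (configuration, seed): it seeds the
# RNG explicitly and restores the caller's RNG state on exit.

.set_seed <- function(seed) {
  if (is.null(seed)) return(function() invisible())
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv())
  set.seed(seed)
  function() {
    if (has_old) assign(".Random.seed", old, globalenv())
    else rm(".Random.seed", envir = globalenv())
    invisible()
  }
}

#' Discrete truncated power-law distribution of clone abundance
#'
#' Probability mass `P(X = x)` proportional to `x^-exponent` on
#' `1..x_max`, the right-skewed family used for clone read counts.
#' `power_law_cdf` gives the theoretical CDF for marginal checks.
#'
#' @param n Number of draws.
#' @param exponent Power-law exponent (> 1).
#' @param x_max Truncation point.
#' @return `rpower_law`: integer draws; `power_law_cdf`: CDF values.
#' @export
rpower_law <- function(n, exponent = 2.5, x_max = 10000) {
  stopifnot(exponent > 1, x_max >= 1)
  w <- (1:x_max)^(-exponent)
  sample.int(x_max, n, replace = TRUE, prob = w)
}

#' @rdname rpower_law
#' @param x Points at which the CDF is evaluated.
#' @export
power_law_cdf <- function(x, exponent = 2.5, x_max = 10000) {
  w <- (1:x_max)^(-exponent)
  cdf <- cumsum(w) / sum(w)
  ifelse(x < 1, 0, cdf[pmin(floor(x), x_max)])
}

# deterministic unique CDR3 strings from a clone index
.cdr3_nt <- function(idx, width = 16L) {
  alpha <- c("A", "C", "G", "T")
  vapply(idx, function(i) {
    digits <- integer(width)
    for (k in seq_len(width)) {
      digits[k] <- i %% 4L
      i <- i %/% 4L
    }
    paste0("TGTGCCAGC", paste(alpha[digits + 1L], collapse = ""), "TTT")
  }, character(1))
}

.cdr3_aa <- function(idx, width = 7L) {
  alpha <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  vapply(idx, function(i) {
    digits <- integer(width)
    for (k in seq_len(width)) {
      digits[k] <- i %% 20L
      i <- i %/% 20L
    }
    paste0("CASS", paste(alpha[digits + 1L], collapse = ""), "F")
  }, character(1))
}

#' Simulate multi-region TCR repertoires with controlled sharing
#'
#' Generates one clonotype table per tumor sample (plus an optional
#' peripheral-blood sample) with right-skewed clone abundances and planted
#' inter-sample sharing.  A fraction `sharing_blood` of each sample's
#' clones comes from a pool common to every sample (blood included), and
#' tumors share an additional pool so that any two tumors share a fraction
#' `sharing_tumor` of their clones; the remainder is sample-private.  When
#' a blood sample is present, one hyperexpanded public clone is planted at
#' frequency `public_clone_freq` in every sample.  Abundances are i.i.d.
#' draws from a truncated discrete power law (`"zipf"`) or a log-normal.
#' Defaults mirror the study: ten tumor regions plus blood, an average
#' tumor-tumor repertoire overlap near 15% and tumor-blood overlap near
#' 6%, and a dominant public clone at 10% of the blood repertoire.
#'
#' @param n_tumor_samples Number of tumor regions (default 10).
#' @param n_blood_samples 0 or 1 peripheral-blood samples.
#' @param clones_per_sample Unique clonotypes per sample (default 10000).
#' @param exponent Power-law exponent for clone abundance (> 1).
#' @param sharing_tumor Fraction of clones any two tumors share.
#' @param sharing_blood Fraction shared by all samples including blood
#'   (must not exceed `sharing_tumor`).
#' @param public_clone_freq Frequency of the planted public clone.
#' @param abundance `"zipf"` or `"lognormal"` abundance family.
#' @param seed Integer seed; identical seeds give identical output.
#' @return List with `tables` (named list of [clonotype_table]s; blood is
#'   `"blood"`) and `truth` (clone-id pools `shared_all`, `shared_tumor`,
#'   per-sample clone ids, and the public clone id or NA).
#' @export
simulate_repertoires <- function(n_tumor_samples = 10,
                                 n_blood_samples = 1,
                                 clones_per_sample = 10000,
                                 exponent = 2.5,
                                 sharing_tumor = 0.15,
                                 sharing_blood = 0.06,
                                 public_clone_freq = 0.10,
                                 abundance = c("zipf", "lognormal"),
                                 seed = NULL) {
  abundance <- match.arg(abundance)
  stopifnot(n_tumor_samples >= 1, n_blood_samples %in% c(0, 1),
            clones_per_sample >= 10, exponent > 1,
            sharing_tumor >= 0, sharing_tumor <= 1,
            sharing_blood >= 0, sharing_blood <= sharing_tumor,
            public_clone_freq > 0, public_clone_freq < 1)
  restore <- .set_seed(seed)
  on.exit(restore())
  N <- as.integer(clones_per_sample)
  n_all <- as.integer(round(sharing_blood * N))
  n_tum <- as.integer(round(sharing_tumor * N)) - n_all
  if (n_blood_samples == 0L) {
    n_tum <- n_all + n_tum
    n_all <- 0L
  }
  if ((sharing_tumor > 0 || sharing_blood > 0) && n_all + n_tum == 0L) {
    warning("sharing rates round to zero shared clones")
  }
  n_samples <- n_tumor_samples + n_blood_samples
  max_private <- N                 # private-id block per sample
  total_ids <- n_all + n_tum + n_samples * max_private
  v_of <- sample(paste0("TRBV", 1:30), total_ids, replace = TRUE)
  d_of <- sample(c("TRBD1", "TRBD2", ""), total_ids, replace = TRUE)
  j_of <- sample(paste0("TRBJ", rep(1:2, each = 6), "-",
                        rep(1:6, times = 2)), total_ids, replace = TRUE)
  pool_all <- seq_len(n_all)
  pool_tumor <- seq_len(n_tum) + n_all
  next_private <- n_all + n_tum
  public_id <- if (n_blood_samples == 1L && n_all >= 1L) 1L else NA_integer_
  sample_names <- c(paste0("tumor_", seq_len(n_tumor_samples)),
                    if (n_blood_samples == 1L) "blood")
  draw_counts <- function(n) {
    if (abundance == "zipf") rpower_law(n, exponent) else
      pmax(1L, as.integer(ceiling(rlnorm(n, meanlog = 1, sdlog = 1.5))))
  }
  sample_ids <- list()
  tables <- lapply(seq_len(n_samples), function(si) {
    is_blood <- si > n_tumor_samples
    n_priv <- N - n_all - (if (is_blood) 0L else n_tum)
    priv <- if (n_priv > 0) next_private + (si - 1L) * max_private +
      seq_len(n_priv) else integer(0)
    ids <- c(pool_all, if (!is_blood) pool_tumor, priv)
    counts <- draw_counts(length(ids))
    if (!is.na(public_id)) {
      others <- sum(counts[ids != public_id])
      counts[ids == public_id] <- max(1L, as.integer(round(
        public_clone_freq / (1 - public_clone_freq) * others)))
    }
    sample_ids[[si]] <<- ids
    clonotype_table(data.frame(
      cdr3_nt = .cdr3_nt(ids), cdr3_aa = .cdr3_aa(ids),
      v_segment = v_of[ids], d_segment = d_of[ids],
      j_segment = j_of[ids], count = counts,
      stringsAsFactors = FALSE), sample_id = sample_names[si])
  })
  names(tables) <- sample_names
  names(sample_ids) <- sample_names
  list(tables = tables,
       truth = list(shared_all = pool_all, shared_tumor = pool_tumor,
                    sample_clone_ids = sample_ids,
                    public_clone = public_id))
}

#' Simulate a planted branching mutation phylogeny
#'
#' Builds the binary mutation presence/absence matrix implied by a
#' trunk-and-branch phylogeny over two (or more) tumor masses: trunk
#' mutations occur in every sample, each mass branch carries mutations
#' private to that mass, and optional per-sample private mutations sit on
#' leaf edges.  The defaults plant 9 trunk and 22/13 branch mutations over
#' a 3-sample and a 7-sample mass, echoing a two-mass glioblastoma with 44
#' nonsynonymous mutations of which 9 are shared.  Optional dropout flips
#' present calls to absent independently (sequencing false negatives);
#' rows left all-absent are removed from the matrix (the truth keeps
#' them).
#'
#' @param samples_per_mass Named integer vector, samples per tumor mass.
#' @param n_trunk Trunk mutations present in every sample.
#' @param n_branch Mutations per mass branch (same length as
#'   `samples_per_mass`).
#' @param n_private Private mutations per sample (leaf edges).
#' @param dropout Per-call probability of flipping 1 to 0.
#' @param seed Integer seed.
#' @return List with `matrix` (binary mutations x samples),
#'   `mass_of_sample` (named vector), `tree` (`ape::phylo` of the planted
#'   topology, germline-rooted, edge lengths = planted mutation counts)
#'   and `truth` (per-mutation planted class and pre-dropout matrix).
#' @export
simulate_mutation_matrix <- function(samples_per_mass = c(occipital = 3,
                                                          temporal = 7),
                                     n_trunk = 9,
                                     n_branch = c(22, 13),
                                     n_private = 0,
                                     dropout = 0,
                                     seed = NULL) {
  stopifnot(length(samples_per_mass) >= 2,
            length(n_branch) == length(samples_per_mass),
            n_trunk >= 0, all(n_branch >= 0), n_private >= 0,
            dropout >= 0, dropout < 1)
  if (is.null(names(samples_per_mass))) {
    names(samples_per_mass) <- paste0("mass", seq_along(samples_per_mass))
  }
  restore <- .set_seed(seed)
  on.exit(restore())
  masses <- names(samples_per_mass)
  samples <- unlist(lapply(masses, function(m) {
    paste0(m, "_", seq_len(samples_per_mass[[m]]))
  }))
  mass_of_sample <- setNames(rep(masses, samples_per_mass), samples)
  rows <- list()
  classes <- character(0)
  add_row <- function(present, id, cls) {
    row <- setNames(as.integer(samples %in% present), samples)
    rows[[id]] <<- row
    classes <<- c(classes, cls)
  }
  for (i in seq_len(n_trunk)) {
    add_row(samples, sprintf("trunk_%02d", i), "shared")
  }
  for (m in seq_along(masses)) {
    in_mass <- samples[mass_of_sample == masses[m]]
    for (i in seq_len(n_branch[m])) {
      add_row(in_mass, sprintf("%s_branch_%02d", masses[m], i),
              if (length(in_mass) > 1L) "mass_specific" else
                "region_unique")
    }
  }
  for (s in samples) {
    for (i in seq_len(n_private)) {
      add_row(s, sprintf("%s_private_%02d", s, i), "region_unique")
    }
  }
  full <- do.call(rbind, rows)
  observed <- full
  if (dropout > 0 && length(observed)) {
    flip <- matrix(runif(length(observed)) < dropout, nrow(observed))
    observed[flip & observed == 1L] <- 0L
  }
  kept <- rowSums(observed) > 0L
  # planted topology: germline -> trunk node -> one subtree per mass
  subtrees <- vapply(seq_along(masses), function(m) {
    tips <- paste0(samples[mass_of_sample == masses[m]], ":", n_private)
    sprintf("(%s):%d", paste(tips, collapse = ","), n_branch[m])
  }, character(1))
  newick <- sprintf("(germline:0,(%s):%d);",
                    paste(subtrees, collapse = ","), n_trunk)
  list(matrix = observed[kept, , drop = FALSE],
       mass_of_sample = mass_of_sample,
       tree = ape::read.tree(text = newick),
       truth = list(classes = setNames(classes, rownames(full)),
                    full_matrix = full))
}

#' Simulate a random perfect-phylogeny mutation matrix
#'
#' Plants a uniformly grown random rooted binary tree over the samples
#' (germline outgroup at the root) and assigns every edge - trunk,
#' internal and leaf edges alike - at least one mutation; each mutation is
#' present exactly in the leaves below its edge.  The resulting matrix is
#' conflict-free and its unique most-parsimonious tree is the planted one,
#' with parsimony score equal to the number of mutations.
#'
#' @param n_samples Number of tumor samples (>= 2).
#' @param min_muts,max_muts Range of mutations per edge.
#' @param seed Integer seed.
#' @return List with `matrix`, `newick` (planted germline-rooted tree with
#'   integer edge lengths), `tree` (`ape::phylo`) and `canonical`
#'   (canonical topology string used for equality checks).
#' @export
simulate_perfect_phylogeny <- function(n_samples, min_muts = 1,
                                       max_muts = 3, seed = NULL) {
  stopifnot(n_samples >= 2, min_muts >= 1, max_muts >= min_muts)
  restore <- .set_seed(seed)
  on.exit(restore())
  samples <- sprintf("s%02d", seq_len(n_samples))
  # grow a random binary topology by inserting leaves at random edges
  tree <- samples[1L]
  for (s in samples[-1L]) {
    spots <- .insertions(tree, s)
    tree <- spots[[sample.int(length(spots), 1L)]]
  }
  rows <- list()
  lens <- new.env(parent = emptyenv())
  decorate <- function(node) {
    below <- .tree_leaves(node)
    k <- if (max_muts > min_muts) {
      min_muts + sample.int(max_muts - min_muts + 1L, 1L) - 1L
    } else min_muts
    for (i in seq_len(k)) {
      id <- sprintf("m_%s_%d", paste(below, collapse = ""), i)
      rows[[id]] <<- setNames(as.integer(samples %in% below), samples)
    }
    if (is.character(node)) return(sprintf("%s:%d", node, k))
    sprintf("(%s,%s):%d", decorate(node[[1L]]), decorate(node[[2L]]), k)
  }
  body <- decorate(tree)
  newick <- sprintf("(germline:0,%s);", body)
  list(matrix = do.call(rbind, rows),
       newick = newick,
       tree = ape::read.tree(text = newick),
       canonical = .canon(tree))
}

#' Simulate expression with pathway-structured diversity signal
#'
#' Generates a gene-by-sample expression matrix (log2-intensity scale), a
#' gene-set collection, and ground truth for screen and signature tests.
#' Background genes are i.i.d. Gaussian around gene-specific baselines.
#' The first `n_planted` gene sets receive dedicated genes whose values
#' follow `baseline + effect * standardize(diversity) + noise` with
#' `effect = noise_sd * rho / sqrt(1 - rho^2)`, so each planted gene has
#' target correlation `target_rho` with the supplied diversity vector.
#' `n_low_cv` additional genes are stable by construction - their total
#' standard deviation is a small fraction (CV between 0.004 and 0.012,
#' log2 CV well below -5.5) of their baseline - while still tracking
#' diversity at the same target correlation; they are appended to the
#' planted sets (or kept as background genes when `n_planted = 0`).
#' Null sets draw their members from background genes only.
#'
#' @param diversity Named numeric vector of per-sample diversity values;
#'   its length fixes the number of samples.
#' @param n_genes Background gene universe size (default 2000).
#' @param n_gene_sets Total number of gene sets (default 200).
#' @param set_size Genes per set (default 20).
#' @param n_planted Number of diversity-correlated sets (default 5).
#' @param target_rho Target gene-diversity correlation (default 0.9).
#' @param noise_sd Residual standard deviation (default 1); zero with
#'   `target_rho < 1` is a configuration error.
#' @param n_low_cv Number of planted stable genes (default 25).
#' @param seed Integer seed.
#' @return List with `matrix`, `sets` (a `gene_set_collection`) and
#'   `truth` (`planted_sets`, `low_cv_genes`, `effect`).
#' @export
simulate_expression <- function(diversity, n_genes = 2000,
                                n_gene_sets = 200, set_size = 20,
                                n_planted = 5, target_rho = 0.9,
                                noise_sd = 1, n_low_cv = 25,
                                seed = NULL) {
  n <- length(diversity)
  stopifnot(n >= 3, n_genes >= 10 * set_size, n_gene_sets >= n_planted,
            target_rho >= 0, target_rho < 1)
  if (noise_sd == 0 && target_rho < 1) {
    stop("noise_sd = 0 with target_rho < 1 is impossible")
  }
  if (is.null(names(diversity))) {
    names(diversity) <- sprintf("sample_%02d", seq_len(n))
  }
  restore <- .set_seed(seed)
  on.exit(restore())
  z <- as.numeric(scale(diversity))
  effect <- noise_sd * target_rho / sqrt(1 - target_rho^2)
  bg_genes <- sprintf("G%05d", seq_len(n_genes))
  mu_bg <- runif(n_genes, 7, 9)
  mat <- matrix(rnorm(n_genes * n, mean = mu_bg, sd = noise_sd),
                nrow = n_genes, dimnames = list(bg_genes,
                                                names(diversity)))
  planted_sets <- list()
  low_cv_genes <- character(0)
  if (n_planted > 0) {
    for (ps in seq_len(n_planted)) {
      g_names <- sprintf("PG%02d_%03d", ps, seq_len(set_size))
      planted_sets[[sprintf("PW%03d", ps)]] <- g_names
      mu <- runif(set_size, 7, 9)
      block <- outer(rep(effect, set_size), z) + mu +
        matrix(rnorm(set_size * n, sd = noise_sd), set_size)
      rownames(block) <- g_names
      colnames(block) <- names(diversity)
      mat <- rbind(mat, block)
    }
  }
  if (n_low_cv > 0) {
    g_names <- sprintf("LC%03d", seq_len(n_low_cv))
    mu <- runif(n_low_cv, 7, 9)
    cv_target <- runif(n_low_cv, 0.004, 0.012)
    sd_tot <- cv_target * mu
    eff_g <- target_rho * sd_tot
    noise_g <- sd_tot * sqrt(1 - target_rho^2)
    block <- outer(eff_g, z) + mu +
      matrix(rnorm(n_low_cv * n, sd = rep(noise_g, n)), n_low_cv)
    rownames(block) <- g_names
    colnames(block) <- names(diversity)
    mat <- rbind(mat, block)
    low_cv_genes <- g_names
    if (n_planted > 0) {
      split_idx <- rep(seq_len(n_planted), length.out = n_low_cv)
      for (ps in seq_len(n_planted)) {
        planted_sets[[ps]] <- c(planted_sets[[ps]],
                                g_names[split_idx == ps])
      }
    }
  }
  sets <- planted_sets
  for (i in seq_len(n_gene_sets - n_planted)) {
    sets[[sprintf("NW%03d", i)]] <- sample(bg_genes, set_size)
  }
  class(sets) <- "gene_set_collection"
  list(matrix = mat, sets = sets,
       truth = list(planted_sets = names(planted_sets),
                    low_cv_genes = low_cv_genes, effect = effect))
}

#' Simulate a two-class survival cohort with signature expression
#'
#' Two latent patient classes differ in signature-gene expression: class 2
#' is shifted by `separation` standard-deviation units on every signature
#' gene, upward for half of the genes and downward for the other half
#' (emulating the high/low expression blocks of signature heatmaps; an
#' alternating sign also keeps the class contrast visible to the
#' shift-invariant correlation distance used for clustering).  The classes
#' differ in hazard: event times are exponential with the class-2 rate
#' `hazard_ratio` times the class-1 rate (class-1 median
#' `median_survival` months).  A fraction of patients is censored at an
#' independent uniform time before their event.  Defaults mirror a
#' 50-patient glioblastoma cohort split into two prognostic groups.
#'
#' @param n_patients Cohort size (default 50).
#' @param n_signature_genes Signature genes (default 23).
#' @param separation Between-class expression shift in sd units.
#' @param hazard_ratio Class-2 versus class-1 hazard ratio (> 0).
#' @param censoring_fraction Expected fraction of censored patients.
#' @param median_survival Class-1 median survival in months.
#' @param seed Integer seed.
#' @return List with `survival` (data.frame `patient`, `time`, `event`),
#'   `expression` (signature-gene by patient matrix) and `classes`
#'   (named true class labels in 1/2).
#' @export
simulate_cohort <- function(n_patients = 50, n_signature_genes = 23,
                            separation = 3, hazard_ratio = 3,
                            censoring_fraction = 0.3,
                            median_survival = 20, seed = NULL) {
  stopifnot(n_patients >= 2, n_signature_genes >= 2, hazard_ratio > 0,
            censoring_fraction >= 0, censoring_fraction < 1,
            median_survival > 0)
  restore <- .set_seed(seed)
  on.exit(restore())
  patients <- sprintf("patient_%03d", seq_len(n_patients))
  classes <- setNames(sample(rep(1:2, length.out = n_patients)), patients)
  lambda1 <- log(2) / median_survival
  rate <- ifelse(classes == 2L, hazard_ratio * lambda1, lambda1)
  t_event <- rexp(n_patients, rate = rate)
  censored <- rbinom(n_patients, 1L, censoring_fraction) == 1L
  time <- ifelse(censored, runif(n_patients, 0, t_event), t_event)
  time <- pmax(time, 1e-6)
  genes <- sprintf("SIG%02d", seq_len(n_signature_genes))
  mu <- runif(n_signature_genes, 7, 9)
  direction <- rep(c(1, -1), length.out = n_signature_genes)
  expr <- mu + outer(separation * direction,
                     as.numeric(classes == 2L)) +
    matrix(rnorm(n_signature_genes * n_patients), n_signature_genes)
  dimnames(expr) <- list(genes, patients)
  list(survival = data.frame(patient = patients, time = time,
                             event = as.integer(!censored),
                             stringsAsFactors = FALSE),
       expression = expr,
       classes = classes)
}
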