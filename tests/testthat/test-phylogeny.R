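make_calls <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(chrom = r$chrom, pos = r$pos, ref = "A", alt = "T",
               gene = r$gene, effect = r$effect,
               germline_depth = r$gd, germline_alt = r$ga,
               stringsAsFactors = FALSE)
  }))
}

test_that("variant filter cascade applies every rule and logs reasons", {
  calls <- make_calls(
    list(chrom = "1", pos = 1000, gene = "KEEP", effect = "missense",
         gd = 30, ga = 0),
    list(chrom = "2", pos = 500, gene = "LOWCOV", effect = "missense",
         gd = 9, ga = 0),
    list(chrom = "3", pos = 500, gene = "GLALT", effect = "stopgain",
         gd = 30, ga = 2),
    list(chrom = "4", pos = 500, gene = "SYN", effect = "synonymous",
         gd = 30, ga = 0),
    list(chrom = "5", pos = 100, gene = "CL1", effect = "missense",
         gd = 30, ga = 0),
    list(chrom = "5", pos = 180, gene = "CL2", effect = "missense",
         gd = 30, ga = 0))
  res <- filter_variants(calls)
  expect_equal(res$retained$gene, "KEEP")
  reason_of <- setNames(res$rejected$reason, res$rejected$gene)
  expect_equal(unname(reason_of["LOWCOV"]), "germline_coverage")
  expect_equal(unname(reason_of["GLALT"]), "germline_contamination")
  expect_equal(unname(reason_of["SYN"]), "effect")
  expect_equal(unname(reason_of["CL1"]), "cluster")
  expect_equal(unname(reason_of["CL2"]), "cluster")
})

test_that("variant filtering is independent of input row order", {
  set.seed(9)
  calls <- make_calls(
    list(chrom = "1", pos = 100, gene = "a", effect = "missense",
         gd = 30, ga = 0),
    list(chrom = "1", pos = 150, gene = "b", effect = "missense",
         gd = 30, ga = 0),
    list(chrom = "1", pos = 900, gene = "c", effect = "missense",
         gd = 30, ga = 0),
    list(chrom = "2", pos = 100, gene = "d", effect = "synonymous",
         gd = 30, ga = 0),
    list(chrom = "2", pos = 500, gene = "e", effect = "frameshift",
         gd = 50, ga = 0))
  base <- sort(filter_variants(calls)$retained$gene)
  for (i in 1:5) {
    shuffled <- calls[sample(nrow(calls)), ]
    expect_equal(sort(filter_variants(shuffled)$retained$gene), base)
  }
})

test_that("mutations are classified by their distribution over masses", {
  m <- rbind(c(1, 1, 1, 1), c(1, 1, 0, 0), c(0, 0, 1, 0))
  dimnames(m) <- list(c("m1", "m2", "m3"), c("a1", "a2", "b1", "b2"))
  mass <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  cl <- classify_mutations(m, mass)
  expect_equal(cl$labels, c("shared", "mass_specific", "region_unique"))
  expect_equal(unname(cl$counts),
               c(1L, 1L, 1L))
  expect_error(classify_mutations(m, mass[-1]), "unassigned")
  expect_error(classify_mutations(m, setNames(rep("A", 4), names(mass))),
               "two tumor masses")
})

test_that("Fitch length matches hand computations on fixed topologies", {
  # all leaves identical: changes only on the germline root edge
  m_same <- matrix(1L, 3, 4,
                   dimnames = list(paste0("m", 1:3), paste0("s", 1:4)))
  topo <- list(list("s1", "s2"), list("s3", "s4"))
  expect_equal(fitch_length(topo, m_same), 3L)

  # two leaves differing at k = 2 of 3 sites
  m2 <- matrix(c(1L, 1L, 1L, 1L, 0L, 0L), 3, 2,
               dimnames = list(paste0("m", 1:3), c("x", "y")))
  # m1 present in both (1 root change), m2/m3 in x only (1 each) = 3
  expect_equal(fitch_length(list("x", "y"), m2), 3L)

  # 4-leaf case scored by hand: trunk + clade(s1,s2) + private s3
  m4 <- rbind(trunk = c(1, 1, 1, 1), clade = c(1, 1, 0, 0),
              priv = c(0, 0, 1, 0))
  colnames(m4) <- paste0("s", 1:4)
  expect_equal(fitch_length(topo, m4), 3L)
  # same characters on the wrong tree cost one extra change for the clade
  bad <- list(list("s1", "s3"), list("s2", "s4"))
  expect_equal(fitch_length(bad, m4), 4L)
  expect_error(fitch_length(list("s1", "s2"), m4), "match")
})

test_that("Fitch length equals brute-force minimum over internal states", {
  set.seed(77)
  for (i in 1:40) {
    k <- sample(3:5, 1)
    leaves <- paste0("s", 1:k)
    topo <- random_topology(leaves)
    m <- matrix(rbinom(k * 6, 1, 0.5), 6, k,
                dimnames = list(paste0("m", 1:6), leaves))
    expect_equal(fitch_length(topo, m), oracle_parsimony_length(topo, m))
  }
})

test_that("parsimony search equals exhaustive topology enumeration", {
  set.seed(55)
  for (i in 1:8) {
    k <- sample(4:5, 1)
    leaves <- paste0("s", 1:k)
    m <- matrix(rbinom(k * 8, 1, 0.4), 8, k,
                dimnames = list(paste0("m", 1:8), leaves))
    m <- m[rowSums(m) > 0, , drop = FALSE]
    keep <- colSums(m) > 0
    if (sum(keep) < 2 || nrow(m) < 2) next
    m <- m[, keep, drop = FALSE]
    m <- m[rowSums(m) > 0, , drop = FALSE]
    fit <- build_parsimony_tree(m)
    exhaustive <- min(vapply(all_topologies(colnames(m)),
                             function(tp) fitch_length(tp, m), integer(1)))
    expect_equal(fit$score, exhaustive)
  }
})

test_that("parsimony handles degenerate and conflicting matrices", {
  m1 <- matrix(1L, 5, 1, dimnames = list(paste0("m", 1:5), "only"))
  r1 <- build_parsimony_tree(m1)
  expect_equal(r1$score, 5L)
  expect_equal(sum(r1$tree$edge.length), 5)

  # perfect-phylogeny toy recovers the planted clades and lengths
  m <- rbind(trunk = c(1, 1, 1, 1), c12 = c(1, 1, 0, 0),
             c34 = c(0, 0, 1, 1), p1 = c(1, 0, 0, 0), p2 = c(0, 1, 0, 0),
             p3 = c(0, 0, 1, 0), p4 = c(0, 0, 0, 1))
  colnames(m) <- paste0("s", 1:4)
  fit <- build_parsimony_tree(m)
  expect_equal(fit$score, 7L)
  expect_equal(fit$newick,
               "(germline:0,((s1:1,s2:1):1,(s3:1,s4:1):1):1);")

  # homoplasy: three pairwise-incompatible characters on 3 samples
  mh <- rbind(a = c(1, 1, 0), b = c(0, 1, 1), c = c(1, 0, 1))
  colnames(mh) <- paste0("s", 1:3)
  fith <- build_parsimony_tree(mh)
  exh <- min(vapply(all_topologies(colnames(mh)),
                    function(tp) fitch_length(tp, mh), integer(1)))
  expect_equal(fith$score, exh)
  expect_gt(fith$score, nrow(mh))

  expect_warning(build_parsimony_tree(cbind(mh, s4 = c(0, 0, 0))),
                 "without detected mutations")
  big <- matrix(1L, 2, 13,
                dimnames = list(c("m1", "m2"), paste0("s", 1:13)))
  expect_error(build_parsimony_tree(big), "12 samples")
})

test_that("branch lengths sum to the score and duplicates form cherries", {
  set.seed(88)
  for (i in 1:10) {
    sim <- simulate_perfect_phylogeny(sample(4:6, 1), seed = 300 + i)
    fit <- build_parsimony_tree(sim$matrix)
    expect_equal(sum(fit$tree$edge.length), fit$score)
    expect_gte(fit$score, nrow(sim$matrix))

    dup <- cbind(sim$matrix, dup_s = sim$matrix[, 1])
    fit2 <- build_parsimony_tree(dup)
    expect_equal(fit2$score, fit$score)
    # the duplicate pair is a zero-length cherry
    phy <- fit2$tree
    tip_a <- which(phy$tip.label == colnames(sim$matrix)[1])
    tip_b <- which(phy$tip.label == "dup_s")
    parent_a <- phy$edge[phy$edge[, 2] == tip_a, 1]
    parent_b <- phy$edge[phy$edge[, 2] == tip_b, 1]
    expect_equal(parent_a, parent_b)
    expect_equal(phy$edge.length[phy$edge[, 2] %in% c(tip_a, tip_b)],
                 c(0, 0))
  }
})

test_that("parsimony score agrees with phangorn on random matrices", {
  skip_if_not_installed("phangorn")
  set.seed(99)
  for (i in 1:10) {
    k <- sample(4:6, 1)
    m <- matrix(rbinom(k * 10, 1, 0.4), 10, k,
                dimnames = list(paste0("m", 1:10), paste0("s", 1:k)))
    m <- m[rowSums(m) > 0, , drop = FALSE]
    if (any(colSums(m) == 0) || nrow(m) < 2) next
    fit <- build_parsimony_tree(m)
    full <- cbind(m, germline = 0L)
    pd <- phangorn::phyDat(t(full), type = "USER", levels = c(0, 1))
    expect_equal(unname(phangorn::parsimony(fit$tree, pd)), fit$score)
    best_ph <- phangorn::pratchet(pd, trace = 0, all = FALSE)
    expect_equal(fit$score,
                 unname(phangorn::parsimony(best_ph, pd)))
  }
})

test_that("diversity-mutation correlation behaves like Spearman's rho", {
  r <- diversity_mutation_correlation(c(1, 2, 3, 4), c(10, 20, 30, 40))
  expect_equal(r$rho, 1)
  r2 <- diversity_mutation_correlation(c(1, 2, 3, 4), c(8, 6, 4, 2))
  expect_equal(r2$rho, -1)
  expect_error(diversity_mutation_correlation(1:3, 3:1), "length >= 4")
  expect_error(diversity_mutation_correlation(1:4, rep(2, 4)), "constant")
})
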