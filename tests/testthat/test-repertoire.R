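test_that("Shannon diversity matches direct summation", {
  expect_equal(shannon_diversity(make_table(c(1, 1, 1, 1)))$shannon_di,
               log(4), tolerance = 1e-12)
  expect_equal(shannon_diversity(make_table(5))$shannon_di, 0)
  expect_equal(shannon_diversity(make_table(1:4))$shannon_di,
               1.279854, tolerance = 1e-6)
  expect_error(shannon_diversity(make_table(numeric(0))), "empty|missing")
})

test_that("Shannon diversity equals the brute-force oracle on random tables", {
  set.seed(101)
  for (i in 1:50) {
    tab <- random_table(sample(2:60, 1))
    h <- shannon_diversity(tab)
    expect_equal(h$shannon_di, oracle_shannon(tab$frequency),
                 tolerance = 1e-12)
    expect_lte(h$shannon_di, log(h$richness) + 1e-12)
  }
})

test_that("Shannon diversity agrees with vegan's implementation", {
  skip_if_not_installed("vegan")
  set.seed(7)
  for (i in 1:10) {
    tab <- random_table(sample(3:50, 1))
    expect_equal(shannon_diversity(tab)$shannon_di,
                 unname(vegan::diversity(tab$count, index = "shannon")),
                 tolerance = 1e-12)
  }
})

test_that("frequency spectrum counts clones per frequency class", {
  expect_equal(unname(frequency_spectrum(
    make_table(c(50, 30, 15, 5)), c(0, 1))), 1)
  expect_equal(unname(frequency_spectrum(
    make_table(c(5, 5)), c(0, 0.1, 1))), c(0, 1))
  tab <- make_table(c(rep(1, 5), rep(19, 5)))   # freqs .01 and .19
  expect_equal(unname(frequency_spectrum(tab, c(0, 0.1, 1))), c(0.5, 0.5))
  expect_equal(sum(frequency_spectrum(random_table(30))), 1)
  expect_error(frequency_spectrum(make_table(c(9, 1)), c(0, 0.5)),
               "cover")
})

test_that("TOP-N selection truncates and breaks ties deterministically", {
  expect_equal(top_clones(make_table(c(5, 3, 2)), 2)$count, c(5, 3))
  expect_equal(nrow(top_clones(make_table(c(5, 3, 2)), 10)), 3L)
  tab <- make_table(c(5, 3, 3), ids = c(7, 9, 2))  # tie between ids 9, 2
  picked <- top_clones(tab, 2)
  expect_equal(picked$count, c(5, 3))
  expect_equal(picked$cdr3_nt[2], "TGT0002")       # lexicographically first
})

test_that("cumulative TOP-N frequency gives partial sums, bounded by 1", {
  expect_equal(cumulative_top_frequency(make_table(c(5, 3, 2)), 2),
               c(0.5, 0.8))
  expect_equal(cumulative_top_frequency(make_table(rep(1, 4)), 4),
               c(0.25, 0.5, 0.75, 1))
  expect_equal(cumulative_top_frequency(make_table(c(4, 3, 2, 1)), 3),
               c(0.4, 0.7, 0.9))
  set.seed(5)
  for (i in 1:25) {
    cf <- cumulative_top_frequency(random_table(sample(3:40, 1)), 20)
    expect_true(all(diff(cf) >= -1e-12))
    expect_lte(cf[length(cf)], 1 + 1e-12)
  }
})

test_that("pairwise TOP-N overlap matches set-intersection enumeration", {
  a <- make_table(c(5, 4, 3), ids = 1:3)
  b <- make_table(c(9, 2, 1), ids = c(2, 3, 4))
  m <- pairwise_topn_overlap(list(a = a, b = b), 3)
  expect_equal(m["a", "b"], 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(m["b", "a"], m["a", "b"])
  expect_equal(diag(unclass(m)), c(a = 100, b = 100))

  same <- pairwise_topn_overlap(list(x = a, y = a), 3)
  expect_equal(same["x", "y"], 100)
  disj <- pairwise_topn_overlap(
    list(x = make_table(1:3, ids = 1:3),
         y = make_table(1:3, ids = 4:6)), 3)
  expect_equal(disj["x", "y"], 0)
})

test_that("TOP-N versus full-repertoire overlap is the detected fraction", {
  a <- make_table(c(5, 4), ids = 1:2)
  b <- make_table(c(1, 1), ids = c(1, 9))
  m <- topn_vs_full_overlap(list(a = a, b = b), 2)
  expect_equal(m["a", "b"], 50)
  sup <- make_table(rep(1, 5), ids = 1:5)
  m2 <- topn_vs_full_overlap(list(a = a, s = sup), 2)
  expect_equal(m2["a", "s"], 100)
  a4 <- make_table(c(9, 8, 7, 6), ids = 1:4)
  b3 <- make_table(rep(1, 3), ids = c(1, 2, 3))
  m3 <- topn_vs_full_overlap(list(a = a4, b = b3), 4)
  expect_equal(m3["a", "b"], 75)
})

test_that("both overlap operators agree with naive oracles on random data", {
  set.seed(202)
  for (i in 1:40) {
    a <- random_table(sample(5:30, 1), "a", id_pool = 40)
    b <- random_table(sample(5:30, 1), "b", id_pool = 40)
    n <- sample(3:10, 1)
    ka <- top_clones(a, n)$key; kb <- top_clones(b, n)$key
    m1 <- pairwise_topn_overlap(list(a = a, b = b), n)
    expect_equal(m1["a", "b"],
                 100 * length(intersect(ka, kb)) /
                   min(n, length(ka), length(kb)))
    m2 <- topn_vs_full_overlap(list(a = a, b = b), n)
    expect_equal(m2["a", "b"], 100 * sum(ka %in% b$key) / length(ka))
  }
})

test_that("pooled TOP-N blood statistics follow the printed definitions", {
  t1 <- make_table(c(5, 3), ids = 1:2)
  t2 <- make_table(c(4, 2), ids = 1:2)
  blood <- make_table(c(6, 2, 2), ids = 1:3)
  st <- pooled_topn_blood_stats(list(t1, t2), blood, 2)
  expect_equal(st$pooled_unique, 2L)
  expect_equal(st$detected, 2L)
  expect_equal(st$detected_pct, 100)
  expect_equal(st$share_of_blood_clone_count_pct, 100 * 2 / 3,
               tolerance = 1e-9)
  expect_equal(st$share_of_blood_frequency_mass_pct, 80)

  far <- make_table(c(1, 1), ids = 8:9)
  st0 <- pooled_topn_blood_stats(list(t1), far, 2)
  expect_equal(st0$detected_pct, 0)
  expect_equal(st0$share_of_blood_frequency_mass_pct, 0)
})

test_that("common clones are the full intersection, ranked by abundance", {
  a <- make_table(c(50, 10, 1), ids = 1:3)
  b <- make_table(c(5, 80, 1), ids = c(1, 2, 9))
  cc <- common_clones(list(a = a, b = b))
  expect_equal(nrow(cc), 2L)
  expect_equal(cc$rank_stat, sort(rowMeans(cbind(
    a$frequency[1:2], b$frequency[1:2])), decreasing = TRUE))
  none <- common_clones(list(a = make_table(1, ids = 1),
                             b = make_table(1, ids = 2)))
  expect_equal(nrow(none), 0L)
  only_x <- common_clones(list(make_table(c(2, 1), ids = 1:2),
                               make_table(c(3, 1), ids = c(1, 5)),
                               make_table(c(9, 1), ids = c(1, 8))))
  expect_equal(nrow(only_x), 1L)
})

test_that("overlap Kruskal-Wallis test matches the hand rank formula", {
  ids <- c("a", "b", "c", "d")
  m <- matrix(50, 4, 4, dimnames = list(ids, ids))
  om <- structure(m, class = c("overlap_matrix", "matrix", "array"),
                  mode_label = "topn_topn")
  r <- overlap_difference_test(om)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  # untied rows: groups (1,2), (4,6), (8,9); hand formula
  # H = 12/(N(N+1)) * sum R_g^2/n_g - 3(N+1) with N = 6
  m2 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  m2["a", -1] <- c(1, 2); m2["b", -2] <- c(4, 6); m2["c", -3] <- c(8, 9)
  om2 <- structure(m2, class = c("overlap_matrix", "matrix", "array"),
                   mode_label = "topn_full")
  r2 <- overlap_difference_test(om2)
  rr <- rank(c(1, 2, 4, 6, 8, 9))
  sums <- tapply(rr, rep(1:3, each = 2), sum)
  h_hand <- 12 / (6 * 7) * sum(sums^2 / 2) - 3 * 7
  expect_equal(r2$statistic, h_hand, tolerance = 1e-9)
})

test_that("group permutation null of H matches the asymptotic p-value", {
  set.seed(33)
  vals <- list(c(12, 25, 31, 8), c(40, 44, 29, 35), c(20, 18, 22, 27))
  kt <- kruskal.test(vals)
  pooled <- unlist(vals)
  g <- rep(1:3, times = lengths(vals))
  r <- rank(pooled)
  h_stat <- function(rr, gg) {
    n <- length(rr)
    sums <- tapply(rr, gg, sum)
    ns <- tabulate(gg)
    12 / (n * (n + 1)) * sum(sums^2 / ns) - 3 * (n + 1)
  }
  h_obs <- h_stat(r, g)
  perm <- replicate(10000, h_stat(r, sample(g)))
  expect_lt(abs(mean(perm >= h_obs - 1e-9) - kt$p.value), 0.02)
})

test_that("rank-sum group comparison uses exact enumeration for small n", {
  r1 <- diversity_group_test(c(1, 2, 3, 1, 2, 3), rep(1:2, each = 3))
  expect_equal(r1$p_value, 1)
  r2 <- diversity_group_test(c(1, 2, 3, 4, 5, 6), rep(1:2, each = 3))
  expect_equal(r2$p_value, 0.1)
  r3 <- diversity_group_test(10 * c(1, 2, 3, 4, 5, 6), rep(1:2, each = 3))
  expect_equal(r3$p_value, r2$p_value)    # scale invariance of ranks
  expect_equal(r3$statistic, r2$statistic)
  expect_error(diversity_group_test(1:4, rep(1, 4)), "two")
})

test_that("merging duplicated rows leaves every repertoire statistic fixed", {
  base <- data.frame(cdr3_nt = c("TGTA", "TGTC", "TGTG"),
                     cdr3_aa = "C", v_segment = "TRBV1", d_segment = "",
                     j_segment = "TRBJ1-1", count = c(4, 2, 2),
                     stringsAsFactors = FALSE)
  dup <- rbind(base, base[2, ])
  dup$count[4] <- 0
  t_base <- clonotype_table(base)
  t_dup <- clonotype_table(dup)
  expect_equal(shannon_diversity(t_dup)$shannon_di,
               shannon_diversity(t_base)$shannon_di)
  expect_equal(cumulative_top_frequency(t_dup, 3),
               cumulative_top_frequency(t_base, 3))
})
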