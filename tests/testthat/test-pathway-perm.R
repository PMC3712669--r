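test_that("feature counting follows the any-member rule", {
  fix <- counting_fixture()
  expect_equal(as.integer(count_significant(fix$features, fix$p)), 39)

  # nothing significant when every p-value is 1
  p1 <- fix$p; p1[] <- 1
  expect_equal(as.integer(count_significant(fix$features, p1)), 0)

  # count is non-decreasing in alpha
  set.seed(303)
  fs <- make_feature_set(sprintf("s%d", 1:20),
                         lapply(1:10, function(i) sprintf("c%d_%d", i, 1:3)))
  p <- setNames(runif(50), c(fs$simple, unlist(fs$complex)))
  counts <- vapply(seq(0.01, 0.10, by = 0.01), function(a) {
    as.integer(count_significant(fs, p, alpha = a))
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("features with missing p-values use available members or drop out", {
  fs <- make_feature_set(c("a", "b"), list(c("c", "d"), c("e", "f")))
  p <- c(a = 0.01, c = NA, d = 0.02, e = NA, f = NA)  # b fully missing too
  expect_message(cnt <- count_significant(fs, p), "dropped")
  expect_equal(as.integer(cnt), 2)          # a and block c/d
  expect_equal(attr(cnt, "n_dropped"), 2)   # b and block e/f
})

test_that("empirical p is the strict-exceedance fraction k / N", {
  nulls <- c(rep(50, 6), rep(39, 10), rep(10, 984))
  expect_equal(empirical_p(39, nulls), 0.006)           # ties do not count
  expect_equal(empirical_p(39, nulls, estimator = "plus_one"), 7 / 1001)
  expect_equal(empirical_p(100, nulls), 0)
  expect_equal(empirical_p(-1, nulls), 1)
})

test_that("a pool exactly matching the architecture forces the unique draw", {
  pool <- make_pool(c("s1", "s2"), list(c("x1", "x2", "x3")))
  arch <- architecture(make_feature_set(c("a", "b"), list(c("p", "q", "r"))))
  for (i in 1:5) {
    draw <- sample_matched_null(arch, pool)
    expect_setequal(draw$simple, c("s1", "s2"))
    expect_equal(draw$complex[[1]], c("x1", "x2", "x3"))
    expect_equal(nrow(draw$fallback), 0)
  }
})

test_that("size fallback selects the nearest class and strict mode errors", {
  pool <- make_pool(character(0), list(sprintf("a%d", 1:6),
                                       sprintf("b%d", 1:4)))
  arch <- structure(list(n_simple = 0L, sizes = 7L),
                    class = "pathway_architecture")
  draw <- sample_matched_null(arch, pool)
  expect_equal(draw$fallback$requested, 7L)
  expect_equal(draw$fallback$used, 6L)
  expect_error(sample_matched_null(arch, pool, size_match = "strict"),
               "size 7")
  # nothing within +/- 2 -> failure names the class
  arch9 <- structure(list(n_simple = 0L, sizes = 9L),
                     class = "pathway_architecture")
  expect_error(sample_matched_null(arch9, pool), "size 9")
  # simple-feature exhaustion
  arch_s <- structure(list(n_simple = 3L, sizes = integer(0)),
                      class = "pathway_architecture")
  expect_error(sample_matched_null(arch_s, pool), "simple")
})

test_that("non-fallback draws always reproduce the target architecture", {
  set.seed(11)
  pool <- make_pool(sprintf("s%d", 1:30),
                    c(lapply(1:8, function(i) sprintf("c2_%d_%d", i, 1:2)),
                      lapply(1:8, function(i) sprintf("c3_%d_%d", i, 1:3)),
                      lapply(1:8, function(i) sprintf("c5_%d_%d", i, 1:5))))
  arch <- structure(list(n_simple = 4L, sizes = c(2L, 2L, 3L, 5L, 5L)),
                    class = "pathway_architecture")
  for (i in 1:50) {
    draw <- sample_matched_null(arch, pool)
    expect_equal(nrow(draw$fallback), 0)
    expect_equal(length(draw$simple), 4L)
    expect_equal(sort(lengths(draw$complex)), c(2L, 2L, 3L, 5L, 5L))
    # without replacement within the draw
    expect_false(anyDuplicated(draw$complex_idx) > 0)
    expect_false(anyDuplicated(draw$simple) > 0)
  }
})

test_that("identical seeds give identical permutation results", {
  fix <- counting_fixture()
  pool <- make_pool(sprintf("ps%03d", 1:300),
                    lapply(1:200, function(i) sprintf("pc%03d_%d", i, 1:(2 + i %% 4))))
  set.seed(17)
  p_pool <- setNames(runif(300 + sum(lengths(pool$complex))),
                     c(pool$simple, unlist(pool$complex)))
  p <- c(fix$p, p_pool)
  r1 <- permutation_test(fix$features, p, pool, n_perm = 500, seed = 42)
  r2 <- permutation_test(fix$features, p, pool, n_perm = 500, seed = 42)
  expect_identical(r1$null_counts, r2$null_counts)
  expect_identical(r1$p, r2$p)
  r3 <- permutation_test(fix$features, p, pool, n_perm = 500, seed = 43)
  expect_false(identical(r1$null_counts, r3$null_counts))
})

test_that("hypergeometric and explicit samplers agree in distribution", {
  fs <- make_feature_set(sprintf("s%d", 1:10),
                         lapply(1:5, function(i) sprintf("c%d_%d", i, 1:3)))
  pool <- make_pool(sprintf("ps%d", 1:40),
                    lapply(1:30, function(i) sprintf("pc%d_%d", i, 1:3)))
  set.seed(29)
  p <- setNames(runif(10 + 15 + 40 + 90),
                c(fs$simple, unlist(fs$complex), pool$simple,
                  unlist(pool$complex)))
  fast <- permutation_test(fs, p, pool, n_perm = 4000, seed = 1)
  slow <- permutation_test(fs, p, pool, n_perm = 4000, seed = 1,
                           force_loop = TRUE)
  expect_lt(abs(mean(fast$null_counts) - mean(slow$null_counts)), 0.25)
  expect_lt(abs(sd(fast$null_counts) - sd(slow$null_counts)), 0.25)
  brks <- unique(quantile(c(fast$null_counts, slow$null_counts),
                          probs = seq(0, 1, 0.2)))
  f1 <- table(cut(fast$null_counts, brks, include.lowest = TRUE))
  f2 <- table(cut(slow$null_counts, brks, include.lowest = TRUE))
  chi <- suppressWarnings(chisq.test(rbind(f1, f2)))
  expect_gt(chi$p.value, 0.001)
})

test_that("a gene with only p = 1 SNPs gets permuted p 1 under an enriched pool", {
  fs <- make_feature_set(c("g1", "g2"), list(c("g3", "g4")))
  pool <- make_pool(sprintf("ps%d", 1:20),
                    lapply(1:10, function(i) sprintf("pc%d_%d", i, 1:2)))
  p <- setNames(c(rep(1, 4), rep(0.01, 40)),
                c("g1", "g2", "g3", "g4", pool$simple, unlist(pool$complex)))
  r <- permutation_test(fs, p, pool, n_perm = 200, seed = 5)
  expect_equal(r$observed, 0L)
  expect_equal(r$p, 1)
})

test_that("per-gene investigation is reproducible and shaped like a gene table", {
  panel <- generate_reference_panel(panel_config(
    n_haplotypes = 300, n_chromosomes = 6, blocks_per_chromosome = 10,
    seed = 91
  ))
  ann <- generate_annotations(panel, n_genes = 8, pathway_genes = 5,
                              pathway_x_genes = 1, snps_per_gene = c(3, 8),
                              seed = 6)
  blocks <- find_blocks(panel)
  feats <- suppressWarnings(
    pathway_features(ann$pathway, ann$annotations, panel$snps, blocks)
  )
  set.seed(7)
  p <- setNames(runif(nrow(panel$snps)), panel$snps$id)
  pool <- genome_feature_pool(blocks, panel$snps, p,
                              exclude_snps = feats$snp_ids)
  inv1 <- investigate(feats, ann$annotations, p, pool, n_perm = 300, seed = 12)
  inv2 <- investigate(feats, ann$annotations, p, pool, n_perm = 300, seed = 12)
  expect_identical(inv1$genes, inv2$genes)
  expect_equal(nrow(inv1$genes), 5)
  expect_named(inv1$genes, c("gene", "chr", "n_simple", "n_complex",
                             "observed", "p_perm"))
  expect_true(all(inv1$genes$p_perm >= 0 & inv1$genes$p_perm <= 1, na.rm = TRUE))
  expect_true(all(inv1$snp_table$snp %in% unlist(feats$gene_snps)))
})

test_that("the genome pool excludes pathway SNPs and X when asked", {
  panel <- small_panel(seed = 95)
  blocks <- find_blocks(panel)
  set.seed(8)
  p <- setNames(runif(nrow(panel$snps)), panel$snps$id)
  excl <- panel$snps$id[1:20]
  pool <- genome_feature_pool(blocks, panel$snps, p, exclude_snps = excl)
  expect_false(any(excl %in% pool$simple))
  expect_false(any(excl %in% unlist(pool$complex)))
  pool_nox <- genome_feature_pool(blocks, panel$snps, p, exclude_chr = "X")
  x_ids <- panel$snps$id[panel$snps$chr == "X"]
  expect_false(any(x_ids %in% c(pool_nox$simple, unlist(pool_nox$complex))))
})
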