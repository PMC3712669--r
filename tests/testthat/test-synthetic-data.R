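test_that("panel genotypes are valid dosages with frequencies in range", {
  panel <- small_panel(seed = 21)
  G <- panel_genotypes(panel)
  expect_true(all(G %in% 0:2))
  expect_true(all(panel$haplotypes %in% 0:1))
  # realized counted-allele frequencies stay near the configured range
  # (three-sigma binomial slack at 400 haplotypes)
  tol <- 3 * sqrt(0.25 / 400)
  expect_true(all(panel$snps$freq >= 0.1 - tol))
  expect_true(all(panel$snps$freq <= 0.5 + tol))
})

test_that("identical seeds reproduce identical panels and cohorts", {
  p1 <- small_panel(seed = 5)
  p2 <- small_panel(seed = 5)
  expect_identical(p1$haplotypes, p2$haplotypes)
  expect_identical(p1$snps, p2$snps)
  c1 <- generate_cohort(p1, cohort_config(50, 60, seed = 9))
  c2 <- generate_cohort(p1, cohort_config(50, 60, seed = 9))
  expect_identical(c1$genotypes, c2$genotypes)
  expect_identical(c1$subjects, c2$subjects)
})

test_that("singleton_fraction = 1 yields independent SNPs and no blocks", {
  panel <- generate_reference_panel(panel_config(
    n_haplotypes = 400, n_chromosomes = 2, blocks_per_chromosome = 5,
    singleton_fraction = 1, seed = 3
  ))
  expect_length(panel$blocks, 0)
  blocks <- find_blocks(panel, threshold = 0.8)
  expect_length(blocks, 0)
})

test_that("within_block_r2 = 1 makes block member columns identical", {
  panel <- generate_reference_panel(panel_config(
    n_haplotypes = 200, n_chromosomes = 1, blocks_per_chromosome = 1,
    block_size_range = c(3, 3), singleton_fraction = 0, within_block_r2 = 1,
    include_x = FALSE, seed = 7
  ))
  ids <- panel$blocks[[1]]
  expect_length(ids, 3)
  H <- panel$haplotypes[, ids]
  expect_identical(H[, 1], H[, 2])
  expect_identical(H[, 1], H[, 3])
})

test_that("realized within-block r2 tracks the configured target", {
  panel <- generate_reference_panel(panel_config(
    n_haplotypes = 1000, n_chromosomes = 3, blocks_per_chromosome = 8,
    block_size_range = c(3, 6), within_block_r2 = 0.8, seed = 13
  ))
  r2s <- unlist(lapply(panel$blocks, function(ids) {
    r <- stats::cor(panel$haplotypes[, ids])^2
    r[upper.tri(r)]
  }))
  expect_gt(mean(r2s), 0.7)
  expect_lt(mean(r2s), 0.9)
})

test_that("flip-rate solver closes the loop between eps and r2", {
  for (q in c(0.1, 0.3, 0.5)) {
    for (r2 in c(0.5, 0.8, 0.95)) {
      fr <- flip_rate_for_r2(q, r2)
      p0 <- fr$p0
      eps <- fr$eps
      qq <- p0 + eps * (1 - 2 * p0)
      expect_equal(qq, q, tolerance = 1e-8)
      r_back <- p0 * (1 - p0) * (1 - 2 * eps)^2 / (q * (1 - q))
      expect_equal(r_back^2, r2, tolerance = 1e-8)
    }
  }
})

test_that("cohorts hit exact case/control counts and X males are 0/2", {
  panel <- small_panel(seed = 31)
  coh <- generate_cohort(panel, cohort_config(80, 120, seed = 2))
  expect_equal(sum(coh$subjects$status == 1), 80)
  expect_equal(sum(coh$subjects$status == 0), 120)
  x_ids <- panel$snps$id[panel$snps$chr == "X"]
  male <- coh$subjects$sex == "M"
  expect_true(all(coh$genotypes[male, x_ids] %in% c(0L, 2L)))
  female <- !male
  expect_true(any(coh$genotypes[female, x_ids] == 1L))
  # cases carry IOP values with some missing; controls carry none
  iop_cases <- coh$subjects$iop[coh$subjects$status == 1]
  expect_true(any(is.na(iop_cases)) && any(!is.na(iop_cases)))
  expect_true(all(is.na(coh$subjects$iop[coh$subjects$status == 0])))
})

test_that("infeasible case counts fail with an informative error", {
  panel <- small_panel(seed = 31)
  cfg <- cohort_config(50, 50, intercept = -30, max_attempts = 3, seed = 1)
  expect_error(generate_cohort(panel, cfg), "infeasible")
})

test_that("unknown causal SNPs are rejected", {
  panel <- small_panel(seed = 31)
  cfg <- cohort_config(10, 10, causal_snps = data.frame(snp = "rs999999",
                                                        beta = 0.3))
  expect_error(generate_cohort(panel, cfg), "not in panel")
})

test_that("a simulated effect of log OR = log(1.5) is recovered within 3 SE", {
  panel <- generate_reference_panel(panel_config(
    n_haplotypes = 400, n_chromosomes = 2, blocks_per_chromosome = 3,
    singleton_fraction = 0.5, maf_range = c(0.2, 0.4), include_x = FALSE,
    seed = 17
  ))
  target <- panel$snps$id[is.na(panel$snps$block)][1]
  coh <- generate_cohort(panel, cohort_config(
    2000, 2000, causal_snps = data.frame(snp = target, beta = log(1.5)),
    seed = 23
  ))
  fit <- logistic_association(coh$genotypes[, target], coh$subjects$status,
                              coh$subjects[, c("age", "sex", "site")])
  expect_equal(fit$status, "ok")
  expect_lt(abs(fit$beta - log(1.5)), 3 * fit$se)
})

test_that("gene annotations tile SNP regions and shape the pathway", {
  panel <- small_panel(seed = 41)
  # background genes may not all fit on a small panel; that is fine
  ann <- suppressWarnings(
    generate_annotations(panel, n_genes = 10, pathway_genes = 6,
                         pathway_x_genes = 1, seed = 2)
  )
  expect_true(all(ann$annotations$start <= ann$annotations$end))
  expect_length(ann$pathway$genes, 6)
  pw_ann <- ann$annotations[ann$annotations$symbol %in% ann$pathway$genes, ]
  expect_equal(sum(pw_ann$chr == "X"), 1)
  # every pathway gene window holds at least one genotyped SNP
  for (g in ann$pathway$genes) {
    row <- ann$annotations[ann$annotations$symbol == g, ]
    expect_gt(length(map_snps_to_gene(panel$snps, row, ann$pathway$flank)), 0)
  }
})

test_that("a pathway mimicking the 23-gene/2-X shape is constructible", {
  panel <- generate_reference_panel(panel_config(
    n_haplotypes = 200, n_chromosomes = 15, blocks_per_chromosome = 8,
    seed = 19
  ))
  ann <- generate_annotations(panel, n_genes = 30, pathway_genes = 23,
                              pathway_x_genes = 2, seed = 4)
  expect_length(ann$pathway$genes, 23)
  pw_ann <- ann$annotations[ann$annotations$symbol %in% ann$pathway$genes, ]
  expect_equal(sum(pw_ann$chr == "X"), 2)
  expect_gt(length(unique(pw_ann$chr)), 10)
})
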