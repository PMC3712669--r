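snp_frame <- function(pos, chr = "1") {
  data.frame(id = sprintf("v%03d", seq_along(pos)), chr = chr, pos = pos,
             stringsAsFactors = FALSE)
}

test_that("pairwise r2 is 1 for duplicated columns and ~0 for independent SNPs", {
  set.seed(1)
  g <- matrix(rbinom(2000, 2, 0.3), ncol = 2)
  g <- cbind(g, g[, 2])
  snps <- snp_frame(c(100, 200, 300))
  colnames(g) <- snps$id
  r2 <- pairwise_r2(g, snps, "1")
  expect_equal(unname(r2["v002", "v003"]), 1, tolerance = 1e-12)
  expect_equal(unname(diag(r2)), rep(1, 3))
  expect_equal(r2, t(r2))

  set.seed(2)
  gi <- matrix(rbinom(1000 * 12, 2, 0.3), nrow = 1000)
  si <- snp_frame(seq(100, by = 100, length.out = 12))
  colnames(gi) <- si$id
  r2i <- pairwise_r2(gi, si, "1")
  expect_lt(mean(r2i[upper.tri(r2i)]), 0.01)
})

test_that("r2 on a four-haplotype toy equals the hand-computed value", {
  # haplotypes AB, AB, aB, ab; allele 1 = A at locus 1, B at locus 2
  h <- cbind(c(1, 1, 0, 0), c(1, 1, 1, 0))
  snps <- snp_frame(c(100, 200))
  colnames(h) <- snps$id
  r2 <- pairwise_r2(h, snps, "1")
  # pAB = 1/2, pA = 1/2, pB = 3/4; D = 1/2 - 3/8 = 1/8
  # r2 = D^2 / (pA qA pB qB) = (1/64)/(1/4 * 3/16) = 1/3
  expect_equal(unname(r2["v001", "v002"]), 1 / 3, tolerance = 1e-12)
})

test_that("monomorphic SNPs get r2 0 with a message", {
  g <- cbind(rbinom(100, 2, 0.4), rep(1L, 100))
  snps <- snp_frame(c(100, 200))
  colnames(g) <- snps$id
  expect_message(r2 <- pairwise_r2(g, snps, "1"), "monomorphic")
  expect_equal(unname(r2["v001", "v002"]), 0)
})

test_that("the greedy any-member rule chains SNPs into one block", {
  snps <- snp_frame(c(100, 200, 300))
  r2 <- matrix(c(1, 0.9, 0.5,
                 0.9, 1, 0.9,
                 0.5, 0.9, 1), 3, 3,
               dimnames = list(snps$id, snps$id))
  blocks <- build_blocks(r2, snps, threshold = 0.8)
  expect_length(blocks, 1)
  expect_equal(blocks[[1]]$snps, snps$id)
  expect_equal(blocks[[1]]$start, 100)
  expect_equal(blocks[[1]]$end, 300)
})

test_that("zero correlation yields no blocks; ordering does not matter", {
  snps <- snp_frame(c(100, 200, 300, 400))
  r2 <- diag(4)
  dimnames(r2) <- list(snps$id, snps$id)
  expect_length(build_blocks(r2, snps), 0)

  # block structure recovered identically under shuffled row order
  snps2 <- snp_frame(c(10, 20, 1000, 1010))
  r2b <- diag(4)
  r2b[1, 2] <- r2b[2, 1] <- 0.95
  r2b[3, 4] <- r2b[4, 3] <- 0.95
  dimnames(r2b) <- list(snps2$id, snps2$id)
  b1 <- build_blocks(r2b, snps2)
  shuffle <- c(3, 1, 4, 2)
  b2 <- build_blocks(r2b[shuffle, shuffle], snps2[shuffle, ])
  expect_equal(b1, b2)
  expect_length(b1, 2)
})

test_that("ground-truth blocks are recovered with Jaccard >= 0.9", {
  panel <- generate_reference_panel(panel_config(
    n_haplotypes = 600, n_chromosomes = 3, blocks_per_chromosome = 8,
    block_size_range = c(2, 6), within_block_r2 = 0.95, seed = 71
  ))
  found <- find_blocks(panel, threshold = 0.8)
  expect_gte(block_jaccard(panel$blocks, found), 0.9)
})

test_that("gene windows are closed intervals of exactly +/- flank bases", {
  gene <- data.frame(symbol = "G1", chr = "1", start = 100000, end = 120000)
  snps <- snp_frame(c(100000 - 50000, 100000 - 50001, 120000 + 50000,
                      120000 + 50001, 110000))
  hits <- map_snps_to_gene(snps, gene, flank = 50000)
  expect_setequal(hits, c("v001", "v003", "v005"))
  # flank 0: only SNPs inside the transcript bounds
  hits0 <- map_snps_to_gene(snps, gene, flank = 0)
  expect_equal(hits0, "v005")
  # off-chromosome SNPs never map
  snps_x <- snp_frame(110000, chr = "X")
  expect_length(map_snps_to_gene(snps_x, gene, flank = 50000), 0)
})

test_that("decompose partitions mapped SNPs into simple and complex features", {
  # a gene region shaped like the densest pathway genes: 11 blocks with >= 2
  # mapped SNPs plus 11 singletons -> 11 complex and 11 simple features
  blocks <- lapply(1:11, function(i) {
    list(chr = "22", snps = sprintf("b%02d_%d", i, 1:3),
         start = i * 1000, end = i * 1000 + 20)
  })
  mapped <- c(unlist(lapply(blocks, `[[`, "snps")), sprintf("solo%02d", 1:11))
  fs <- decompose_features(mapped, blocks, owner = "gene22")
  expect_length(fs$complex, 11)
  expect_length(fs$simple, 11)
  arch <- architecture(fs)
  expect_equal(arch$n_simple, 11)
  expect_equal(arch$sizes, rep(3L, 11))

  # a lone mapped SNP from a block is demoted to a simple feature
  fs2 <- decompose_features(c("b01_1", "solo01"), blocks, owner = "thin")
  expect_length(fs2$complex, 0)
  expect_setequal(fs2$simple, c("b01_1", "solo01"))
})

test_that("feature partition conserves totals over random fixtures", {
  set.seed(202)
  for (i in 1:100) {
    n_blocks <- sample(3:8, 1)
    blocks <- lapply(seq_len(n_blocks), function(b) {
      list(chr = "1", snps = sprintf("r%d_b%d_%d", i, b, seq_len(sample(2:6, 1))),
           start = b * 100, end = b * 100 + 50)
    })
    universe <- c(unlist(lapply(blocks, `[[`, "snps")),
                  sprintf("r%d_solo%d", i, 1:10))
    mapped <- sample(universe, sample(5:length(universe), 1))
    fs <- decompose_features(mapped, blocks)
    members <- c(fs$simple, unlist(fs$complex))
    expect_equal(sort(members), sort(unique(mapped)))
    expect_false(anyDuplicated(members) > 0)
  }
})

test_that("architecture (0 simple, one block of 5) is derived deterministically", {
  blocks <- list(list(chr = "1", snps = sprintf("s%d", 1:5),
                      start = 1, end = 500))
  fs <- decompose_features(sprintf("s%d", 1:5), blocks)
  arch <- architecture(fs)
  expect_equal(arch$n_simple, 0)
  expect_equal(arch$sizes, 5L)
})

test_that("SNPs shared by overlapping genes count once in the pathway union", {
  panel <- small_panel(seed = 81)
  snps <- panel$snps
  # two genes whose windows overlap around the same SNP run
  mid <- snps[snps$chr == "1", ]
  mid <- mid[order(mid$pos), ]
  ann <- data.frame(
    symbol = c("GA", "GB"),
    chr = "1",
    start = c(mid$pos[1], mid$pos[3]),
    end = c(mid$pos[6], mid$pos[8]),
    stringsAsFactors = FALSE
  )
  pw <- pathway_definition("ovl", c("GA", "GB"), flank = 0, annotations = ann)
  blocks <- find_blocks(panel)
  feats <- pathway_features(pw, ann, snps, blocks)
  shared <- intersect(feats$gene_snps$GA, feats$gene_snps$GB)
  expect_gt(length(shared), 0)
  expect_equal(feats$snp_ids, unique(feats$snp_ids))
  expect_setequal(feats$snp_ids, union(feats$gene_snps$GA, feats$gene_snps$GB))
})
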