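#' Configuration for a synthetic reference genotype panel
#'
#' Describes a haplotype panel with block-structured linkage disequilibrium
#' (LD). Each chromosome carries a set of LD blocks (runs of correlated SNPs)
#' interleaved with singleton SNPs that belong to no block. Within a block,
#' haplotype alleles are noisy copies of a shared block "tag" allele; the
#' per-SNP copy-error (flip) rate is solved so that the pairwise squared
#' correlation between member SNPs hits `within_block_r2` in expectation
#' (see [flip_rate_for_r2()]).
#'
#' @param n_haplotypes Number of haplotypes (two per diploid individual).
#' @param n_chromosomes Number of chromosomes. When `include_x` is `TRUE`,
#'   the last one is labelled `"X"` and the rest `"1"`, `"2"`, ...
#' @param blocks_per_chromosome Number of ground-truth LD blocks per
#'   chromosome.
#' @param block_size_range Length-2 integer vector, minimum and maximum
#'   number of SNPs per block (minimum must be >= 2).
#' @param singleton_fraction Fraction of SNPs that belong to no block, in
#'   \[0, 1\]. At 1 the panel has no blocks at all: each chromosome instead
#'   carries `blocks_per_chromosome * mean(block_size_range)` independent
#'   singleton SNPs.
#' @param within_block_r2 Target pairwise squared correlation between SNPs
#'   of one block, in \[0, 1\].
#' @param maf_range Length-2 numeric vector in (0, 0.5], the range the
#'   counted-allele frequencies are drawn from.
#' @param include_x Label the last chromosome `"X"`?
#' @param seed Integer seed; identical seeds give byte-identical panels.
#'
#' @return An object of class `panel_config`.
#' @seealso [generate_reference_panel()]
#' @export
panel_config <- function(n_haplotypes = 1000L,
                         n_chromosomes = 15L,
                         blocks_per_chromosome = 12L,
                         block_size_range = c(2L, 8L),
                         singleton_fraction = 0.35,
                         within_block_r2 = 0.9,
                         maf_range = c(0.05, 0.5),
                         include_x = TRUE,
                         seed = 1L) {
  stopifnot_scalar_count(n_haplotypes, "n_haplotypes", min = 2L)
  if (n_haplotypes %% 2L != 0L) {
    stop("`n_haplotypes` must be even (two haplotypes per individual)",
         call. = FALSE)
  }
  stopifnot_scalar_count(n_chromosomes, "n_chromosomes")
  stopifnot_scalar_count(blocks_per_chromosome, "blocks_per_chromosome", min = 0L)
  if (length(block_size_range) != 2L || block_size_range[1] < 2L ||
      block_size_range[2] < block_size_range[1]) {
    stop("`block_size_range` must be c(min, max) with min >= 2", call. = FALSE)
  }
  stopifnot_range(singleton_fraction, "singleton_fraction", 0, 1)
  stopifnot_range(within_block_r2, "within_block_r2", 0, 1)
  if (length(maf_range) != 2L || maf_range[2] < maf_range[1]) {
    stop("`maf_range` must be c(min, max)", call. = FALSE)
  }
  stopifnot_range(maf_range, "maf_range", 0, 0.5, lo_open = TRUE)
  cfg <- list(
    n_haplotypes = as.integer(n_haplotypes),
    n_chromosomes = as.integer(n_chromosomes),
    blocks_per_chromosome = as.integer(blocks_per_chromosome),
    block_size_range = as.integer(block_size_range),
    singleton_fraction = singleton_fraction,
    within_block_r2 = within_block_r2,
    maf_range = maf_range,
    include_x = isTRUE(include_x),
    seed = as.integer(seed)
  )
  structure(cfg, class = "panel_config")
}

#' Block-tag flip rate that yields a target within-block r-squared
#'
#' Within a block, a haplotype's allele at each member SNP is the block tag
#' (frequency `p0`) flipped independently with probability `eps`. The
#' correlation between two member SNPs is then
#' `r = p0 (1 - p0) (1 - 2 eps)^2 / (q (1 - q))` with marginal allele
#' frequency `q = p0 + eps (1 - 2 p0)`. Given the desired marginal frequency
#' `q` and target squared correlation `r2`, this solves for `eps` (and the
#' implied `p0 = (q - eps) / (1 - 2 eps)`).
#'
#' @param q Desired marginal counted-allele frequency, in (0, 0.5].
#' @param r2 Target pairwise squared correlation, in \[0, 1\].
#' @return List with elements `eps` and `p0`.
#' @export
flip_rate_for_r2 <- function(q, r2) {
  stopifnot_range(q, "q", 0, 0.5, lo_open = TRUE)
  stopifnot_range(r2, "r2", 0, 1)
  if (r2 >= 1) return(list(eps = 0, p0 = q))
  r_target <- sqrt(r2)
  corr_at <- function(eps) {
    p0 <- (q - eps) / (1 - 2 * eps)
    p0 * (1 - p0) * (1 - 2 * eps)^2 / (q * (1 - q))
  }
  upper <- min(q, 0.5) - 1e-9
  if (r2 <= 0) {
    # tag carries no information: p0 -> 0, every SNP is an independent flip
    return(list(eps = upper, p0 = (q - upper) / (1 - 2 * upper)))
  }
  root <- stats::uniroot(function(e) corr_at(e) - r_target,
                         lower = 0, upper = upper, tol = 1e-12)
  eps <- root$root
  list(eps = eps, p0 = (q - eps) / (1 - 2 * eps))
}

# Lay out SNP records for one chromosome: blocks and singletons shuffled as
# units, cumulative positions with wide gaps between units and narrow gaps
# within blocks. Returns a data.frame of per-SNP generative parameters.
layout_chromosome <- function(cfg, chrom) {
  n_blocks <- cfg$blocks_per_chromosome
  if (cfg$singleton_fraction >= 1 || n_blocks == 0L) {
    sizes <- integer(0)
  } else {
    size_choices <- seq(cfg$block_size_range[1], cfg$block_size_range[2])
    sizes <- size_choices[sample.int(length(size_choices), n_blocks,
                                     replace = TRUE)]
  }
  n_block_snps <- sum(sizes)
  sf <- cfg$singleton_fraction
  n_singletons <- if (sf >= 1) {
    n_blocks * round(mean(cfg$block_size_range))
  } else if (sf <= 0) {
    0L
  } else {
    max(0L, round(n_block_snps * sf / (1 - sf)))
  }

  unit_sizes <- c(sizes, rep(1L, n_singletons))
  if (length(unit_sizes) == 0L) {
    stop("degenerate panel config: chromosome with zero SNPs", call. = FALSE)
  }
  unit_is_block <- c(rep(TRUE, length(sizes)), rep(FALSE, n_singletons))
  ord <- sample.int(length(unit_sizes))
  unit_sizes <- unit_sizes[ord]
  unit_is_block <- unit_is_block[ord]
  n_units <- length(unit_sizes)
  m <- sum(unit_sizes)
  unit_of <- rep.int(seq_len(n_units), unit_sizes)

  # wide gaps between units, narrow gaps between SNPs of one block
  gap <- sample(500:2000, m, replace = TRUE)
  first <- !duplicated(unit_of)
  gap[first] <- sample(20000:60000, n_units, replace = TRUE)
  gap[1] <- 0
  pos <- as.integer(1e6 + cumsum(gap))

  qs <- stats::runif(n_units, cfg$maf_range[1], cfg$maf_range[2])
  q <- qs[unit_of]
  block <- rep(NA_character_, m)
  eps <- p0 <- rep(NA_real_, m)
  bunits <- which(unit_is_block)
  if (length(bunits)) {
    labs <- sprintf("%s_b%02d", chrom, seq_along(bunits))
    for (k in seq_along(bunits)) {
      u <- bunits[k]
      fr <- flip_rate_for_r2(qs[u], cfg$within_block_r2)
      members <- unit_of == u
      block[members] <- labs[k]
      eps[members] <- fr$eps
      p0[members] <- fr$p0
    }
  }
  data.frame(chr = chrom, pos = pos, block = block,
             q = q, eps = eps, p0 = p0, stringsAsFactors = FALSE)
}

# Draw haplotypes (0/1 matrix, n_hap x n_snp) from per-SNP generative
# parameters. Shared by the panel generator and the cohort generator so
# cohorts are fresh draws from the same population.
draw_haplotypes <- function(gen, n_hap, fixed_tags = NULL) {
  m <- nrow(gen)
  H <- matrix(0L, nrow = n_hap, ncol = m)
  bcol <- which(!is.na(gen$block))
  if (length(bcol)) {
    labels <- gen$block[bcol]
    ublocks <- unique(labels)
    bi <- match(labels, ublocks)
    p0 <- gen$p0[bcol[!duplicated(labels)]]
    tags <- stats::runif(n_hap * length(ublocks)) < rep(p0, each = n_hap)
    dim(tags) <- c(n_hap, length(ublocks))
    if (!is.null(fixed_tags)) {
      hit <- match(colnames(fixed_tags), ublocks)
      ok <- !is.na(hit)
      tags[, hit[ok]] <- fixed_tags[, ok, drop = FALSE]
    }
    X <- tags[, bi, drop = FALSE] + 0L
    # flip rates are small: draw flip counts per SNP, then flip positions
    nflip <- stats::rbinom(length(bcol), n_hap, gen$eps[bcol])
    pos <- which(nflip > 0L)
    if (length(pos)) {
      cols <- rep.int(pos, nflip[pos])
      rows <- unlist(lapply(nflip[pos], function(k) sample.int(n_hap, k)),
                     use.names = FALSE)
      idx <- rows + (cols - 1L) * n_hap
      X[idx] <- 1L - X[idx]
    }
    H[, bcol] <- X
  }
  singles <- which(is.na(gen$block))
  if (length(singles)) {
    S <- stats::runif(n_hap * length(singles)) < rep(gen$q[singles], each = n_hap)
    dim(S) <- c(n_hap, length(singles))
    H[, singles] <- S
  }
  H
}

#' Generate a synthetic reference genotype panel with block LD structure
#'
#' Simulates `n_haplotypes` haplotypes whose SNPs are organised in
#' ground-truth LD blocks (pairwise r-squared near `within_block_r2`)
#' separated by independent singleton SNPs. Ground-truth block membership is
#' returned so block-detection can be validated against it.
#'
#' @param config A [panel_config()].
#' @return An object of class `snp_panel`: a list with
#'   \describe{
#'     \item{haplotypes}{integer 0/1 matrix, haplotypes x SNPs.}
#'     \item{snps}{data.frame with `id`, `chr`, `pos` (1-based), `ref`,
#'       `alt`, `freq` (realized counted-allele frequency), `block`
#'       (ground-truth block label or `NA`).}
#'     \item{blocks}{named list: ground-truth block -> member SNP ids in
#'       position order.}
#'     \item{gen}{per-SNP generative parameters, reused by
#'       [generate_cohort()].}
#'     \item{config}{the configuration.}
#'   }
#' @examples
#' panel <- generate_reference_panel(panel_config(
#'   n_haplotypes = 200, n_chromosomes = 2, blocks_per_chromosome = 3,
#'   seed = 7
#' ))
#' dim(panel$haplotypes)
#' @export
generate_reference_panel <- function(config) {
  if (!inherits(config, "panel_config")) {
    stop("`config` must be a panel_config()", call. = FALSE)
  }
  with_seed(config$seed, {
    chroms <- as.character(seq_len(config$n_chromosomes))
    if (config$include_x) chroms[config$n_chromosomes] <- "X"
    gen <- do.call(rbind, lapply(chroms, function(ch) layout_chromosome(config, ch)))
    gen$id <- sprintf("rs%06d", seq_len(nrow(gen)))
    base <- c("A", "C", "G", "T")
    ref <- sample(base, nrow(gen), replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(base, r), 1L), character(1))
    H <- draw_haplotypes(gen, config$n_haplotypes)
    colnames(H) <- gen$id
    snps <- data.frame(
      id = gen$id, chr = gen$chr, pos = gen$pos,
      ref = ref, alt = alt,
      freq = colMeans(H), block = gen$block,
      stringsAsFactors = FALSE
    )
    blocks <- split(gen$id, gen$block)
    blocks <- lapply(blocks, function(ids) ids[order(gen$pos[match(ids, gen$id)])])
    structure(
      list(haplotypes = H, snps = snps, blocks = blocks,
           gen = gen[, c("id", "chr", "pos", "block", "q", "eps", "p0")],
           config = config),
      class = "snp_panel"
    )
  })
}

#' Diploid genotypes of a reference panel
#'
#' Pairs consecutive haplotypes into diploid individuals and returns the
#' dosage matrix (values 0/1/2) used for LD estimation.
#'
#' @param panel An `snp_panel`.
#' @return Integer matrix, individuals x SNPs.
#' @export
panel_genotypes <- function(panel) {
  stopifnot(inherits(panel, "snp_panel"))
  H <- panel$haplotypes
  odd <- seq(1L, nrow(H), by = 2L)
  G <- H[odd, , drop = FALSE] + H[odd + 1L, , drop = FALSE]
  rownames(G) <- NULL
  G
}

#' @export
print.snp_panel <- function(x, ...) {
  cat(sprintf(
    "<snp_panel> %d haplotypes, %d SNPs on %d chromosomes (%d ground-truth blocks)\n",
    nrow(x$haplotypes), nrow(x$snps),
    length(unique(x$snps$chr)), length(x$blocks)
  ))
  invisible(x)
}
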