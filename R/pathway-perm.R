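#' Count significant features of a feature set
#'
#' A simple feature is significant iff its SNP's p-value is below `alpha`;
#' a complex feature is significant iff any member SNP's p-value is below
#' `alpha`. Member SNPs without a p-value are ignored; a feature with no
#' p-value at all is dropped (count reported in the `n_dropped` attribute).
#'
#' @param features A `feature_set`.
#' @param p Named numeric vector of per-SNP p-values.
#' @param alpha Feature significance threshold (default 0.05).
#' @return Integer count of significant features, with attributes
#'   `n_features` (features evaluated) and `n_dropped`.
#' @examples
#' fs <- structure(list(owner = "toy", simple = c("a", "b"),
#'                      complex = list(c("c", "d"))), class = "feature_set")
#' count_significant(fs, c(a = 0.01, b = 0.5, c = 0.2, d = 0.04))
#' @export
count_significant <- function(features, p, alpha = 0.05) {
  stopifnot(inherits(features, "feature_set"))
  dropped <- 0L
  count <- 0L
  evaluated <- 0L
  ps <- p[features$simple]
  known <- !is.na(ps)
  dropped <- dropped + sum(!known)
  evaluated <- evaluated + sum(known)
  count <- count + sum(ps[known] < alpha)
  for (members in features$complex) {
    pm <- p[members]
    pm <- pm[!is.na(pm)]
    if (length(pm) == 0L) {
      dropped <- dropped + 1L
      next
    }
    evaluated <- evaluated + 1L
    if (min(pm) < alpha) count <- count + 1L
  }
  if (dropped > 0L) {
    message(sprintf("count_significant: %d feature(s) with no p-value dropped",
                    dropped))
  }
  structure(as.integer(count), n_features = evaluated, n_dropped = dropped)
}

#' Genome-wide feature pool for architecture-matched null sampling
#'
#' Builds the pool of candidate null features from the panel's LD blocks
#' and the meta-analyzed p-values: every SNP with a p-value that belongs to
#' no block is a candidate simple feature, and every block is a candidate
#' complex feature (its members restricted to SNPs with p-values, size
#' counted accordingly). By default the tested set's own features remain in
#' the pool — a random feature set drawn from the whole genome may land on
#' them — which keeps the permutation test calibrated when the tested
#' pathway is a non-negligible fraction of the genome (the null draws then
#' co-vary with the observed count instead of being centred on an
#' independent, finite-pool estimate). `exclude_snps` removes chosen SNPs'
#' features from the pool (e.g. to forbid self-overlap), and X-chromosome
#' features can be excluded wholesale for male-only or gender-combined
#' analyses.
#'
#' @param blocks `ld_blocks` for the whole panel.
#' @param snps SNP table (`id`, `chr`, `pos`).
#' @param p Named numeric vector of per-SNP p-values.
#' @param exclude_snps SNP ids to exclude (typically the pathway's own).
#' @param exclude_chr Chromosome labels to exclude entirely (e.g. `"X"`).
#' @return Object of class `feature_pool`: list with `simple` (ids),
#'   `complex` (list of member-id vectors), `complex_sizes`.
#' @export
genome_feature_pool <- function(blocks, snps, p,
                                exclude_snps = character(0),
                                exclude_chr = character(0)) {
  has_p <- names(p)[!is.na(p)]
  snps <- snps[snps$id %in% has_p & !(snps$chr %in% exclude_chr), ]
  in_block <- unlist(lapply(blocks, `[[`, "snps"), use.names = FALSE)
  complex <- list()
  for (b in blocks) {
    if (b$chr %in% exclude_chr) next
    members <- intersect(b$snps, snps$id)
    if (length(members) < 2L) next
    if (any(members %in% exclude_snps)) next
    complex[[length(complex) + 1L]] <- members
  }
  simple <- setdiff(setdiff(snps$id, in_block), exclude_snps)
  structure(
    list(simple = simple, complex = complex,
         complex_sizes = as.integer(lengths(complex))),
    class = "feature_pool"
  )
}

#' @export
print.feature_pool <- function(x, ...) {
  cat(sprintf("<feature_pool> %d simple + %d complex features (sizes %s)\n",
              length(x$simple), length(x$complex),
              paste(range(c(x$complex_sizes, NA), na.rm = TRUE), collapse = "-")))
  invisible(x)
}

#' Draw one architecture-matched null feature selection
#'
#' Samples, uniformly and without replacement within the draw,
#' `n_simple` simple features from the pool and, for each complex-feature
#' size in the architecture's multiset, one complex feature of matching
#' size. When a size class is exhausted the nearest available size within
#' +/-1, then +/-2, is used (features at the two equidistant sizes are
#' pooled and sampled uniformly); deviations are recorded. With
#' `size_match = "strict"` exhaustion is an error instead.
#'
#' @param arch A [architecture()] result.
#' @param pool A [genome_feature_pool()].
#' @param size_match `"fallback"` (default) or `"strict"`.
#' @return List with `simple` (sampled ids), `complex` (list of member-id
#'   vectors), `complex_idx` (pool indices), and `fallback` (data.frame of
#'   requested vs used sizes; zero rows when the draw matched exactly).
#'   Uses the caller's RNG stream.
#' @export
sample_matched_null <- function(arch, pool, size_match = c("fallback", "strict")) {
  size_match <- match.arg(size_match)
  stopifnot(inherits(arch, "pathway_architecture"))
  if (arch$n_simple > length(pool$simple)) {
    stop(sprintf("pool exhausted: need %d simple features, have %d",
                 arch$n_simple, length(pool$simple)), call. = FALSE)
  }
  simple <- if (arch$n_simple > 0L) {
    pool$simple[sample.int(length(pool$simple), arch$n_simple)]
  } else {
    character(0)
  }
  sizes <- sort(arch$sizes, decreasing = TRUE)
  avail <- rep(TRUE, length(pool$complex))
  picked <- integer(length(sizes))
  fb_req <- fb_used <- integer(0)
  for (k in seq_along(sizes)) {
    s <- sizes[k]
    cand <- which(avail & pool$complex_sizes == s)
    used_size <- s
    if (length(cand) == 0L) {
      if (size_match == "strict") {
        stop(sprintf("pool exhausted for complex features of size %d (strict matching)", s),
             call. = FALSE)
      }
      for (d in 1:2) {
        cand <- which(avail & abs(pool$complex_sizes - s) == d &
                        pool$complex_sizes >= 2L)
        if (length(cand)) break
      }
      if (length(cand) == 0L) {
        stop(sprintf(
          "pool exhausted for complex features of size %d (no candidate within +/-2)", s
        ), call. = FALSE)
      }
    }
    pick <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
    if (pool$complex_sizes[pick] != s) {
      fb_req <- c(fb_req, s)
      fb_used <- c(fb_used, pool$complex_sizes[pick])
    }
    avail[pick] <- FALSE
    picked[k] <- pick
  }
  list(
    simple = simple,
    complex = pool$complex[picked],
    complex_idx = picked,
    fallback = data.frame(requested = fb_req, used = fb_used)
  )
}

#' Strict-exceedance empirical p-value
#'
#' Fraction of null counts strictly greater than the observed count,
#' computed as `k / n_perm` exactly (so 6 exceedances in 1,000 permutations
#' give 0.006). The positively biased `(k + 1) / (n_perm + 1)` estimator is
#' available as an option.
#'
#' @param observed Observed significant-feature count.
#' @param null_counts Integer vector of null significant-feature counts.
#' @param estimator `"raw"` (default, `k/N`) or `"plus_one"`.
#' @return Empirical p-value in \[0, 1\].
#' @export
empirical_p <- function(observed, null_counts, estimator = c("raw", "plus_one")) {
  estimator <- match.arg(estimator)
  k <- sum(null_counts > observed)
  n <- length(null_counts)
  if (n < 1L) stop("need at least one null count", call. = FALSE)
  if (estimator == "raw") k / n else (k + 1) / (n + 1)
}

# Per-pool-feature significance indicators at `alpha`, NA for features
# with no usable p-value.
pool_indicators <- function(pool, p, alpha) {
  ps <- p[pool$simple]
  simple_sig <- !is.na(ps) & ps < alpha
  complex_sig <- vapply(pool$complex, function(members) {
    pm <- p[members]
    pm <- pm[!is.na(pm)]
    if (length(pm) == 0L) return(NA)
    min(pm) < alpha
  }, logical(1))
  list(simple = simple_sig, complex = complex_sig)
}

#' Architecture-matched permutation test for a pathway or gene
#'
#' The observed statistic is the number of significant features of the
#' tested set ([count_significant()]). Each permutation draws an
#' architecture-matched random feature selection from the genome-wide pool
#' ([sample_matched_null()]) and counts its significant features; the
#' empirical p-value is the strictly-greater exceedance fraction
#' ([empirical_p()]). Identical seeds reproduce identical null counts.
#'
#' When every size class of the architecture is available in sufficient
#' number (no fallback possible), the per-class draws are independent
#' uniform without-replacement subsets, so each class's significant count
#' is hypergeometric; the null counts are then drawn directly from sums of
#' hypergeometrics, which is distributionally identical to the explicit
#' per-feature sampler and far faster. The explicit sampler is used
#' whenever fallback may occur (or `force_loop = TRUE`).
#'
#' @param features Tested `feature_set`.
#' @param p Named per-SNP p-value vector.
#' @param pool [genome_feature_pool()] excluding the tested set's features.
#' @param n_perm Number of permutations (default 1000).
#' @param alpha Feature significance threshold (default 0.05).
#' @param seed Integer seed, stored in the result.
#' @param estimator Passed to [empirical_p()].
#' @param size_match Passed to [sample_matched_null()].
#' @param force_loop Always use the explicit per-draw sampler.
#' @return Object of class `permutation_result`: list with `owner`,
#'   `observed`, `null_counts`, `n_perm`, `p`, `alpha`, `seed`,
#'   `n_features`, `n_fallback` (draws that needed a size fallback).
#' @export
permutation_test <- function(features, p, pool, n_perm = 1000L,
                             alpha = 0.05, seed = NULL,
                             estimator = c("raw", "plus_one"),
                             size_match = c("fallback", "strict"),
                             force_loop = FALSE) {
  estimator <- match.arg(estimator)
  size_match <- match.arg(size_match)
  if (!is.numeric(n_perm) || n_perm < 1L) {
    stop("`n_perm` must be a positive integer", call. = FALSE)
  }
  n_perm <- as.integer(n_perm)
  observed <- count_significant(features, p, alpha = alpha)
  arch <- architecture(features)
  ind <- pool_indicators(pool, p, alpha)
  if (arch$n_simple > length(pool$simple)) {
    stop(sprintf("pool exhausted: need %d simple features, have %d",
                 arch$n_simple, length(pool$simple)), call. = FALSE)
  }

  need <- table(arch$sizes)
  have <- table(pool$complex_sizes)
  exact_ok <- all(as.integer(need) <=
                    as.integer(have[names(need)]) %zero% 0)

  n_fallback <- 0L
  null_counts <- with_seed(seed, {
    if (exact_ok && !force_loop) {
      # sum of independent hypergeometric class counts
      counts <- integer(n_perm)
      sig_s <- sum(ind$simple, na.rm = TRUE)
      tot_s <- length(ind$simple)
      if (arch$n_simple > 0L) {
        counts <- counts + stats::rhyper(n_perm, sig_s, tot_s - sig_s,
                                         arch$n_simple)
      }
      for (s in as.integer(names(need))) {
        in_class <- pool$complex_sizes == s
        sig_c <- sum(ind$complex[in_class], na.rm = TRUE)
        tot_c <- sum(in_class)
        k <- as.integer(need[as.character(s)])
        counts <- counts + stats::rhyper(n_perm, sig_c, tot_c - sig_c, k)
      }
      counts
    } else {
      vapply(seq_len(n_perm), function(i) {
        draw <- sample_matched_null(arch, pool, size_match = size_match)
        if (nrow(draw$fallback) > 0L) n_fallback <<- n_fallback + 1L
        sum(ind$simple[match(draw$simple, pool$simple)], na.rm = TRUE) +
          sum(ind$complex[draw$complex_idx], na.rm = TRUE)
      }, integer(1))
    }
  })
  structure(
    list(owner = features$owner, observed = as.integer(observed),
         null_counts = as.integer(null_counts), n_perm = n_perm,
         p = empirical_p(observed, null_counts, estimator = estimator),
         alpha = alpha, seed = seed,
         n_features = attr(observed, "n_features"),
         n_fallback = n_fallback),
    class = "permutation_result"
  )
}

`%zero%` <- function(x, default) {
  x[is.na(x)] <- default
  x
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> '%s': %d of %d features significant at alpha=%g; permuted p %s (%d permutations)\n",
    x$owner, x$observed, x$n_features, x$alpha,
    format_permuted_p(x$p, x$n_perm), x$n_perm
  ))
  invisible(x)
}

#' Per-gene drill-down of a pathway signal
#'
#' Runs the architecture-matched permutation test for every gene of the
#' pathway (each with its own architecture, against the same genome-wide
#' pool) and tabulates the member SNPs' p-values, mirroring the
#' investigate mode of pathway-association drill-downs. Per-gene seeds are
#' derived from `seed` by gene index, so each gene's result is
#' reproducible independently of which genes are run.
#'
#' @param features Result of [pathway_features()] (gene feature sets and
#'   SNP mappings).
#' @param annotations Gene annotation table (for chromosome labels).
#' @param p Named per-SNP p-value vector.
#' @param pool [genome_feature_pool()].
#' @param n_perm,alpha,estimator As in [permutation_test()].
#' @param seed Base integer seed.
#' @return List with `genes` (data.frame: `gene`, `chr`, `n_simple`,
#'   `n_complex`, `observed`, `p_perm`; `NA` p for untestable genes) and
#'   `snp_table` (data.frame: `gene`, `snp`, `chr`, `pos`, `p`).
#' @export
investigate <- function(features, annotations, p, pool,
                        n_perm = 1000L, alpha = 0.05, seed = NULL,
                        estimator = c("raw", "plus_one")) {
  estimator <- match.arg(estimator)
  genes <- names(features$genes)
  rows <- vector("list", length(genes))
  snp_rows <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    fs <- features$genes[[g]]
    chr <- annotations$chr[annotations$symbol == g][1]
    n_feat <- length(fs$simple) + length(fs$complex)
    if (n_feat == 0L) {
      rows[[i]] <- data.frame(gene = g, chr = chr, n_simple = 0L,
                              n_complex = 0L, observed = NA_integer_,
                              p_perm = NA_real_, stringsAsFactors = FALSE)
    } else {
      pr <- permutation_test(fs, p, pool, n_perm = n_perm, alpha = alpha,
                             seed = derive_seed(seed, i),
                             estimator = estimator)
      rows[[i]] <- data.frame(gene = g, chr = chr,
                              n_simple = length(fs$simple),
                              n_complex = length(fs$complex),
                              observed = pr$observed, p_perm = pr$p,
                              stringsAsFactors = FALSE)
    }
    ids <- features$gene_snps[[g]]
    if (length(ids)) {
      snp_rows[[i]] <- data.frame(gene = g, snp = ids, p = unname(p[ids]),
                                  stringsAsFactors = FALSE)
    }
  }
  list(genes = do.call(rbind, rows), snp_table = do.call(rbind, snp_rows))
}
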