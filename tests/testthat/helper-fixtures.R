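# Shared in-code fixtures. Everything is generated; nothing is read from disk.

# A small multi-chromosome panel used across tests.
small_panel <- function(seed = 11, n_hap = 400L, r2 = 0.9) {
  generate_reference_panel(panel_config(
    n_haplotypes = n_hap, n_chromosomes = 4L, blocks_per_chromosome = 5L,
    block_size_range = c(2L, 6L), singleton_fraction = 0.35,
    within_block_r2 = r2, maf_range = c(0.1, 0.5), include_x = TRUE,
    seed = seed
  ))
}

# Build a feature_set directly from its parts (bypassing block detection),
# for tests of the counting and permutation machinery.
make_feature_set <- function(simple, complex, owner = "fix") {
  structure(list(owner = owner, simple = simple, complex = complex),
            class = "feature_set")
}

make_pool <- function(simple, complex) {
  structure(
    list(simple = simple, complex = complex,
         complex_sizes = as.integer(lengths(complex))),
    class = "feature_pool"
  )
}

# The worked counting fixture: 123 simple and 122 complex features with
# exactly n_sig_simple significant singletons and n_sig_complex blocks
# holding at least one significant SNP at alpha = 0.05.
counting_fixture <- function(n_simple = 123L, n_complex = 122L,
                             n_sig_simple = 15L, n_sig_complex = 24L,
                             shuffle_seed = NULL) {
  simple <- sprintf("s%03d", seq_len(n_simple))
  complex <- lapply(seq_len(n_complex), function(i) {
    sprintf("c%03d_%d", i, seq_len(2L + (i %% 4L)))
  })
  p <- c(
    stats::setNames(rep(0.5, n_simple), simple),
    stats::setNames(rep(0.99, sum(lengths(complex))),
                    unlist(complex, use.names = FALSE))
  )
  sig_simple <- seq_len(n_sig_simple)
  sig_complex <- seq_len(n_sig_complex)
  if (!is.null(shuffle_seed)) {
    sig_simple <- with_fixed_seed(shuffle_seed, sample(n_simple, n_sig_simple))
    sig_complex <- with_fixed_seed(shuffle_seed + 1L,
                                   sample(n_complex, n_sig_complex))
  }
  p[simple[sig_simple]] <- 0.01
  for (i in sig_complex) p[complex[[i]][1]] <- 0.01
  list(features = make_feature_set(simple, complex, owner = "worked"),
       p = p)
}

with_fixed_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Mean best-match Jaccard overlap between two block partitions.
block_jaccard <- function(truth, found) {
  found_sets <- lapply(found, `[[`, "snps")
  mean(vapply(truth, function(ts) {
    if (length(found_sets) == 0L) return(0)
    max(vapply(found_sets, function(fs) {
      length(intersect(ts, fs)) / length(union(ts, fs))
    }, numeric(1)))
  }, numeric(1)))
}
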