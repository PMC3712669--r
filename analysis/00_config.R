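# Shared study configuration for the analysis scripts.
#
# Each numbered script is a standalone Rscript: it sources this file and
# deterministically regenerates whatever upstream objects it needs from the
# seeds below, so no binary intermediates are passed between scripts.
# Outputs land under results/.

library(pathperm)

STUDY_SEED <- 20260926L

# Desk-scale genome: ~5,000 SNPs in LD blocks over 14 autosomes plus X.
study_panel_config <- function() {
  panel_config(
    n_haplotypes = 1000L,
    n_chromosomes = 15L,
    blocks_per_chromosome = 43L,
    block_size_range = c(2L, 8L),
    singleton_fraction = 0.35,
    within_block_r2 = 0.9,
    maf_range = c(0.05, 0.5),
    include_x = TRUE,
    seed = STUDY_SEED
  )
}

# A 23-gene pathway spanning all 15 chromosomes with two X-linked genes.
study_annotations <- function(panel) {
  generate_annotations(
    panel, n_genes = 60L, pathway_genes = 23L, pathway_x_genes = 2L,
    flank = 50000, snps_per_gene = c(4L, 40L), name = "estrogen_like",
    seed = STUDY_SEED + 1L
  )
}

# Modest female-only risk embedded in ten pathway SNPs (|log OR| = log 1.3,
# alternating sign so the stratum prevalence stays put).
study_causal <- function(panel, annotations) {
  blocks <- NULL  # mapping only needs windows, not LD
  feats <- suppressWarnings(pathway_features(
    annotations$pathway, annotations$annotations, panel$snps, list()
  ))
  auto <- feats$snp_ids[panel$snps$chr[match(feats$snp_ids, panel$snps$id)] != "X"]
  set.seed(STUDY_SEED + 2L)
  data.frame(
    snp = sample(auto, 10L),
    beta = log(1.3) * rep_len(c(1, -1), 10L),
    sex = "female",
    stringsAsFactors = FALSE
  )
}

# Two cohorts shaped like the source collections.
study_cohorts <- function(panel, causal) {
  list(
    glaugen_like = generate_cohort(
      panel,
      cohort_config(n_cases = 976L, n_controls = 1140L, causal_snps = causal,
                    seed = STUDY_SEED + 10L),
      name = "glaugen_like"
    ),
    neighbor_like = generate_cohort(
      panel,
      cohort_config(n_cases = 2132L, n_controls = 2290L, causal_snps = causal,
                    seed = STUDY_SEED + 11L),
      name = "neighbor_like"
    )
  )
}

results_dir <- function(...) {
  d <- file.path("results", ...)
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}
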