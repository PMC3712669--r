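#' Simulate a two-cohort pathway study and run it end to end
#'
#' Convenience runner used by the calibration and power studies: generates
#' a reference panel, annotations with a designated multi-chromosome
#' pathway, and two case-control cohorts; scans each cohort per stratum,
#' meta-analyzes, detects LD blocks on the panel, and runs the
#' architecture-matched permutation test in each requested stratum.
#'
#' @param seed Master seed; panel, annotation, cohort and permutation
#'   seeds are derived from it.
#' @param panel_cfg A [panel_config()] (its `seed` is overridden by a
#'   derived seed).
#' @param cohort_sizes List of two `c(cases, controls)` vectors.
#' @param causal_snps `NULL` (global null) or a spec list with `n_snps`,
#'   `beta`, `sex`; the causal SNPs are drawn from the pathway's SNPs.
#' @param strata List of [stratum_spec()]s to test.
#' @param n_genes,pathway_genes,pathway_x_genes,flank,snps_per_gene
#'   Annotation layout (see [generate_annotations()]). The default gene
#'   richness keeps the pathway a modest fraction of the genome, as in
#'   full-scale pathway analyses where the tested set is a sliver of the
#'   feature pool.
#' @param n_perm,alpha Permutation settings.
#' @param block_threshold r-squared threshold for LD-block detection.
#' @param method Association scan method.
#' @return List with `results` (data.frame: `stratum`, `observed`,
#'   `p_perm`, `n_cases`, `n_controls`), `causal` (chosen causal SNP ids)
#'   and `n_pathway_snps`.
#' @export
run_pipeline <- function(seed,
                         panel_cfg = panel_config(),
                         cohort_sizes = list(c(976L, 1140L), c(2132L, 2290L)),
                         causal_snps = NULL,
                         strata = list(stratum_spec("all", "overall")),
                         n_genes = 40L,
                         pathway_genes = 23L,
                         pathway_x_genes = 2L,
                         flank = 50000,
                         snps_per_gene = c(3L, 12L),
                         n_perm = 1000L,
                         alpha = 0.05,
                         block_threshold = 0.8,
                         method = "score") {
  panel_cfg$seed <- derive_seed(seed, 1L)
  panel <- generate_reference_panel(panel_cfg)
  ann <- generate_annotations(panel, n_genes = n_genes,
                              pathway_genes = pathway_genes,
                              pathway_x_genes = pathway_x_genes,
                              flank = flank, snps_per_gene = snps_per_gene,
                              seed = derive_seed(seed, 2L))
  blocks <- find_blocks(panel, threshold = block_threshold)
  feats0 <- suppressWarnings(
    pathway_features(ann$pathway, ann$annotations, panel$snps, blocks)
  )

  causal <- NULL
  if (!is.null(causal_snps)) {
    causal <- with_seed(derive_seed(seed, 3L), {
      auto <- feats0$snp_ids[panel$snps$chr[match(feats0$snp_ids, panel$snps$id)] != "X"]
      k <- causal_snps$n_snps
      data.frame(
        snp = sample(auto, k),
        # alternate risk/protective signs so the aggregate does not shift
        # the stratum's baseline prevalence
        beta = causal_snps$beta * rep_len(c(1, -1), k),
        sex = causal_snps$sex %||% "both",
        stringsAsFactors = FALSE
      )
    })
  }

  studies <- lapply(seq_along(cohort_sizes), function(i) {
    sz <- cohort_sizes[[i]]
    generate_cohort(panel, cohort_config(
      n_cases = sz[1], n_controls = sz[2], causal_snps = causal,
      seed = derive_seed(seed, 10L + i)
    ), name = sprintf("cohort%d", i))
  })

  feats_noX <- NULL  # pathway features are gender-dependent only through X
  rows <- lapply(seq_along(strata), function(si) {
    spec <- strata[[si]]
    filtered <- lapply(studies, apply_stratum, spec = spec)
    covs <- c("age", "site", if (spec$gender == "all") "sex")
    assoc <- lapply(filtered, assoc_scan, covariates = covs, method = method)
    meta <- suppressWarnings(inverse_variance_meta(assoc))
    p <- stats::setNames(meta$p, meta$snp)
    snp_table <- filtered[[1]]$snps
    feats <- if (spec$gender == "female") {
      feats0
    } else {
      if (is.null(feats_noX)) {
        feats_noX <<- suppressWarnings(
          pathway_features(ann$pathway, ann$annotations, snp_table, blocks)
        )
      }
      feats_noX
    }
    pool <- genome_feature_pool(
      blocks, snp_table, p,
      exclude_chr = if (spec$gender != "female") "X" else character(0)
    )
    pr <- permutation_test(feats$pathway, p, pool, n_perm = n_perm,
                           alpha = alpha, seed = derive_seed(seed, 50L + si))
    data.frame(
      stratum = spec$label,
      observed = pr$observed, p_perm = pr$p,
      n_cases = sum(vapply(filtered, function(f) sum(f$subjects$status == 1L), 0)),
      n_controls = sum(vapply(filtered, function(f) sum(f$subjects$status == 0L), 0)),
      stringsAsFactors = FALSE
    )
  })
  list(results = do.call(rbind, rows),
       causal = causal$snp,
       n_pathway_snps = length(feats0$snp_ids))
}
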