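#' Specify an analysis stratum
#'
#' A stratum is a gender filter crossed with a case outcome: overall
#' disease, the high-pressure subtype (IOP at diagnosis >= `iop_threshold`
#' mmHg) or the normal-pressure subtype (IOP < `iop_threshold`). Controls
#' are shared across outcome strata; cases with no recorded IOP stay in
#' "overall" and are excluded from both pressure subtypes.
#'
#' @param gender `"all"`, `"female"` or `"male"`.
#' @param outcome `"overall"`, `"hpg"` or `"npg"`.
#' @param iop_threshold Pressure cut in mmHg (default 22; the
#'   greater-or-equal side is the high-pressure subtype).
#' @return Object of class `stratum_spec`.
#' @export
stratum_spec <- function(gender = c("all", "female", "male"),
                         outcome = c("overall", "hpg", "npg"),
                         iop_threshold = 22) {
  gender <- match.arg(gender)
  outcome <- match.arg(outcome)
  structure(list(gender = gender, outcome = outcome,
                 iop_threshold = iop_threshold,
                 label = paste(gender, outcome, sep = "_")),
            class = "stratum_spec")
}

#' The default nine-stratum grid
#'
#' Overall, males-only and females-only analyses of the overall disease
#' and of the two pressure-defined subtypes.
#' @return List of [stratum_spec()] objects.
#' @export
default_strata <- function() {
  out <- list()
  for (g in c("all", "male", "female")) {
    for (o in c("overall", "hpg", "npg")) {
      out[[paste(g, o, sep = "_")]] <- stratum_spec(g, o)
    }
  }
  out
}

#' Filter a study to one stratum
#'
#' Subjects are filtered by gender and (for cases) by the outcome's IOP
#' rule; controls are always retained within the gender filter. For
#' male-only and gender-combined strata, X-chromosome SNPs are removed
#' from the genotype set (and hence from every downstream feature);
#' female-only strata retain X.
#'
#' @param study A `study_data` object.
#' @param spec A [stratum_spec()].
#' @return The filtered `study_data`.
#' @export
apply_stratum <- function(study, spec) {
  stopifnot(inherits(spec, "stratum_spec"))
  sub <- study$subjects
  keep <- rep(TRUE, nrow(sub))
  if (spec$gender == "female") keep <- sub$sex == "F"
  if (spec$gender == "male") keep <- sub$sex == "M"
  is_case <- sub$status == 1L
  case_keep <- switch(spec$outcome,
    overall = is_case,
    hpg = is_case & !is.na(sub$iop) & sub$iop >= spec$iop_threshold,
    npg = is_case & !is.na(sub$iop) & sub$iop < spec$iop_threshold
  )
  keep <- keep & (case_keep | !is_case)
  if (sum(sub$status[keep] == 1L) == 0L || sum(sub$status[keep] == 0L) == 0L) {
    stop(sprintf("stratum '%s' is empty (no cases or no controls)", spec$label),
         call. = FALSE)
  }
  snp_keep <- if (spec$gender == "female") {
    rep(TRUE, nrow(study$snps))
  } else {
    study$snps$chr != "X"
  }
  structure(
    list(genotypes = study$genotypes[keep, study$snps$id[snp_keep], drop = FALSE],
         subjects = sub[keep, , drop = FALSE],
         snps = study$snps[snp_keep, , drop = FALSE],
         study = study$study),
    class = "study_data"
  )
}

#' Bonferroni-corrected significance threshold
#'
#' `alpha / (n_snps * n_strata)`, reported to three significant figures
#' (e.g. 903 SNPs over 3 strata at alpha 0.05 gives 1.85e-05).
#'
#' @param n_snps Number of SNPs tested.
#' @param n_strata Stratification multiplier (default 3).
#' @param alpha Family-wise error target.
#' @return The corrected per-SNP threshold.
#' @export
bonferroni_threshold <- function(n_snps, n_strata = 3L, alpha = 0.05) {
  stopifnot_scalar_count(n_snps, "n_snps")
  stopifnot_scalar_count(n_strata, "n_strata")
  stopifnot_range(alpha, "alpha", 0, 1, lo_open = TRUE)
  signif(alpha / (n_snps * n_strata), 3)
}

#' Display form of a permuted p-value
#'
#' A zero exceedance count prints as `"<1/n_perm"` (so `"<0.001"` at 1,000
#' permutations), values above 0.99 print as `">0.99"`, and everything
#' else to three significant figures.
#'
#' @param p Stored empirical p-value(s).
#' @param n_perm Number of permutations behind each value.
#' @return Character vector.
#' @export
format_permuted_p <- function(p, n_perm = 1000L) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi == 0) return(paste0("<", format(1 / n_perm, scientific = FALSE)))
    if (pi > 0.99) return(">0.99")
    format(signif(pi, 3), scientific = FALSE)
  }, character(1))
}

#' Run the full stratified pathway analysis
#'
#' For each stratum: filters every study ([apply_stratum()]), runs the
#' per-study association scan, meta-analyzes the studies, rebuilds the
#' pathway and gene feature sets on the stratum's SNP set (X excluded for
#' male-only and combined strata), builds the genome-wide feature pool, and
#' runs the architecture-matched permutation test (plus the per-gene
#' drill-down when `investigate_genes` covers the stratum's gender). By
#' default the pool retains the tested pathway's own features, so null
#' draws are genuine random feature sets from the whole genome;
#' `exclude_pathway_from_pool = TRUE` removes them instead.
#'
#' @param studies List of `study_data` objects (the cohorts to combine).
#' @param blocks `ld_blocks` detected on the reference panel.
#' @param annotations Gene annotation table.
#' @param pathway A [pathway_definition()].
#' @param strata List of [stratum_spec()]s (default [default_strata()]).
#' @param n_perm,alpha As in [permutation_test()].
#' @param seed Base seed; per-stratum and per-gene streams are derived
#'   from it.
#' @param method Association scan method (see [assoc_scan()]).
#' @param covariates Subject columns to adjust for; `"sex"` is added
#'   automatically in gender-combined strata.
#' @param investigate_genes Genders for which the per-gene drill-down is
#'   run (default female and male).
#' @param n_strata_bonferroni Multiplier for [bonferroni_threshold()].
#' @param exclude_pathway_from_pool Remove the tested pathway's features
#'   from the sampling pool (default `FALSE`; see
#'   [genome_feature_pool()] for the calibration rationale).
#' @return Object of class `analysis_report`: list with `pathway_table`,
#'   `gene_tables` (one per investigated gender, columns per outcome),
#'   `snp_appendix` (nominally significant SNPs per stratum),
#'   `bonferroni`, `n_snps`, `n_perm`, `alpha`, `seed`.
#' @export
run_stratified_analysis <- function(studies, blocks, annotations, pathway,
                                    strata = default_strata(),
                                    n_perm = 1000L, alpha = 0.05,
                                    seed = 1L, method = "score",
                                    covariates = c("age", "site"),
                                    investigate_genes = c("female", "male"),
                                    n_strata_bonferroni = 3L,
                                    exclude_pathway_from_pool = FALSE) {
  stopifnot(length(studies) >= 1L)
  path_rows <- list()
  gene_rows <- list()
  snp_rows <- list()
  n_snps_pathway <- NA_integer_

  for (si in seq_along(strata)) {
    spec <- strata[[si]]
    filtered <- lapply(studies, apply_stratum, spec = spec)
    covs <- covariates
    if (spec$gender == "all" && !("sex" %in% covs)) covs <- c(covs, "sex")
    assoc <- lapply(filtered, assoc_scan, covariates = covs, method = method)
    meta <- suppressWarnings(inverse_variance_meta(assoc))
    p <- stats::setNames(meta$p, meta$snp)

    snp_table <- filtered[[1]]$snps
    feats <- suppressWarnings(
      pathway_features(pathway, annotations, snp_table, blocks)
    )
    if (spec$gender == "female") n_snps_pathway <- length(feats$snp_ids)
    pool <- genome_feature_pool(blocks, snp_table, p,
                                exclude_snps = if (exclude_pathway_from_pool) feats$snp_ids else character(0),
                                exclude_chr = if (spec$gender != "female") "X" else character(0))
    pr <- permutation_test(feats$pathway, p, pool, n_perm = n_perm,
                           alpha = alpha, seed = derive_seed(seed, si))
    path_rows[[spec$label]] <- data.frame(
      stratum = spec$label, gender = spec$gender, outcome = spec$outcome,
      n_cases = sum(vapply(filtered, function(f) sum(f$subjects$status == 1L), 0)),
      n_controls = sum(vapply(filtered, function(f) sum(f$subjects$status == 0L), 0)),
      n_snps = length(feats$snp_ids),
      observed = pr$observed, p_perm = pr$p, n_perm = n_perm,
      stringsAsFactors = FALSE
    )

    if (spec$gender %in% investigate_genes) {
      inv <- investigate(feats, annotations, p, pool, n_perm = n_perm,
                         alpha = alpha, seed = derive_seed(seed, 100L + si))
      g <- inv$genes
      g$gender <- spec$gender
      g$outcome <- spec$outcome
      gene_rows[[spec$label]] <- g
    }

    sig <- meta[!is.na(meta$p) & meta$p < alpha & meta$snp %in% feats$snp_ids, ]
    if (nrow(sig)) {
      sig$stratum <- spec$label
      snp_rows[[spec$label]] <- sig
    }
  }

  pathway_table <- do.call(rbind, path_rows)
  rownames(pathway_table) <- NULL

  gene_tables <- list()
  for (g in unique(vapply(gene_rows, function(x) x$gender[1], character(1)))) {
    sub <- do.call(rbind, Filter(function(x) x$gender[1] == g, gene_rows))
    if (is.null(sub)) next
    wide <- stats::reshape(
      sub[, c("gene", "chr", "n_simple", "n_complex", "outcome", "p_perm")],
      idvar = c("gene", "chr", "n_simple", "n_complex"),
      timevar = "outcome", direction = "wide"
    )
    names(wide) <- sub("^p_perm\\.", "p_", names(wide))
    rownames(wide) <- NULL
    gene_tables[[g]] <- wide
  }

  snp_appendix <- if (length(snp_rows)) {
    out <- do.call(rbind, snp_rows)
    rownames(out) <- NULL
    out
  } else {
    NULL
  }

  structure(
    list(pathway_table = pathway_table, gene_tables = gene_tables,
         snp_appendix = snp_appendix,
         n_snps = n_snps_pathway,
         bonferroni = bonferroni_threshold(max(n_snps_pathway, 1L),
                                           n_strata_bonferroni, alpha),
         n_perm = n_perm, alpha = alpha, seed = seed),
    class = "analysis_report"
  )
}

#' Write an analysis report as tab-separated tables
#'
#' Emits `pathway_table.tsv` (stratified pathway results with display-form
#' permuted p-values), one `gene_table_<gender>.tsv` per investigated
#' gender (gene, chromosome, feature counts, permuted p per outcome),
#' `snp_appendix.tsv` (nominally significant SNPs) and
#' `pathway_table_full.tsv` (machine-readable, full-precision p-values).
#' Rendering is deterministic: regenerating from the same report is
#' byte-identical.
#'
#' @param report An `analysis_report`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
render_tables <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  pt <- report$pathway_table
  disp <- pt
  disp$p_perm <- format_permuted_p(pt$p_perm, report$n_perm)
  f <- file.path(dir, "pathway_table.tsv")
  write_tsv(disp, f)
  paths <- c(paths, f)

  full <- pt
  full$p_perm <- format(full$p_perm, digits = 15, trim = TRUE)
  f <- file.path(dir, "pathway_table_full.tsv")
  write_tsv(full, f)
  paths <- c(paths, f)

  for (g in names(report$gene_tables)) {
    gt <- report$gene_tables[[g]]
    for (cl in grep("^p_", names(gt), value = TRUE)) {
      gt[[cl]] <- format_permuted_p(gt[[cl]], report$n_perm)
    }
    f <- file.path(dir, sprintf("gene_table_%s.tsv", g))
    write_tsv(gt, f)
    paths <- c(paths, f)
  }

  if (!is.null(report$snp_appendix)) {
    ap <- report$snp_appendix
    for (cl in intersect(c("beta", "se", "p"), names(ap))) {
      ap[[cl]] <- signif(ap[[cl]], 3)
    }
    f <- file.path(dir, "snp_appendix.tsv")
    write_tsv(ap, f)
    paths <- c(paths, f)
  }

  meta <- data.frame(
    key = c("n_pathway_snps", "bonferroni_threshold", "n_perm", "alpha", "seed"),
    value = c(report$n_snps, format(report$bonferroni, digits = 3),
              report$n_perm, report$alpha, report$seed %||% NA),
    stringsAsFactors = FALSE
  )
  f <- file.path(dir, "analysis_summary.tsv")
  write_tsv(meta, f)
  paths <- c(paths, f)
  invisible(paths)
}
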