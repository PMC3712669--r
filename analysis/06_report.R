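#!/usr/bin/env Rscript
# Stage 6: narrative summary of the rendered tables — the pathway table,
# the per-gender gene tables and the multiple-testing accounting.

source(if (file.exists("analysis/00_config.R")) "analysis/00_config.R" else "00_config.R")

td <- "results/tables"
if (!file.exists(file.path(td, "pathway_table.tsv"))) {
  stop("run analysis/05_pathway_permutation.R first")
}

pt <- read.delim(file.path(td, "pathway_table.tsv"),
                 colClasses = c(p_perm = "character"))
cat("== Pathway significance by stratum ==\n")
print(pt[, c("stratum", "n_cases", "n_controls", "observed", "p_perm")],
      row.names = FALSE)

sig <- pt[!startsWith(pt$p_perm, ">") &
            suppressWarnings(as.numeric(sub("<", "", pt$p_perm))) < 0.05, ]
cat("\nstrata with permuted p < 0.05:",
    if (nrow(sig)) paste(sig$stratum, collapse = ", ") else "none", "\n")

for (g in c("female", "male")) {
  f <- file.path(td, sprintf("gene_table_%s.tsv", g))
  if (!file.exists(f)) next
  gt <- read.delim(f, colClasses = "character")
  cat(sprintf("\n== Gene-level drill-down (%s strata) ==\n", g))
  print(gt, row.names = FALSE)
}

summ <- read.delim(file.path(td, "analysis_summary.tsv"))
thr <- summ$value[summ$key == "bonferroni_threshold"]
n_snps <- summ$value[summ$key == "n_pathway_snps"]
cat(sprintf("\nBonferroni accounting: %s pathway SNPs x 3 strata -> per-SNP threshold %s\n",
            n_snps, thr))
ap <- file.path(td, "snp_appendix.tsv")
if (file.exists(ap)) {
  snps <- read.delim(ap)
  cat(sprintf("nominally significant pathway SNPs (p < 0.05) across strata: %d rows; %d below the corrected threshold\n",
              nrow(snps), sum(snps$p < as.numeric(thr))))
}
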