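#!/usr/bin/env Rscript
# Stage 1: simulate the reference panel, the 23-gene pathway annotation and
# two case-control cohorts, and export the plain-text data products.

source(if (file.exists("analysis/00_config.R")) "analysis/00_config.R" else "00_config.R")

panel <- generate_reference_panel(study_panel_config())
print(panel)

ann <- study_annotations(panel)
pw_ann <- ann$annotations[ann$annotations$symbol %in% ann$pathway$genes, ]
cat(sprintf("pathway '%s': %d genes on %d chromosomes (%d on X)\n",
            ann$pathway$name, length(ann$pathway$genes),
            length(unique(pw_ann$chr)), sum(pw_ann$chr == "X")))

causal <- study_causal(panel, ann)
cat("female-only causal SNPs (log OR, alternating sign):\n")
print(causal)

cohorts <- study_cohorts(panel, causal)
for (s in cohorts) print(s)

dd <- results_dir("data")
write_annotations_bed(ann$annotations, file.path(dd, "annotations.bed"))
write_pathway(ann$pathway, file.path(dd, "pathway_genes.txt"))
for (nm in names(cohorts)) {
  write_phenotypes(cohorts[[nm]], file.path(dd, sprintf("%s_pheno.tsv", nm)))
}
# a demonstration VCF slice of the panel (first chromosome, 50 individuals)
chr1 <- panel$snps$id[panel$snps$chr == "1"]
write_vcf(panel_genotypes(panel)[1:50, chr1],
          panel$snps, file.path(dd, "panel_chr1_demo.vcf"))
cat("wrote", dd, ":", paste(list.files(dd), collapse = ", "), "\n")
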