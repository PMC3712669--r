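#!/usr/bin/env Rscript
# Stage 3: fixed-effect meta-analysis of the two cohorts' summary tables,
# reading the stage-2 files back from disk (the summary-statistic interface).

source(if (file.exists("analysis/00_config.R")) "analysis/00_config.R" else "00_config.R")

dd <- results_dir("assoc")
files <- list.files(dd, pattern = "_overall\\.assoc$", full.names = TRUE)
if (length(files) < 2) stop("run analysis/02_association.R first")
studies <- lapply(files, read_assoc)
names(studies) <- sub("_overall\\.assoc$", "", basename(files))

meta <- suppressWarnings(inverse_variance_meta(studies))
cat(sprintf("combined set: %d SNPs from %d studies (intersection of QC-passing SNPs)\n",
            nrow(meta), length(studies)))
cat(sprintf("both-study SNPs: %d; single-study passthrough: %d\n",
            sum(meta$n_studies == 2), sum(meta$n_studies == 1)))
lambda <- median(qchisq(meta$p, 1, lower.tail = FALSE)) / qchisq(0.5, 1)
cat(sprintf("genomic inflation-style median-chisq ratio: %.3f\n", lambda))
top <- meta[order(meta$p)[1:5], c("snp", "chr", "pos", "beta", "se", "p")]
cat("top combined signals:\n")
print(top, row.names = FALSE, digits = 3)

write_assoc(meta, file.path(results_dir("meta"), "meta_overall.assoc"))
cat("wrote results/meta/meta_overall.assoc\n")
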