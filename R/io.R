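# plain deterministic TSV writer (no quoting, no row names)
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' Write per-SNP association summaries in a PLINK-assoc-like format
#'
#' Tab-separated columns `SNP CHR BP A1 A2 OR SE P N STATUS`, where `OR`
#' is the odds ratio `exp(beta)` for the counted allele `A1` and `SE` is
#' the standard error of the log odds ratio. Values are written with
#' enough digits that a read/write round trip preserves at least six
#' significant digits.
#'
#' @param tab An `assoc_table` or `meta_table` data.frame.
#' @param path Output file.
#' @export
write_assoc <- function(tab, path) {
  out <- data.frame(
    SNP = tab$snp, CHR = tab$chr, BP = tab$pos,
    A1 = tab$a1, A2 = tab$a2,
    OR = format(exp(tab$beta), digits = 10, trim = TRUE),
    SE = format(tab$se, digits = 10, trim = TRUE),
    P = format(tab$p, digits = 10, trim = TRUE),
    N = tab$n,
    STATUS = if (!is.null(tab$status)) tab$status else "ok",
    stringsAsFactors = FALSE
  )
  write_tsv(out, path)
}

#' Read association summaries written by [write_assoc()]
#'
#' @param path File path.
#' @return An `assoc_table` data.frame (`beta` recovered as `log(OR)`).
#' @export
read_assoc <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c(CHR = "character"))
  out <- data.frame(
    snp = raw$SNP, chr = raw$CHR, pos = raw$BP,
    a1 = raw$A1, a2 = raw$A2,
    beta = log(as.numeric(raw$OR)), se = as.numeric(raw$SE),
    p = as.numeric(raw$P), n = raw$N,
    status = if (!is.null(raw$STATUS)) raw$STATUS else "ok",
    stringsAsFactors = FALSE
  )
  structure(out, class = c("assoc_table", "data.frame"))
}

#' Write genotypes as a minimal VCF v4.2
#'
#' One line per SNP with `CHROM POS ID REF ALT QUAL FILTER INFO FORMAT`
#' and per-sample diploid `GT` fields derived from the dosage of the ALT
#' (counted) allele: 0 -> `0/0`, 1 -> `0/1`, 2 -> `1/1`.
#'
#' @param genotypes Dosage matrix (subjects x SNPs).
#' @param snps SNP table (`id`, `chr`, `pos`, `ref`, `alt`).
#' @param path Output file.
#' @param sample_ids Sample column names (defaults to `S1`, `S2`, ...).
#' @export
write_vcf <- function(genotypes, snps, path, sample_ids = NULL) {
  n <- nrow(genotypes)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%d", seq_len(n))
  snps <- snps[match(colnames(genotypes), snps$id), ]
  gt_codes <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t")
  ), con)
  gt <- matrix(gt_codes[genotypes + 1L], nrow = n)
  lines <- paste(
    snps$chr, snps$pos, snps$id, snps$ref, snps$alt, ".", ".", ".", "GT",
    apply(gt, 2, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(lines, con)
}

#' Read genotypes from a minimal VCF written by [write_vcf()]
#'
#' @param path VCF file path.
#' @return List with `genotypes` (dosage matrix, subjects x SNPs) and
#'   `snps` (data.frame `id`, `chr`, `pos`, `ref`, `alt`).
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  header <- strsplit(body[1], "\t")[[1]]
  samples <- header[-(1:9)]
  rows <- strsplit(body[-1], "\t")
  snps <- data.frame(
    id = vapply(rows, `[[`, "", 3L),
    chr = vapply(rows, `[[`, "", 1L),
    pos = as.integer(vapply(rows, `[[`, "", 2L)),
    ref = vapply(rows, `[[`, "", 4L),
    alt = vapply(rows, `[[`, "", 5L),
    stringsAsFactors = FALSE
  )
  dose <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  G <- vapply(rows, function(r) unname(dose[r[-(1:9)]]),
              integer(length(samples)))
  if (is.null(dim(G))) G <- matrix(G, nrow = length(samples))
  colnames(G) <- snps$id
  list(genotypes = G, snps = snps)
}

#' Write subject phenotypes and covariates as tab-separated text
#'
#' @param study A `study_data` object.
#' @param path Output file.
#' @export
write_phenotypes <- function(study, path) {
  write_tsv(study$subjects, path)
}

#' Read a phenotype table written by [write_phenotypes()]
#' @param path File path.
#' @return data.frame of subjects.
#' @export
read_phenotypes <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c(sex = "character"))
  out$site <- factor(out$site)
  out
}

#' Write gene annotations as BED-like tab-separated text
#'
#' The native annotation table is 1-based inclusive; BED output converts
#' to 0-based half-open (`start - 1`, `end`). Columns: chrom, start, end,
#' symbol.
#'
#' @param annotations Annotation data.frame (`symbol`, `chr`, `start`,
#'   `end`).
#' @param path Output file.
#' @export
write_annotations_bed <- function(annotations, path) {
  out <- data.frame(
    chrom = annotations$chr,
    start = annotations$start - 1L,
    end = annotations$end,
    symbol = annotations$symbol,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read BED-like annotations back to the native 1-based inclusive table
#' @param path File path.
#' @return data.frame with `symbol`, `chr`, `start`, `end`.
#' @export
read_annotations_bed <- function(path) {
  raw <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "symbol"),
                           colClasses = c("character", "integer", "integer",
                                          "character"))
  data.frame(symbol = raw$symbol, chr = raw$chrom,
             start = raw$start + 1L, end = raw$end,
             stringsAsFactors = FALSE)
}

#' Write a pathway definition (one gene symbol per line)
#' @param pathway A [pathway_definition()].
#' @param path Output file.
#' @export
write_pathway <- function(pathway, path) {
  writeLines(pathway$genes, path)
}

#' Read a pathway gene list written by [write_pathway()]
#' @param path File path.
#' @param name Pathway name to attach.
#' @param flank Flanking window in bases.
#' @return A [pathway_definition()].
#' @export
read_pathway <- function(path, name = "pathway", flank = 50000) {
  pathway_definition(name, readLines(path), flank = flank)
}
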