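#' Define a pathway as a named gene set with a flanking window
#'
#' @param name Pathway name.
#' @param genes Character vector of unique gene symbols.
#' @param flank Window in bases added on each side of a gene's transcript
#'   span when mapping SNPs to the gene (default 50,000; the window is a
#'   closed interval).
#' @param annotations Optional gene annotation table; when given, every
#'   symbol must resolve in it.
#' @return Object of class `pathway_definition`.
#' @export
pathway_definition <- function(name, genes, flank = 50000, annotations = NULL) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) {
    stop("pathway gene symbols must be unique", call. = FALSE)
  }
  if (!is.null(annotations)) {
    missing_g <- setdiff(genes, annotations$symbol)
    if (length(missing_g)) {
      stop("pathway gene(s) not in annotation table: ",
           paste(missing_g, collapse = ", "), call. = FALSE)
    }
  }
  if (!is.numeric(flank) || length(flank) != 1L || flank < 0) {
    stop("`flank` must be a single non-negative number of bases", call. = FALSE)
  }
  structure(list(name = name, genes = genes, flank = flank),
            class = "pathway_definition")
}

#' Generate gene annotations tiling a panel, with a designated pathway
#'
#' Lays genes over SNP-bearing regions of the panel: each gene's transcript
#' span covers a contiguous run of genotyped SNPs, so every gene window is
#' guaranteed at least one SNP. A designated pathway of `pathway_genes`
#' genes is assembled with `pathway_x_genes` of them on chromosome X (when
#' the panel has one), mimicking a multi-chromosome metabolic pathway.
#'
#' @param panel An `snp_panel`.
#' @param n_genes Total genes to annotate (pathway genes plus background
#'   genes used only to exercise gene mapping).
#' @param pathway_genes Number of genes in the designated pathway.
#' @param pathway_x_genes How many pathway genes to place on chromosome X.
#' @param flank Pathway flanking window in bases (default 50,000).
#' @param snps_per_gene Range of genotyped SNPs covered by one transcript.
#' @param name Pathway name.
#' @param seed Integer seed (layout is randomized).
#' @return List with `annotations` (data.frame: `symbol`, `chr`, `start`,
#'   `end`; 1-based inclusive) and `pathway` (a [pathway_definition()]).
#' @export
generate_annotations <- function(panel,
                                 n_genes = 40L,
                                 pathway_genes = 23L,
                                 pathway_x_genes = 2L,
                                 flank = 50000,
                                 snps_per_gene = c(4L, 40L),
                                 name = "pathway23",
                                 seed = 1L) {
  stopifnot(inherits(panel, "snp_panel"))
  stopifnot_scalar_count(n_genes, "n_genes")
  if (pathway_genes > n_genes) {
    stop("`pathway_genes` cannot exceed `n_genes`", call. = FALSE)
  }
  snps <- panel$snps[order(panel$snps$chr, panel$snps$pos), ]
  chroms <- unique(snps$chr)
  has_x <- "X" %in% chroms
  if (pathway_x_genes > 0L && !has_x) {
    stop("panel has no X chromosome but `pathway_x_genes` > 0", call. = FALSE)
  }
  autosomes <- setdiff(chroms, "X")

  with_seed(seed, {
    # reserve disjoint SNP runs per chromosome
    free <- lapply(chroms, function(ch) which(snps$chr == ch))
    names(free) <- chroms

    place_gene <- function(ch) {
      avail <- free[[ch]]
      if (length(avail) < 1L) return(NULL)
      len_choices <- seq(snps_per_gene[1], snps_per_gene[2])
      len <- min(len_choices[sample.int(length(len_choices), 1L)],
                 length(avail))
      start_idx <- sample.int(length(avail) - len + 1L, 1L)
      run <- avail[start_idx:(start_idx + len - 1L)]
      # require the run to be contiguous in the chromosome's SNP order
      run <- run[seq_len(which.max(c(diff(run) != 1L, TRUE)))]
      free[[ch]] <<- setdiff(avail, run)
      c(start = snps$pos[run[1]], end = snps$pos[run[length(run)]])
    }

    # place on the requested chromosome, falling back to any other
    # chromosome of the same kind (autosome vs X) with room left
    place_gene_anywhere <- function(ch) {
      span <- place_gene(ch)
      if (!is.null(span)) return(list(chr = ch, span = span))
      pool_chr <- if (ch == "X") "X" else autosomes
      for (alt in sample(pool_chr)) {
        span <- place_gene(alt)
        if (!is.null(span)) return(list(chr = alt, span = span))
      }
      NULL
    }

    n_auto_path <- pathway_genes - pathway_x_genes
    # spread pathway genes across as many autosomes as possible, reusing
    # chromosomes once each autosome has one gene
    path_chr <- c(
      rep(autosomes, length.out = n_auto_path),
      rep("X", pathway_x_genes)
    )
    extra_chr <- sample(chroms, n_genes - pathway_genes, replace = TRUE)
    all_chr <- c(path_chr, extra_chr)
    symbols <- sprintf("GENE%03d", seq_len(n_genes))

    rows <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      placed <- place_gene_anywhere(all_chr[i])
      if (is.null(placed)) {
        warning(sprintf("no SNP run left anywhere for %s; gene skipped",
                        symbols[i]))
        next
      }
      rows[[i]] <- data.frame(symbol = symbols[i], chr = placed$chr,
                              start = unname(placed$span["start"]),
                              end = unname(placed$span["end"]),
                              stringsAsFactors = FALSE)
    }
    ann <- do.call(rbind, rows)
    pw_genes <- symbols[seq_len(pathway_genes)]
    pw_genes <- intersect(pw_genes, ann$symbol)
    list(
      annotations = ann,
      pathway = pathway_definition(name, pw_genes, flank = flank,
                                   annotations = ann)
    )
  })
}
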