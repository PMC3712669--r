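#' Pairwise squared genotype correlation on one chromosome
#'
#' Computes r-squared between SNP dosage columns of a genotype matrix for
#' all pairs on a chromosome, optionally restricted to pairs within
#' `max_dist` bases (entries beyond the window are set to 0). Monomorphic
#' SNPs yield undefined correlations, which are treated as 0 and counted in
#' a message.
#'
#' @param genotypes Dosage matrix (individuals x SNPs) with SNP ids as
#'   column names; typically [panel_genotypes()] of a reference panel.
#' @param snps SNP table with `id`, `chr`, `pos`.
#' @param chr Chromosome label to compute.
#' @param max_dist Maximum pair distance in bases (default `Inf`).
#' @return Symmetric r-squared matrix (diagonal 1) whose dimnames are the
#'   chromosome's SNP ids in position order.
#' @export
pairwise_r2 <- function(genotypes, snps, chr, max_dist = Inf) {
  sel <- snps[snps$chr == chr, ]
  if (nrow(sel) < 2L) {
    stop(sprintf("need at least 2 SNPs on chromosome %s", chr), call. = FALSE)
  }
  sel <- sel[order(sel$pos), ]
  G <- genotypes[, sel$id, drop = FALSE]
  sds <- apply(G, 2, stats::sd)
  mono <- sds == 0
  if (any(mono)) {
    message(sprintf("pairwise_r2: %d monomorphic SNP(s) on chr %s, r2 set to 0",
                    sum(mono), chr))
  }
  r2 <- suppressWarnings(stats::cor(G))^2
  r2[!is.finite(r2)] <- 0
  diag(r2) <- 1
  if (is.finite(max_dist)) {
    d <- abs(outer(sel$pos, sel$pos, "-"))
    r2[d > max_dist] <- 0
    diag(r2) <- 1
  }
  dimnames(r2) <- list(sel$id, sel$id)
  r2
}

#' Greedy LD-block detection from an r-squared map
#'
#' Walks the chromosome's SNPs in position order, extending the current
#' block while the candidate SNP has r-squared at or above `threshold`
#' with at least one SNP already in the block. Blocks of two or more SNPs
#' are emitted; every other SNP is left a singleton. The result is
#' deterministic given the panel and threshold.
#'
#' @param r2 Symmetric r-squared matrix from [pairwise_r2()] (dimnames are
#'   SNP ids in position order).
#' @param snps SNP table (`id`, `chr`, `pos`) covering the matrix ids.
#' @param threshold Minimum r-squared to join a block (default 0.8).
#' @return List of blocks, each a list with `chr`, `snps` (member ids in
#'   position order), `start`, `end`.
#' @export
build_blocks <- function(r2, snps, threshold = 0.8) {
  ids <- rownames(r2)
  if (is.null(ids) || length(ids) == 0L) return(list())
  info <- snps[match(ids, snps$id), ]
  ord <- order(info$pos)
  ids <- ids[ord]
  info <- info[ord, ]

  blocks <- list()
  current <- ids[1]
  flush <- function(members) {
    if (length(members) >= 2L) {
      pos <- info$pos[match(members, info$id)]
      blocks[[length(blocks) + 1L]] <<- list(
        chr = info$chr[1], snps = members,
        start = min(pos), end = max(pos)
      )
    }
  }
  for (i in seq_along(ids)[-1]) {
    cand <- ids[i]
    if (max(r2[cand, current]) >= threshold) {
      current <- c(current, cand)
    } else {
      flush(current)
      current <- cand
    }
  }
  flush(current)
  blocks
}

#' Detect LD blocks genome-wide from a reference panel
#'
#' Convenience wrapper running [pairwise_r2()] and [build_blocks()] per
#' chromosome on the panel's diploid genotypes.
#'
#' @param panel An `snp_panel`.
#' @param threshold Minimum r-squared to join a block.
#' @param max_dist Maximum pair distance in bases passed to
#'   [pairwise_r2()].
#' @return Object of class `ld_blocks`: list of blocks (as in
#'   [build_blocks()]) with the threshold stored as an attribute.
#' @export
find_blocks <- function(panel, threshold = 0.8, max_dist = Inf) {
  stopifnot(inherits(panel, "snp_panel"))
  G <- panel_genotypes(panel)
  out <- list()
  for (ch in unique(panel$snps$chr)) {
    if (sum(panel$snps$chr == ch) < 2L) next
    r2 <- pairwise_r2(G, panel$snps, ch, max_dist = max_dist)
    out <- c(out, build_blocks(r2, panel$snps, threshold = threshold))
  }
  structure(out, class = "ld_blocks", threshold = threshold)
}

#' Map SNPs to a gene's flanked window
#'
#' A SNP maps to a gene iff it lies on the gene's chromosome with position
#' in the closed interval `[start - flank, end + flank]`. A SNP may map to
#' several overlapping genes.
#'
#' @param snps SNP table (`id`, `chr`, `pos`).
#' @param gene One-row gene annotation (`symbol`, `chr`, `start`, `end`;
#'   1-based inclusive).
#' @param flank Window in bases added to each side (closed interval).
#' @return Character vector of mapped SNP ids (position order).
#' @export
map_snps_to_gene <- function(snps, gene, flank = 50000) {
  hit <- snps$chr == gene$chr &
    snps$pos >= gene$start - flank &
    snps$pos <= gene$end + flank
  sel <- snps[hit, ]
  sel$id[order(sel$pos)]
}

#' Decompose a mapped SNP set into simple and complex features
#'
#' A complex feature is the intersection of an LD block with the mapped SNP
#' set when that intersection keeps at least two SNPs; every other mapped
#' SNP (including a block member left alone by the intersection) is a
#' simple feature. The features partition the mapped set:
#' `n_simple + sum(complex sizes) = n mapped SNPs`.
#'
#' @param mapped_snps Character vector of mapped SNP ids.
#' @param blocks `ld_blocks` (or plain list of blocks).
#' @param owner Gene symbol or pathway name the features belong to.
#' @return Object of class `feature_set`: list with `owner`, `simple`
#'   (character vector of singleton SNP ids) and `complex` (list of member
#'   id vectors).
#' @export
decompose_features <- function(mapped_snps, blocks, owner = "set") {
  mapped_snps <- unique(as.character(mapped_snps))
  block_ids <- unlist(lapply(blocks, `[[`, "snps"), use.names = FALSE)
  block_lab <- rep.int(seq_along(blocks),
                       vapply(blocks, function(b) length(b$snps), 0L))
  lab <- block_lab[match(mapped_snps, block_ids)]
  groups <- split(mapped_snps[!is.na(lab)], lab[!is.na(lab)])
  keep <- lengths(groups) >= 2L
  # keep members in the block's own (position) order
  complex <- unname(Map(
    function(g, bi) g[order(match(g, blocks[[bi]]$snps))],
    groups[keep], as.integer(names(groups)[keep])
  ))
  simple <- setdiff(mapped_snps, unlist(complex, use.names = FALSE))
  structure(list(owner = owner, simple = simple, complex = complex),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> '%s': %d simple + %d complex features (%d SNPs)\n",
              x$owner, length(x$simple), length(x$complex),
              length(x$simple) + sum(lengths(x$complex))))
  invisible(x)
}

#' Architecture of a feature set
#'
#' The matching key used to assemble null feature sets: the number of
#' simple features and the multiset of complex-feature sizes.
#'
#' @param features A `feature_set`.
#' @return Object of class `pathway_architecture`: list with `n_simple`
#'   and `sizes` (sorted integer vector).
#' @export
architecture <- function(features) {
  stopifnot(inherits(features, "feature_set"))
  structure(
    list(n_simple = length(features$simple),
         sizes = sort(as.integer(lengths(features$complex)))),
    class = "pathway_architecture"
  )
}

#' Feature sets for a pathway and its genes
#'
#' Maps SNPs into every pathway gene's flanked window, then decomposes the
#' deduplicated union into the pathway-level feature set and each gene's
#' mapped SNPs into per-gene feature sets (a SNP shared by overlapping
#' windows counts in each gene but once in the pathway union). Genes whose
#' windows capture no genotyped SNP are flagged with a warning and kept
#' with an empty feature set.
#'
#' @param pathway A [pathway_definition()].
#' @param annotations Gene annotation table.
#' @param snps SNP table (typically restricted to the SNPs with association
#'   results).
#' @param blocks `ld_blocks`.
#' @return List with `pathway` (pathway-level `feature_set`), `genes`
#'   (named list of per-gene `feature_set`s), `gene_snps` (named list of
#'   mapped ids per gene) and `snp_ids` (the pathway union).
#' @export
pathway_features <- function(pathway, annotations, snps, blocks) {
  stopifnot(inherits(pathway, "pathway_definition"))
  gene_snps <- list()
  gene_sets <- list()
  for (g in pathway$genes) {
    ann <- annotations[annotations$symbol == g, ]
    if (nrow(ann) != 1L) {
      stop(sprintf("gene %s not found (or duplicated) in annotations", g),
           call. = FALSE)
    }
    ids <- map_snps_to_gene(snps, ann, flank = pathway$flank)
    if (length(ids) == 0L) {
      warning(sprintf("gene %s has no genotyped SNP in its window", g),
              call. = FALSE)
    }
    gene_snps[[g]] <- ids
    gene_sets[[g]] <- decompose_features(ids, blocks, owner = g)
  }
  union_ids <- unique(unlist(gene_snps, use.names = FALSE))
  list(
    pathway = decompose_features(union_ids, blocks, owner = pathway$name),
    genes = gene_sets,
    gene_snps = gene_snps,
    snp_ids = union_ids
  )
}
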