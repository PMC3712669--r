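STRAND_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# Harmonize one study's rows to the reference effect allele. Returns the
# table with beta signs flipped where alleles were swapped, and NA rows
# where the labels are irreconcilable (neither a match, a swap, nor a
# strand flip of either).
harmonize_alleles <- function(tab, ref) {
  m <- match(tab$snp, ref$snp)
  ra1 <- ref$a1[m]
  ra2 <- ref$a2[m]
  same <- tab$a1 == ra1 & tab$a2 == ra2
  swap <- tab$a1 == ra2 & tab$a2 == ra1
  fa1 <- unname(STRAND_COMPLEMENT[tab$a1])
  fa2 <- unname(STRAND_COMPLEMENT[tab$a2])
  same_f <- !is.na(fa1) & fa1 == ra1 & fa2 == ra2
  swap_f <- !is.na(fa1) & fa1 == ra2 & fa2 == ra1
  ambiguous <- !is.na(fa1) & fa1 == tab$a2   # A/T and C/G SNPs
  if (any(ambiguous)) {
    warning(sprintf("%d strand-ambiguous (A/T or C/G) SNP(s) harmonized by label match",
                    sum(ambiguous)), call. = FALSE)
  }
  flip <- !same & (swap | (swap_f & !same_f))
  ok <- same | swap | same_f | swap_f
  tab$beta[flip] <- -tab$beta[flip]
  a1 <- tab$a1
  tab$a1[flip] <- tab$a2[flip]
  tab$a2[flip] <- a1[flip]
  tab$.harmonized <- ok
  tab
}

#' Inverse-variance fixed-effect meta-analysis of per-SNP summaries
#'
#' Combines association tables from several studies with weights
#' `w_i = 1 / se_i^2`: combined `beta = sum(w_i beta_i) / sum(w_i)`,
#' combined `se = 1 / sqrt(sum(w_i))`, two-sided normal p-value. Effect
#' alleles are harmonized to the first contributing study (allele swap
#' flips the sign; strand complements are recognized); SNPs whose labels
#' are irreconcilable are dropped with a message.
#'
#' A SNP flagged (`status != "ok"`) in any study that measures it is
#' excluded from the combined set, so only SNPs passing every measuring
#' study's checks enter; a SNP entirely absent from a study passes through
#' as the remaining studies' combination.
#'
#' @param studies List of `assoc_table` data.frames (one per study).
#' @return A `meta_table` data.frame with columns `snp`, `chr`, `pos`,
#'   `a1`, `a2`, `beta`, `se`, `p`, `n` (summed), `n_studies`.
#' @examples
#' s1 <- data.frame(snp = "rs1", chr = "1", pos = 100, a1 = "A", a2 = "G",
#'                  beta = 0.3, se = 0.1, p = 0.0027, n = 1000, status = "ok")
#' s2 <- data.frame(snp = "rs1", chr = "1", pos = 100, a1 = "A", a2 = "G",
#'                  beta = 0.0, se = 0.2, p = 1, n = 800, status = "ok")
#' inverse_variance_meta(list(s1, s2))
#' @export
inverse_variance_meta <- function(studies) {
  stopifnot(is.list(studies), length(studies) >= 1L)
  studies <- lapply(studies, as.data.frame)

  # reference allele frame: first study in which each SNP appears
  all_snps <- unique(unlist(lapply(studies, `[[`, "snp")))
  ref <- NULL
  for (s in studies) {
    add <- s[!(s$snp %in% ref$snp), c("snp", "chr", "pos", "a1", "a2")]
    ref <- rbind(ref, add)
  }
  ref <- ref[match(all_snps, ref$snp), ]

  # flagged anywhere it was measured -> out of the combined set
  flagged <- unique(unlist(lapply(studies, function(s) s$snp[s$status != "ok"])))

  harmonized <- lapply(studies, harmonize_alleles, ref = ref)
  n_irrec <- sum(vapply(harmonized, function(s) sum(!s$.harmonized), 0))
  if (n_irrec > 0L) {
    message(sprintf("meta-analysis: %d SNP record(s) with irreconcilable alleles dropped",
                    n_irrec))
  }

  wsum <- bsum <- nsum <- ksum <- stats::setNames(numeric(length(all_snps)), all_snps)
  for (s in harmonized) {
    use <- s$status == "ok" & s$.harmonized & is.finite(s$beta) & is.finite(s$se)
    idx <- match(s$snp[use], all_snps)
    w <- 1 / s$se[use]^2
    wsum[idx] <- wsum[idx] + w
    bsum[idx] <- bsum[idx] + w * s$beta[use]
    nsum[idx] <- nsum[idx] + s$n[use]
    ksum[idx] <- ksum[idx] + 1
  }
  keep <- ksum >= 1 & !(all_snps %in% flagged)
  beta <- bsum[keep] / wsum[keep]
  se <- 1 / sqrt(wsum[keep])
  z <- beta / se
  out <- data.frame(
    snp = all_snps[keep],
    chr = ref$chr[keep], pos = ref$pos[keep],
    a1 = ref$a1[keep], a2 = ref$a2[keep],
    beta = unname(beta), se = unname(se),
    p = pmax(2 * stats::pnorm(-abs(unname(z))), .Machine$double.xmin),
    n = unname(nsum[keep]), n_studies = as.integer(unname(ksum[keep])),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, class = c("meta_table", "data.frame"))
}

#' Sample-size-weighted z-score meta-analysis
#'
#' Direction-aware combination of per-study p-values:
#' `z_i = sign(beta_i) * qnorm(p_i / 2, lower.tail = FALSE)` and combined
#' `z = sum(sqrt(n_i) z_i) / sqrt(sum(n_i))`. Reports a p-value (and z)
#' only; no combined effect size.
#'
#' @inheritParams inverse_variance_meta
#' @return A `meta_table` data.frame with `snp`, `chr`, `pos`, `a1`, `a2`,
#'   `z`, `p`, `n`, `n_studies`.
#' @export
sample_size_weighted_z <- function(studies) {
  stopifnot(is.list(studies), length(studies) >= 1L)
  studies <- lapply(studies, as.data.frame)
  for (s in studies) {
    if (any(s$status == "ok" & (is.na(s$n) | s$n <= 0))) {
      stop("sample-size-weighted meta-analysis requires n for every SNP",
           call. = FALSE)
    }
  }
  all_snps <- unique(unlist(lapply(studies, `[[`, "snp")))
  ref <- NULL
  for (s in studies) {
    add <- s[!(s$snp %in% ref$snp), c("snp", "chr", "pos", "a1", "a2")]
    ref <- rbind(ref, add)
  }
  ref <- ref[match(all_snps, ref$snp), ]
  flagged <- unique(unlist(lapply(studies, function(s) s$snp[s$status != "ok"])))
  harmonized <- lapply(studies, harmonize_alleles, ref = ref)

  zn <- nsum <- ksum <- stats::setNames(numeric(length(all_snps)), all_snps)
  for (s in harmonized) {
    use <- s$status == "ok" & s$.harmonized & is.finite(s$beta) & is.finite(s$p)
    idx <- match(s$snp[use], all_snps)
    zi <- sign(s$beta[use]) * stats::qnorm(s$p[use] / 2, lower.tail = FALSE)
    zn[idx] <- zn[idx] + sqrt(s$n[use]) * zi
    nsum[idx] <- nsum[idx] + s$n[use]
    ksum[idx] <- ksum[idx] + 1
  }
  keep <- ksum >= 1 & !(all_snps %in% flagged)
  z <- zn[keep] / sqrt(nsum[keep])
  out <- data.frame(
    snp = all_snps[keep], chr = ref$chr[keep], pos = ref$pos[keep],
    a1 = ref$a1[keep], a2 = ref$a2[keep],
    z = unname(z),
    p = pmax(2 * stats::pnorm(-abs(unname(z))), .Machine$double.xmin),
    n = unname(nsum[keep]), n_studies = as.integer(unname(ksum[keep])),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, class = c("meta_table", "data.frame"))
}
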