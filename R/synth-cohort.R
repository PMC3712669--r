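#' Configuration for a synthetic case-control cohort
#'
#' Disease status is drawn from an additive logistic model on genotype
#' dosages and covariates:
#' `logit P(case) = intercept + sum(beta_j * g_j) + beta_age * age +
#' site effect (+ beta_sex * female)`. SNP effects may be restricted to one
#' gender stratum (`sex = "female"` or `"male"`), in which case the term
#' enters the linear predictor only for subjects of that gender. Sampling is
#' by rejection conditional on status so the realized case/control counts
#' equal the configured counts exactly.
#'
#' Defaults emulate the two source collections the package's worked analyses
#' mirror: use `n_cases = 976, n_controls = 1140` for a GLAUGEN-like cohort
#' and `n_cases = 2132, n_controls = 2290` for a NEIGHBOR-like one.
#'
#' @param n_cases,n_controls Exact case and control counts to return.
#' @param causal_snps `NULL` or a data.frame with columns `snp` (panel SNP
#'   id), `beta` (log odds ratio per counted allele) and optionally `sex`
#'   (`"both"` (default), `"female"`, `"male"`).
#' @param covariate_effects Named numeric vector of covariate coefficients:
#'   `age` (per SD of the standardized age-like covariate), `sex` (female
#'   vs male) and `site` (second site vs first).
#' @param female_fraction Probability a subject is female.
#' @param n_sites Number of collection sites (categorical covariate).
#' @param intercept Baseline log-odds of disease.
#' @param iop_mean,iop_sd Normal parameters for intraocular pressure (IOP,
#'   mmHg) at diagnosis, recorded for cases and used to split them into
#'   high-pressure (IOP >= 22) and normal-pressure (IOP < 22) subtypes.
#' @param iop_missing Fraction of cases with no recorded IOP at diagnosis
#'   (kept in overall analyses, excluded from the pressure subtypes).
#' @param max_attempts Batches of candidate subjects to draw before
#'   declaring the requested counts infeasible.
#' @param seed Integer seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_cases,
                          n_controls,
                          causal_snps = NULL,
                          covariate_effects = c(age = 0.2, sex = 0, site = 0.1),
                          female_fraction = 0.55,
                          n_sites = 2L,
                          intercept = 0,
                          iop_mean = 24.5,
                          iop_sd = 4.5,
                          iop_missing = 0.24,
                          max_attempts = 50L,
                          seed = 1L) {
  stopifnot_scalar_count(n_cases, "n_cases")
  stopifnot_scalar_count(n_controls, "n_controls")
  stopifnot_range(female_fraction, "female_fraction", 0, 1)
  stopifnot_scalar_count(n_sites, "n_sites")
  if (!is.null(causal_snps)) {
    causal_snps <- as.data.frame(causal_snps, stringsAsFactors = FALSE)
    if (!all(c("snp", "beta") %in% names(causal_snps))) {
      stop("`causal_snps` needs columns `snp` and `beta`", call. = FALSE)
    }
    if (is.null(causal_snps$sex)) causal_snps$sex <- "both"
    bad <- setdiff(causal_snps$sex, c("both", "female", "male"))
    if (length(bad)) stop("invalid `sex` restriction: ", bad[1], call. = FALSE)
  }
  eff <- c(age = 0, sex = 0, site = 0)
  eff[names(covariate_effects)] <- covariate_effects
  structure(
    list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
         causal_snps = causal_snps, covariate_effects = eff,
         female_fraction = female_fraction, n_sites = as.integer(n_sites),
         intercept = intercept, iop_mean = iop_mean, iop_sd = iop_sd,
         iop_missing = iop_missing, max_attempts = as.integer(max_attempts),
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# Draw one batch of candidate subjects: covariates plus only the causal
# SNPs' haplotype alleles (and their blocks' tags), enough to decide
# status. The rest of the genome is drawn later, only for subjects that
# are retained, conditionally on these tags.
draw_candidate_batch <- function(panel, config, n) {
  gen <- panel$gen
  sex <- ifelse(stats::runif(n) < config$female_fraction, "F", "M")
  age <- stats::rnorm(n)
  site <- sample.int(config$n_sites, n, replace = TRUE)

  cs <- config$causal_snps
  tags1 <- tags2 <- NULL
  a1 <- a2 <- NULL
  eta <- rep(config$intercept, n)
  if (!is.null(cs) && nrow(cs)) {
    idx <- match(cs$snp, gen$id)
    active <- unique(stats::na.omit(gen$block[idx]))
    if (length(active)) {
      p0 <- gen$p0[match(active, gen$block)]
      tags1 <- matrix(stats::runif(n * length(active)) < rep(p0, each = n), n,
                      dimnames = list(NULL, active))
      tags2 <- matrix(stats::runif(n * length(active)) < rep(p0, each = n), n,
                      dimnames = list(NULL, active))
    }
    a1 <- a2 <- matrix(0L, n, length(idx))
    for (k in seq_along(idx)) {
      j <- idx[k]
      if (is.na(gen$block[j])) {
        a1[, k] <- (stats::runif(n) < gen$q[j]) + 0L
        a2[, k] <- (stats::runif(n) < gen$q[j]) + 0L
      } else {
        b <- gen$block[j]
        a1[, k] <- (tags1[, b] != (stats::runif(n) < gen$eps[j])) + 0L
        a2[, k] <- (tags2[, b] != (stats::runif(n) < gen$eps[j])) + 0L
      }
      g <- a1[, k] + a2[, k]
      if (gen$chr[j] == "X") {
        male <- sex == "M"
        g[male] <- 2L * a1[male, k]
      }
      term <- cs$beta[k] * g
      term <- switch(cs$sex[k],
        both = term,
        female = term * (sex == "F"),
        male = term * (sex == "M")
      )
      eta <- eta + term
    }
  }
  eff <- config$covariate_effects
  eta <- eta + eff[["age"]] * age + eff[["sex"]] * (sex == "F") +
    eff[["site"]] * (site == 2L)
  status <- stats::rbinom(n, 1L, stats::plogis(eta))
  list(
    subjects = data.frame(
      status = status, sex = sex, age = age,
      site = factor(site, levels = seq_len(config$n_sites)),
      stringsAsFactors = FALSE
    ),
    tags1 = tags1, tags2 = tags2, a1 = a1, a2 = a2
  )
}

#' Simulate a case-control cohort from a reference panel's population model
#'
#' Draws fresh individuals from the same block-LD population the panel was
#' generated from, assigns disease status from the configured logistic
#' model, and retains subjects conditional on status until the exact
#' configured case and control counts are reached. Cases additionally
#' receive an IOP-at-diagnosis value (a fraction of them missing).
#'
#' @param panel An `snp_panel` from [generate_reference_panel()].
#' @param config A [cohort_config()]. Every causal SNP id must exist in the
#'   panel.
#' @param name Study label stored with the data.
#' @return An object of class `study_data`: list with `genotypes`
#'   (subjects x SNPs dosage matrix), `subjects` (data.frame: `status`
#'   1 = case / 0 = control, `sex` "F"/"M", `age`, `site`, `iop`), `snps`
#'   (the panel's SNP table) and `study`.
#' @export
generate_cohort <- function(panel, config, name = "study") {
  stopifnot(inherits(panel, "snp_panel"))
  if (!inherits(config, "cohort_config")) {
    stop("`config` must be a cohort_config()", call. = FALSE)
  }
  cs <- config$causal_snps
  if (!is.null(cs) && nrow(cs)) {
    missing_ids <- setdiff(cs$snp, panel$snps$id)
    if (length(missing_ids)) {
      stop("causal SNP(s) not in panel: ",
           paste(missing_ids, collapse = ", "), call. = FALSE)
    }
  }
  with_seed(config$seed, {
    gen <- panel$gen
    need_ca <- config$n_cases
    need_co <- config$n_controls
    got_sub <- NULL
    got_tags1 <- got_tags2 <- got_a1 <- got_a2 <- NULL
    batch <- ceiling(1.3 * (need_ca + need_co))
    attempts <- 0L
    while (need_ca > 0L || need_co > 0L) {
      attempts <- attempts + 1L
      if (attempts > config$max_attempts) {
        stop(sprintf(
          "requested case/control counts infeasible: still need %d cases and %d controls after %d sampling batches",
          need_ca, need_co, config$max_attempts
        ), call. = FALSE)
      }
      b <- draw_candidate_batch(panel, config, batch)
      is_case <- b$subjects$status == 1L
      take_ca <- utils::head(which(is_case), need_ca)
      take_co <- utils::head(which(!is_case), need_co)
      keep <- c(take_ca, take_co)
      need_ca <- need_ca - length(take_ca)
      need_co <- need_co - length(take_co)
      got_sub <- rbind(got_sub, b$subjects[keep, , drop = FALSE])
      if (!is.null(b$tags1)) {
        got_tags1 <- rbind(got_tags1, b$tags1[keep, , drop = FALSE])
        got_tags2 <- rbind(got_tags2, b$tags2[keep, , drop = FALSE])
      }
      if (!is.null(b$a1)) {
        got_a1 <- rbind(got_a1, b$a1[keep, , drop = FALSE])
        got_a2 <- rbind(got_a2, b$a2[keep, , drop = FALSE])
      }
      batch <- max(200L, ceiling(1.5 * (need_ca + need_co)))
    }
    ord <- order(got_sub$status, decreasing = TRUE)
    subjects <- got_sub[ord, , drop = FALSE]
    n_tot <- nrow(subjects)

    # draw the genome only for retained subjects, conditional on the
    # causal blocks' tags, then overwrite the causal alleles actually used
    ft1 <- if (is.null(got_tags1)) NULL else got_tags1[ord, , drop = FALSE]
    ft2 <- if (is.null(got_tags2)) NULL else got_tags2[ord, , drop = FALSE]
    h1 <- draw_haplotypes(gen, n_tot, fixed_tags = ft1)
    h2 <- draw_haplotypes(gen, n_tot, fixed_tags = ft2)
    if (!is.null(got_a1)) {
      cidx <- match(cs$snp, gen$id)
      h1[, cidx] <- got_a1[ord, , drop = FALSE]
      h2[, cidx] <- got_a2[ord, , drop = FALSE]
    }
    G <- h1 + h2
    x_cols <- which(gen$chr == "X")
    if (length(x_cols)) {
      # males are hemizygous on X: one haplotype, dosage coded 0/2
      male <- subjects$sex == "M"
      G[male, x_cols] <- 2L * h1[male, x_cols, drop = FALSE]
    }
    colnames(G) <- gen$id
    rownames(G) <- rownames(subjects) <- NULL
    subjects$id <- sprintf("%s_%05d", name, seq_len(nrow(subjects)))

    iop <- rep(NA_real_, nrow(subjects))
    is_case <- subjects$status == 1L
    n_case <- sum(is_case)
    has_iop <- stats::runif(n_case) >= config$iop_missing
    vals <- pmax(8, stats::rnorm(n_case, config$iop_mean, config$iop_sd))
    iop[is_case][has_iop] <- vals[has_iop]
    subjects$iop <- iop

    structure(
      list(genotypes = G,
           subjects = subjects[, c("id", "status", "sex", "age", "site", "iop")],
           snps = panel$snps, study = name),
      class = "study_data"
    )
  })
}

#' @export
print.study_data <- function(x, ...) {
  cat(sprintf(
    "<study_data> '%s': %d cases / %d controls, %d SNPs (%.0f%% female)\n",
    x$study, sum(x$subjects$status == 1), sum(x$subjects$status == 0),
    ncol(x$genotypes), 100 * mean(x$subjects$sex == "F")
  ))
  invisible(x)
}
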