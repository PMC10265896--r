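#' Hardy-Weinberg equilibrium test for dosage vectors
#'
#' Chi-squared goodness-of-fit with 1 df on the three genotype counts
#' against Hardy-Weinberg proportions at the sample allele frequency.
#' Adequate at reference-panel sizes of a few hundred; monomorphic sites
#' return P = 1.
#'
#' @param dosages Vector of 0/1/2 dosages, or a matrix (SNPs in columns).
#' @return P value(s).
#' @export
hwe_test <- function(dosages) {
  one <- function(g) {
    n <- length(g)
    obs <- tabulate(g + 1L, 3L)
    p <- (obs[2] + 2 * obs[3]) / (2 * n)
    if (p == 0 || p == 1) return(1)
    expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    chi2 <- sum((obs - expd)^2 / expd)
    stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  if (is.matrix(dosages)) apply(dosages, 2, one) else one(dosages)
}

#' Per-SNP LD scores from a reference panel
#'
#' For each focal SNP, the sum over same-chromosome SNPs within
#' `window_bp` (self included) of the bias-adjusted squared correlation
#' `r2 - (1 - r2) / (n - 2)` of unphased dosages. Flanking SNPs failing the
#' MAF or Hardy-Weinberg filters are excluded from the sums; the self term
#' (adjusted value exactly 1) is always included.
#'
#' @param panel A [ref_panel] with at least 3 individuals.
#' @param window_bp Window half-width in base pairs (default 10 Mb).
#' @param maf_min Flanking-SNP MAF filter.
#' @param hwe_p_min Flanking-SNP Hardy-Weinberg P-value filter.
#' @return Named vector of LD scores keyed by `snp_id`.
#' @export
ld_scores <- function(panel, window_bp = 1e7, maf_min = 0.01,
                      hwe_p_min = 1e-5) {
  n <- panel$n_ind
  if (n < 3) stop("ld_scores: need at least 3 individuals")
  map <- panel$map
  maf <- unname(panel_maf(panel))
  keep <- maf > maf_min & hwe_test(panel$geno) > hwe_p_min
  scores <- stats::setNames(rep(1, nrow(map)), map$snp_id)
  for (ch in unique(map$chrom)) {
    i <- which(map$chrom == ch)
    g <- panel$geno[, i, drop = FALSE]
    r2 <- suppressWarnings(cor(g)^2)
    r2[is.na(r2)] <- 0
    adj <- r2 - (1 - r2) / (n - 2)
    bp <- map$bp[i]
    inwin <- abs(outer(bp, bp, "-")) <= window_bp
    use <- inwin & matrix(keep[i], nrow = length(i), ncol = length(i),
                          byrow = TRUE)
    diag(use) <- TRUE
    diag(adj) <- 1
    scores[i] <- rowSums(adj * use)
  }
  scores
}

#' Hudson's Fst estimator for one SNP
#'
#' `((f1 - f2)^2 - f1(1-f1)/(n1-1) - f2(1-f2)/(n2-1)) /
#'  (f1(1-f2) + f2(1-f1))`, where `n1`, `n2` are sampled chromosome counts.
#' The sampling correction makes the estimator unbiased around zero, so
#' small negative values occur for undifferentiated SNPs; values are
#' reported unclamped. Symmetric in the two populations. A zero denominator
#' (both frequencies 0, or both 1) yields `NA` with a warning.
#'
#' @param f1,f2 Allele frequencies of the same allele in each population.
#' @param n1,n2 Chromosome counts (2 x individuals), >= 2.
#' @return Fst value(s), vectorized.
#' @export
hudson_fst <- function(f1, n1, f2, n2) {
  stopifnot(all(f1 >= 0 & f1 <= 1), all(f2 >= 0 & f2 <= 1),
            all(n1 >= 2), all(n2 >= 2))
  num <- (f1 - f2)^2 - f1 * (1 - f1) / (n1 - 1) - f2 * (1 - f2) / (n2 - 1)
  den <- f1 * (1 - f2) + f2 * (1 - f1)
  bad <- den == 0
  if (any(bad)) warning("hudson_fst: undefined for ", sum(bad),
                        " SNP(s) fixed in both populations")
  out <- num / den
  out[bad] <- NA_real_
  out
}

#' Per-SNP Fst between two panels
#'
#' @param panel1,panel2 [ref_panel] objects sharing SNP ids.
#' @param snp_ids Optional subset of SNPs.
#' @return Named vector of Hudson Fst values.
#' @export
panel_fst <- function(panel1, panel2, snp_ids = NULL) {
  ids <- snp_ids %||% intersect(panel1$map$snp_id, panel2$map$snp_id)
  f1 <- panel_freq(panel1)[ids]
  f2 <- panel_freq(panel2)[ids]
  stats::setNames(hudson_fst(f1, 2 * panel1$n_ind, f2, 2 * panel2$n_ind), ids)
}

#' Compare a per-SNP metric between transFDR groups
#'
#' Per phenotype: a two-sided Mann-Whitney U test (normal approximation with
#' tie correction, no continuity correction) of the metric between the
#' significant and non-significant SNP groups. Across phenotypes: each
#' phenotype's group means are reduced to the binary indicator
#' "significant-group mean < non-significant-group mean" and an exact
#' binomial sign test against 0.5 is reported — the paired-design analog of
#' a McNemar test when per-phenotype uncertainty of the averages is ignored.
#' With `literal_mcnemar = TRUE`, McNemar's chi-squared on the
#' discordant-pair construction `(b - c)^2 / (b + c)` is also reported for
#' transparency.
#'
#' @param metrics Data frame with columns `phenotype`, `group`
#'   (`"significant"` / `"non_significant"`), and the metric column named by
#'   `metric_name`.
#' @param metric_name Column to compare (e.g. `"mafcv"`, `"ldcv"`, `"fst"`).
#' @param literal_mcnemar Also compute the literal McNemar chi-squared?
#' @return List with `per_phenotype` (n per group, group means, Mann-Whitney
#'   P), `sign_test` (successes = phenotypes with smaller significant-group
#'   mean, exact binomial P), `group_means` (cross-phenotype mean +/- SD per
#'   group), and optionally `mcnemar`.
#' @export
group_compare <- function(metrics, metric_name, literal_mcnemar = FALSE) {
  stopifnot(all(c("phenotype", "group", metric_name) %in% names(metrics)))
  res <- NULL
  for (ph in unique(metrics$phenotype)) {
    d <- metrics[metrics$phenotype == ph, ]
    sig <- d[[metric_name]][d$group == "significant"]
    non <- d[[metric_name]][d$group == "non_significant"]
    sig <- sig[!is.na(sig)]; non <- non[!is.na(non)]
    if (!length(sig) || !length(non)) {
      warning("group_compare: phenotype '", ph,
              "' has an empty group; skipped")
      next
    }
    wt <- suppressWarnings(wilcox.test(sig, non, exact = FALSE,
                                       correct = FALSE))
    res <- rbind(res, data.frame(
      phenotype = ph, n_sig = length(sig), n_non = length(non),
      mean_sig = mean(sig), mean_non = mean(non),
      p_mann_whitney = wt$p.value, stringsAsFactors = FALSE))
  }
  if (is.null(res)) stop("group_compare: no phenotype with both groups")
  lower <- res$mean_sig < res$mean_non
  bt <- binom.test(sum(lower), nrow(res), p = 0.5)
  out <- list(per_phenotype = res,
              sign_test = list(successes = sum(lower), n = nrow(res),
                               proportion = mean(lower), p = bt$p.value),
              group_means = data.frame(
                group = c("significant", "non_significant"),
                mean = c(mean(res$mean_sig), mean(res$mean_non)),
                sd = c(sd(res$mean_sig), sd(res$mean_non))))
  if (literal_mcnemar) {
    b <- sum(lower); cc <- sum(!lower)
    chi2 <- if (b + cc > 0) (b - cc)^2 / (b + cc) else NA_real_
    out$mcnemar <- list(chi2 = chi2,
                        p = stats::pchisq(chi2, 1, lower.tail = FALSE))
  }
  out
}

#' Per-SNP cross-population metrics for a classified index set
#'
#' Assembles the per-SNP group-metrics table: MAFs and folded MAF CV
#' ([pair_cv()] on folded frequencies, invariant to which allele is labeled
#' minor), LD scores in both panels and their CV, and Hudson's Fst, joined
#' with the transFDR group labels.
#'
#' @param corrected `paired_sumstats` rows of the index SNPs (needs `snp_id`,
#'   `maf1`, `maf2`).
#' @param groups Per-SNP transFDR group labels.
#' @param panel1,panel2 Target and discovery [ref_panel]s; when supplied, LD
#'   scores and Fst are computed from them (Fst frequencies and LD scores
#'   come from the panels, MAFs from the summary statistics).
#' @param phenotype Phenotype label attached to every row.
#' @param ld1,ld2 Optional precomputed LD-score vectors (named by snp_id) to
#'   avoid recomputing across phenotypes.
#' @return Data frame with one row per SNP: `phenotype`, `snp_id`, `group`,
#'   `maf_1`, `maf_2`, `mafcv`, `ld_score_1`, `ld_score_2`, `ldcv`, `fst`.
#' @export
group_metrics <- function(corrected, groups, panel1 = NULL, panel2 = NULL,
                          phenotype = "phenotype", ld1 = NULL, ld2 = NULL) {
  ids <- corrected$snp_id
  out <- data.frame(phenotype = phenotype, snp_id = ids, group = groups,
                    maf_1 = corrected$maf1, maf_2 = corrected$maf2,
                    stringsAsFactors = FALSE)
  out$mafcv <- suppressWarnings(
    pair_cv(pmin(out$maf_1, 1 - out$maf_1), pmin(out$maf_2, 1 - out$maf_2)))
  if (!is.null(panel1) && !is.null(panel2)) {
    if (is.null(ld1)) ld1 <- ld_scores(panel1)
    if (is.null(ld2)) ld2 <- ld_scores(panel2)
    out$ld_score_1 <- unname(ld1[ids])
    out$ld_score_2 <- unname(ld2[ids])
    out$ldcv <- suppressWarnings(pair_cv(out$ld_score_1, out$ld_score_2))
    out$fst <- unname(panel_fst(panel1, panel2, ids))
  }
  out
}
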