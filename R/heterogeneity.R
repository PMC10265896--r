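#' Disattenuated cross-population correlation of effect estimates
#'
#' The Pearson correlation of noisy effect estimates is attenuated below the
#' correlation of the true effects. Under a measurement-error model with
#' known sampling variances, the disattenuated estimator is
#' `r_m = S12 / sqrt((S1^2 - mean(se1^2)) (S2^2 - mean(se2^2)))`, where
#' `S12` is the sample covariance of the estimates and `S1^2`, `S2^2` their
#' sample variances. If a noise-corrected variance is non-positive (possible
#' in small groups), the raw Pearson correlation is returned with a warning.
#' The result is clipped to `[-1, 1]`.
#'
#' @param beta1,se1 Target-population effect estimates and SEs.
#' @param beta2,se2 Discovery-population effect estimates and SEs.
#' @return Scalar `r_m`.
#' @export
marginal_correlation <- function(beta1, se1, beta2, se2) {
  if (length(beta1) < 5) stop("marginal_correlation: need >= 5 SNPs")
  s12 <- cov(beta1, beta2)
  v1 <- var(beta1) - mean(se1^2)
  v2 <- var(beta2) - mean(se2^2)
  if (v1 <= 0 || v2 <= 0) {
    warning("marginal_correlation: noise-corrected variance non-positive; ",
            "falling back to the raw Pearson correlation")
    return(max(-1, min(1, cor(beta1, beta2))))
  }
  max(-1, min(1, s12 / sqrt(v1 * v2)))
}

#' Per-SNP trans-ethnic effect-heterogeneity test
#'
#' Tests whether a SNP's effect differs between the target and discovery
#' populations:
#' `u = (b1 - b2) / sqrt(s1^2 + s2^2 - 2 r_m s1 s2)`, two-sided normal P.
#' `b1` is the unadjusted target marginal effect with its standardized SE;
#' `b2` is the winner's-curse-reduced discovery effect with its recomputed
#' SE; `r_m` is the disattenuated effect correlation of the SNP's group,
#' which accounts for the dependence of the two estimates. With `r_m = 0`
#' this is the standard two-sample z statistic.
#'
#' @param b1,s1 Target effects and SEs (vectorized).
#' @param b2,s2 Discovery effects and SEs.
#' @param r_m Marginal trans-ethnic effect correlation (scalar).
#' @return Data frame with columns `u` and `p`.
#' @export
heterogeneity_test <- function(b1, s1, b2, s2, r_m = 0) {
  stopifnot(all(s1 > 0), all(s2 > 0), abs(r_m) <= 1)
  v <- s1^2 + s2^2 - 2 * r_m * s1 * s2
  if (any(v <= 0)) stop("heterogeneity_test: non-positive variance")
  u <- (b1 - b2) / sqrt(v)
  data.frame(u = u, p = z_to_p(u))
}

#' Effect-direction concordance between populations
#'
#' Classifies SNPs by the sign pair of their effects, target then discovery:
#' `++`, `+-` (positive target, negative discovery), `-+`, `--`. Exact-zero
#' effects cannot be signed and are excluded from the classes but counted.
#'
#' @param beta1,beta2 Target and discovery effects.
#' @param group Optional per-SNP group labels; proportions are then also
#'   reported per group.
#' @return List with `overall` (named class proportions), `n_zero`,
#'   `discordance` (share of `+-` plus `-+`), and `per_group` when `group`
#'   is supplied.
#' @export
direction_concordance <- function(beta1, beta2, group = NULL) {
  cls_of <- function(b1, b2) {
    paste0(ifelse(b1 > 0, "+", "-"), ifelse(b2 > 0, "+", "-"))
  }
  nz <- beta1 != 0 & beta2 != 0
  lv <- c("++", "+-", "-+", "--")
  prop <- function(i) {
    cl <- factor(cls_of(beta1[i], beta2[i]), levels = lv)
    p <- as.numeric(table(cl)) / max(1, sum(i))
    stats::setNames(p, lv)
  }
  out <- list(overall = prop(nz), n_zero = sum(!nz))
  out$discordance <- unname(out$overall["+-"] + out$overall["-+"])
  if (!is.null(group)) {
    gs <- unique(group)
    out$per_group <- stats::setNames(lapply(gs, function(g) {
      p <- prop(nz & group == g)
      c(p, discordance = unname(p["+-"] + p["-+"]))
    }), gs)
  }
  out
}

#' Contrast heterogeneity proportions between SNP groups
#'
#' Pearson chi-squared test (no continuity correction) on the 2x2 table of
#' heterogeneous/non-heterogeneous x significant/non-significant SNP counts.
#'
#' @param het_counts 2x2 numeric matrix or table.
#' @return List with `chi2`, `df` and `p`.
#' @export
group_heterogeneity_contrast <- function(het_counts) {
  m <- as.matrix(het_counts)
  stopifnot(all(dim(m) == c(2, 2)), all(m >= 0))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("group_heterogeneity_contrast: zero margin in the 2x2 table")
  ct <- suppressWarnings(chisq.test(m, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Group-wise heterogeneity analysis of a classified index set
#'
#' For each transFDR group separately: estimates the group's disattenuated
#' effect correlation `r_m` ([marginal_correlation()]) from the unadjusted
#' target effects (standardized SEs) and corrected discovery effects, runs
#' the per-SNP heterogeneity test with the group's `r_m`, BH-adjusts within
#' the group, and flags SNPs with FDR < `fdr_threshold`. Groups smaller than
#' 5 SNPs use `r_m = 0` with a warning.
#'
#' @param corrected A `paired_sumstats` after [correct_index_effects()]
#'   (columns `beta1`, `se1_std`, `beta2_corrected`, `se2_corrected`).
#' @param groups Per-SNP labels from [transfdr()] (`"significant"` /
#'   `"non_significant"`).
#' @param fdr_threshold Heterogeneity call level.
#' @return List with `per_snp` (u, p, fdr, heterogeneous, group),
#'   `r_m` (named per group), `het_counts` (2x2 table), `contrast`
#'   ([group_heterogeneity_contrast()] when both margins allow), and
#'   `direction` ([direction_concordance()]).
#' @export
heterogeneity_summary <- function(corrected, groups, fdr_threshold = 0.05) {
  stopifnot(nrow(corrected) == length(groups))
  b1 <- corrected$beta1; s1 <- corrected$se1_std
  b2 <- corrected$beta2_corrected; s2 <- corrected$se2_corrected
  per <- data.frame(snp_id = corrected$snp_id, group = groups,
                    u = NA_real_, p = NA_real_, fdr = NA_real_,
                    heterogeneous = NA, stringsAsFactors = FALSE)
  r_m <- c()
  for (gname in unique(groups)) {
    i <- which(groups == gname)
    rm_g <- if (length(i) >= 5) {
      marginal_correlation(b1[i], s1[i], b2[i], s2[i])
    } else {
      warning("heterogeneity_summary: group '", gname,
              "' has < 5 SNPs; using r_m = 0")
      0
    }
    r_m[gname] <- rm_g
    ht <- heterogeneity_test(b1[i], s1[i], b2[i], s2[i], rm_g)
    per$u[i] <- ht$u
    per$p[i] <- ht$p
    per$fdr[i] <- bh_adjust(ht$p)
    per$heterogeneous[i] <- per$fdr[i] < fdr_threshold
  }
  het_counts <- table(factor(per$heterogeneous, c(TRUE, FALSE)),
                      factor(per$group,
                             c("significant", "non_significant")))
  contrast <- if (all(rowSums(het_counts) > 0) && all(colSums(het_counts) > 0))
    group_heterogeneity_contrast(het_counts) else NULL
  list(per_snp = per, r_m = r_m, het_counts = het_counts,
       contrast = contrast,
       direction = direction_concordance(b1, b2, groups))
}
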