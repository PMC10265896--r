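#' Heritability-difference test between two populations
#'
#' Tests whether the SNP-based heritability of a phenotype differs between
#' the target and discovery populations, accounting for the correlation of
#' the two heritability estimators through the trans-ethnic genetic
#' correlation:
#' `u = (h2_1 - h2_2) / sqrt(se1^2 + se2^2 - 2 rho_g se1 se2)`, with a
#' two-sided normal P value. With `rho_g = 0` this is the independent
#' two-sample z-test.
#'
#' @param h2_1,se_1 Target-population heritability estimate and SE.
#' @param h2_2,se_2 Discovery-population heritability estimate and SE.
#' @param rho_g Trans-ethnic genetic correlation estimate; `NA` is treated
#'   as 0 (independent estimators).
#' @return Data frame with columns `u` and `p` (vectorized).
#' @export
h2_difference_test <- function(h2_1, se_1, h2_2, se_2, rho_g = 0) {
  rho_g <- ifelse(is.na(rho_g), 0, rho_g)
  v <- se_1^2 + se_2^2 - 2 * rho_g * se_1 * se_2
  if (any(v <= 0))
    stop("h2_difference_test: non-positive variance for record(s) ",
         paste(which(v <= 0), collapse = ", "))
  u <- (h2_1 - h2_2) / sqrt(v)
  data.frame(u = u, p = z_to_p(u))
}

#' Tests of the trans-ethnic genetic correlation against 0 and 1
#'
#' Approximate normal tests `u0 = rho_g / se` (H0: rho_g = 0) and
#' `u1 = (rho_g - 1) / se` (H0: rho_g = 1), both two-sided.
#'
#' @param rho_g Estimated trans-ethnic genetic correlation(s).
#' @param se_rho Standard error(s), positive.
#' @return Data frame with columns `u0`, `p0`, `u1`, `p1`.
#' @export
rho_tests <- function(rho_g, se_rho) {
  stopifnot(all(se_rho > 0, na.rm = TRUE))
  u0 <- rho_g / se_rho
  u1 <- (rho_g - 1) / se_rho
  data.frame(u0 = u0, p0 = z_to_p(u0), u1 = u1, p1 = z_to_p(u1))
}

#' Benjamini-Hochberg adjusted P values
#'
#' Step-up FDR adjustment with enforced monotonicity, capped at 1 (delegates
#' to [stats::p.adjust()]). Exact zeros are accepted: they arise from
#' floating-point underflow of two-sided normal P values at extreme z.
#'
#' @param p_values P values in \[0, 1\].
#' @return Adjusted values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  p.adjust(p_values, method = "BH")
}

#' Count genetic correlations significantly below one
#'
#' Applies the two-sided H0: rho_g = 1 test of [rho_tests()] across
#' phenotypes, BH-adjusts, and counts rejections at `fdr_threshold`.
#' Records with missing `rho_g` (e.g. estimates out of range upstream) are
#' excluded.
#'
#' @param rho_g,se_rho Per-phenotype estimates and SEs.
#' @param fdr_threshold Rejection level on the adjusted values.
#' @return List with `count`, `n` (records tested) and `proportion`.
#' @export
count_rho_less_than_one <- function(rho_g, se_rho, fdr_threshold = 0.05) {
  ok <- !is.na(rho_g) & !is.na(se_rho)
  rt <- rho_tests(rho_g[ok], se_rho[ok])
  fdr <- bh_adjust(rt$p1)
  list(count = sum(fdr < fdr_threshold), n = sum(ok),
       proportion = sum(fdr < fdr_threshold) / sum(ok))
}

#' Cross-population correlation of heritability estimates
#'
#' Pearson correlation between the per-phenotype heritability estimates of
#' the two populations, with the standard t-based P value.
#'
#' @param h2_1,h2_2 Per-phenotype heritability estimates (>= 3 records).
#' @return List with `r` and `p`.
#' @export
heritability_correlation <- function(h2_1, h2_2) {
  if (length(h2_1) < 3) stop("heritability_correlation: need >= 3 records")
  if (sd(h2_1) == 0 || sd(h2_2) == 0)
    stop("heritability_correlation: zero variance in a heritability column")
  ct <- cor.test(h2_1, h2_2, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Cross-population coefficient of variation of a two-value pair
#'
#' Sample standard deviation (n - 1 denominator, i.e. `|a - b| / sqrt(2)`)
#' over the pair mean. Scale invariant; used for per-phenotype heritability
#' variation and per-SNP MAF/LD-score variation (MAFCV, LDCV).
#'
#' @param value_1,value_2 Paired values; the pair mean must be positive.
#' @return CV value(s); `NA` with a warning where the mean is non-positive.
#' @export
pair_cv <- function(value_1, value_2) {
  m <- (value_1 + value_2) / 2
  bad <- !is.na(m) & m <= 0
  if (any(bad)) warning("pair_cv: ", sum(bad),
                        " pair(s) with non-positive mean set to NA")
  out <- (abs(value_1 - value_2) / sqrt(2)) / m
  out[bad] <- NA_real_
  out
}

#' Heritability variation vs genetic correlation
#'
#' Correlates the per-phenotype cross-population heritability CV
#' ([pair_cv()] of the two heritability estimates) with the trans-ethnic
#' genetic correlation. A negative correlation indicates that phenotypes
#' whose heritability differs more across populations also share less of
#' their per-SNP genetic effects.
#'
#' @param h2_1,h2_2,rho_g Per-phenotype values; records with missing `rho_g`
#'   or non-positive heritability pair mean are excluded with a warning.
#' @return List with `r`, `p` and `n` (records used).
#' @export
h2cv_vs_rho <- function(h2_1, h2_2, rho_g) {
  cv <- suppressWarnings(pair_cv(h2_1, h2_2))
  ok <- !is.na(cv) & !is.na(rho_g)
  if (sum(ok) < length(rho_g))
    warning("h2cv_vs_rho: excluded ", length(rho_g) - sum(ok), " record(s)")
  if (sum(ok) < 3) stop("h2cv_vs_rho: need >= 3 usable records")
  if (sd(cv[ok]) == 0)
    stop("h2cv_vs_rho: degenerate heritability CVs (all equal)")
  ct <- cor.test(cv[ok], rho_g[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
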