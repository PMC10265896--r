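#' Winner's-curse / sample-size correction settings
#'
#' @param alpha Selection significance level used in the discovery
#'   population (default genome-wide, 5e-8). The truncation point is
#'   `c = qnorm(1 - alpha/2)` (about 5.4513 at the default).
#' @param grid_points Grid resolution of the shrinkage-equation search.
#' @param ci_multiplier Half-width of the search interval in units of the
#'   pooled SE (1.96 spans the 95% confidence interval of the observed
#'   effect).
#' @return List of class `correction_config`.
#' @export
correction_config <- function(alpha = 5e-8, grid_points = 10001,
                              ci_multiplier = 1.96) {
  stopifnot(alpha > 0, alpha < 1, grid_points >= 3)
  structure(list(alpha = alpha, c = qnorm(1 - alpha / 2),
                 grid_points = grid_points, ci_multiplier = ci_multiplier),
            class = "correction_config")
}

#' Pooled standard error of an index-SNP set
#'
#' The selection-truncation model uses one SE per phenotype: the arithmetic
#' mean of the discovery SEs across all selected SNPs.
#'
#' @param se Vector of discovery-population SEs of the selected SNPs, or an
#'   `index_snps` object whose records carry an `se` column.
#' @return Scalar mean SE.
#' @export
pooled_se <- function(se) {
  if (inherits(se, "index_snps")) se <- se$snps$se
  if (!length(se)) stop("pooled_se: empty index set")
  mean(se)
}

# E[beta_hat | beta, selected]: true effect plus the truncation-induced bias
# of two-sided selection at |z| > c. Log-domain tails guard against 0/0 when
# both normal arguments are far negative.
wc_expected_obs <- function(beta, s, c) {
  x1 <- beta / s - c
  x2 <- -beta / s - c
  num <- dnorm(x1) - dnorm(x2)
  den <- pnorm(x1) + pnorm(x2)
  bias <- num / den
  deep <- pmax(x1, x2) < -30
  if (any(deep)) {
    l1 <- pnorm(x1[deep], log.p = TRUE)
    l2 <- pnorm(x2[deep], log.p = TRUE)
    lden <- pmax(l1, l2) + log1p(exp(-abs(l1 - l2)))
    ld1 <- dnorm(x1[deep], log = TRUE)
    ld2 <- dnorm(x2[deep], log = TRUE)
    hi <- pmax(ld1, ld2)
    bias[deep] <- sign(x1[deep] - x2[deep]) * # numerator sign follows |x1|<|x2|
      exp(hi - lden) * abs(expm1(-abs(ld1 - ld2)))
    bias[deep][ld1 == ld2] <- 0
  }
  beta + s * bias
}

#' Correct discovery effect estimates for winner's curse
#'
#' Effects of SNPs selected at `|z| > c` in the same data that estimated them
#' are inflated away from zero. The corrected effect is the value `b` solving
#' the conditional-mean identity
#' `beta_hat = b + s * (phi(b/s - c) - phi(-b/s - c)) / (Psi(b/s - c) + Psi(-b/s - c))`,
#' found by a dense grid search over `beta_hat +/- ci_multiplier * s`
#' (ties broken toward smaller `|b|`, the more conservative shrinkage). The
#' correction is antisymmetric in `beta_hat` and never increases the effect
#' magnitude. SNPs with `|beta_hat|/s < c` lie outside the truncation model
#' and are returned unchanged with a warning.
#'
#' @param beta_hat Observed (selected) discovery effects; vectorized.
#' @param s Pooled per-phenotype SE, from [pooled_se()].
#' @param config A [correction_config()].
#' @return Corrected effects, same length as `beta_hat`.
#' @export
winners_curse_correct <- function(beta_hat, s, config = correction_config()) {
  stopifnot(s > 0)
  below <- abs(beta_hat) / s < config$c
  if (any(below))
    warning("winners_curse_correct: ", sum(below),
            " effect(s) below the selection threshold left uncorrected")
  out <- beta_hat
  idx <- which(!below)
  for (i in idx) {
    grid <- seq(beta_hat[i] - config$ci_multiplier * s,
                beta_hat[i] + config$ci_multiplier * s,
                length.out = config$grid_points)
    d <- abs(wc_expected_obs(grid, s, config$c) - beta_hat[i])
    best <- which(d == min(d))
    if (length(best) > 1) best <- best[which.min(abs(grid[best]))]
    out[i] <- grid[best]
  }
  out
}

#' Recompute an SE from a corrected effect and the original Z score
#'
#' After shrinking the effect, the marginal Z score (and hence P value) is
#' kept unchanged, so `se = beta / z`.
#'
#' @param beta Corrected effect(s).
#' @param z Original Z score(s); must be nonzero.
#' @return Positive SE(s).
#' @export
recompute_se_from_z <- function(beta, z) {
  if (any(z == 0)) stop("recompute_se_from_z: z must be nonzero")
  beta / z
}

#' Standard error implied by sample size and allele frequency
#'
#' For a continuous phenotype, `se = sqrt(1 / (N f (1 - f)))`; for a binary
#' phenotype, `se = sqrt((N1 + N0) / (2 N1 N0 f (1 - f)))`. Used to put the
#' target population's SEs on the discovery sample-size scale, so `N`
#' (or `N1`/`N0`) is the DISCOVERY study's size.
#'
#' @param f Allele frequency in (0, 1); symmetric in `f` vs `1 - f`.
#' @param n Total sample size (continuous phenotypes).
#' @param binary Binary-phenotype flag.
#' @param n_case,n_control Case/control sizes (binary phenotypes).
#' @return SE(s), vectorized over `f`.
#' @export
standardize_se <- function(f, n = NULL, binary = FALSE,
                           n_case = NULL, n_control = NULL) {
  if (any(f <= 0 | f >= 1)) stop("standardize_se: f must be in (0, 1)")
  if (binary) {
    stopifnot(!is.null(n_case), !is.null(n_control),
              n_case > 0, n_control > 0)
    sqrt((n_case + n_control) / (2 * n_case * n_control * f * (1 - f)))
  } else {
    stopifnot(!is.null(n), n > 0)
    sqrt(1 / (n * f * (1 - f)))
  }
}

#' Standardize target-population statistics to the discovery sample size
#'
#' Replaces each target SNP's SE by the [standardize_se()] value computed at
#' the target allele frequency and the DISCOVERY sample size, keeps the
#' effect unchanged, and recomputes `z = beta / se` and the two-sided normal
#' P value. This removes the component of non-replication that is explained
#' purely by the target study being smaller.
#'
#' @param paired A `paired_sumstats` data frame (population 1 = target).
#' @param n_discovery Discovery total sample size (continuous phenotypes).
#' @param binary Binary-phenotype flag.
#' @param n_case,n_control Discovery case/control sizes (binary phenotypes).
#' @param panel Optional target [ref_panel] used to backfill missing target
#'   MAFs.
#' @return `paired` with added columns `se1_std`, `z1_std`, `p1_std`.
#' @export
rescale_target_stats <- function(paired, n_discovery = NULL, binary = FALSE,
                                 n_case = NULL, n_control = NULL,
                                 panel = NULL) {
  f <- paired$maf1
  if (is.null(f)) f <- rep(NA_real_, nrow(paired))
  if (any(is.na(f))) {
    if (is.null(panel))
      stop("rescale_target_stats: missing target allele frequencies and no panel")
    pf <- panel_maf(panel)
    f[is.na(f)] <- pf[match(paired$snp_id[is.na(f)], names(pf))]
    if (any(is.na(f)))
      stop("rescale_target_stats: allele frequency unavailable for some SNPs")
  }
  paired$se1_std <- standardize_se(f, n = n_discovery, binary = binary,
                                   n_case = n_case, n_control = n_control)
  paired$z1_std <- paired$beta1 / paired$se1_std
  paired$p1_std <- z_to_p(paired$z1_std)
  paired
}

#' Winner's-curse correct an index set and standardize the target side
#'
#' Convenience wrapper running the full per-phenotype correction stage on a
#' paired table restricted to the index SNPs: pools the discovery SEs,
#' shrinks the discovery effects ([winners_curse_correct()]), recomputes the
#' discovery SEs at unchanged Z ([recompute_se_from_z()]), and standardizes
#' the target SEs/Z/P to the discovery sample size
#' ([rescale_target_stats()]).
#'
#' @param paired_index `paired_sumstats` rows for the index SNPs.
#' @param config A [correction_config()].
#' @param binary Discovery phenotype binary flag (drives the SE formula).
#' @param panel Optional target panel for MAF backfill.
#' @return `paired_index` with added columns `beta2_corrected`,
#'   `se2_corrected`, `se1_std`, `z1_std`, `p1_std`.
#' @export
correct_index_effects <- function(paired_index, config = correction_config(),
                                  binary = FALSE, panel = NULL) {
  s <- pooled_se(paired_index$se2)
  paired_index$beta2_corrected <-
    winners_curse_correct(paired_index$beta2, s, config)
  paired_index$se2_corrected <-
    recompute_se_from_z(paired_index$beta2_corrected, paired_index$z2)
  if (binary) {
    rescale_target_stats(paired_index, binary = TRUE,
                         n_case = paired_index$n_case2[1],
                         n_control = paired_index$n_control2[1], panel = panel)
  } else {
    rescale_target_stats(paired_index, n_discovery = paired_index$n2[1],
                         panel = panel)
  }
}
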