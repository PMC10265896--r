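#' Empirical-Bayes local false discovery rate
#'
#' Efron-style two-group model with a theoretical standard-normal null:
#' `fdr(z) = pi0 * f0(z) / f(z)` where `f0 = dnorm` and the marginal density
#' `f` is estimated by Poisson-regression natural-spline smoothing of
#' histogram counts over `n_bins` equal-width bins spanning the observed z
#' range. The null proportion `pi0` is Storey's estimator at
#' `lambda = pi0_lambda` on the two-sided P values, capped at 1. Estimates
#' are clipped to `[0, 1]` and made monotone non-increasing in `|z|` on each
#' side of zero by isotonic regression (the two-sided hypothesis only orders
#' evidence by distance from the null).
#'
#' @param z Numeric vector of z-scores (at least 30; fewer returns the
#'   conservative value 1 for all, with a warning).
#' @param n_bins Histogram bins (>= 20).
#' @param spline_df Degrees of freedom of the natural spline
#'   (< `n_bins`).
#' @param pi0_lambda Storey threshold for the null-proportion estimate.
#' @param pi0 Optional fixed null proportion overriding the estimate.
#' @return Vector of local-fdr values in `[0, 1]`, aligned with `z`;
#'   `attr(, "pi0")` carries the null-proportion estimate.
#' @export
local_fdr <- function(z, n_bins = 120, spline_df = 7, pi0_lambda = 0.5,
                      pi0 = NULL) {
  stopifnot(n_bins >= 20, spline_df < n_bins)
  n <- length(z)
  if (n < 30) {
    warning("local_fdr: fewer than 30 z-scores; returning the conservative ",
            "estimate 1 for all")
    return(structure(rep(1, n), pi0 = 1))
  }
  if (diff(range(z)) == 0) {
    warning("local_fdr: degenerate input (all values identical)")
    return(structure(rep(1, n), pi0 = 1))
  }
  if (is.null(pi0)) {
    p <- z_to_p(z)
    pi0 <- min(1, mean(p > pi0_lambda) / (1 - pi0_lambda))
  }

  breaks <- seq(min(z), max(z), length.out = n_bins + 1)
  width <- breaks[2] - breaks[1]
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  counts <- tabulate(pmin(pmax(findInterval(z, breaks, all.inside = TRUE),
                               1L), n_bins), nbins = n_bins)
  basis <- splines::ns(mids, df = spline_df)
  # empty bins routinely drive fitted Poisson rates to zero; that is expected
  fit <- suppressWarnings(glm(counts ~ basis, family = poisson()))
  lp <- cbind(1, predict(basis, z)) %*% coef(fit)
  f <- pmax(exp(drop(lp)) / (n * width), 1e-300)

  fdr <- pmin(pmax(pi0 * dnorm(z) / f, 0), 1)

  # isotonic regularization: non-increasing in |z| separately per sign
  for (side in c(FALSE, TRUE)) {
    i <- which((z >= 0) == side)
    if (length(i) > 1) {
      o <- i[order(abs(z[i]))]
      fdr[o] <- -stats::isoreg(seq_along(o), -fdr[o])$yf
    }
  }
  structure(pmin(pmax(fdr, 0), 1), pi0 = pi0)
}

#' Fit the trans-ethnic false discovery rate classifier
#'
#' The transFDR of an index SNP is the posterior probability that it is null
#' for the phenotype in the target population, given that it was selected as
#' genome-wide significant in the discovery population. Conditioning on
#' discovery significance is realized by fitting the empirical-Bayes
#' two-group model ([local_fdr()]) on exactly the discovery-significant index
#' set, using the sample-size-standardized target z-scores. SNPs with
#' transFDR below `threshold` form the significant (population-common)
#' group; the rest are the non-significant (discovery-specific) group.
#'
#' Sets smaller than `min_snps` fall back to Benjamini-Hochberg adjusted
#' target P values as a conservative surrogate (with a notice), since the
#' density estimate is unstable there.
#'
#' @param z Standardized target-population z-scores of the index SNPs
#'   (`z1_std` from [rescale_target_stats()]), or a `paired_sumstats` data
#'   frame carrying that column (MHC SNPs, which violate the independence
#'   assumption, are excluded first when coordinates are present).
#' @param threshold Declaration cutoff (default 0.05).
#' @param n_bins,spline_df,pi0_lambda Passed to [local_fdr()].
#' @param min_snps Minimum set size for density estimation.
#' @param snp_id Optional SNP identifiers for the output table.
#' @return Object of class `transfdr`: list with `table` (per-SNP `snp_id`,
#'   `z`, `transfdr`, `group`), counts `k`, `f11`, `f01`, `pi0`, `threshold`
#'   and the estimation `method` (`"local_fdr"` or `"bh"`).
#' @export
transfdr <- function(z, threshold = 0.05, n_bins = 120, spline_df = 7,
                     pi0_lambda = 0.5, min_snps = 30, snp_id = NULL) {
  stopifnot(threshold > 0, threshold < 1)
  if (is.data.frame(z)) {
    df <- z
    if (all(c("chrom", "bp") %in% names(df))) df <- exclude_mhc(df)
    if (is.null(df$z1_std))
      stop("transfdr: paired input must carry standardized target z-scores ",
           "(z1_std); run rescale_target_stats() first")
    snp_id <- snp_id %||% df$snp_id
    z <- df$z1_std
  }
  if (!length(z)) stop("transfdr: empty index set")
  snp_id <- snp_id %||% paste0("snp", seq_along(z))

  if (length(z) < min_snps) {
    message("transfdr: ", length(z), " SNPs < ", min_snps,
            "; using Benjamini-Hochberg adjusted P values as a conservative ",
            "surrogate")
    fdr <- bh_adjust(z_to_p(z))
    pi0 <- 1
    method <- "bh"
  } else {
    fdr <- local_fdr(z, n_bins = n_bins, spline_df = spline_df,
                     pi0_lambda = pi0_lambda)
    pi0 <- attr(fdr, "pi0")
    method <- "local_fdr"
  }
  group <- ifelse(fdr < threshold, "significant", "non_significant")
  tab <- data.frame(snp_id = snp_id, z = z, transfdr = as.numeric(fdr),
                    group = group, stringsAsFactors = FALSE)
  structure(list(table = tab, k = nrow(tab),
                 f11 = sum(group == "significant"),
                 f01 = sum(group == "non_significant"),
                 pi0 = pi0, threshold = threshold, method = method),
            class = "transfdr")
}

#' @export
print.transfdr <- function(x, ...) {
  cat("transFDR classification (", x$method, "): k = ", x$k,
      ", significant f11 = ", x$f11, ", non-significant f01 = ", x$f01,
      " at threshold ", x$threshold, "\n", sep = "")
  cat("estimated null proportion pi0 =", round(x$pi0, 3), "\n")
  invisible(x)
}

#' @export
summary.transfdr <- function(object, ...) {
  out <- list(k = object$k, f11 = object$f11, f01 = object$f01,
              detection_proportion = object$f11 / object$k,
              pi0 = object$pi0, threshold = object$threshold,
              method = object$method,
              transfdr_quartiles = stats::quantile(object$table$transfdr))
  class(out) <- "summary.transfdr"
  out
}

#' @export
print.summary.transfdr <- function(x, ...) {
  cat("k =", x$k, " f11 =", x$f11, " f01 =", x$f01,
      sprintf(" detection = %.1f%%\n", 100 * x$detection_proportion))
  cat("pi0 =", round(x$pi0, 3), " method =", x$method, "\n")
  print(round(x$transfdr_quartiles, 4))
  invisible(x)
}

#' @export
plot.transfdr <- function(x, ...) {
  o <- order(x$table$z)
  graphics::hist(x$table$z, breaks = 40, freq = FALSE,
                 main = "target z-scores and transFDR",
                 xlab = "standardized target z", col = "grey90", ...)
  graphics::lines(x$table$z[o], x$table$transfdr[o], col = "firebrick",
                  lwd = 2)
  graphics::abline(h = x$threshold, lty = 2)
  invisible(x)
}

#' @export
fitted.transfdr <- function(object, ...) {
  stats::setNames(object$table$transfdr, object$table$snp_id)
}

#' Per-phenotype detection proportions and their summary
#'
#' @param results A list of `transfdr` objects (optionally named by
#'   phenotype), or a data frame with columns `phenotype`, `k`, `f11`.
#' @return List with `per_phenotype` (phenotype, k, f11, f01, proportion),
#'   `mean_proportion` (unweighted mean across phenotypes), `range`, and
#'   `n_above_half`/`share_above_half` (phenotypes at >= 50% detection).
#'   Phenotypes with `k = 0` are excluded with a warning.
#' @export
detection_summary <- function(results) {
  if (is.data.frame(results)) {
    tab <- data.frame(phenotype = results$phenotype, k = results$k,
                      f11 = results$f11, stringsAsFactors = FALSE)
  } else {
    tab <- data.frame(
      phenotype = names(results) %||% paste0("pheno", seq_along(results)),
      k = vapply(results, `[[`, numeric(1), "k"),
      f11 = vapply(results, `[[`, numeric(1), "f11"),
      stringsAsFactors = FALSE)
  }
  if (any(tab$k == 0)) {
    warning("detection_summary: excluded ", sum(tab$k == 0),
            " phenotype(s) with an empty index set")
    tab <- tab[tab$k > 0, , drop = FALSE]
  }
  if (!nrow(tab)) stop("detection_summary: no phenotype with index SNPs")
  tab$f01 <- tab$k - tab$f11
  tab$proportion <- tab$f11 / tab$k
  list(per_phenotype = tab,
       mean_proportion = mean(tab$proportion),
       range = range(tab$proportion),
       n_above_half = sum(tab$proportion >= 0.5),
       share_above_half = mean(tab$proportion >= 0.5))
}
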