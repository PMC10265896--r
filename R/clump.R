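#' Select index SNPs by greedy P-value clumping
#'
#' Iterates the discovery-population SNPs with `p < p_threshold` in ascending
#' P order; a SNP becomes an index SNP unless it lies within `window_kb` of
#' an already-selected index SNP on the same chromosome with squared dosage
#' correlation (panel r^2) above `r2_threshold`. Ties in P are broken toward
#' lower (chrom, bp), and the result is invariant to input row order.
#' Distance is measured index-to-candidate, and r^2 is the squared Pearson
#' correlation of unphased reference-panel dosages (the PLINK `--clump`
#' convention).
#'
#' @param records Discovery-population records (`sumstats` or the discovery
#'   side of a `paired_sumstats`) with columns `snp_id`, `chrom`, `bp`, `p`.
#' @param panel A [ref_panel] supplying genotypes for r^2; candidates absent
#'   from the panel are dropped with a warning.
#' @param p_threshold Significance level for index SNPs (default genome-wide,
#'   5e-8).
#' @param r2_threshold LD threshold above which a candidate is absorbed into
#'   an existing clump.
#' @param window_kb Physical window (kb) around an index SNP.
#' @return An object of class `index_snps`: list with `snps` (selected
#'   records plus `n_clumped`, the number of candidates each index absorbed),
#'   `k`, and the parameters used.
#' @export
clump <- function(records, panel, p_threshold = 5e-8, r2_threshold = 0.01,
                  window_kb = 1000) {
  x <- as.data.frame(records)
  stopifnot(all(c("snp_id", "chrom", "bp", "p") %in% names(x)))
  cand <- x[x$p < p_threshold, , drop = FALSE]
  params <- list(p_threshold = p_threshold, r2_threshold = r2_threshold,
                 window_kb = window_kb)
  if (!nrow(cand)) {
    warning("clump: no SNP below the significance threshold")
    return(structure(list(snps = cbind(cand, n_clumped = integer(0)),
                          k = 0L, params = params), class = "index_snps"))
  }
  in_panel <- cand$snp_id %in% panel$map$snp_id
  if (any(!in_panel)) {
    warning("clump: ", sum(!in_panel),
            " candidate SNP(s) absent from the panel were dropped")
    cand <- cand[in_panel, , drop = FALSE]
  }
  cand <- cand[order(cand$p, as.character(cand$chrom), cand$bp), , drop = FALSE]
  g <- panel$geno[, cand$snp_id, drop = FALSE]
  window <- window_kb * 1000

  sel <- integer(0)
  n_clumped <- integer(0)
  for (i in seq_len(nrow(cand))) {
    absorbed <- FALSE
    if (length(sel)) {
      near <- sel[as.character(cand$chrom[sel]) == as.character(cand$chrom[i]) &
                  abs(cand$bp[sel] - cand$bp[i]) <= window]
      for (j in near) {
        r2 <- suppressWarnings(cor(g[, i], g[, j])^2)
        if (!is.na(r2) && r2 > r2_threshold) {
          n_clumped[match(j, sel)] <- n_clumped[match(j, sel)] + 1L
          absorbed <- TRUE
          break
        }
      }
    }
    if (!absorbed) { sel <- c(sel, i); n_clumped <- c(n_clumped, 0L) }
  }
  snps <- cand[sel, , drop = FALSE]
  snps$n_clumped <- n_clumped
  rownames(snps) <- NULL
  structure(list(snps = snps, k = nrow(snps), params = params),
            class = "index_snps")
}

#' @export
print.index_snps <- function(x, ...) {
  cat("Index SNP set: k =", x$k, "at p <", format(x$params$p_threshold),
      ", r2 <=", x$params$r2_threshold, ", window", x$params$window_kb, "kb\n")
  if (x$k) print(utils::head(x$snps[c("snp_id", "chrom", "bp", "p",
                                      "n_clumped")], 10))
  invisible(x)
}
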