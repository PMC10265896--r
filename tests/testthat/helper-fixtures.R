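# In-code fixtures and independent brute-force oracles used across tests.

# small sumstats data frame with sensible defaults
make_sumstats <- function(snp_id, beta, se, chrom = "1",
                          bp = seq_along(snp_id) * 1e5,
                          effect_allele = "A", other_allele = "G",
                          freq = 0.3, n = 10000) {
  z <- beta / se
  df <- data.frame(snp_id = snp_id, chrom = chrom, bp = bp,
                   effect_allele = effect_allele, other_allele = other_allele,
                   beta = beta, se = se, z = z, p = 2 * pnorm(-abs(z)),
                   freq = freq, maf = pmin(freq, 1 - freq), n = n,
                   stringsAsFactors = FALSE)
  class(df) <- c("sumstats", "data.frame")
  df
}

# deterministic toy panel from an explicit dosage matrix
make_panel <- function(geno, chrom = "1", bp = seq_len(ncol(geno)) * 1e5,
                       ref = "G", alt = "A", population = "toy") {
  m <- ncol(geno)
  map <- data.frame(snp_id = colnames(geno) %||% paste0("rs", seq_len(m)),
                    chrom = chrom, bp = bp,
                    ref = rep_len(ref, m), alt = rep_len(alt, m),
                    stringsAsFactors = FALSE)
  colnames(geno) <- map$snp_id
  ref_panel(geno, map, population)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive-pair greedy clumping reference: full r2 matrix + double loop
bf_clump <- function(records, panel, p_threshold = 5e-8, r2_threshold = 0.01,
                     window_kb = 1000) {
  cand <- records[records$p < p_threshold, , drop = FALSE]
  cand <- cand[order(cand$p, as.character(cand$chrom), cand$bp), , drop = FALSE]
  if (!nrow(cand)) return(character(0))
  r2m <- suppressWarnings(cor(panel$geno[, cand$snp_id, drop = FALSE]))^2
  sel <- integer(0)
  for (i in seq_len(nrow(cand))) {
    free <- TRUE
    for (j in sel) {
      if (as.character(cand$chrom[j]) == as.character(cand$chrom[i]) &&
          abs(cand$bp[j] - cand$bp[i]) <= window_kb * 1000 &&
          !is.na(r2m[i, j]) && r2m[i, j] > r2_threshold) {
        free <- FALSE
        break
      }
    }
    if (free) sel <- c(sel, i)
  }
  cand$snp_id[sel]
}

# brute-force LD scores: explicit double loop over SNP pairs
bf_ld_scores <- function(panel, window_bp = 1e7, maf_min = 0.01,
                         hwe_p_min = 1e-5) {
  g <- panel$geno
  n <- nrow(g)
  map <- panel$map
  maf <- pmin(colMeans(g) / 2, 1 - colMeans(g) / 2)
  keep <- maf > maf_min & hwe_test(g) > hwe_p_min
  m <- ncol(g)
  out <- numeric(m)
  for (i in seq_len(m)) {
    s <- 1 # self term
    for (j in seq_len(m)) {
      if (j == i || !keep[j]) next
      if (map$chrom[j] != map$chrom[i]) next
      if (abs(map$bp[j] - map$bp[i]) > window_bp) next
      r2 <- suppressWarnings(cor(g[, i], g[, j])^2)
      if (is.na(r2)) r2 <- 0
      s <- s + r2 - (1 - r2) / (n - 2)
    }
    out[i] <- s
  }
  names(out) <- map$snp_id
  out
}

# literal Benjamini-Hochberg step-up from the definition
bf_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  for (i in seq_len(n)) {
    vals <- vapply(i:n, function(j) min(1, p[o[j]] * n / j), numeric(1))
    adj[o[i]] <- min(vals)
  }
  adj
}

# direct Hudson Fst formula, coded independently
bf_hudson <- function(f1, n1, f2, n2) {
  ((f1 - f2)^2 - f1 * (1 - f1) / (n1 - 1) - f2 * (1 - f2) / (n2 - 1)) /
    (f1 * (1 - f2) + f2 * (1 - f1))
}

# per-SNP rejection sampling of selected observations: each true effect keeps
# resampling its estimate until it passes two-sided selection at |z| > c
rejection_selected <- function(z_true, s, c) {
  vapply(z_true, function(zt) {
    repeat {
      zo <- zt + rnorm(1)
      if (abs(zo) > c) return(zo * s)
    }
  }, numeric(1))
}
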