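#' Generate paired two-population reference panels
#'
#' Draws ancestral allele frequencies from Uniform(0.05, 0.5), diverges them
#' into two population-specific frequencies under the Balding-Nichols model
#' with divergence parameter `fst_level` (expected Wright's Fst), and samples
#' haplotypes with block LD: the two haplotypes of an individual each share a
#' latent Gaussian factor across the SNPs of a block, producing within-block
#' dosage correlation of roughly the requested strength (liability
#' thresholding attenuates the latent correlation somewhat, so realized r^2
#' sits a little below `within_block_r2`; analyses use realized r^2
#' throughout, so only the order of magnitude matters).
#'
#' @param n1,n2 Individuals per panel (defaults mirror the 1000 Genomes
#'   EAS/EUR panel sizes, 504 and 503).
#' @param m Number of SNPs.
#' @param block_size SNPs per LD block.
#' @param within_block_r2 Target squared dosage correlation within a block,
#'   in `[0, 1)`.
#' @param fst_level Balding-Nichols divergence parameter in `[0, 1)`; 0 means
#'   both populations share the ancestral frequencies.
#' @param seed Integer seed; the output is reproducible bit-for-bit.
#' @param chrom_count SNPs are split evenly across this many chromosomes.
#' @param bp_step Base-pair spacing between adjacent SNPs.
#' @return List with elements `pop1` and `pop2`, each a [ref_panel], sharing
#'   one variant map.
#' @export
generate_panels <- function(n1 = 504, n2 = 503, m = 1000, block_size = 10,
                            within_block_r2 = 0.5, fst_level = 0.01,
                            seed = 1, chrom_count = 1, bp_step = 20000) {
  stopifnot(n1 > 0, n2 > 0, m > 0, block_size > 0,
            within_block_r2 >= 0, within_block_r2 < 1,
            fst_level >= 0, fst_level < 1)
  set.seed(as.integer(seed))
  p0 <- runif(m, 0.05, 0.5)
  div <- function(p) {
    if (fst_level == 0) return(p)
    a <- p * (1 - fst_level) / fst_level
    b <- (1 - p) * (1 - fst_level) / fst_level
    pmin(pmax(rbeta(length(p), a, b), 0.01), 0.99)
  }
  f1 <- div(p0); f2 <- div(p0)

  per_chrom <- ceiling(m / chrom_count)
  chrom <- as.character(rep(seq_len(chrom_count), each = per_chrom)[seq_len(m)])
  bp <- (ave(seq_len(m), chrom, FUN = seq_along)) * bp_step
  block <- rep(seq_len(ceiling(m / block_size)), each = block_size)[seq_len(m)]
  alleles <- matrix(c("A", "G", "C", "A", "G", "T", "T", "C"),
                    ncol = 2, byrow = TRUE)
  al <- alleles[sample.int(4, m, replace = TRUE), , drop = FALSE]
  map <- data.frame(snp_id = paste0("rs", seq_len(m)), chrom = chrom, bp = bp,
                    ref = al[, 1], alt = al[, 2], stringsAsFactors = FALSE)

  rho <- sqrt(within_block_r2)
  draw <- function(n, f, pop) {
    g <- matrix(0L, n, m)
    n_block <- max(block)
    thr <- qnorm(f)
    for (h in 1:2) {
      u <- matrix(rnorm(n * n_block), n, n_block)[, block, drop = FALSE]
      e <- matrix(rnorm(n * m), n, m)
      lat <- sqrt(rho) * u + sqrt(1 - rho) * e
      g <- g + (lat <= matrix(thr, n, m, byrow = TRUE))
    }
    storage.mode(g) <- "integer"
    rownames(g) <- sprintf("%s_ind%04d", tolower(pop), seq_len(n))
    colnames(g) <- map$snp_id
    g
  }
  list(pop1 = ref_panel(draw(n1, f1, "pop1"), map, "pop1"),
       pop2 = ref_panel(draw(n2, f2, "pop2"), map, "pop2"))
}

#' Generate paired summary statistics with known truth
#'
#' Simulates per-SNP true effects for the same phenotype in two populations
#' and the noisy GWAS estimates of them. Causal standardized effects are
#' bivariate normal with correlation `rho_g` (the trans-ethnic genetic
#' correlation) and variance `h2_k / m_causal` per population; non-causal
#' effects are zero. Standardized effects are converted to the per-allele
#' scale by dividing by `sqrt(2 f (1 - f))` with the population's own allele
#' frequency, and observed effects add sampling noise with
#' `se = 1 / sqrt(2 N f (1 - f))` (continuous phenotype, standardized scale
#' consistency: the expected association chi-square over all SNPs is
#' `1 + N h2 / m`). Binary phenotypes use the effective sample size
#' `4 n_case n_control / (n_case + n_control)`.
#'
#' @param panels Optional output of [generate_panels()]; supplies `m`, the
#'   variant map and realized panel allele frequencies. If `NULL`,
#'   frequencies are drawn as in [generate_panels()] (no LD).
#' @param m SNP count (ignored when `panels` given).
#' @param causal_frac Fraction of SNPs with nonzero effects, in `(0, 1]`.
#' @param rho_g True trans-ethnic effect correlation.
#' @param h2_1,h2_2 Per-population heritability in `[0, 1)`.
#' @param n1,n2 Per-population GWAS sample sizes (population 1 = target role,
#'   population 2 = discovery role).
#' @param binary1,binary2 Binary-phenotype flags; when `TRUE` the
#'   corresponding `n_case*`/`n_control*` must be given.
#' @param n_case1,n_control1,n_case2,n_control2 Case/control sizes.
#' @param fst_level Frequency divergence used when `panels` is `NULL`.
#' @param seed Integer seed.
#' @return List with `sumstats` (a `paired_sumstats` data frame) and `truth`
#'   (true per-allele and standardized effects, causal indicator, frequencies
#'   and the generating parameters).
#' @export
generate_paired_sumstats <- function(panels = NULL, m = 10000,
                                     causal_frac = 0.01, rho_g = 0.8,
                                     h2_1 = 0.3, h2_2 = 0.3,
                                     n1 = 1e5, n2 = 3e5,
                                     binary1 = FALSE, binary2 = FALSE,
                                     n_case1 = NULL, n_control1 = NULL,
                                     n_case2 = NULL, n_control2 = NULL,
                                     fst_level = 0.01, seed = 1) {
  stopifnot(h2_1 >= 0, h2_1 < 1, h2_2 >= 0, h2_2 < 1,
            causal_frac > 0, causal_frac <= 1, abs(rho_g) <= 1)
  set.seed(as.integer(seed))
  if (!is.null(panels)) {
    map <- panels$pop1$map
    m <- nrow(map)
    f1 <- unname(panel_freq(panels$pop1))
    f2 <- unname(panel_freq(panels$pop2))
    f1 <- pmin(pmax(f1, 0.01), 0.99)
    f2 <- pmin(pmax(f2, 0.01), 0.99)
  } else {
    p0 <- runif(m, 0.05, 0.5)
    div <- function(p) {
      if (fst_level == 0) return(p)
      pmin(pmax(rbeta(m, p * (1 - fst_level) / fst_level,
                      (1 - p) * (1 - fst_level) / fst_level), 0.01), 0.99)
    }
    f1 <- div(p0); f2 <- div(p0)
    map <- data.frame(snp_id = paste0("rs", seq_len(m)), chrom = "1",
                      bp = seq_len(m) * 20000,
                      ref = "A", alt = "G", stringsAsFactors = FALSE)
  }

  mc <- max(1L, round(m * causal_frac))
  causal <- sort(sample.int(m, mc))
  b1s <- numeric(m); b2s <- numeric(m)
  z1 <- rnorm(mc); z2 <- rnorm(mc)
  b1s[causal] <- sqrt(h2_1 / mc) * z1
  b2s[causal] <- sqrt(h2_2 / mc) * (rho_g * z1 + sqrt(1 - rho_g^2) * z2)

  eff_n <- function(n, binary, nca, nco) {
    if (binary) {
      stopifnot(!is.null(nca), !is.null(nco))
      4 * nca * nco / (nca + nco)
    } else n
  }
  ne1 <- eff_n(n1, binary1, n_case1, n_control1)
  ne2 <- eff_n(n2, binary2, n_case2, n_control2)

  beta1 <- b1s / sqrt(2 * f1 * (1 - f1))
  beta2 <- b2s / sqrt(2 * f2 * (1 - f2))
  se1 <- 1 / sqrt(2 * ne1 * f1 * (1 - f1))
  se2 <- 1 / sqrt(2 * ne2 * f2 * (1 - f2))
  bh1 <- beta1 + rnorm(m, 0, se1)
  bh2 <- beta2 + rnorm(m, 0, se2)

  out <- data.frame(snp_id = map$snp_id, chrom = map$chrom, bp = map$bp,
                    effect_allele = map$alt, other_allele = map$ref,
                    beta1 = bh1, se1 = se1, z1 = bh1 / se1,
                    p1 = z_to_p(bh1 / se1),
                    freq1 = f1, maf1 = pmin(f1, 1 - f1), n1 = n1,
                    beta2 = bh2, se2 = se2, z2 = bh2 / se2,
                    p2 = z_to_p(bh2 / se2),
                    freq2 = f2, maf2 = pmin(f2, 1 - f2), n2 = n2,
                    allele_flipped = FALSE, stringsAsFactors = FALSE)
  if (binary1) { out$n_case1 <- n_case1; out$n_control1 <- n_control1 }
  if (binary2) { out$n_case2 <- n_case2; out$n_control2 <- n_control2 }
  class(out) <- c("paired_sumstats", "data.frame")

  truth <- list(beta1 = beta1, beta2 = beta2, b_std1 = b1s, b_std2 = b2s,
                causal = causal, rho_g = rho_g, h2_1 = h2_1, h2_2 = h2_2,
                n1 = n1, n2 = n2, eff_n1 = ne1, eff_n2 = ne2,
                f1 = f1, f2 = f2, seed = seed)
  list(sumstats = out, truth = truth)
}

#' Simulate a conditioned index-SNP set for transFDR calibration
#'
#' Emulates the set handed to [transfdr()]: index SNPs already significant in
#' the discovery population, of which a fraction is truly shared with the
#' target population (target z non-central) and the rest target-null
#' (standard normal z).
#'
#' @param n_shared,n_null Counts of shared and target-null index SNPs.
#' @param ncp_mean,ncp_sd Mean/SD of the absolute non-centrality of shared
#'   SNPs' target z-scores (default 6, approximately full power at local-FDR
#'   0.05).
#' @param seed Integer seed.
#' @return Data frame with `z_target`, `p_target` and the truth flag `shared`.
#' @export
simulate_index_set <- function(n_shared, n_null, ncp_mean = 6, ncp_sd = 1,
                               seed = 1) {
  set.seed(as.integer(seed))
  ncp <- abs(rnorm(n_shared, ncp_mean, ncp_sd)) *
    sample(c(-1, 1), n_shared, replace = TRUE)
  z <- c(ncp + rnorm(n_shared), rnorm(n_null))
  data.frame(z_target = z, p_target = z_to_p(z),
             shared = rep(c(TRUE, FALSE), c(n_shared, n_null)))
}
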