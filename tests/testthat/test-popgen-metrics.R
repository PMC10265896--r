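test_that("LD scores handle isolated and duplicated SNPs", {
  set.seed(16)
  a <- sample(0:2, 100, replace = TRUE, prob = c(0.49, 0.42, 0.09))
  # two chromosomes so rs1 has no neighbor in its window
  g <- cbind(rs1 = a, rs2 = a, rs3 = sample(a))
  panel <- make_panel(g, chrom = c("1", "2", "2"), bp = c(1e6, 1e6, 2e6))
  sc <- ld_scores(panel)
  expect_equal(unname(sc["rs1"]), 1)          # only the self term
  # rs2 and its exact duplicate rs3? rs3 is a permutation, nearly independent;
  # duplicate the column instead
  g2 <- cbind(rs1 = a, rs2 = a)
  panel2 <- make_panel(g2, chrom = "1", bp = c(1e6, 1.5e6))
  sc2 <- ld_scores(panel2)
  expect_equal(unname(sc2["rs1"]), 2)         # self + perfect copy
  expect_error(ld_scores(make_panel(g2[1:2, ])), "3 individuals")
})

test_that("LD scores equal the brute-force double loop on a block panel", {
  p <- generate_panels(n1 = 80, n2 = 80, m = 200, block_size = 8,
                       within_block_r2 = 0.5, fst_level = 0.02, seed = 17,
                       bp_step = 40000)$pop1
  expect_equal(ld_scores(p), bf_ld_scores(p), tolerance = 1e-10)
  # window restriction matters and matches
  expect_equal(ld_scores(p, window_bp = 1e5),
               bf_ld_scores(p, window_bp = 1e5), tolerance = 1e-10)
  # invariant to permuting individuals
  p2 <- p
  p2$geno <- p$geno[sample(nrow(p$geno)), ]
  expect_equal(ld_scores(p2), ld_scores(p))
})

test_that("HWE filter excludes distorted flanking SNPs from LD sums", {
  set.seed(18)
  n <- 200
  hw <- c(rep(0L, 81), rep(1L, 98), rep(2L, 21))      # near HWE at f ~ 0.35
  dist <- c(rep(0L, 130), rep(2L, 70))                # no heterozygotes
  g <- cbind(rs1 = hw, rs2 = dist[sample(n)], rs3 = hw[sample(n)])
  panel <- make_panel(g, bp = c(1e6, 1.1e6, 1.2e6))
  expect_gt(hwe_test(hw), 1e-5)
  expect_lt(hwe_test(dist), 1e-5)
  sc <- ld_scores(panel)
  bf <- bf_ld_scores(panel)
  expect_equal(sc, bf, tolerance = 1e-10)
  # rs2 contributes to no other SNP's score but keeps its own self term
  g3 <- cbind(rs1 = hw, rs2 = hw)                     # perfect LD pair
  panel3 <- make_panel(g3, bp = c(1e6, 1.1e6))
  g4 <- cbind(rs1 = hw, rs2 = dist)                   # filtered partner
  panel4 <- make_panel(g4, bp = c(1e6, 1.1e6))
  expect_equal(unname(ld_scores(panel3)["rs1"]), 2)
  expect_lt(unname(ld_scores(panel4)["rs1"]), 1.5)
})

test_that("Hudson Fst matches the direct formula, symmetry, and limits", {
  # no differentiation: near zero, slightly negative from the correction
  v <- hudson_fst(0.3, 10000, 0.3, 10000)
  expect_lt(v, 0)
  expect_equal(v, 0, tolerance = 1e-3)
  # fixation
  expect_equal(hudson_fst(1, 10000, 0, 10000), 1, tolerance = 1e-3)
  # independent formula oracle
  expect_equal(hudson_fst(0.3, 1008, 0.5, 1006),
               bf_hudson(0.3, 1008, 0.5, 1006), tolerance = 1e-12)
  # symmetric in populations
  expect_equal(hudson_fst(0.3, 1008, 0.5, 1006),
               hudson_fst(0.5, 1006, 0.3, 1008))
  expect_warning(nd <- hudson_fst(0, 100, 0, 100), "undefined")
  expect_true(is.na(nd))
})

test_that("panel Fst increases with the generating divergence level", {
  mean_fst <- vapply(c(0, 0.01, 0.05, 0.1), function(fl) {
    mean(vapply(1:5, function(s) {
      p <- generate_panels(n1 = 100, n2 = 100, m = 300, block_size = 3,
                           fst_level = fl, seed = 300 + s)
      mean(panel_fst(p$pop1, p$pop2), na.rm = TRUE)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_fst) > 0))
})

test_that("group comparison runs Mann-Whitney per phenotype and a sign test across", {
  # identical groups: two-sided tie-corrected p = 1
  m <- data.frame(phenotype = "a",
                  group = rep(c("significant", "non_significant"), each = 4),
                  fst = rep(c(0.1, 0.2, 0.3, 0.4), 2))
  r <- group_compare(m, "fst")
  expect_equal(r$per_phenotype$p_mann_whitney, 1)

  # a 1-SD shift at n = 200 per group is detected essentially always
  det <- vapply(1:100, function(s) {
    set.seed(s)
    d <- data.frame(phenotype = "a",
                    group = rep(c("significant", "non_significant"),
                                each = 200),
                    fst = c(rnorm(200), rnorm(200, 1)))
    group_compare(d, "fst")$per_phenotype$p_mann_whitney < 1e-6
  }, logical(1))
  expect_gte(sum(det), 95)

  # sign test equals the exact binomial for 24/31 phenotypes in one direction
  rows <- lapply(1:31, function(i) {
    lower <- i <= 24   # deterministic group means, 24 in one direction
    base <- seq(0.1, 0.5, by = 0.1)
    data.frame(phenotype = paste0("ph", i),
               group = rep(c("significant", "non_significant"), each = 5),
               fst = c(base + ifelse(lower, 0, 1),
                       base + ifelse(lower, 1, 0)))
  })
  d <- do.call(rbind, rows)
  r2 <- group_compare(d, "fst", literal_mcnemar = TRUE)
  expect_equal(r2$sign_test$successes, 24)
  hand <- 2 * sum(dbinom(24:31, 31, 0.5))
  expect_equal(r2$sign_test$p, min(1, hand), tolerance = 1e-10)
  expect_equal(r2$mcnemar$chi2, (24 - 7)^2 / 31)

  # an empty group skips the phenotype with a warning
  d2 <- rbind(d, data.frame(phenotype = "ph32", group = "significant",
                            fst = 0.1))
  expect_warning(r3 <- group_compare(d2, "fst"), "empty group")
  expect_equal(nrow(r3$per_phenotype), 31)
})

test_that("group_metrics assembles MAF, LD and Fst columns with folding", {
  p <- generate_panels(n1 = 60, n2 = 60, m = 40, block_size = 4,
                       fst_level = 0.02, seed = 20)
  corrected <- data.frame(snp_id = p$pop1$map$snp_id,
                          maf1 = unname(panel_maf(p$pop1)),
                          maf2 = unname(panel_maf(p$pop2)),
                          stringsAsFactors = FALSE)
  gm <- group_metrics(corrected, rep(c("significant", "non_significant"), 20),
                      p$pop1, p$pop2, phenotype = "toy")
  expect_equal(names(gm), c("phenotype", "snp_id", "group", "maf_1", "maf_2",
                            "mafcv", "ld_score_1", "ld_score_2", "ldcv",
                            "fst"))
  expect_true(all(gm$mafcv >= 0, na.rm = TRUE))
  # MAFCV invariant to which allele is labeled minor
  expect_equal(pair_cv(pmin(0.3, 0.7), pmin(0.45, 0.55)),
               pair_cv(pmin(0.7, 0.3), pmin(0.55, 0.45)))
})
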