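test_that("read_sumstats parses well-formed files and drops bad rows", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("SNP CHR BP A1 A2 BETA SE P FRQ N",
               "rs1 1 1000 A G 0.10 0.01 1e-20 0.30 5000",
               "rs2 1 2000 C T -0.05 0.02 0.012 0.45 5000",
               "rs3 2 3000 G A 0.02 0.01 0.045 0.10 5000"), f)
  schema <- c(snp_id = "SNP", chrom = "CHR", bp = "BP",
              effect_allele = "A1", other_allele = "A2", beta = "BETA",
              se = "SE", p = "P", freq = "FRQ", n = "N")
  x <- read_sumstats(f, schema)
  expect_s3_class(x, "sumstats")
  expect_equal(nrow(x), 3)
  expect_equal(x$z, x$beta / x$se)
  expect_equal(x$maf, pmin(x$freq, 1 - x$freq))

  # NA standard error row is dropped and counted
  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("SNP CHR BP A1 A2 BETA SE P FRQ N",
               "rs1 1 1000 A G 0.10 0.01 1e-20 0.30 5000",
               "rs2 1 2000 C T -0.05 NA 0.012 0.45 5000",
               "rs3 2 3000 G A 0.02 0.01 0.045 0.10 5000"), f2)
  expect_message(x2 <- read_sumstats(f2, schema), "dropped 1")
  expect_equal(nrow(x2), 2)
  expect_equal(attr(x2, "n_dropped"), 1)

  # shuffled columns with remapped schema give identical records
  f3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("P SE SNP N FRQ BETA A2 A1 BP CHR",
               "1e-20 0.01 rs1 5000 0.30 0.10 G A 1000 1",
               "0.012 0.02 rs2 5000 0.45 -0.05 T C 2000 1",
               "0.045 0.01 rs3 5000 0.10 0.02 A G 3000 2"), f3)
  x3 <- read_sumstats(f3, schema)
  expect_equal(x3, x, ignore_attr = TRUE)

  # missing mandatory column is a hard error naming the column
  f4 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("SNP CHR BP A1 A2 BETA P", "rs1 1 1000 A G 0.1 0.01"), f4)
  expect_error(read_sumstats(f4, schema[names(schema) != "se"]), "se")
})

test_that("qc_filter applies the five steps in order with counts", {
  g <- matrix(c(0L, 1L, 2L, 1L, 0L, 2L, 1L, 1L, 2L, 0L, 1L, 0L), nrow = 4)
  colnames(g) <- c("rs1", "rs2", "rs3")
  panel <- make_panel(g, ref = c("G", "C", "T"), alt = c("A", "T", "C"))

  x <- make_sumstats(c("rs1", "rs1", "rs2", "rs9", "chr1:5", "rs3"),
                     beta = rep(0.1, 6), se = rep(0.02, 6),
                     effect_allele = c("A", "A", "T", "A", "A", "C"),
                     other_allele = c("G", "G", "C", "G", "G", "T"),
                     freq = c(0.3, 0.3, 0.2, 0.3, 0.3, 0.005))
  out <- suppressMessages(suppressWarnings(qc_filter(x, panel)))
  rem <- attr(out, "qc_removed")
  expect_equal(unname(rem["duplicated"]), 2)   # both rs1 copies removed
  expect_equal(unname(rem["no_rs"]), 1)        # chr1:5
  expect_equal(unname(rem["not_in_panel"]), 1) # rs9
  expect_equal(unname(rem["maf"]), 1)          # rs3 at 0.005
  expect_equal(out$snp_id, "rs2")              # swapped allele order allowed

  # allele mismatch against the panel is removed at the panel step
  y <- make_sumstats("rs2", 0.1, 0.02, effect_allele = "A",
                     other_allele = "G", freq = 0.2)
  outy <- suppressMessages(suppressWarnings(qc_filter(y, panel)))
  expect_equal(nrow(outy), 0)

  # idempotence: a second pass removes nothing
  out2 <- suppressMessages(qc_filter(out, panel))
  expect_equal(as.data.frame(out2), as.data.frame(out), ignore_attr = TRUE)
  expect_true(all(attr(out2, "qc_removed") == 0))
})

test_that("harmonize_pair aligns, flips, and drops irreconcilable alleles", {
  p1 <- make_sumstats(c("rs1", "rs2", "rs3"), beta = c(0.2, 0.1, 0.3),
                      se = rep(0.02, 3),
                      effect_allele = c("A", "A", "A"),
                      other_allele = c("G", "G", "G"),
                      freq = c(0.4, 0.3, 0.3))
  p2 <- make_sumstats(c("rs1", "rs2", "rs3"), beta = c(0.25, 0.12, 0.28),
                      se = rep(0.01, 3),
                      effect_allele = c("A", "G", "A"),
                      other_allele = c("G", "A", "C"),
                      freq = c(0.45, 0.6, 0.3))
  out <- suppressMessages(harmonize_pair(p1, p2))
  expect_equal(out$snp_id, c("rs1", "rs2"))        # rs3 irreconcilable
  expect_false(out$allele_flipped[1])
  expect_true(out$allele_flipped[2])
  expect_equal(out$beta1[2], -0.1)                 # sign negated
  expect_equal(out$freq1[2], 0.7)                  # frequency complemented
  expect_equal(out$effect_allele, c("A", "G"))

  # symmetry up to roles: same |beta| and invariant product sign
  rev <- suppressMessages(harmonize_pair(p2, p1))
  expect_equal(sort(abs(out$beta1)), sort(abs(rev$beta2)))
  expect_equal(sign(out$beta1 * out$beta2), sign(rev$beta1 * rev$beta2))
  expect_equal(out$allele_flipped, rev$allele_flipped)

  expect_error(harmonize_pair(p1[0, ], p2), "no SNPs shared")
})

test_that("palindromic SNPs are kept only at low MAF in both populations", {
  p1 <- make_sumstats(c("rs1", "rs2"), beta = c(0.1, 0.1), se = rep(0.02, 2),
                      effect_allele = "A", other_allele = "T",
                      freq = c(0.45, 0.1))
  p2 <- make_sumstats(c("rs1", "rs2"), beta = c(0.1, 0.1), se = rep(0.02, 2),
                      effect_allele = "A", other_allele = "T",
                      freq = c(0.44, 0.12))
  out <- suppressMessages(harmonize_pair(p1, p2))
  expect_equal(out$snp_id, "rs2")
  keep_all <- suppressMessages(harmonize_pair(p1, p2,
                                              palindromic_maf_max = NULL))
  expect_equal(keep_all$snp_id, c("rs1", "rs2"))
})

test_that("exclude_mhc removes chr6:28.5-33.5 Mb inclusively", {
  x <- make_sumstats(paste0("rs", 1:4), beta = rep(0.1, 4), se = rep(0.01, 4),
                     chrom = c("6", "6", "6", "7"),
                     bp = c(30e6, 28499999, 28.5e6, 30e6))
  out <- exclude_mhc(x)
  expect_equal(out$snp_id, c("rs2", "rs4"))
})
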