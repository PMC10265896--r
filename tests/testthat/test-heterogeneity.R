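test_that("disattenuated correlation equals Pearson when noise-free", {
  set.seed(12)
  b <- rnorm(50)
  expect_equal(marginal_correlation(b, rep(0, 50), b, rep(0, 50)), 1)
  b2 <- rnorm(50)
  expect_equal(marginal_correlation(b, rep(0, 50), b2, rep(0, 50)),
               cor(b, b2))
  expect_error(marginal_correlation(1:4, 1:4, 1:4, 1:4), ">= 5")
})

test_that("disattenuated correlation recovers the latent correlation", {
  set.seed(13)
  m <- 5000; rho <- 0.6; noise_sd <- 0.5
  t1 <- rnorm(m)
  t2 <- rho * t1 + sqrt(1 - rho^2) * rnorm(m)
  se1 <- rep(noise_sd, m); se2 <- rep(noise_sd, m)
  b1 <- t1 + rnorm(m, 0, noise_sd)
  b2 <- t2 + rnorm(m, 0, noise_sd)
  r_m <- marginal_correlation(b1, se1, b2, se2)
  raw <- cor(b1, b2)
  expect_equal(r_m, rho, tolerance = 0.03)
  # raw Pearson is attenuated by the noise (factor 1/(1 + noise_sd^2))
  expect_lt(raw, rho - 0.05)
  # unstable correction falls back to raw Pearson with a warning
  expect_warning(fb <- marginal_correlation(b1, rep(10, m), b2, se2),
                 "falling back")
  expect_equal(fb, raw)
})

test_that("heterogeneity test matches its algebra and symmetry", {
  expect_equal(heterogeneity_test(0.1, 0.02, 0.1, 0.03, 0.5)$p, 1)
  r <- heterogeneity_test(0.2, 0.05, 0.1, 0.04, 0)
  expect_equal(r$u, (0.2 - 0.1) / sqrt(0.05^2 + 0.04^2))
  # swapping populations flips u and preserves p
  r2 <- heterogeneity_test(0.1, 0.04, 0.2, 0.05, 0)
  expect_equal(r2$u, -r$u)
  expect_equal(r2$p, r$p)
  # extreme discordant effect pair: |u| ~ 21.7
  r3 <- heterogeneity_test(0.207, 0.040, -0.892, 0.031, 0)
  expect_equal(abs(r3$u), 21.7, tolerance = 0.01)
  expect_lt(r3$p, 1e-30)
  expect_error(heterogeneity_test(0.1, 0.02, 0.1, 0.02, 1),
               "non-positive")
})

test_that("heterogeneity test controls type I error with shared effects", {
  props <- vapply(1:50, function(s) {
    set.seed(s)
    m <- 200
    b <- rnorm(m, 0, 0.05)
    s1 <- runif(m, 0.01, 0.03); s2 <- runif(m, 0.01, 0.03)
    b1 <- b + rnorm(m, 0, s1); b2 <- b + rnorm(m, 0, s2)
    ht <- heterogeneity_test(b1, s1, b2, s2, 0)
    mean(bh_adjust(ht$p) < 0.05)
  }, numeric(1))
  expect_lte(mean(props), 0.075)
})

test_that("direction concordance classifies sign pairs", {
  d <- direction_concordance(rep(1, 10), rep(1, 10))
  expect_equal(unname(d$overall["++"]), 1)
  d2 <- direction_concordance(c(1, 1, -1, -1), c(1, -1, 1, -1))
  expect_equal(unname(d2$overall), rep(0.25, 4))
  expect_equal(d2$discordance, 0.5)
  # zero effects are excluded and counted
  d3 <- direction_concordance(c(0, 1), c(1, 1))
  expect_equal(d3$n_zero, 1)
  # independent signs: ~50% discordance
  set.seed(14)
  d4 <- direction_concordance(rnorm(10000), rnorm(10000))
  expect_equal(d4$discordance, 0.5, tolerance = 0.03)
})

test_that("group heterogeneity contrast is the Pearson chi-square", {
  even <- matrix(c(50, 50, 50, 50), 2)
  r <- group_heterogeneity_contrast(even)
  expect_equal(r$chi2, 0)
  expect_equal(r$p, 1)
  skew <- matrix(c(10, 90, 90, 10), 2)
  r2 <- group_heterogeneity_contrast(skew)
  expect_equal(r2$chi2, 128)
  expect_lt(r2$p, 1e-20)
  # chi-square scales linearly with total count
  expect_equal(group_heterogeneity_contrast(2 * skew)$chi2, 256)
  expect_error(group_heterogeneity_contrast(matrix(c(0, 0, 5, 5), 2)),
               "zero margin")
})

test_that("group-dependent sharing yields more heterogeneity in the non-significant group", {
  set.seed(15)
  n <- 300; s <- 0.02
  # significant group: correlated effects of modest spread; non-significant
  # group: independent, more dispersed effects (population-specific signals)
  rho <- 0.7; sig_sd <- 0.025
  t1 <- rnorm(n, 0, sig_sd)
  t2 <- rho * t1 + sqrt(1 - rho^2) * rnorm(n, 0, sig_sd)
  u1 <- rnorm(n, 0, 0.06); u2 <- rnorm(n, 0, 0.06)
  corrected <- data.frame(
    snp_id = paste0("rs", 1:(2 * n)),
    beta1 = c(t1, u1) + rnorm(2 * n, 0, s), se1_std = s,
    beta2_corrected = c(t2, u2) + rnorm(2 * n, 0, s), se2_corrected = s,
    stringsAsFactors = FALSE)
  groups <- rep(c("significant", "non_significant"), each = n)
  hs <- heterogeneity_summary(corrected, groups)
  prop <- tapply(hs$per_snp$heterogeneous, hs$per_snp$group, mean)
  expect_gte(prop[["non_significant"]], prop[["significant"]])
  expect_gt(hs$r_m[["significant"]], hs$r_m[["non_significant"]])
  expect_equal(sum(hs$het_counts), 2 * n)
})
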