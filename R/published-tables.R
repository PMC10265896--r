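#' Published cross-population summary tables for 31 complex phenotypes
#'
#' Two small tables bundled with the package, transcribed from a published
#' EUR/EAS transferability study of 31 complex phenotypes (6 binary, 25
#' continuous; population 1 = EAS, population 2 = EUR):
#'
#' * `published_heritability()`: per-phenotype LDSC SNP-heritability
#'   estimates with SEs in both populations, the popcorn trans-ethnic
#'   genetic correlation with SE (`NA` for TG, whose estimate fell outside
#'   `[0, 1]` and was excluded), and the printed heritability-difference P
#'   value `p_dh2`.
#' * `published_detection_counts()`: per-phenotype index-SNP count `k`,
#'   transFDR-significant count `f11`, and non-significant count `f01`.
#'
#' These serve as worked-example inputs for [h2_difference_test()],
#' [rho_tests()], [count_rho_less_than_one()], [heritability_correlation()],
#' [h2cv_vs_rho()] and [detection_summary()].
#'
#' @return A data frame.
#' @export
published_heritability <- function() {
  utils::read.table(system.file("extdata", "published_heritability.tsv",
                                package = "crosspop"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname published_heritability
#' @export
published_detection_counts <- function() {
  utils::read.table(system.file("extdata", "published_detection_counts.tsv",
                                package = "crosspop"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
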