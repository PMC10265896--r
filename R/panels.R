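#' Reference genotype panel
#'
#' Lightweight container for a small reference panel of one population:
#' a dosage matrix (individuals x SNPs, counted allele = `alt`) and a variant
#' map sorted by (chrom, bp).
#'
#' @param geno Integer/numeric matrix of dosages in \{0, 1, 2\}, individuals
#'   in rows, SNPs in columns; column names must equal `map$snp_id`.
#' @param map Data frame with columns `snp_id`, `chrom`, `bp`, `ref`, `alt`.
#' @param population Population label (e.g. `"EAS"`, `"EUR"`).
#' @return An object of class `ref_panel`.
#' @export
ref_panel <- function(geno, map, population = "pop") {
  stopifnot(is.matrix(geno), ncol(geno) == nrow(map),
            all(c("snp_id", "chrom", "bp", "ref", "alt") %in% names(map)))
  if (!all(geno %in% 0:2)) stop("ref_panel: dosages must be 0, 1 or 2")
  o <- order(map$chrom, map$bp)
  map <- map[o, , drop = FALSE]
  geno <- geno[, o, drop = FALSE]
  colnames(geno) <- map$snp_id
  rownames(map) <- NULL
  structure(list(geno = geno, map = map, population = population,
                 n_ind = nrow(geno)),
            class = "ref_panel")
}

#' @export
print.ref_panel <- function(x, ...) {
  cat("Reference panel:", x$population, "-", x$n_ind, "individuals,",
      nrow(x$map), "SNPs on", length(unique(x$map$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Alt-allele frequencies of a panel
#' @param panel A [ref_panel].
#' @param folded Return minor allele frequencies (`min(f, 1 - f)`)?
#' @return Named numeric vector keyed by `snp_id`.
#' @export
panel_freq <- function(panel, folded = FALSE) {
  f <- colMeans(panel$geno) / 2
  if (folded) f <- pmin(f, 1 - f)
  stats::setNames(f, panel$map$snp_id)
}

#' @rdname panel_freq
#' @export
panel_maf <- function(panel) panel_freq(panel, folded = TRUE)

#' Write a panel as an uncompressed VCF (biallelic sites, GT field)
#'
#' @param panel A [ref_panel].
#' @param path Output `.vcf` path.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  map <- panel$map
  g <- panel$geno
  gt <- matrix(c("0/0", "0/1", "1/1")[g + 1], nrow = nrow(g))
  body <- cbind(as.character(map$chrom), map$bp, map$snp_id, map$ref, map$alt,
                ".", "PASS", ".", "GT", t(gt))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT",
                       rownames(g) %||% paste0(tolower(panel$population),
                                               seq_len(nrow(g)))),
                     collapse = "\t")), con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a panel from VCF (requires vcfR)
#'
#' @param path A VCF file of biallelic sites with GT genotypes.
#' @param population Population label to attach.
#' @return A [ref_panel].
#' @export
read_panel_vcf <- function(path, population = "pop") {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_panel_vcf requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(0L, nrow = ncol(gt), ncol = nrow(gt))
  for (j in seq_len(nrow(gt))) {
    alleles <- strsplit(gsub("\\|", "/", gt[j, ]), "/", fixed = TRUE)
    dos[, j] <- vapply(alleles, function(a) sum(a == "1"), integer(1))
  }
  map <- data.frame(snp_id = fix[, "ID"], chrom = fix[, "CHROM"],
                    bp = as.numeric(fix[, "POS"]), ref = fix[, "REF"],
                    alt = fix[, "ALT"], stringsAsFactors = FALSE)
  colnames(dos) <- map$snp_id
  rownames(dos) <- colnames(gt)
  ref_panel(dos, map, population)
}
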