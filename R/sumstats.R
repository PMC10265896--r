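#' Read GWAS summary statistics from delimited text
#'
#' Reads a whitespace- or tab-delimited summary-statistics file (gzip
#' transparent) into the standard column layout used throughout the package.
#' Column names in the file are mapped to standard fields through `schema`.
#'
#' Standard fields: `snp_id`, `chrom`, `bp`, `effect_allele`, `other_allele`,
#' `beta`, `se`, `p`, `freq` (effect-allele frequency), `maf`, `n`, `n_case`,
#' `n_control`. Mandatory: `snp_id`, `effect_allele`, `other_allele`, `se`,
#' and at least one of `beta` or `p`. `z` is recomputed as `beta/se`; a
#' missing `p` is filled in as `2 * pnorm(-|z|)`; a missing `maf` is folded
#' from `freq` when present.
#'
#' Rows whose mandatory numeric fields do not parse are dropped; the count of
#' dropped rows is reported via `message()` and attached as
#' `attr(x, "n_dropped")`.
#'
#' @param path Path to a delimited text file with a header row (".gz" allowed).
#' @param schema Named character vector mapping standard field names to the
#'   file's column names, e.g. `c(snp_id = "SNP", beta = "BETA", ...)`.
#'   Standard-named columns present in the file are picked up automatically.
#' @param sep Field separator passed to [utils::read.table()]; the default
#'   `""` accepts any whitespace.
#' @return A `data.frame` of class `c("sumstats", "data.frame")`.
#' @export
read_sumstats <- function(path, schema = NULL, sep = "") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  fields <- c("snp_id", "chrom", "bp", "effect_allele", "other_allele",
              "beta", "se", "p", "freq", "maf", "n", "n_case", "n_control")
  map <- stats::setNames(fields, fields)
  if (!is.null(schema)) map[names(schema)] <- schema
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (f in fields) {
    if (map[[f]] %in% names(raw)) out[[f]] <- raw[[map[[f]]]]
  }
  mandatory <- c("snp_id", "effect_allele", "other_allele", "se")
  missing_cols <- setdiff(mandatory, names(out))
  if (length(missing_cols))
    stop("mandatory column(s) missing from ", path, ": ",
         paste(missing_cols, collapse = ", "))
  if (!any(c("beta", "p") %in% names(out)))
    stop("mandatory column missing from ", path, ": beta or p")
  for (f in intersect(c("bp", "beta", "se", "p", "freq", "maf",
                        "n", "n_case", "n_control"), names(out)))
    out[[f]] <- suppressWarnings(as.numeric(out[[f]]))
  need_num <- intersect(c("beta", "se", "p"), names(out))
  ok <- stats::complete.cases(out[need_num]) & out$se > 0
  n_dropped <- sum(!ok)
  if (n_dropped) message("read_sumstats: dropped ", n_dropped,
                         " row(s) with unparseable or invalid numeric fields")
  out <- out[ok, , drop = FALSE]
  out$effect_allele <- toupper(as.character(out$effect_allele))
  out$other_allele <- toupper(as.character(out$other_allele))
  if ("beta" %in% names(out)) out$z <- out$beta / out$se
  if (!"p" %in% names(out)) out$p <- z_to_p(out$z)
  if (!"maf" %in% names(out) && "freq" %in% names(out))
    out$maf <- pmin(out$freq, 1 - out$freq)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("sumstats", "data.frame")
  out
}

#' Write summary statistics as tab-delimited text
#'
#' @param x A `sumstats` or plain data frame.
#' @param path Output path.
#' @export
write_sumstats <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Quality-control filter for summary statistics
#'
#' Applies, in order: (i) remove all copies of duplicated SNP ids; (ii) remove
#' non-biallelic variants (allele strings not a single base in A/C/G/T);
#' (iii) remove records without an rs label; (iv) remove records absent from
#' the reference panel's variant map or whose allele pair does not match the
#' panel's (swapped order allowed); (v) keep MAF > `maf_min`. A missing MAF is
#' backfilled from the panel before step (v). Removal counts per step are
#' reported via `message()` and attached as `attr(x, "qc_removed")`.
#'
#' @param records A `sumstats` data frame.
#' @param panel A [ref_panel] providing the authoritative variant map.
#' @param maf_min Minimum minor allele frequency retained (exclusive bound).
#' @return Filtered `sumstats` with a named removal-count attribute.
#' @export
qc_filter <- function(records, panel, maf_min = 0.01) {
  x <- as.data.frame(records)
  counts <- c(duplicated = 0L, non_biallelic = 0L, no_rs = 0L,
              not_in_panel = 0L, maf = 0L)

  dup <- x$snp_id %in% x$snp_id[duplicated(x$snp_id)]
  counts["duplicated"] <- sum(dup)
  x <- x[!dup, , drop = FALSE]

  bases <- c("A", "C", "G", "T")
  bi <- x$effect_allele %in% bases & x$other_allele %in% bases &
    x$effect_allele != x$other_allele
  counts["non_biallelic"] <- sum(!bi)
  x <- x[bi, , drop = FALSE]

  rs <- grepl("^rs[0-9]+$", x$snp_id)
  counts["no_rs"] <- sum(!rs)
  x <- x[rs, , drop = FALSE]

  map <- panel$map
  idx <- match(x$snp_id, map$snp_id)
  same <- !is.na(idx) &
    ((x$effect_allele == map$alt[idx] & x$other_allele == map$ref[idx]) |
     (x$effect_allele == map$ref[idx] & x$other_allele == map$alt[idx]))
  counts["not_in_panel"] <- sum(!same)
  x <- x[same, , drop = FALSE]

  if (!"maf" %in% names(x)) x$maf <- NA_real_
  need <- is.na(x$maf)
  if (any(need)) {
    pf <- panel_maf(panel)
    x$maf[need] <- pf[match(x$snp_id[need], names(pf))]
  }
  keep <- !is.na(x$maf) & x$maf > maf_min
  counts["maf"] <- sum(!keep)
  x <- x[keep, , drop = FALSE]

  message("qc_filter: removed ",
          paste(names(counts), counts, sep = "=", collapse = ", "))
  if (!nrow(x)) warning("qc_filter: no records survived quality control")
  rownames(x) <- NULL
  attr(x, "qc_removed") <- counts
  class(x) <- c("sumstats", "data.frame")
  x
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
  (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Pair and allele-align two populations' summary statistics
#'
#' Intersects the two record sets on `snp_id` and aligns population 1's
#' effect allele to population 2's. Where the effect alleles disagree but the
#' allele pair matches in swapped order, population 1's beta is negated and
#' its effect-allele frequency complemented (`allele_flipped = TRUE`);
#' irreconcilable allele pairs are dropped and counted. Palindromic (A/T,
#' C/G) variants are retained only when the MAF is below
#' `palindromic_maf_max` in both populations (set to `NULL` to keep all).
#'
#' @param pop1 Target-population `sumstats` (e.g. EAS role).
#' @param pop2 Discovery-population `sumstats` (e.g. EUR role).
#' @param palindromic_maf_max Strand-ambiguity guard; default 0.4.
#' @return A `data.frame` of class `c("paired_sumstats", "data.frame")` with
#'   suffixed columns (`beta1`, `se1`, ... for the target population;
#'   `beta2`, ... for the discovery population) and an `allele_flipped` flag.
#' @export
harmonize_pair <- function(pop1, pop2, palindromic_maf_max = 0.4) {
  p1 <- as.data.frame(pop1); p2 <- as.data.frame(pop2)
  common <- intersect(p1$snp_id, p2$snp_id)
  if (!length(common)) stop("harmonize_pair: no SNPs shared between inputs")
  p1 <- p1[match(common, p1$snp_id), , drop = FALSE]
  p2 <- p2[match(common, p2$snp_id), , drop = FALSE]

  same <- p1$effect_allele == p2$effect_allele &
          p1$other_allele == p2$other_allele
  swap <- p1$effect_allele == p2$other_allele &
          p1$other_allele == p2$effect_allele
  n_irrec <- sum(!(same | swap))
  if (n_irrec) message("harmonize_pair: dropped ", n_irrec,
                       " SNP(s) with irreconcilable alleles")
  keep <- same | swap
  p1 <- p1[keep, , drop = FALSE]; p2 <- p2[keep, , drop = FALSE]
  flip <- swap[keep]

  p1$beta[flip] <- -p1$beta[flip]
  if ("z" %in% names(p1)) p1$z[flip] <- -p1$z[flip]
  if ("freq" %in% names(p1)) p1$freq[flip] <- 1 - p1$freq[flip]
  p1$effect_allele <- p2$effect_allele
  p1$other_allele <- p2$other_allele
  if ("freq" %in% names(p1)) p1$maf <- pmin(p1$freq, 1 - p1$freq)

  if (!is.null(palindromic_maf_max)) {
    pal <- is_palindromic(p2$effect_allele, p2$other_allele)
    m1 <- p1$maf %||% rep(NA_real_, nrow(p1))
    m2 <- p2$maf %||% rep(NA_real_, nrow(p2))
    bad <- pal & !(ifelse(is.na(m1), FALSE, m1 < palindromic_maf_max) &
                   ifelse(is.na(m2), FALSE, m2 < palindromic_maf_max))
    if (any(bad)) message("harmonize_pair: dropped ", sum(bad),
                          " ambiguous palindromic SNP(s)")
    p1 <- p1[!bad, , drop = FALSE]; p2 <- p2[!bad, , drop = FALSE]
    flip <- flip[!bad]
  }

  shared <- c("snp_id", "chrom", "bp", "effect_allele", "other_allele")
  out <- p2[intersect(shared, names(p2))]
  percol <- c("beta", "se", "z", "p", "freq", "maf", "n", "n_case", "n_control")
  for (f in intersect(percol, names(p1))) out[[paste0(f, "1")]] <- p1[[f]]
  for (f in intersect(percol, names(p2))) out[[paste0(f, "2")]] <- p2[[f]]
  out$allele_flipped <- flip
  rownames(out) <- NULL
  class(out) <- c("paired_sumstats", "data.frame")
  out
}

#' Exclude the MHC region
#'
#' Removes SNPs in the major histocompatibility complex,
#' chr6:28.5-33.5 Mb (inclusive bounds), whose long-range LD structure
#' distorts both LD-score and local-FDR estimation.
#'
#' @param records A `sumstats` or `paired_sumstats` data frame with `chrom`
#'   and `bp` columns.
#' @param chrom,start,end Region to exclude.
#' @return The input without MHC records.
#' @export
exclude_mhc <- function(records, chrom = "6", start = 28.5e6, end = 33.5e6) {
  inside <- as.character(records$chrom) == as.character(chrom) &
    records$bp >= start & records$bp <= end
  records[!inside, , drop = FALSE]
}
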