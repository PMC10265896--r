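#' Validate a pipeline configuration
#'
#' Checks a configuration (a nested list, or a path to a YAML file with the
#' same structure) without running anything or mutating state.
#'
#' Expected structure:
#' ```
#' seed: 1                       # mandatory, non-negative integer
#' out_dir: "results"            # mandatory
#' panels:                       # synthetic block, or vcf1 + vcf2 paths
#'   synthetic: {m: 600, n1: 300, n2: 300, block_size: 5,
#'               within_block_r2: 0.4, fst_level: 0.02}
#' phenotypes:                   # one entry per phenotype
#'   - name: trait_a
#'     synthetic: {causal_frac: 0.05, rho_g: 0.8, h2_1: 0.3, h2_2: 0.3,
#'                 n1: 20000, n2: 200000}
#'   # or: {name: ..., sumstats1: path, sumstats2: path, binary: false}
#' heritability_table: path      # optional, Table-1-style layout
#' clump: {p_threshold: 5.0e-8, r2_threshold: 0.01, window_kb: 1000}
#' transfdr: {threshold: 0.05, n_bins: 120, spline_df: 7}
#' ```
#'
#' @param config List or YAML path.
#' @return Character vector of problems (empty when valid).
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  problems <- character(0)
  add <- function(msg) problems <<- c(problems, msg)
  if (is.null(config$seed)) add("missing field: seed")
  else if (!is.numeric(config$seed) || config$seed < 0 ||
           config$seed != round(config$seed))
    add("seed must be a non-negative integer")
  if (is.null(config$out_dir)) add("missing field: out_dir")
  ph <- config$phenotypes
  if (is.null(ph) || !length(ph)) add("missing field: phenotypes (need >= 1)")
  else for (i in seq_along(ph)) {
    p <- ph[[i]]
    if (is.null(p$name)) add(sprintf("phenotypes[%d]: missing name", i))
    if (is.null(p$synthetic)) {
      for (f in c("sumstats1", "sumstats2")) {
        if (is.null(p[[f]]))
          add(sprintf("phenotypes[%d]: missing %s (or a synthetic block)",
                      i, f))
        else if (!file.exists(p[[f]]))
          add(sprintf("phenotypes[%d]: %s does not exist: %s", i, f, p[[f]]))
      }
    }
  }
  pn <- config$panels
  if (is.null(pn)) add("missing field: panels")
  else if (is.null(pn$synthetic)) {
    for (f in c("vcf1", "vcf2")) {
      if (is.null(pn[[f]]))
        add(sprintf("panels: missing %s (or a synthetic block)", f))
      else if (!file.exists(pn[[f]]))
        add(sprintf("panels: %s does not exist: %s", f, pn[[f]]))
    }
  }
  ht <- config$heritability_table
  if (!is.null(ht) && !file.exists(ht))
    add(paste("heritability_table does not exist:", ht))
  problems
}

#' Run the full trans-ethnic transferability pipeline
#'
#' Sequences the analysis stages in order: panel acquisition, per-phenotype
#' pairing and QC, MHC exclusion, discovery clumping, winner's-curse
#' correction, target SE standardization, transFDR classification,
#' group-wise heterogeneity, and the MAFCV/LDCV/Fst group comparisons; plus
#' the phenotype-level heritability/correlation tests when a heritability
#' table is supplied. All randomness flows from `config$seed` through
#' per-stage substreams, so a rerun with the same configuration reproduces
#' every output file exactly.
#'
#' Writes to `config$out_dir`: `detection_table.tsv` (per-phenotype k, f11,
#' f01, proportion), `transfdr_snps.tsv` (per-SNP classification),
#' `heterogeneity_groups.tsv` (per-group r_m, heterogeneity and discordance
#' proportions), `group_metrics.tsv` (per-SNP MAFCV/LDCV/Fst with groups),
#' `metric_comparisons.tsv` (per-metric group tests),
#' `phenotype_tests.tsv` (when a heritability table is given), and
#' `manifest.json` (full parameter set; sufficient to re-run). A stage
#' failure aborts with the stage name and leaves a `FAILED` marker file.
#'
#' @param config List or YAML path (see [validate_config()]).
#' @return Invisible list of the in-memory result objects.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  problems <- validate_config(config)
  if (length(problems))
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  seed <- as.integer(config$seed)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(out_dir, "FAILED")
  if (file.exists(marker)) file.remove(marker)
  stage <- "setup"
  on.exit({
    if (!is.null(stage)) {
      writeLines(paste("pipeline failed at stage:", stage), marker)
    }
  })

  cl <- utils::modifyList(list(p_threshold = 5e-8, r2_threshold = 0.01,
                               window_kb = 1000), config$clump %||% list())
  tf <- utils::modifyList(list(threshold = 0.05, n_bins = 120, spline_df = 7),
                          config$transfdr %||% list())

  stage <- "panels"
  pn <- config$panels
  if (!is.null(pn$synthetic)) {
    args <- utils::modifyList(list(seed = stage_seed(seed, "panels")),
                              pn$synthetic)
    panels <- do.call(generate_panels, args)
  } else {
    panels <- list(pop1 = read_panel_vcf(pn$vcf1, "pop1"),
                   pop2 = read_panel_vcf(pn$vcf2, "pop2"))
  }
  ld1 <- ld_scores(panels$pop1)
  ld2 <- ld_scores(panels$pop2)

  fits <- list(); metrics_all <- NULL; het_rows <- NULL; snp_rows <- NULL
  for (p in config$phenotypes) {
    stage <- paste0("phenotype:", p$name)
    if (!is.null(p$synthetic)) {
      args <- utils::modifyList(
        list(panels = panels,
             seed = stage_seed(seed, paste0("sumstats:", p$name))),
        p$synthetic)
      paired <- do.call(generate_paired_sumstats, args)$sumstats
    } else {
      s1 <- qc_filter(read_sumstats(p$sumstats1, p$schema1), panels$pop1)
      s2 <- qc_filter(read_sumstats(p$sumstats2, p$schema2), panels$pop2)
      paired <- harmonize_pair(s1, s2)
    }
    paired <- exclude_mhc(paired)

    idx <- clump(data.frame(snp_id = paired$snp_id, chrom = paired$chrom,
                            bp = paired$bp, p = paired$p2,
                            stringsAsFactors = FALSE),
                 panels$pop2, p_threshold = cl$p_threshold,
                 r2_threshold = cl$r2_threshold, window_kb = cl$window_kb)
    if (idx$k == 0) {
      warning("phenotype '", p$name, "': no index SNPs; skipped")
      next
    }
    sel <- paired[match(idx$snps$snp_id, paired$snp_id), , drop = FALSE]
    corrected <- correct_index_effects(sel, binary = isTRUE(p$binary),
                                       panel = panels$pop1)
    fit <- transfdr(corrected, threshold = tf$threshold, n_bins = tf$n_bins,
                    spline_df = tf$spline_df)
    fits[[p$name]] <- fit
    snp_rows <- rbind(snp_rows, cbind(phenotype = p$name, fit$table))

    het <- heterogeneity_summary(corrected, fit$table$group)
    for (g in names(het$r_m)) {
      i <- het$per_snp$group == g
      het_rows <- rbind(het_rows, data.frame(
        phenotype = p$name, group = g, n = sum(i), r_m = het$r_m[[g]],
        het_proportion = mean(het$per_snp$heterogeneous[i]),
        discordance = unname(het$direction$per_group[[g]]["discordance"]),
        stringsAsFactors = FALSE))
    }
    metrics_all <- rbind(metrics_all,
                         group_metrics(corrected, fit$table$group,
                                       panels$pop1, panels$pop2,
                                       phenotype = p$name,
                                       ld1 = ld1, ld2 = ld2))
  }
  if (!length(fits)) stop("pipeline: no phenotype produced index SNPs")

  stage <- "summaries"
  det <- detection_summary(fits)
  wt <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(det$per_phenotype, "detection_table.tsv")
  wt(snp_rows, "transfdr_snps.tsv")
  wt(het_rows, "heterogeneity_groups.tsv")
  wt(metrics_all, "group_metrics.tsv")

  comps <- NULL
  for (mname in intersect(c("mafcv", "ldcv", "fst"), names(metrics_all))) {
    gc_ <- tryCatch(group_compare(metrics_all, mname),
                    error = function(e) NULL)
    if (!is.null(gc_))
      comps <- rbind(comps, data.frame(
        metric = mname,
        mean_sig = gc_$group_means$mean[1], sd_sig = gc_$group_means$sd[1],
        mean_non = gc_$group_means$mean[2], sd_non = gc_$group_means$sd[2],
        sign_test_successes = gc_$sign_test$successes,
        sign_test_n = gc_$sign_test$n, sign_test_p = gc_$sign_test$p,
        stringsAsFactors = FALSE))
  }
  if (!is.null(comps)) wt(comps, "metric_comparisons.tsv")

  pheno_tests <- NULL
  if (!is.null(config$heritability_table)) {
    stage <- "heritability_tests"
    ht <- utils::read.table(config$heritability_table, header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
    dh <- h2_difference_test(ht$h2_1, ht$se_1, ht$h2_2, ht$se_2, ht$rho_g)
    rt <- rho_tests(ht$rho_g, ht$se_rho)
    pheno_tests <- data.frame(phenotype = ht$phenotype,
                              u_dh2 = dh$u, p_dh2 = dh$p,
                              fdr_dh2 = bh_adjust(dh$p),
                              u_rho0 = rt$u0, p_rho0 = rt$p0,
                              u_rho1 = rt$u1, p_rho1 = rt$p1,
                              stringsAsFactors = FALSE)
    wt(pheno_tests, "phenotype_tests.tsv")
  }

  stage <- "manifest"
  manifest <- list(package = "crosspop",
                   version = as.character(utils::packageVersion("crosspop")),
                   seed = seed, clump = cl, transfdr = tf, config = config)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  stage <- NULL
  invisible(list(fits = fits, detection = det, heterogeneity = het_rows,
                 metrics = metrics_all, comparisons = comps,
                 phenotype_tests = pheno_tests, out_dir = out_dir))
}
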