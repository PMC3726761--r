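# Full-pipeline orchestration: differential expression -> signature
# shifts -> strain-SNP region scan -> positional enrichment ->
# methylation comparison, from one declarative config, with a
# consolidated JSON report.  The report is byte-identical across reruns
# with the same config and seed (no timestamps inside it).

#' Run the complete passenger-region audit
#'
#' The config is a named list (or path to a JSON file).  Either
#' `simulate` names a scenario ("GC", "activated", "naive", "null") and
#' data are generated with `seed` (field overrides under
#' `sim_overrides`), or the `inputs` section gives file paths: `counts`,
#' `groups`, `annotation` (BED written by [write_annotation_bed()]),
#' `calls` (VCF), `panel` (VCF with strain labels), `sets` (directory
#' of gene-set files), and optionally `methyl_a`/`methyl_b` (profile
#' TSVs).  Tunables: `fdr_cutoff` (default 0.01), `top_n` (default
#' 100), `window_size` (50000), `threshold` (5), `merge_gap` (2),
#' `min_span` (3), `strain` (default "CBA"), `family_prefix`
#' (default "Ighv").
#'
#' Any stage failure aborts with the failing stage named.  Enrichment
#' is marked skipped when no region is called.
#'
#' @param config Named list or JSON path.
#' @param out_dir Optional directory for stage outputs and the report
#'   (`report.json`, plus per-stage TSV/BED files).
#' @return The report, an `audit_report` list with sections de,
#'   signatures, family, regions, enrichment, methylation, provenance.
#' @export
run_audit <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  cfg <- utils::modifyList(list(fdr_cutoff = 0.01, top_n = 100,
                                window_size = 50000, threshold = 5,
                                merge_gap = 2, min_span = 3,
                                strain = "CBA", family_prefix = "Ighv",
                                seed = 1), config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("audit stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  meth_a <- NULL; meth_b <- NULL; sets <- NULL
  if (!is.null(cfg$simulate)) {
    sim_args <- c(list(scenario = cfg$simulate, seed = cfg$seed),
                  cfg$sim_overrides)
    scfg <- stage("simulate", do.call(scenario_config, sim_args))
    sim <- stage("simulate", simulate_dataset(scfg))
    ann <- sim$annotation
    cm <- sim$counts
    calls <- sim$variants; calls$strain <- "unknown"
    panel <- sim$variants
    sets <- sim$truth$sets
    meth_a <- sim$methylation$a; meth_b <- sim$methylation$b
  } else {
    inp <- cfg$inputs
    miss <- setdiff(c("counts", "groups", "annotation", "calls",
                      "panel"), names(inp))
    if (length(miss) > 0)
      stop("audit config missing input path(s): ",
           paste(miss, collapse = ", "))
    for (f in unlist(inp[c("counts", "groups", "annotation", "calls",
                           "panel")]))
      if (!file.exists(f)) stop("input file not found: ", f)
    ann <- stage("load", read_annotation_bed(inp$annotation))
    cm <- stage("load", read_counts_tsv(inp$counts, inp$groups))
    calls <- stage("load", read_vcf(inp$calls))
    panel <- stage("load", read_vcf(inp$panel))
    if (!is.null(inp$sets)) {
      files <- list.files(inp$sets, full.names = TRUE)
      sets <- lapply(files, read_gene_set)
    }
    if (!is.null(inp$methyl_a)) {
      meth_a <- stage("load", read_methyl_tsv(inp$methyl_a))
      meth_b <- stage("load", read_methyl_tsv(inp$methyl_b))
    }
  }

  de <- stage("de", run_de(cm, fdr_cutoff = cfg$fdr_cutoff,
                           annotation = ann))

  sig <- if (!is.null(sets))
    stage("signatures", score_signatures(de$table, sets)) else NULL
  fam <- tryCatch(gene_family_shift(de$table, cfg$family_prefix),
                  error = function(e) NULL)

  labelled <- stage("scan", label_strain(calls, panel))
  sc <- scan_config(cfg$window_size, cfg$threshold, cfg$merge_gap,
                    cfg$min_span)
  dens <- stage("scan", window_density(labelled, chrom_sizes(ann), sc,
                                       strain = cfg$strain))
  regions <- stage("scan", call_regions(dens, sc, variants = labelled))

  enr <- if (nrow(regions) > 0) {
    top_region <- regions[which.max(regions$n_variants), ]
    stage("enrich", region_enrichment_test(de$table, top_region, ann,
                                           n = min(cfg$top_n,
                                                   nrow(de$table))))
  } else NULL

  meth <- if (!is.null(meth_a))
    stage("methyl", compare_methylation(meth_a, meth_b)) else NULL

  report <- list(
    de = list(n_genes = nrow(de$table),
              n_significant = length(de$significant),
              fdr_cutoff = cfg$fdr_cutoff,
              dispersion = de$dispersion$phi,
              size_factors = as.list(round(de$size_factors, 6))),
    signatures = if (is.null(sig)) "skipped" else sig,
    family = if (is.null(fam)) "skipped" else fam,
    regions = if (nrow(regions) == 0) "none called" else regions,
    enrichment = if (is.null(enr)) "skipped" else
      list(table = as.vector(t(enr$table)), chisq = enr$chisq,
           p_chisq = enr$p_chisq, p_fisher = enr$p_fisher,
           odds_ratio = enr$odds_ratio),
    methylation = if (is.null(meth)) "skipped" else
      list(per_class = meth$per_class, pearson_r = meth$pearson_r),
    provenance = list(seed = cfg$seed,
                      config = cfg[setdiff(names(cfg), "inputs")],
                      package_version =
                        as.character(utils::packageVersion("passengerScan"))))
  class(report) <- "audit_report"

  if (!is.null(out_dir)) {
    write_de_tsv(de, file.path(out_dir, "de.tsv"))
    writeLines(de$significant, file.path(out_dir, "significant.txt"))
    write_density_bedgraph(dens, file.path(out_dir, "windows.bedgraph"))
    if (nrow(regions) > 0)
      write_regions_bed(regions, file.path(out_dir, "regions.bed"))
    if (!is.null(sig))
      data.table::fwrite(sig, file.path(out_dir, "signatures.tsv"),
                         sep = "\t")
    jsonlite::write_json(unclass(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows", na = "null")
    writeLines(format_report(report), file.path(out_dir, "report.txt"))
  }
  report
}

format_report <- function(report) {
  lines <- c("passenger-region audit",
             sprintf("DE: %d of %d genes significant at FDR < %g (phi = %.4f)",
                     report$de$n_significant, report$de$n_genes,
                     report$de$fdr_cutoff, report$de$dispersion))
  if (is.data.frame(report$signatures)) {
    s <- report$signatures
    lines <- c(lines, "signature shifts:",
               sprintf("  %s: median log2FC %+.3f, sign-test p %.3g",
                       s$label, s$median_log2FC, s$p_sign))
  }
  if (is.data.frame(report$regions)) {
    r <- report$regions
    lines <- c(lines,
               sprintf("region: %s:%d-%d (%d windows, %d variants, strain %s)",
                       r$chrom, r$start, r$end, r$n_windows,
                       r$n_variants, r$strain))
  } else lines <- c(lines, "regions: none called")
  if (is.list(report$enrichment) && !is.character(report$enrichment)) {
    e <- report$enrichment
    lines <- c(lines,
               sprintf("enrichment: chi-square %.1f (p = %.3g), Fisher p = %.3g, OR = %.1f",
                       e$chisq, e$p_chisq, e$p_fisher, e$odds_ratio))
  }
  if (is.list(report$methylation) && !is.character(report$methylation)) {
    m <- report$methylation
    lines <- c(lines,
               sprintf("methylation: per-TSS Pearson r = %.4f",
                       m$pearson_r),
               sprintf("  %s: p = %.3g", m$per_class$class,
                       m$per_class$p))
  }
  lines
}

#' @export
print.audit_report <- function(x, ...) {
  cat(paste(format_report(x), collapse = "\n"), "\n")
  invisible(x)
}

#' Box plot of signature log2 fold-change distributions
#'
#' @param de_table DE data.frame.
#' @param sets List of `gene_set` objects.
#' @export
plot_signature_shifts <- function(de_table, sets) {
  vals <- lapply(sets, function(s)
    de_table$log2FC[match(intersect(s$members, de_table$gene),
                          de_table$gene)])
  names(vals) <- vapply(sets, `[[`, "", "label")
  graphics::boxplot(vals, ylab = "log2 fold change")
  graphics::abline(h = 0, lty = 2)
  invisible(NULL)
}
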