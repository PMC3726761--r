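# Synthetic-data generator.
#
# Emulates the statistical structure the audit pipeline assumes: a
# multi-chromosome genome with non-overlapping genes, negative-binomial
# RNA-Seq counts with a common dispersion, a cis-deregulated passenger
# region on one chromosome carrying clustered strain-informative SNPs
# (a symmetric mixture of up and down effects), directional fold-change
# offsets in designated signature gene sets plus an Ighv-like gene
# family, and a null (or optionally perturbed) methylation landscape
# across element classes.  Every stochastic choice is recorded in a
# ground-truth object so downstream stages are testable by parameter
# recovery.
#
# One global seed drives independent sub-streams per data type
# (annotation, sets, counts, variants, methylation) so regenerating one
# data type does not perturb the others.

#' Simulation configuration
#'
#' Defaults describe a desk-scale genome that preserves the relative
#' scales of the real design: 12,000 expressed genes on five 100-Mb
#' chromosomes, a 20-Mb donor-strain passenger region on chr2 holding
#' 200 cis-deregulated genes, strain-informative SNP rates of 10 per
#' 50 kb inside the region versus 0.2 per 50 kb outside, and
#' negative-binomial counts with common dispersion 0.1.
#'
#' @param n_genes Number of genes.
#' @param n_chromosomes Number of chromosomes (`chr1`, `chr2`, ...).
#' @param chrom_length Length of each chromosome in bp.
#' @param n_per_group Samples per group: 2 for the pooled-library
#'   design, 4 for the individually indexed design.
#' @param group_labels Two group labels, reference first.
#' @param mu_meanlog,mu_sdlog Log-normal parameters of per-gene baseline
#'   mean expression (defaults give a median of ~100 counts, emulating
#'   a count matrix already filtered to expressed genes).
#' @param dispersion Common NB dispersion phi (>= 0; 0 = Poisson).
#' @param libsize_range Per-sample library-size factors are drawn
#'   log-uniformly from this range, so normalization matters.
#' @param region Passenger region as `list(chrom=, start=, end=)`
#'   (0-based half-open, window-aligned by default).
#' @param n_cis_deregulated Number of in-region genes given a nonzero
#'   cis log2 effect.
#' @param cis_effect_range Magnitudes of cis log2 effects are drawn
#'   uniformly from this range, signs +/- with probability 1/2 each
#'   (region genes are up- as well as downregulated).
#' @param signature_shift Named numeric vector of log2-fold-change
#'   offsets delta per signature set label.
#' @param family_shift Log2 offset applied to the Ighv-like gene family.
#' @param set_size Genes per signature set.
#' @param family_size Genes in the Ighv-like family.
#' @param snp_background_rate,snp_region_rate Expected strain-informative
#'   variants per 50 kb outside / inside the region.
#' @param strain Donor strain label attached to simulated variants.
#' @param methyl_class_means Mean load (reads per element, at 1 kb
#'   reference length) per element class; TSS elements are drawn from a
#'   bimodal high/low mixture around this value (see vignette).
#' @param methyl_sdlog Between-element log-normal spread of latent mean
#'   loads (shared between groups).
#' @param methyl_dispersion NB dispersion of element loads around their
#'   latent means.
#' @param tss_halfwidth TSS window half-width (bp).
#' @param seed Global random seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 12000,
                       n_chromosomes = 5,
                       chrom_length = 1e8,
                       n_per_group = 2,
                       group_labels = c("WT", "KO"),
                       mu_meanlog = log(100),
                       mu_sdlog = 1.2,
                       dispersion = 0.1,
                       libsize_range = c(0.7, 1.4),
                       region = list(chrom = "chr2", start = 4e7,
                                     end = 6e7),
                       n_cis_deregulated = 200,
                       cis_effect_range = c(1, 3),
                       signature_shift = c(CON = 0, LZS = 0, DZS = 0,
                                           NVS = 0, CBS = 0),
                       family_shift = 0,
                       set_size = 100,
                       family_size = 30,
                       snp_background_rate = 0.2,
                       snp_region_rate = 10,
                       strain = "CBA",
                       methyl_class_means = c(TSS = 100, EXN = 50,
                                              INT = 30, ING = 10),
                       methyl_sdlog = 1.0,
                       methyl_dispersion = 0.002,
                       tss_halfwidth = 1000,
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$dispersion >= 0, cfg$n_genes >= 0,
            cfg$region$start < cfg$region$end,
            cfg$region$end <= cfg$chrom_length,
            cfg$snp_region_rate > cfg$snp_background_rate,
            length(cfg$group_labels) == 2)
  class(cfg) <- "sim_config"
  cfg
}

#' Scenario presets
#'
#' `GC` mirrors the germinal-center comparison (pooled 2-vs-2 design;
#' light-zone signature up, dark-zone signature down, Ighv family up).
#' `activated` and `naive` mirror the individually indexed 4-vs-4
#' designs with the dark-zone signature elevated (and, for `activated`,
#' the Ighv family depressed).  `null` has no cis-deregulation, no
#' signature shifts and only background SNPs.
#'
#' @param scenario One of "GC", "activated", "naive", "null".
#' @param seed Global seed.
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
scenario_config <- function(scenario = c("GC", "activated", "naive",
                                         "null"), seed = 1, ...) {
  scenario <- match.arg(scenario)
  base <- switch(scenario,
    GC = list(n_per_group = 2,
              signature_shift = c(CON = 0, LZS = 0.5, DZS = -0.5,
                                  NVS = 0, CBS = 0),
              family_shift = 1),
    activated = list(n_per_group = 4,
                     signature_shift = c(CON = 0, LZS = -0.5, DZS = 0.5,
                                         NVS = 0, CBS = 0),
                     family_shift = -1),
    naive = list(n_per_group = 4,
                 signature_shift = c(CON = 0, LZS = 0, DZS = 0.5,
                                     NVS = 0, CBS = 0),
                 family_shift = 0),
    null = list(n_per_group = 4,
                signature_shift = c(CON = 0, LZS = 0, DZS = 0, NVS = 0,
                                    CBS = 0),
                family_shift = 0, n_cis_deregulated = 0,
                snp_region_rate = 0.2000001))
  args <- utils::modifyList(c(base, seed = seed), list(...))
  cfg <- do.call(sim_config, args)
  cfg$scenario <- scenario
  cfg
}

# independent deterministic sub-streams per data type
sub_seed <- function(cfg, stream) {
  offs <- c(annotation = 1, sets = 2, counts = 3, variants = 4,
            methylation = 5)
  (as.integer(cfg$seed) * 101L + offs[[stream]]) %% 2147483647L
}

#' Simulate a gene annotation
#'
#' Genes (log-normal lengths, median ~10 kb, 2-8 exons) are placed
#' uniformly at random without overlap along the chromosomes, separated
#' by at least twice the TSS half-width so TSS windows stay disjoint.
#'
#' @param config A `sim_config`.
#' @return A `gene_annotation`.
#' @export
simulate_annotation <- function(config) {
  set.seed(sub_seed(config, "annotation"))
  sizes <- stats::setNames(rep(config$chrom_length, config$n_chromosomes),
                           paste0("chr", seq_len(config$n_chromosomes)))
  n <- config$n_genes
  if (n == 0)
    return(gene_annotation(character(0), character(0), numeric(0),
                           numeric(0), character(0), sizes,
                           exons = data.frame(gene = character(0),
                                              start = numeric(0),
                                              end = numeric(0))))
  chrom <- sort(sample(names(sizes), n, replace = TRUE))
  lens <- pmin(round(stats::rlnorm(n, log(1e4), 0.5)), 1e5)
  min_gap <- 2 * config$tss_halfwidth + 1
  starts <- numeric(n)
  for (cc in unique(chrom)) {
    i <- which(chrom == cc)
    free <- sizes[[cc]] - sum(lens[i]) - (length(i) + 1) * min_gap
    if (free < 0)
      stop("cannot pack ", length(i), " genes into ", cc)
    gaps <- diff(c(0, sort(stats::runif(length(i))))) * free
    starts[i] <- min_gap + cumsum(gaps + c(0, lens[i][-length(i)] +
                                           min_gap))
  }
  starts <- floor(starts)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  genes <- sprintf("g%05d", seq_len(n))
  # the Ighv-like family: off-region genes whose ids carry the prefix,
  # so prefix-based family scoring works on simulated data
  off <- which(!(chrom == config$region$chrom &
                   starts < config$region$end &
                   starts + lens > config$region$start))
  fam <- sort(sample(off, min(config$family_size, length(off))))
  genes[fam] <- sprintf("Ighv%03d", seq_along(fam))

  # exon structure: 2-8 exons via sorted internal cutpoints
  n_ex <- sample(2:8, n, replace = TRUE)
  ex <- lapply(seq_len(n), function(i) {
    k <- n_ex[i]
    cuts <- sort(sample(seq_len(lens[i] - 1), 2 * (k - 1)))
    bounds <- c(0, cuts, lens[i])
    s <- bounds[seq(1, length(bounds) - 1, by = 2)]
    e <- bounds[seq(2, length(bounds), by = 2)]
    data.frame(gene = genes[i], start = starts[i] + s,
               end = starts[i] + e)
  })
  gene_annotation(genes, chrom, starts, starts + lens, strand, sizes,
                  exons = do.call(rbind, ex))
}

# assign signature sets, the Ighv-like family and cis-deregulated genes
assign_truth <- function(config, annotation) {
  set.seed(sub_seed(config, "sets"))
  ann <- annotation
  in_region <- ann$chrom == config$region$chrom &
    ann$start < config$region$end & ann$end > config$region$start
  region_genes <- ann$gene[in_region]
  if (config$n_cis_deregulated > length(region_genes))
    stop("passenger region holds only ", length(region_genes),
         " genes; cannot deregulate ", config$n_cis_deregulated)
  cis <- sort(sample(region_genes, config$n_cis_deregulated))
  sgn <- sample(c(-1, 1), length(cis), replace = TRUE)
  mag <- stats::runif(length(cis), config$cis_effect_range[1],
                      config$cis_effect_range[2])

  family <- ann$gene[startsWith(ann$gene, "Ighv")]
  pool <- setdiff(ann$gene[!in_region], c(cis, family))
  labels <- names(config$signature_shift)
  need <- length(labels) * config$set_size
  if (need > length(pool))
    stop("not enough off-region genes for signature sets")
  picked <- sample(pool, need)
  sets <- list()
  for (i in seq_along(labels)) {
    idx <- ((i - 1) * config$set_size + 1):(i * config$set_size)
    sets[[labels[i]]] <- gene_set(labels[i], picked[idx])
  }

  beta <- stats::setNames(rep(0, nrow(ann)), ann$gene)
  beta[cis] <- sgn * mag
  for (lb in labels)
    beta[sets[[lb]]$members] <- beta[sets[[lb]]$members] +
      config$signature_shift[[lb]]
  beta[family] <- beta[family] + config$family_shift

  list(beta = beta, cis_genes = cis, sets = sets, family = family,
       region = config$region)
}

#' Simulate a count matrix with ground truth
#'
#' Counts are drawn `NB(mean = s_j * mu_g * 2^(x_j * beta_g),
#' dispersion phi)` where `s_j` is a per-sample library-size factor,
#' `x_j` the group indicator and `beta_g` the signed log2 effect:
#' nonzero for the configured cis-deregulated genes inside the
#' passenger region and offset by the configured delta for signature
#' set members (and the Ighv-like family).
#'
#' @param config A `sim_config`.
#' @param annotation A `gene_annotation` (from [simulate_annotation()]
#'   or user-supplied) whose genes receive the effects.
#' @return list(counts = `count_matrix`, truth = ground-truth list with
#'   elements beta, cis_genes, sets, family, region, dispersion,
#'   size_factors, mu).
#' @export
simulate_counts <- function(config, annotation) {
  truth <- assign_truth(config, annotation)
  set.seed(sub_seed(config, "counts"))
  n <- nrow(annotation)
  mu <- stats::rlnorm(n, config$mu_meanlog, config$mu_sdlog)
  names(mu) <- annotation$gene
  n_s <- 2 * config$n_per_group
  s <- exp(stats::runif(n_s, log(config$libsize_range[1]),
                        log(config$libsize_range[2])))
  x <- rep(c(0, 1), each = config$n_per_group)
  samples <- paste0(rep(config$group_labels, each = config$n_per_group),
                    "_", rep(seq_len(config$n_per_group), 2))
  mean_mat <- outer(mu, s) * 2^(outer(truth$beta, x))
  counts <- matrix(0, n, n_s, dimnames = list(annotation$gene, samples))
  if (n > 0) {
    if (config$dispersion == 0) {
      counts[] <- stats::rpois(n * n_s, mean_mat)
    } else {
      counts[] <- stats::rnbinom(n * n_s, size = 1 / config$dispersion,
                                 mu = mean_mat)
    }
  }
  groups <- stats::setNames(rep(config$group_labels,
                                each = config$n_per_group), samples)
  truth$dispersion <- config$dispersion
  truth$size_factors <- stats::setNames(s, samples)
  truth$mu <- mu
  list(counts = count_matrix(counts, groups), truth = truth)
}

#' Simulate strain-informative variants
#'
#' Variants fall as a Poisson process with rate `snp_background_rate`
#' per 50 kb genome-wide plus an extra `snp_region_rate -
#' snp_background_rate` per 50 kb inside the passenger region, so the
#' in-region rate equals `snp_region_rate`.  Each variant carries the
#' donor strain label; the coding flag marks variants falling in exons.
#'
#' @param config A `sim_config`.
#' @param annotation A `gene_annotation` (supplies chromosome sizes and
#'   exons for the coding flag).
#' @return A `variant_table`.
#' @export
simulate_variants <- function(config, annotation) {
  set.seed(sub_seed(config, "variants"))
  sizes <- chrom_sizes(annotation)
  chroms <- character(0); pos <- numeric(0)
  for (cc in names(sizes)) {
    k <- stats::rpois(1, config$snp_background_rate * sizes[[cc]] / 5e4)
    if (k > 0) {
      chroms <- c(chroms, rep(cc, k))
      pos <- c(pos, ceiling(stats::runif(k) * sizes[[cc]]))
    }
  }
  span <- config$region$end - config$region$start
  extra_rate <- config$snp_region_rate - config$snp_background_rate
  k <- stats::rpois(1, extra_rate * span / 5e4)
  if (k > 0) {
    chroms <- c(chroms, rep(config$region$chrom, k))
    pos <- c(pos, config$region$start +
               ceiling(stats::runif(k) * span))
  }
  nv <- length(pos)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nv, replace = TRUE)
  alt <- bases[(match(ref, bases) + sample(1:3, nv, replace = TRUE) - 1)
               %% 4 + 1]
  vt <- variant_table(chroms, pos, ref, alt,
                      strain = rep(config$strain, nv))
  intersect_variants_coding(vt, annotation, keep_all = TRUE)
}

#' Simulate methylation profiles for two groups
#'
#' Per element instance, a latent mean load is drawn once (log-normal
#' spread around the class mean, scaled by element length relative to
#' 1 kb; TSS elements use a bimodal high/low mixture emulating
#' methylated versus unmethylated promoters) and shared between the two
#' groups; each group's observed load is an NB draw around that latent
#' mean.  With no injection the two profiles are exchangeable draws
#' from one distribution — the null the capture assay comparison is
#' expected to reproduce.
#'
#' @param config A `sim_config`.
#' @param annotation A `gene_annotation`.
#' @param inject_demethylation Optional named numeric, e.g.
#'   `c(EXN = 0.5)`: group-B latent means for that class are multiplied
#'   by the factor.
#' @param max_elements Cap on elements per class (uniform subsample)
#'   to keep desk-scale runs fast; NULL = no cap.
#' @return list(a = `methyl_profile`, b = `methyl_profile`).
#' @export
simulate_methylation <- function(config, annotation,
                                 inject_demethylation = NULL,
                                 max_elements = 3000) {
  set.seed(sub_seed(config, "methylation"))
  el <- derive_elements(annotation, config$tss_halfwidth)
  df <- data.frame(element_id = S4Vectors::mcols(el)$element_id,
                   class = S4Vectors::mcols(el)$class,
                   chrom = as.character(GenomicRanges::seqnames(el)),
                   start = GenomicRanges::start(el) - 1,
                   end = GenomicRanges::end(el),
                   stringsAsFactors = FALSE)
  if (!is.null(max_elements)) {
    keep <- unlist(lapply(split(seq_len(nrow(df)), df$class), function(i)
      if (length(i) > max_elements) sort(sample(i, max_elements)) else i))
    df <- df[sort(keep), , drop = FALSE]
  }
  base <- config$methyl_class_means[df$class]
  # promoter bimodality: half the TSS windows sit at unmethylated CpG
  # islands with ~5% of the methylated load
  is_tss <- df$class == "TSS"
  low <- is_tss & stats::runif(nrow(df)) < 0.5
  base[is_tss] <- base[is_tss] * 2          # methylated-promoter mode
  base[low] <- base[low] * 0.025            # unmethylated mode
  latent <- base * (df$end - df$start) / 1000 *
    stats::rlnorm(nrow(df), 0, config$methyl_sdlog)
  mean_b <- latent
  if (!is.null(inject_demethylation)) {
    for (cls in names(inject_demethylation))
      mean_b[df$class == cls] <- mean_b[df$class == cls] *
        inject_demethylation[[cls]]
  }
  draw <- function(m) {
    if (config$methyl_dispersion == 0) stats::rpois(length(m), m)
    else stats::rnbinom(length(m), size = 1 / config$methyl_dispersion,
                        mu = m)
  }
  list(a = methyl_profile(df$element_id, df$class, df$chrom, df$start,
                          df$end, draw(latent)),
       b = methyl_profile(df$element_id, df$class, df$chrom, df$start,
                          df$end, draw(mean_b)))
}

#' Run a full simulation and optionally write all files
#'
#' Generates annotation, counts, variants and methylation for one
#' scenario and, when `out_dir` is given, writes every format the
#' pipeline reads: counts TSV + groups, annotation BED (+ exons +
#' chrom.sizes), calls VCF (strain labels stripped, as a variant
#' caller would emit), panel VCF (with strain labels, standing in for
#' the reference strain panel), methylation profile TSVs, gene-set
#' files, and a ground-truth JSON.
#'
#' @param config A `sim_config` (see [scenario_config()]).
#' @param out_dir Optional output directory (created if needed).
#' @return list(annotation, counts, truth, variants, methylation).
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  ann <- simulate_annotation(config)
  sim <- simulate_counts(config, ann)
  vt <- simulate_variants(config, ann)
  meth <- simulate_methylation(config, ann)
  out <- list(annotation = ann, counts = sim$counts, truth = sim$truth,
              variants = vt, methylation = meth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_counts_tsv(sim$counts, file.path(out_dir, "counts.tsv"))
    write_groups_tsv(sim$counts$groups, file.path(out_dir, "groups.tsv"))
    write_annotation_bed(ann, file.path(out_dir, "annotation.bed"))
    calls <- vt; calls$strain <- "unknown"
    write_vcf(calls, file.path(out_dir, "calls.vcf"))
    write_vcf(vt, file.path(out_dir, "panel.vcf"))
    write_methyl_tsv(meth$a, file.path(out_dir, "methyl_a.tsv"))
    write_methyl_tsv(meth$b, file.path(out_dir, "methyl_b.tsv"))
    sets_dir <- file.path(out_dir, "sets")
    dir.create(sets_dir, showWarnings = FALSE)
    for (s in sim$truth$sets) write_gene_set(s, sets_dir)
    truth <- sim$truth
    jsonlite::write_json(
      list(beta = as.list(truth$beta[truth$beta != 0]),
           cis_genes = truth$cis_genes,
           region = truth$region,
           family = truth$family,
           dispersion = truth$dispersion,
           size_factors = as.list(truth$size_factors)),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}
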