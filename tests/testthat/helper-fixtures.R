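# Shared fixture builders.  Everything is generated in code; the large
# scenario datasets used by several acceptance criteria are memoized so
# each is simulated once per test run.

make_cm <- function(m, groups = NULL) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  if (is.null(groups)) {
    half <- ncol(m) / 2
    groups <- stats::setNames(rep(c("WT", "KO"), each = half),
                              colnames(m))
  }
  count_matrix(m, groups)
}

toy_annotation <- function() {
  # 2 chromosomes of 100 kb; 3 genes with explicit exon structure
  gene_annotation(
    genes = c("gA", "gB", "gC"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(10000, 50000, 20000),
    end = c(20000, 62000, 30000),
    strand = c("+", "-", "+"),
    chrom_sizes = c(chr1 = 100000, chr2 = 100000),
    exons = data.frame(
      gene = c("gA", "gA", "gB", "gC", "gC", "gC"),
      start = c(10000, 15000, 50000, 20000, 24000, 28000),
      end = c(12000, 20000, 62000, 22000, 26000, 30000)))
}

mini_cfg <- function(scenario = "GC", seed = 1, ...) {
  args <- list(scenario = scenario, seed = seed, n_genes = 1200,
               n_chromosomes = 2, chrom_length = 4e7,
               region = list(chrom = "chr2", start = 1e7, end = 2e7),
               set_size = 50, family_size = 15)
  if (scenario != "null") args$n_cis_deregulated <- 50
  do.call(scenario_config, utils::modifyList(args, list(...)))
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# the GC scenario at the scale several acceptance criteria share
gc_world <- function() cached("gc", {
  sim <- simulate_dataset(scenario_config("GC", seed = 101))
  sim$de <- run_de(sim$counts, annotation = sim$annotation)
  sim
})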