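test_that("coding intersection honors the half-open convention", {
  ann <- toy_annotation()
  # exon gA:[10000,12000): 1-based positions 10001..12000 are coding
  vt <- variant_table(rep("chr1", 4), c(10001, 12000, 12001, 10000),
                      rep("A", 4), rep("T", 4))
  out <- intersect_variants_coding(vt, ann)
  expect_setequal(out$pos, c(10001, 12000))
  all_flagged <- intersect_variants_coding(vt, ann, keep_all = TRUE)
  expect_equal(nrow(all_flagged), 4)
  expect_identical(all_flagged$coding, oracle_coding(all_flagged, ann))

  set.seed(51)
  rnd <- variant_table(sample(c("chr1", "chr2"), 300, TRUE),
                       sample.int(100000, 300, TRUE),
                       rep("G", 300), rep("C", 300))
  got <- intersect_variants_coding(rnd, ann, keep_all = TRUE)
  expect_identical(got$coding, oracle_coding(got, ann))
})

test_that("label_strain matches on the full quadruple", {
  panel <- variant_table(c("chr1", "chr1"), c(100, 200), c("A", "C"),
                         c("T", "G"), strain = c("CBA", "B6"))
  v <- variant_table(c("chr1", "chr1", "chr1"), c(100, 200, 300),
                     c("A", "C", "A"), c("T", "T", "G"))
  out <- label_strain(v, panel)
  expect_equal(out$strain[out$pos == 100], "CBA")   # exact match
  expect_equal(out$strain[out$pos == 200], "unknown")  # alt mismatch
  expect_equal(out$strain[out$pos == 300], "unknown")  # absent
  empty <- variant_table(character(0), numeric(0), character(0),
                         character(0), strain = character(0))
  expect_true(all(label_strain(v, empty)$strain == "unknown"))
})

test_that("window_density implements the boundary arithmetic and conserves counts", {
  sizes <- c(chr1 = 120000)
  cfg <- scan_config(window_size = 50000)
  vt <- variant_table(rep("chr1", 3), c(10, 50000, 50001),
                      rep("A", 3), rep("T", 3))
  d <- window_density(vt, sizes, cfg)
  expect_equal(d$count, c(2, 1, 0))
  expect_equal(d$start, c(0, 50000, 100000))
  expect_equal(d$end, c(50000, 100000, 120000))  # last window truncated

  none <- window_density(variant_table(character(0), numeric(0),
                                       character(0), character(0)),
                         sizes, cfg)
  expect_true(all(none$count == 0))

  set.seed(52)
  vt2 <- variant_table(rep("chr1", 500),
                       sample.int(120000, 500, TRUE),
                       rep("A", 500), rep("T", 500),
                       strain = sample(c("CBA", "unknown"), 500, TRUE))
  d2 <- window_density(vt2, sizes, cfg, strain = "CBA")
  expect_equal(sum(d2$count), sum(vt2$strain == "CBA"))

  past <- variant_table("chr1", 130000, "A", "T")
  expect_warning(d3 <- window_density(past, sizes, cfg), "beyond")
  expect_equal(d3$count, c(0, 0, 1))
})

test_that("call_regions merges across small gaps and enforces min span", {
  mkdens <- function(counts) {
    n <- length(counts)
    data.frame(chrom = "chr1", start = (0:(n - 1)) * 5e4,
               end = (1:n) * 5e4, count = counts)
  }
  cfg <- scan_config(threshold = 5, merge_gap = 2, min_span = 3)

  expect_equal(nrow(call_regions(mkdens(rep(0, 20)), cfg)), 0)

  # 10 hot windows interrupted by 1 cold one -> a single 11-window region
  counts <- c(0, rep(9, 5), 1, rep(9, 5), 0)
  r <- call_regions(mkdens(counts), cfg)
  expect_equal(nrow(r), 1)
  expect_equal(r$n_windows, 11)
  expect_equal(r$start, 5e4)
  expect_equal(r$end, 12 * 5e4)
  expect_equal(r$n_hot, 10)
  expect_gte(r$mean_hot_density, cfg$threshold)

  # a gap of 3 cold windows splits; short fragments are dropped
  counts2 <- c(rep(9, 4), 0, 0, 0, rep(9, 2))
  r2 <- call_regions(mkdens(counts2), cfg)
  expect_equal(nrow(r2), 1)
  expect_equal(r2$n_windows, 4)

  # agreement with the connected-components oracle on random densities
  set.seed(53)
  for (i in 1:60) {
    counts <- rpois(sample(10:200, 1), lambda = sample(c(1, 3, 5), 1))
    got <- call_regions(mkdens(counts), cfg)
    want <- oracle_call_regions(counts, cfg$threshold, cfg$merge_gap,
                                cfg$min_span)
    expect_equal(nrow(got), nrow(want), info = paste("case", i))
    if (nrow(want) > 0) {
      expect_equal(got$start / 5e4 + 1, unname(want[, 1]))
      expect_equal(got$end / 5e4, unname(want[, 2]))
    }
  }
})

test_that("raising the threshold never increases total hot windows", {
  set.seed(54)
  counts <- rpois(300, 4)
  d <- data.frame(chrom = "chr1", start = (0:299) * 5e4,
                  end = (1:300) * 5e4, count = counts)
  prev <- Inf
  for (th in 1:8) {
    cfg <- scan_config(threshold = th, merge_gap = 1, min_span = 1)
    r <- call_regions(d, cfg)
    hot <- if (nrow(r) == 0) 0 else sum(r$n_hot)
    expect_lte(hot, prev)
    prev <- hot
  }
})

test_that("the simulated passenger region is recovered within one window", {
  w <- gc_world()
  dens <- window_density(w$variants, chrom_sizes(w$annotation),
                         scan_config(), strain = "CBA")
  reg <- call_regions(dens, scan_config(), variants = w$variants)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$chrom, w$truth$region$chrom)
  expect_lte(abs(reg$start - w$truth$region$start), 5e4)
  expect_lte(abs(reg$end - w$truth$region$end), 5e4)
  expect_equal(reg$strain, "CBA")
  # conservation within the scanned strain
  expect_equal(sum(dens$count), sum(w$variants$strain == "CBA"))
})
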