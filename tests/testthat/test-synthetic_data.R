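test_that("simulate_annotation packs genes without overlap, deterministically", {
  cfg <- mini_cfg(seed = 5)
  ann <- simulate_annotation(cfg)
  expect_equal(nrow(ann), cfg$n_genes)
  for (cc in unique(ann$chrom)) {
    a <- ann[ann$chrom == cc, ]
    a <- a[order(a$start), ]
    expect_true(all(a$start[-1] >= a$end[-nrow(a)]))
    expect_true(all(a$end <= chrom_sizes(ann)[[cc]]))
  }
  # exons tile within gene bounds
  ex <- attr(ann, "exons")
  i <- match(ex$gene, ann$gene)
  expect_true(all(ex$start >= ann$start[i] & ex$end <= ann$end[i]))

  expect_identical(simulate_annotation(cfg), ann)

  cfg0 <- mini_cfg(seed = 5, n_genes = 0, n_cis_deregulated = 0)
  expect_equal(nrow(simulate_annotation(cfg0)), 0)

  too_many <- mini_cfg(seed = 5, n_genes = 20000, chrom_length = 1e6,
                       region = list(chrom = "chr2", start = 1e5,
                                     end = 5e5),
                       n_cis_deregulated = 10)
  expect_error(simulate_annotation(too_many), "pack")
})

test_that("simulated counts carry the configured effects and NB structure", {
  cfg <- mini_cfg(seed = 7, libsize_range = c(1, 1), n_per_group = 4)
  ann <- simulate_annotation(cfg)
  sim <- simulate_counts(cfg, ann)
  truth <- sim$truth

  # bookkeeping: exactly n_cis genes with cis effects, all inside region
  expect_length(truth$cis_genes, cfg$n_cis_deregulated)
  i <- match(truth$cis_genes, ann$gene)
  expect_true(all(ann$chrom[i] == cfg$region$chrom &
                    ann$start[i] < cfg$region$end &
                    ann$end[i] > cfg$region$start))
  expect_true(all(truth$beta[truth$cis_genes] != 0))
  # signs are a mixture of up and down
  expect_true(any(truth$beta[truth$cis_genes] > 0) &&
                any(truth$beta[truth$cis_genes] < 0))

  # variance/mean relationship ~ 1 + phi * mean among null WT samples
  m <- sim$counts$counts[truth$beta == 0,
                         sim$counts$groups == "WT", drop = FALSE]
  mu <- rowMeans(m)
  v <- apply(m, 1, stats::var)
  keep <- mu > 50
  slope <- stats::coef(stats::lm(I(v[keep] - mu[keep]) ~ 0 +
                                   I(mu[keep]^2)))
  expect_gt(slope, cfg$dispersion * 0.6)
  expect_lt(slope, cfg$dispersion * 1.6)

  # genome-wide mean of non-DE genes equal between groups (MC error)
  ko <- rowMeans(sim$counts$counts[truth$beta == 0,
                                   sim$counts$groups == "KO"])
  expect_lt(abs(log2(mean(ko) / mean(mu[names(ko)]))), 0.1)
})

test_that("Poisson limit and signature offsets are recovered", {
  cfg <- mini_cfg("null", seed = 3, dispersion = 0,
                  libsize_range = c(1, 1))
  ann <- simulate_annotation(cfg)
  sim <- simulate_counts(cfg, ann)
  m <- sim$counts$counts
  mu <- rowMeans(m); v <- apply(m, 1, stats::var)
  keep <- mu > 20
  # Poisson: variance ~ mean
  expect_lt(abs(median(v[keep] / mu[keep]) - 1), 0.15)

  # delta = 1 on LZS: observed mean log2FC of members ~ 1
  cfg2 <- mini_cfg(seed = 9, n_per_group = 4,
                   signature_shift = c(CON = 0, LZS = 1, DZS = 0,
                                       NVS = 0, CBS = 0),
                   libsize_range = c(1, 1))
  sim2 <- simulate_counts(cfg2, simulate_annotation(cfg2))
  cts <- sim2$counts$counts
  lzs <- sim2$truth$sets$LZS$members
  lfc <- log2((rowMeans(cts[lzs, sim2$counts$groups == "KO"]) + 0.5) /
                (rowMeans(cts[lzs, sim2$counts$groups == "WT"]) + 0.5))
  expect_lt(abs(mean(lfc) - 1), 0.15)
})

test_that("simulated variants follow the configured Poisson rates", {
  cfg <- mini_cfg(seed = 13)
  ann <- simulate_annotation(cfg)
  vt <- simulate_variants(cfg, ann)
  expect_identical(simulate_variants(cfg, ann), vt)

  inr <- vt$chrom == cfg$region$chrom &
    vt$pos > cfg$region$start & vt$pos <= cfg$region$end
  span <- cfg$region$end - cfg$region$start
  expected_in <- cfg$snp_region_rate * span / 5e4       # 10 * 1e7/5e4 = 2000
  expect_lt(abs(sum(inr) - expected_in), 4 * sqrt(expected_in))
  genome <- sum(chrom_sizes(ann))
  expected_bg <- cfg$snp_background_rate * (genome - span) / 5e4
  expect_lt(abs(sum(!inr) - expected_bg), 4 * sqrt(expected_bg))
  expect_true(all(vt$strain == cfg$strain))
  # coding flag matches brute force on a subsample
  sub <- vt[sample(nrow(vt), 200), ]
  expect_identical(sub$coding, oracle_coding(sub, ann))

  # degenerate rates: everything lands in the region
  cfg2 <- mini_cfg(seed = 13, snp_background_rate = 0,
                   snp_region_rate = 10)
  vt2 <- simulate_variants(cfg2, simulate_annotation(cfg2))
  expect_true(all(vt2$chrom == cfg2$region$chrom &
                    vt2$pos > cfg2$region$start &
                    vt2$pos <= cfg2$region$end))
})

test_that("methylation profiles share latent structure; injection scales means", {
  cfg <- mini_cfg(seed = 21)
  ann <- simulate_annotation(cfg)
  null <- simulate_methylation(cfg, ann)
  expect_identical(null$a$element_id, null$b$element_id)
  # exchangeable null: per-class means agree within noise
  for (cl in c("TSS", "EXN", "INT", "ING")) {
    ra <- mean(null$a$load[null$a$class == cl])
    rb <- mean(null$b$load[null$b$class == cl])
    expect_lt(abs(log2(ra / rb)), 0.4)
  }
  inj <- simulate_methylation(cfg, ann,
                              inject_demethylation = c(EXN = 0.5))
  ratio <- mean(inj$b$load[inj$b$class == "EXN"]) /
    mean(inj$a$load[inj$a$class == "EXN"])
  expect_lt(abs(log2(ratio / 0.5)), 0.4)
  # factor 1 injection is indistinguishable from none (same stream)
  id1 <- simulate_methylation(cfg, ann,
                              inject_demethylation = c(EXN = 1))
  expect_identical(id1$b$load, null$b$load)
})

test_that("a fixed seed fixes every emitted file byte-for-byte", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- mini_cfg(seed = 33, n_genes = 300, n_cis_deregulated = 20,
                  set_size = 30, family_size = 5)
  simulate_dataset(cfg, out_dir = d1)
  simulate_dataset(cfg, out_dir = d2)
  files <- list.files(d1, recursive = TRUE)
  expect_true(length(files) >= 8)
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
})
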