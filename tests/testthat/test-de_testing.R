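test_that("size factors match the median-of-ratios definition", {
  m <- matrix(c(10, 20, 30, 10, 20, 30), 3, 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  expect_equal(unname(estimate_size_factors(m)), c(1, 1))

  m2 <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
  rownames(m2) <- c("a", "b", "c")
  expect_equal(unname(estimate_size_factors(m2)),
               c(1 / sqrt(2), sqrt(2)))

  set.seed(42)
  m3 <- matrix(rpois(15, 50) + 1, 5, 3,
               dimnames = list(letters[1:5], c("x", "y", "z")))
  expect_equal(unname(estimate_size_factors(m3)),
               unname(oracle_size_factors(m3)))

  m3[, 2] <- 0
  expect_error(estimate_size_factors(m3), "all-zero")
})

test_that("common dispersion is recovered from simulated truth", {
  # Poisson counts: estimate near zero
  cfg0 <- mini_cfg("null", seed = 4, n_genes = 2000, dispersion = 0)
  sim0 <- simulate_counts(cfg0, simulate_annotation(cfg0))
  expect_lt(estimate_common_dispersion(sim0$counts)$phi, 0.02)

  # NB phi = 0.1, 2000 genes, 4 vs 4: within 20%
  cfg1 <- mini_cfg("null", seed = 6, n_genes = 2000, dispersion = 0.1)
  sim1 <- simulate_counts(cfg1, simulate_annotation(cfg1))
  phi <- estimate_common_dispersion(sim1$counts)$phi
  expect_gt(phi, 0.08); expect_lt(phi, 0.12)

  # constant counts within groups -> zero residual variance -> phi 0
  m <- matrix(c(5, 5, 5, 9, 9, 9), 1, 6,
              dimnames = list("g1", paste0("s", 1:6)))
  cm <- count_matrix(m, stats::setNames(rep(c("WT", "KO"), each = 3),
                                        paste0("s", 1:6)))
  expect_equal(estimate_common_dispersion(
    cm, factors = stats::setNames(rep(1, 6), paste0("s", 1:6)))$phi, 0)

  # no replication anywhere -> error
  m1 <- matrix(c(5, 9), 1, 2, dimnames = list("g1", c("a", "b")))
  cm1 <- count_matrix(m1, c(a = "WT", b = "KO"))
  expect_error(estimate_common_dispersion(
    cm1, factors = c(a = 1, b = 1)), "replication")
})

test_that("nb_exact_test equals its closed forms and the enumeration oracle", {
  # modal outcome, equal everything -> p = 1
  expect_equal(nb_exact_test(5, 5, phi = 0), 1)
  expect_equal(nb_exact_test(c(3, 2), c(2, 3), phi = 0.2), 1)

  # binomial limit: phi = 0, totals (8, 2), equal sizes
  expect_equal(nb_exact_test(8, 2, phi = 0), 112 / 1024)

  # enumeration oracle across dispersions, totals and group sizes
  for (phi in c(0, 0.1, 0.5)) {
    for (t in c(1, 7, 18, 30)) {
      for (pa in unique(c(0, 3, t %/% 2, t))) {
        if (pa > t) next
        expect_equal(nb_exact_test(pa, t - pa, phi = phi),
                     oracle_nb_exact(pa, t - pa, 1, 1, phi),
                     tolerance = 1e-10,
                     info = sprintf("phi=%g t=%d pa=%d", phi, t, pa))
        expect_equal(nb_exact_test(c(pa, 0), c(t - pa, 0), phi = phi),
                     oracle_nb_exact(pa, t - pa, 2, 2, phi),
                     tolerance = 1e-10)
      }
    }
  }
  expect_error(nb_exact_test(-1, 3), "negative")
})

test_that("nb_exact_test agrees with edgeR's small-p exact test", {
  # equal library sizes, common dispersion: the collapse is exact and
  # the two small-p conditionals should coincide
  set.seed(8)
  y1 <- matrix(rnbinom(200, size = 10, mu = 40), 100, 2)
  y2 <- matrix(rnbinom(200, size = 10, mu = 40), 100, 2)
  ours <- vapply(seq_len(100), function(i)
    nb_exact_test(y1[i, ], y2[i, ], phi = 0.1), 0)
  theirs <- edgeR::exactTestBySmallP(y1, y2, dispersion = 0.1)
  expect_equal(ours, as.vector(theirs), tolerance = 1e-8)
})

test_that("bh_adjust implements the step-up rule", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # permutation equivariance + agreement with stats::p.adjust
  set.seed(1)
  p <- runif(200)^2
  o <- sample(200)
  expect_equal(bh_adjust(p)[o], bh_adjust(p[o]))
  expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"))
})

test_that("run_de: null behavior, power, and group-swap symmetry", {
  cfg <- mini_cfg("null", seed = 14, n_genes = 3000)
  sim <- simulate_counts(cfg, simulate_annotation(cfg))
  de <- run_de(sim$counts)
  expect_lt(mean(de$table$FDR < 0.01), 0.01)
  se <- sqrt(0.05 * 0.95 / nrow(de$table))
  expect_lt(mean(de$table$pvalue < 0.05), 0.05 + 3 * se)

  # power: 200 true DE genes at |beta| = 2, phi = 0.1, 4 vs 4
  cfg2 <- mini_cfg(seed = 15, n_genes = 3000, n_per_group = 4,
                   n_cis_deregulated = 120,
                   cis_effect_range = c(2, 2))
  sim2 <- simulate_counts(cfg2, simulate_annotation(cfg2))
  de2 <- run_de(sim2$counts, fdr_cutoff = 0.01)
  recall <- mean(sim2$truth$cis_genes %in% de2$significant)
  expect_gt(recall, 0.8)

  # swapping the group roles (KO as reference) negates log2FC, keeps
  # p-values; reordering columns makes KO the first-seen level
  cm <- sim2$counts
  swapped <- count_matrix(
    cm$counts[, order(cm$groups, decreasing = TRUE)], cm$groups)
  de_s <- run_de(swapped, phi = de2$dispersion$phi)
  de_f <- run_de(cm, phi = de2$dispersion$phi)
  i <- match(de_f$table$gene, de_s$table$gene)
  expect_equal(de_s$table$log2FC[i], -de_f$table$log2FC)
  expect_equal(de_s$table$pvalue[i], de_f$table$pvalue)
})

test_that("scaling one sample moves only the (rescaled) size factors", {
  set.seed(20)
  m <- matrix(rnbinom(400 * 4, size = 10, mu = 100), 400, 4,
              dimnames = list(sprintf("g%03d", 1:400),
                              c("w1", "w2", "k1", "k2")))
  cm <- make_cm(m)
  m2 <- m; m2[, "k1"] <- m2[, "k1"] * 3L
  cm2 <- make_cm(m2)
  f1 <- estimate_size_factors(cm)
  f2 <- estimate_size_factors(cm2)
  # all factors shift by the global geometric-mean rescale 3^(1/4);
  # relative factors of untouched samples are unchanged
  rel <- (f2 / f1)[c("w1", "w2", "k2")]
  expect_equal(unname(rel / rel[1]), rep(1, 3), tolerance = 1e-6)
  expect_equal(unname((f2 / f1)[["k1"]] / rel[[1]]), 3, tolerance = 1e-6)
  # normalized pseudo-counts are invariant up to that one global scale
  p1 <- colSums(t(m) / f1); p2 <- colSums(t(m2) / f2)
  expect_equal(unname(p2 / p1), rep(3^(1 / 4), 400), tolerance = 1e-6)
  # significance calls are stable
  d1 <- run_de(cm, phi = 0.1)
  d2 <- run_de(cm2, phi = 0.1)
  agree <- mean((d1$table$pvalue < 0.01) ==
                  (d2$table$pvalue[match(d1$table$gene,
                                         d2$table$gene)] < 0.01))
  expect_gt(agree, 0.97)
})
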