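# Two-group differential expression on counts: median-of-ratios
# normalization, pooled method-of-moments common-dispersion estimation,
# an exact negative-binomial test conditioning on the two-group total,
# and Benjamini-Hochberg FDR control.

#' Median-of-ratios library size factors
#'
#' Per-sample factors are the median across genes of the ratio of the
#' sample's count to the per-gene geometric mean (genes with any zero
#' are excluded from the reference), rescaled so the factors have
#' geometric mean 1.
#'
#' @param cm A `count_matrix` (or a bare counts matrix).
#' @return Named positive numeric vector, one factor per sample.
#' @export
estimate_size_factors <- function(cm) {
  m <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  if (any(colSums(m) == 0))
    stop("sample with all-zero counts: ",
         paste(colnames(m)[colSums(m) == 0], collapse = ", "))
  pos <- rowSums(m == 0) == 0
  if (!any(pos))
    stop("no gene has nonzero counts in every sample")
  ref <- exp(rowMeans(log(m[pos, , drop = FALSE])))
  f <- apply(m[pos, , drop = FALSE] / ref, 2, stats::median)
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(m))
}

#' Pooled method-of-moments common dispersion
#'
#' For each gene and group with replication, the within-group sample
#' mean m and unbiased variance v of normalized counts satisfy
#' `E[v] = m * c + phi * m^2` under the NB model (c = mean of 1/s_j
#' over the group), giving a per-cell moment estimate
#' `(v - m*c) / (m^2 - v/n)` (the denominator is the unbiased estimate
#' of mu^2).  A single phi pools these by inverse-variance weighting,
#' `w = 1 / (c/m + phi)^2` (the approximate sampling variance of a
#' per-cell estimate is proportional to `(c/m + phi)^2`), iterated to
#' a fixed point and clipped at 0.  Plain `sum(v - m*c) / sum(m^2)`
#' pooling is dominated by the few highest-expression genes under a
#' heavy-tailed mean distribution; the weighting bounds any one gene's
#' influence.
#'
#' @param cm A `count_matrix`.
#' @param factors Size factors from [estimate_size_factors()].
#' @return list(phi = dispersion estimate >= 0, method = "pooled-MoM").
#' @export
estimate_common_dispersion <- function(cm, factors = NULL) {
  if (is.null(factors)) factors <- estimate_size_factors(cm)
  norm <- sweep(cm$counts, 2, factors, "/")
  ms <- numeric(0); vs <- numeric(0); cs <- numeric(0); ns <- numeric(0)
  for (g in levels(cm$groups)) {
    j <- which(cm$groups == g)
    if (length(j) < 2) next
    sub <- norm[, j, drop = FALSE]
    m <- rowMeans(sub)
    v <- rowSums((sub - m)^2) / (length(j) - 1)
    keep <- m > 0
    ms <- c(ms, m[keep]); vs <- c(vs, v[keep])
    cs <- c(cs, rep(mean(1 / factors[j]), sum(keep)))
    ns <- c(ns, rep(length(j), sum(keep)))
  }
  if (length(ns) == 0)
    stop("dispersion needs within-group replication in at least one group")
  den <- ms^2 - vs / ns
  ok <- den > 0
  if (!any(ok)) return(list(phi = 0, method = "pooled-MoM"))
  phig <- (vs - cs * ms) / den
  phi <- max(1e-4, stats::median(phig[ok]))
  for (it in 1:3) {
    w <- 1 / (cs / ms + phi)^2
    phi <- max(0, sum((w * phig)[ok]) / sum(w[ok]))
    if (phi == 0) break
  }
  list(phi = phi, method = "pooled-MoM")
}

# Conditional log-probabilities of all splits (a, t - a) of the total t
# between pseudo-libraries of relative size n_a and n_b, under a common
# NB dispersion phi (Poisson when phi == 0).  The group totals are
# NB(n*mu, phi/n); conditioning on t, the null mean cancels up to the
# ratio, evaluated at mu = t / (n_a + n_b).
cond_logprob <- function(t, n_a, n_b, phi) {
  x <- 0:t
  if (phi == 0) {
    lp <- stats::dbinom(x, t, n_a / (n_a + n_b), log = TRUE)
  } else {
    mu <- t / (n_a + n_b)
    lp <- stats::dnbinom(x, size = n_a / phi, mu = n_a * mu, log = TRUE) +
      stats::dnbinom(t - x, size = n_b / phi, mu = n_b * mu, log = TRUE)
    lp <- lp - max(lp)
  }
  lp
}

two_sided_smallp <- function(lp, obs) {
  p <- exp(lp)
  p <- p / sum(p)
  min(1, sum(p[p <= p[obs + 1] * (1 + 1e-10)]))
}

#' Exact negative-binomial test for one gene
#'
#' Counts within each group are collapsed to an equivalent pseudo-count
#' at a common per-sample library size (each sample's count divided by
#' its size factor, summed, rounded), then a two-sided exact test is
#' computed on the conditional distribution of the group-A pseudo-count
#' given the two-group total: p is the sum of conditional probabilities
#' not exceeding the observed outcome's probability (small-p method).
#' At phi = 0 with equal library sizes this reduces to the textbook
#' two-sided binomial exact test.  The collapse is exact when all size
#' factors are equal and an approximation otherwise (see vignette).
#'
#' @param counts_a,counts_b Raw counts of the gene per sample, by group.
#' @param factors_a,factors_b Size factors of the corresponding samples
#'   (default 1).
#' @param phi Common NB dispersion (>= 0).
#' @return Two-sided p-value in (0, 1].
#' @export
nb_exact_test <- function(counts_a, counts_b,
                          factors_a = rep(1, length(counts_a)),
                          factors_b = rep(1, length(counts_b)),
                          phi = 0) {
  if (any(counts_a < 0) || any(counts_b < 0)) stop("negative counts")
  if (phi < 0) stop("dispersion must be >= 0")
  pa <- round(sum(counts_a / factors_a))
  pb <- round(sum(counts_b / factors_b))
  t <- pa + pb
  if (t == 0) return(1)
  lp <- cond_logprob(t, length(counts_a), length(counts_b), phi)
  two_sided_smallp(lp, pa)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return q-values on the input order, capped at 1; monotone with
#'   respect to the p-value ranking.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(p[o] * m / (m:1)))
  q[order(o)]
}

#' Run the full differential expression analysis
#'
#' Normalization, common-dispersion estimation, per-gene exact NB test,
#' BH adjustment and log2 fold changes on normalized group means with a
#' pseudo-count.
#'
#' @param cm A `count_matrix`; fold changes are group2 vs group1 in the
#'   order of `levels(cm$groups)`.
#' @param fdr_cutoff Significance cutoff on the BH q-value
#'   (default 0.01).
#' @param annotation Optional `gene_annotation`; when given, the table
#'   gains chrom/start/end columns and is restricted to the shared gene
#'   universe.
#' @param pseudo_count Added to normalized group means before the log2
#'   ratio (default 0.5).
#' @param phi Optional fixed dispersion; default: estimated from the
#'   data.
#' @return list(table = data.frame sorted by p-value (ties broken by
#'   gene id) with columns gene \[chrom start end\] log2FC pvalue FDR
#'   mean_expr, significant = gene ids with FDR < cutoff,
#'   dispersion = the `estimate_common_dispersion` result,
#'   size_factors).
#' @export
run_de <- function(cm, fdr_cutoff = 0.01, annotation = NULL,
                   pseudo_count = 0.5, phi = NULL) {
  if (!is.null(annotation)) {
    shared <- validate_inputs(cm, annotation)$genes
    cm <- count_matrix(cm$counts[shared, , drop = FALSE], cm$groups)
  }
  factors <- estimate_size_factors(cm)
  disp <- if (is.null(phi)) estimate_common_dispersion(cm, factors)
          else list(phi = phi, method = "fixed")
  ja <- which(cm$groups == levels(cm$groups)[1])
  jb <- which(cm$groups == levels(cm$groups)[2])
  norm <- sweep(cm$counts, 2, factors, "/")
  ma <- rowMeans(norm[, ja, drop = FALSE])
  mb <- rowMeans(norm[, jb, drop = FALSE])

  pa <- round(rowSums(sweep(cm$counts[, ja, drop = FALSE], 2,
                            factors[ja], "/")))
  pb <- round(rowSums(sweep(cm$counts[, jb, drop = FALSE], 2,
                            factors[jb], "/")))
  pvals <- nb_exact_test_vec(pa, pb, length(ja), length(jb), disp$phi)

  tab <- data.frame(gene = rownames(cm$counts),
                    log2FC = log2((mb + pseudo_count) /
                                  (ma + pseudo_count)),
                    pvalue = pvals,
                    FDR = bh_adjust(pvals),
                    mean_expr = (ma * length(ja) + mb * length(jb)) /
                      (length(ja) + length(jb)),
                    stringsAsFactors = FALSE)
  if (!is.null(annotation)) {
    i <- match(tab$gene, annotation$gene)
    tab$chrom <- annotation$chrom[i]
    tab$start <- annotation$start[i]
    tab$end <- annotation$end[i]
    tab <- tab[, c("gene", "chrom", "start", "end", "log2FC", "pvalue",
                   "FDR", "mean_expr")]
  }
  tab <- tab[order(tab$pvalue, tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab,
       significant = tab$gene[tab$FDR < fdr_cutoff],
       dispersion = disp,
       size_factors = factors)
}

# vectorized driver over genes given pre-collapsed pseudo-counts;
# groups totals sharing (t, pa) reuse the same conditional distribution
nb_exact_test_vec <- function(pa, pb, n_a, n_b, phi) {
  t <- pa + pb
  p <- rep(1, length(t))
  todo <- which(t > 0)
  key <- paste(t[todo], pa[todo])
  first <- !duplicated(key)
  cache <- new.env(parent = emptyenv())
  for (i in todo[first]) {
    cache[[paste(t[i], pa[i])]] <-
      two_sided_smallp(cond_logprob(t[i], n_a, n_b, phi), pa[i])
  }
  for (i in todo) p[i] <- cache[[paste(t[i], pa[i])]]
  p
}

#' Write a DE table as TSV
#' @param de Result of [run_de()].
#' @param path Output path.
#' @export
write_de_tsv <- function(de, path) {
  data.table::fwrite(de$table, path, sep = "\t")
  invisible(path)
}

#' Read a DE table written by [write_de_tsv()]
#' @param path Input path.
#' @return The DE data.frame.
#' @export
read_de_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}
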