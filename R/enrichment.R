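# Positional enrichment: do the top differentially expressed genes
# concentrate in a called passenger region?  2x2 contingency of
# (top-N vs rest) x (in-region vs out), Pearson chi-square without
# continuity correction plus the Fisher exact test and odds ratio.

#' Top-N genes by p-value
#'
#' @param de_table DE data.frame sorted or not; ties in p are broken by
#'   gene identifier so top-N lists are deterministic.
#' @param n Number of genes (error if the table has fewer).
#' @return Character vector of n gene ids.
#' @export
top_n_genes <- function(de_table, n) {
  if (n > nrow(de_table))
    stop("requested top ", n, " of ", nrow(de_table), " genes")
  o <- order(de_table$pvalue, de_table$gene)
  de_table$gene[o][seq_len(n)]
}

#' Per-chromosome contribution of a gene set
#'
#' @param genes Character vector of gene ids.
#' @param annotation A `gene_annotation`; unannotated genes are dropped
#'   with a warning.
#' @return Named integer vector, one count per chromosome (all
#'   annotation chromosomes, zeros included), summing to the number of
#'   annotated input genes.
#' @export
chromosome_contribution <- function(genes, annotation) {
  i <- match(genes, annotation$gene)
  if (anyNA(i)) {
    warning(sum(is.na(i)), " gene(s) without annotation excluded")
    i <- i[!is.na(i)]
  }
  chroms <- names(chrom_sizes(annotation))
  tab <- table(factor(annotation$chrom[i], levels = chroms))
  stats::setNames(as.integer(tab), chroms)
}

# two-sided Fisher exact p for a 2x2 table via the small-p method on
# the hypergeometric conditional (equivalent to fisher.test's
# two-sided p); kept explicit so it can be enumerated cheaply.
fisher_p_2x2 <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  x <- lo:hi
  lp <- stats::dhyper(x, m, n, k, log = TRUE)
  p <- exp(lp - max(lp))
  min(1, sum(p[p <= p[x == a] * (1 + 1e-7)]) / sum(p))
}

#' Region enrichment of top differentially expressed genes
#'
#' The gene universe is every gene in the DE table with an annotation;
#' a gene is "in region" when its interval overlaps the region (any
#' overlap; `midpoint = TRUE` uses the interval midpoint instead).
#' Reports the 2x2 table, Pearson chi-square (no continuity
#' correction), the Fisher exact p-value, and the sample odds ratio.
#' With a zero margin the chi-square is undefined and only the Fisher
#' p is reported, with the degenerate margin flagged.
#'
#' @param de_table DE data.frame (needs chrom/start/end columns or an
#'   `annotation`).
#' @param region One region: a one-row `region_call` data.frame or
#'   list(chrom=, start=, end=) (0-based half-open).
#' @param annotation A `gene_annotation` giving gene intervals.
#' @param n Size of the top list (default 100).
#' @param midpoint Use gene midpoints for region membership.
#' @return list(table = 2x2 matrix \[top/rest x in/out\], chisq,
#'   df = 1, p_chisq, p_fisher, odds_ratio, degenerate).
#' @export
region_enrichment_test <- function(de_table, region, annotation,
                                   n = 100, midpoint = FALSE) {
  i <- match(de_table$gene, annotation$gene)
  keep <- !is.na(i)
  de_table <- de_table[keep, , drop = FALSE]
  i <- i[keep]
  if (n > nrow(de_table))
    stop("fewer than ", n, " annotated genes in the DE table")
  top <- de_table$gene %in% top_n_genes(de_table, n)
  if (midpoint) {
    mid <- (annotation$start[i] + annotation$end[i]) / 2
    inr <- annotation$chrom[i] == region$chrom &
      mid >= region$start & mid < region$end
  } else {
    inr <- annotation$chrom[i] == region$chrom &
      annotation$start[i] < region$end &
      annotation$end[i] > region$start
  }
  tab <- matrix(c(sum(top & inr), sum(top & !inr),
                  sum(!top & inr), sum(!top & !inr)),
                2, 2, byrow = TRUE,
                dimnames = list(c("top", "rest"), c("in", "out")))
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (degenerate) {
    chisq <- NA_real_; p_chisq <- NA_real_
  } else {
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    chisq <- sum((tab - e)^2 / e)
    p_chisq <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  }
  p_fisher <- fisher_p_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
  odds <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(table = tab, chisq = chisq, df = 1L, p_chisq = p_chisq,
       p_fisher = p_fisher, odds_ratio = odds, degenerate = degenerate)
}
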