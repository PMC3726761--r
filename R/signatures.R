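# Directional gene-signature shift analysis: does a predefined gene set
# (light-zone, dark-zone, naive, centroblast signatures, or an ad-hoc
# family such as Ighv) sit systematically above or below zero in the
# per-gene log2 fold-change distribution?  Tested by the exact sign
# test.

#' Two-sided exact sign test
#'
#' Zeros are excluded (classical treatment); the two-sided p-value is
#' twice the smaller binomial tail of the positive count among nonzero
#' values against probability 1/2, capped at 1.
#'
#' @param values Numeric vector of signed values (e.g. log2FC).
#' @return list(p = two-sided p in (0, 1\], n_pos, n_neg, n_zero).
#' @export
sign_test <- function(values) {
  values <- values[!is.na(values)]
  n_pos <- sum(values > 0)
  n_neg <- sum(values < 0)
  n_zero <- sum(values == 0)
  n <- n_pos + n_neg
  if (n == 0) stop("all values are zero: sign test undefined")
  p <- min(1, 2 * stats::pbinom(min(n_pos, n_neg), n, 0.5))
  list(p = p, n_pos = n_pos, n_neg = n_neg, n_zero = n_zero)
}

score_one_set <- function(de_table, label, members) {
  present <- members[members %in% de_table$gene]
  skipped <- setdiff(members, present)
  lfc <- de_table$log2FC[match(present, de_table$gene)]
  if (length(present) == 0 || all(lfc == 0)) {
    return(data.frame(label = label, n_scored = length(present),
                      n_pos = NA_integer_, n_neg = NA_integer_,
                      n_zero = NA_integer_, median_log2FC = NA_real_,
                      p_sign = NA_real_, n_skipped = length(skipped),
                      testable = FALSE, stringsAsFactors = FALSE))
  }
  st <- sign_test(lfc)
  data.frame(label = label, n_scored = length(present),
             n_pos = st$n_pos, n_neg = st$n_neg, n_zero = st$n_zero,
             median_log2FC = stats::median(lfc), p_sign = st$p,
             n_skipped = length(skipped), testable = TRUE,
             stringsAsFactors = FALSE)
}

#' Score signature gene sets against a DE table
#'
#' Per set: median log2 fold change, sign counts and two-sided
#' sign-test p-value.  Members absent from the DE table are counted as
#' skipped; a set with no scored member is flagged untestable and the
#' others proceed.  The control set's median is also reported relative
#' to each set (`median_vs_con`) when a set labelled "CON" is present.
#'
#' @param de_table DE data.frame (from [run_de()]`$table` or
#'   [read_de_tsv()]).
#' @param sets List of `gene_set` objects.
#' @return data.frame, one row per set, columns label, n_scored, n_pos,
#'   n_neg, n_zero, median_log2FC, p_sign, n_skipped, testable,
#'   median_vs_con.
#' @export
score_signatures <- function(de_table, sets) {
  rows <- lapply(sets, function(s) score_one_set(de_table, s$label,
                                                 s$members))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  con <- out$median_log2FC[out$label == "CON"]
  out$median_vs_con <- if (length(con) == 1 && !is.na(con))
    out$median_log2FC - con else NA_real_
  out
}

#' Shift statistics for an ad-hoc gene family
#'
#' Same statistics as [score_signatures()] for a family resolved from a
#' gene-id prefix (e.g. "Ighv") or an explicit member list.
#'
#' @param de_table DE data.frame.
#' @param family Either a single string treated as a prefix matched
#'   against gene ids, or a character vector of >= 2 treated as the
#'   member list.
#' @param label Row label (default the prefix or "family").
#' @return One-row data.frame as in [score_signatures()].
#' @export
gene_family_shift <- function(de_table, family, label = NULL) {
  if (length(family) == 1) {
    members <- de_table$gene[startsWith(de_table$gene, family)]
    if (is.null(label)) label <- family
  } else {
    members <- family
    if (is.null(label)) label <- "family"
  }
  if (length(members) == 0)
    stop("gene family '", label, "' matches no gene in the DE table")
  out <- score_one_set(de_table, label, members)
  out$median_vs_con <- NA_real_
  out
}
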