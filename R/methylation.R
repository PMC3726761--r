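# Element-wise methylation-load comparison: project capture coverage
# onto classified genomic elements (TSS, exons, introns, intergenic),
# compare per-class load distributions between groups, and correlate
# per-TSS loads.

#' Project coverage onto genomic elements
#'
#' Per element instance, load = coverage mass overlapping the element
#' (value x overlap width, summed over coverage intervals) divided by
#' element length, i.e. mean per-bp coverage.
#'
#' @param coverage data.frame chrom/start/end/value (BedGraph-like,
#'   0-based half-open, values >= 0), e.g. from [read_bedgraph()].
#' @param elements A [GenomicRanges::GRanges] from [derive_elements()],
#'   or a `gene_annotation` (elements derived with defaults).
#' @return A `methyl_profile` with per-bp loads.
#' @export
element_loads <- function(coverage, elements) {
  if (inherits(elements, "gene_annotation"))
    elements <- derive_elements(elements)
  if (any(coverage$value < 0)) stop("coverage must be non-negative")
  width <- GenomicRanges::width(elements)
  if (any(width == 0)) stop("zero-length element")
  load <- numeric(length(elements))
  coverage <- coverage[coverage$chrom %in%
                         unique(as.character(
                           GenomicRanges::seqnames(elements))), ,
                       drop = FALSE]
  if (nrow(coverage) > 0) {
    cgr <- GenomicRanges::GRanges(coverage$chrom,
                                  IRanges::IRanges(coverage$start + 1,
                                                   coverage$end))
    hits <- GenomicRanges::findOverlaps(elements, cgr)
    if (length(hits) > 0) {
      qi <- S4Vectors::queryHits(hits)
      si <- S4Vectors::subjectHits(hits)
      ov <- pmin(GenomicRanges::end(elements)[qi],
                 coverage$end[si]) -
        pmax(GenomicRanges::start(elements)[qi] - 1,
             coverage$start[si])
      mass <- ov * coverage$value[si]
      agg <- tapply(mass, qi, sum)
      load[as.integer(names(agg))] <- agg
    }
  }
  mc <- S4Vectors::mcols(elements)
  methyl_profile(mc$element_id, mc$class,
                 as.character(GenomicRanges::seqnames(elements)),
                 GenomicRanges::start(elements) - 1,
                 GenomicRanges::end(elements), load / width)
}

per_bp <- function(profile) {
  len <- profile$end - profile$start
  profile$load / ifelse(len > 0, len, 1)
}

#' Compare one element class between two profiles
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum, normal approximation)
#' location test on length-normalized loads of the class's element
#' instances; a t-test and the paired signed-rank variant are available
#' behind flags.  Group means are reported alongside.
#'
#' @param a,b `methyl_profile` objects over the same element universe.
#' @param class One of TSS/EXN/INT/ING.
#' @param method "wilcox" (default) or "t".
#' @param paired Pair loads by element id (default FALSE: rank-sum, as
#'   the test is named).
#' @param normalize Length-normalize loads to per-bp before testing
#'   (default TRUE; set FALSE if loads are already per-bp).
#' @return list(class, p, mean_a, mean_b, n_a, n_b, method).
#' @export
compare_class <- function(a, b, class, method = c("wilcox", "t"),
                          paired = FALSE, normalize = TRUE) {
  method <- match.arg(method)
  xa <- if (normalize) per_bp(a) else a$load
  xb <- if (normalize) per_bp(b) else b$load
  xa <- xa[a$class == class]
  xb <- xb[b$class == class]
  if (length(xa) < 2 || length(xb) < 2)
    return(list(class = class, p = NA_real_, mean_a = mean(xa),
                mean_b = mean(xb), n_a = length(xa), n_b = length(xb),
                method = method, testable = FALSE))
  p <- if (method == "wilcox") {
    stats::wilcox.test(xa, xb, paired = paired, exact = FALSE)$p.value
  } else {
    stats::t.test(xa, xb, paired = paired)$p.value
  }
  list(class = class, p = p, mean_a = mean(xa), mean_b = mean(xb),
       n_a = length(xa), n_b = length(xb), method = method,
       testable = TRUE)
}

#' Pearson correlation of per-TSS loads between two profiles
#'
#' Loads are matched by element id over TSS elements shared by the two
#' profiles.  Undefined (NA, with a message) when either vector has
#' zero variance.
#'
#' @param a,b `methyl_profile` objects.
#' @param normalize Length-normalize to per-bp first (default TRUE).
#' @return Pearson r in \[-1, 1\], or NA if undefined.
#' @export
pearson_tss <- function(a, b, normalize = TRUE) {
  ia <- which(a$class == "TSS")
  ib <- which(b$class == "TSS")
  shared <- intersect(a$element_id[ia], b$element_id[ib])
  if (length(shared) < 3) stop("fewer than 3 shared TSS elements")
  xa <- (if (normalize) per_bp(a) else a$load)[match(shared,
                                                     a$element_id)]
  xb <- (if (normalize) per_bp(b) else b$load)[match(shared,
                                                     b$element_id)]
  if (stats::sd(xa) == 0 || stats::sd(xb) == 0) {
    message("pearson_tss: zero variance, correlation undefined")
    return(NA_real_)
  }
  stats::cor(xa, xb)
}

#' Full methylation comparison
#'
#' Per-class location tests plus the global per-TSS Pearson r.
#'
#' @param a,b `methyl_profile` objects.
#' @param classes Element classes to test.
#' @param ... Passed to [compare_class()].
#' @return list(per_class = data.frame(class, p, mean_a, mean_b, n_a,
#'   n_b), pearson_r).
#' @export
compare_methylation <- function(a, b,
                                classes = c("TSS", "EXN", "INT",
                                            "ING"), ...) {
  rows <- lapply(classes, function(cl) {
    r <- compare_class(a, b, cl, ...)
    data.frame(class = r$class, p = r$p, mean_a = r$mean_a,
               mean_b = r$mean_b, n_a = r$n_a, n_b = r$n_b,
               stringsAsFactors = FALSE)
  })
  list(per_class = do.call(rbind, rows),
       pearson_r = tryCatch(pearson_tss(a, b),
                            error = function(e) NA_real_))
}
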