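# Core domain types shared by every pipeline stage.
#
# Coordinate conventions: all internal intervals are 0-based, half-open
# (BED convention).  VCF positions are 1-based and converted on read;
# a VariantTable keeps the 1-based `pos` column so that written VCFs are
# faithful, and `pos0()` gives the internal coordinate.

#' Construct a validated count matrix
#'
#' Bundles an integer read-count matrix (genes x samples) with a
#' sample-to-group assignment.  Exactly two groups are supported: every
#' comparison in the pipeline is knockout versus wildtype.
#'
#' @param counts Integer matrix, genes as rows (rownames = gene ids),
#'   samples as columns (colnames = sample ids).  All entries must be
#'   non-negative and integral.
#' @param groups Named character vector or factor mapping sample id to
#'   group label; must cover every column of `counts` and contain exactly
#'   two distinct labels.
#' @return An object of class `count_matrix` with elements `counts`
#'   (integer matrix) and `groups` (named factor, levels in first-seen
#'   order).
#' @examples
#' m <- matrix(rpois(8, 10), 2, 4,
#'             dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
#' cm <- count_matrix(m, c(s1 = "WT", s2 = "WT", s3 = "KO", s4 = "KO"))
#' @export
count_matrix <- function(counts, groups) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("gene identifiers must be unique")
  if (anyDuplicated(colnames(counts)))
    stop("sample identifiers must be unique")
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative")
  if (any(counts != round(counts)))
    stop("counts must be integral")
  storage.mode(counts) <- "double"  # doubles hold big totals exactly
  groups <- groups[colnames(counts)]
  if (any(is.na(groups)))
    stop("every sample needs a group label")
  lev <- unique(as.character(groups))
  if (length(lev) != 2L)
    stop("exactly two groups are required, got: ",
         paste(lev, collapse = ", "))
  groups <- factor(as.character(groups), levels = lev)
  names(groups) <- colnames(counts)
  structure(list(counts = counts, groups = groups), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s=%d", levels(x$groups),
                            tabulate(x$groups)), collapse = ", ")))
  invisible(x)
}

#' Construct a gene annotation table
#'
#' Per-gene chromosome, interval and strand.  Intervals are 0-based,
#' half-open.  Strand is used only to place TSS windows; all other
#' interval logic is strand-agnostic.
#'
#' @param genes Character vector of unique gene identifiers.
#' @param chrom Chromosome name per gene.
#' @param start,end Integer interval bounds, 0-based half-open, start < end.
#' @param strand "+" or "-" per gene.
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp).
#' @param exons Optional data.frame with columns `gene`, `start`, `end`
#'   (0-based half-open, within the gene interval) describing exon
#'   structure.  When absent each gene is treated as a single exon.
#' @return Object of class `gene_annotation`: a data.frame with one row
#'   per gene plus a `chrom_sizes` attribute and an `exons` attribute.
#' @export
gene_annotation <- function(genes, chrom, start, end, strand,
                            chrom_sizes, exons = NULL) {
  if (anyDuplicated(genes)) stop("gene identifiers must be unique")
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start >= end)) stop("gene intervals need start < end")
  if (any(start < 0)) stop("negative coordinates")
  if (!all(chrom %in% names(chrom_sizes)))
    stop("gene on a chromosome absent from chrom_sizes")
  if (any(end > chrom_sizes[chrom]))
    stop("gene interval exceeds chromosome bounds")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  ann <- data.frame(gene = as.character(genes), chrom = as.character(chrom),
                    start = start, end = end, strand = as.character(strand),
                    stringsAsFactors = FALSE)
  if (is.null(exons)) {
    exons <- data.frame(gene = ann$gene, start = ann$start, end = ann$end,
                        stringsAsFactors = FALSE)
  } else {
    exons <- as.data.frame(exons)[, c("gene", "start", "end")]
    if (!all(exons$gene %in% ann$gene))
      stop("exon rows reference unknown genes")
  }
  attr(ann, "chrom_sizes") <- chrom_sizes
  attr(ann, "exons") <- exons
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' Chromosome sizes of an annotation
#' @param annotation A `gene_annotation`.
#' @return Named numeric vector of chromosome lengths.
#' @export
chrom_sizes <- function(annotation) attr(annotation, "chrom_sizes")

#' Derive classified genomic elements from a gene annotation
#'
#' Classifies the genome into the four element classes used in the
#' methylation comparison: `TSS` (a window of `2 * tss_halfwidth` bp
#' centred on the strand-aware transcription start), `EXN` (exons),
#' `INT` (introns, gene body minus exons) and `ING` (intergenic gaps
#' between gene bodies).
#'
#' @param annotation A `gene_annotation`.
#' @param tss_halfwidth TSS window half-width in bp (default 1000, i.e.
#'   a +/-1 kb window; the choice is a documented convention, see the
#'   methods vignette).
#' @return A [GenomicRanges::GRanges] with metadata columns `class`
#'   (TSS/EXN/INT/ING) and `element_id` (stable per-instance identifier).
#' @export
derive_elements <- function(annotation, tss_halfwidth = 1000) {
  sizes <- chrom_sizes(annotation)
  exons <- attr(annotation, "exons")
  idx <- match(exons$gene, annotation$gene)

  tss_pos <- ifelse(annotation$strand == "+", annotation$start,
                    annotation$end)
  tss_start <- pmax(0, tss_pos - tss_halfwidth)
  tss_end <- pmin(sizes[annotation$chrom], tss_pos + tss_halfwidth)

  gr_of <- function(chr, s, e, cls, id) {
    keep <- e > s
    GenomicRanges::GRanges(
      seqnames = chr[keep],
      ranges = IRanges::IRanges(start = s[keep] + 1, end = e[keep]),
      class = rep(cls, sum(keep)), element_id = id[keep],
      seqlengths = sizes)
  }
  tss <- gr_of(annotation$chrom, tss_start, tss_end, "TSS",
               paste0("TSS:", annotation$gene))
  exn <- gr_of(annotation$chrom[idx], exons$start, exons$end, "EXN",
               paste0("EXN:", exons$gene, ":",
                      stats::ave(seq_along(idx), exons$gene, FUN = seq_along)))

  # introns: per-gene body minus (sorted, disjoint) exons, vectorized
  # over the exon table: the gaps between consecutive exon intervals of
  # one gene, plus flanks to the gene bounds
  body <- GenomicRanges::GRanges(annotation$chrom,
                                 IRanges::IRanges(annotation$start + 1,
                                                  annotation$end),
                                 seqlengths = sizes)
  eo <- order(idx, exons$start)
  eg <- idx[eo]; es <- exons$start[eo]; ee <- exons$end[eo]
  same <- c(FALSE, eg[-1] == eg[-length(eg)])
  first <- !duplicated(eg); last <- !duplicated(eg, fromLast = TRUE)
  gs <- c(c(NA, ee[-length(ee)])[same], annotation$start[eg][first],
          ee[last])
  ge <- c(es[same], es[first], annotation$end[eg][last])
  gi <- c(eg[same], eg[first], eg[last])
  ok <- ge > gs
  intr <- data.frame(chrom = annotation$chrom[gi][ok],
                     start = gs[ok], end = ge[ok],
                     gene = annotation$gene[gi][ok],
                     stringsAsFactors = FALSE)
  int <- if (nrow(intr) == 0) {
    GenomicRanges::GRanges(seqlengths = sizes)
  } else {
    intr <- intr[order(intr$gene, intr$start), , drop = FALSE]
    gr_of(intr$chrom, intr$start, intr$end, "INT",
          paste0("INT:", intr$gene, ":",
                 stats::ave(seq_len(nrow(intr)), intr$gene, FUN = seq_along)))
  }

  # intergenic: complement of gene bodies
  ing <- GenomicRanges::gaps(GenomicRanges::reduce(body))
  ing <- ing[GenomicRanges::strand(ing) == "*"]
  if (length(ing) > 0) {
    S4Vectors::mcols(ing) <- S4Vectors::DataFrame(
      class = "ING", element_id = paste0("ING:", seq_along(ing)))
  }
  out <- c(tss, exn, int, ing)
  sort(out, ignore.strand = TRUE)
}

#' Construct a variant table
#'
#' Records of called variants.  `pos` is 1-based as in VCF; use
#' [pos0()] for the internal 0-based coordinate.
#'
#' @param chrom,pos,ref,alt Vectors of equal length; `pos` 1-based.
#' @param strain Optional strain-of-origin label per variant
#'   (default "unknown").
#' @param coding Optional logical coding flag (default NA).
#' @return Object of class `variant_table`: a data.frame sorted by
#'   (chrom, pos).
#' @export
variant_table <- function(chrom, pos, ref, alt, strain = NULL,
                          coding = NULL) {
  n <- length(pos)
  if (n > 0 && any(pos < 1)) stop("VCF positions are 1-based (pos >= 1)")
  if (n > 0 && (any(!nzchar(ref)) || any(!nzchar(alt))))
    stop("alleles must be non-empty")
  vt <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                   ref = as.character(ref), alt = as.character(alt),
                   strain = if (is.null(strain)) rep("unknown", n)
                            else as.character(strain),
                   coding = if (is.null(coding)) rep(NA, n)
                            else as.logical(coding),
                   stringsAsFactors = FALSE)
  vt <- vt[order(vt$chrom, vt$pos), , drop = FALSE]
  rownames(vt) <- NULL
  class(vt) <- c("variant_table", "data.frame")
  vt
}

#' 0-based positions of a variant table
#' @param variants A `variant_table`.
#' @return Numeric vector of 0-based positions (`pos - 1`).
#' @export
pos0 <- function(variants) variants$pos - 1

#' Construct a gene set
#' @param label Set label, e.g. one of CON, LZS, DZS, NVS, CBS.
#' @param members Character vector of gene identifiers (unique, non-empty).
#' @return Object of class `gene_set`.
#' @export
gene_set <- function(label, members) {
  members <- unique(as.character(members))
  if (length(members) == 0) stop("gene set '", label, "' is empty")
  structure(list(label = as.character(label), members = members),
            class = "gene_set")
}

#' Construct a methylation profile
#'
#' One row per genomic element instance carrying a non-negative capture
#' coverage value ("load", reads per element; length-normalizable).
#'
#' @param element_id Stable element identifiers (shared across profiles
#'   derived from the same annotation).
#' @param class Element class, one of TSS/EXN/INT/ING.
#' @param chrom,start,end Element interval (0-based half-open).
#' @param load Non-negative coverage value per element.
#' @return Object of class `methyl_profile` (a data.frame).
#' @export
methyl_profile <- function(element_id, class, chrom, start, end, load) {
  if (any(load < 0)) stop("loads must be non-negative")
  if (!all(class %in% c("TSS", "EXN", "INT", "ING")))
    stop("element class must be one of TSS, EXN, INT, ING")
  mp <- data.frame(element_id = as.character(element_id),
                   class = as.character(class),
                   chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   load = as.numeric(load), stringsAsFactors = FALSE)
  class(mp) <- c("methyl_profile", "data.frame")
  mp
}

#' Cross-validate a count matrix against an annotation
#'
#' Pipeline stages operate on the intersection of the gene universes of
#' the two inputs; this reports that intersection and any discrepancies.
#'
#' @param counts A `count_matrix`.
#' @param annotation A `gene_annotation`.
#' @return A list with `genes` (intersection, in count-matrix order),
#'   `counts_only` and `annotation_only` (discrepancy lists).
#' @export
validate_inputs <- function(counts, annotation) {
  cg <- rownames(counts$counts)
  ag <- annotation$gene
  shared <- cg[cg %in% ag]
  if (length(shared) == 0)
    stop("no genes shared between counts and annotation")
  list(genes = shared,
       counts_only = setdiff(cg, ag),
       annotation_only = setdiff(ag, cg))
}
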