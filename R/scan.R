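# Windowed strain-SNP density scan and passenger-region calling: count
# strain-informative variants per fixed genomic window (default 50 kb),
# then call maximal runs of high-density windows as candidate
# donor-strain passenger regions.

#' Scan configuration
#'
#' @param window_size Window width in bp (default 50,000).
#' @param threshold Minimum variants per window for a window to count
#'   as "hot" (default 5).
#' @param merge_gap Maximum number of consecutive cold windows bridged
#'   when merging hot runs (default 2).
#' @param min_span Minimum region span in windows (default 3).
#' @return list of class `scan_config`.
#' @export
scan_config <- function(window_size = 50000, threshold = 5,
                        merge_gap = 2, min_span = 3) {
  stopifnot(window_size > 0, threshold >= 1, merge_gap >= 0,
            min_span >= 1)
  structure(list(window_size = window_size, threshold = threshold,
                 merge_gap = merge_gap, min_span = min_span),
            class = "scan_config")
}

#' Flag (or filter to) variants falling in coding exons
#'
#' A variant at 1-based position p lies in a 0-based half-open exon
#' \[s, e) iff s < p <= e.
#'
#' @param variants A `variant_table`.
#' @param annotation A `gene_annotation` supplying exon intervals.
#' @param keep_all If TRUE, return all variants with the coding flag
#'   set; if FALSE (default), return only the coding variants.
#' @return A `variant_table`.
#' @export
intersect_variants_coding <- function(variants, annotation,
                                      keep_all = FALSE) {
  ex <- attr(annotation, "exons")
  idx <- match(ex$gene, annotation$gene)
  if (nrow(variants) == 0 || nrow(ex) == 0) {
    variants$coding <- rep(FALSE, nrow(variants))
    return(if (keep_all) variants else variants[0, , drop = FALSE])
  }
  vgr <- GenomicRanges::GRanges(variants$chrom,
                                IRanges::IRanges(variants$pos,
                                                 variants$pos))
  egr <- GenomicRanges::GRanges(annotation$chrom[idx],
                                IRanges::IRanges(ex$start + 1, ex$end))
  hit <- IRanges::overlapsAny(vgr, egr)
  variants$coding <- hit
  if (keep_all) variants
  else {
    out <- variants[hit, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
}

#' Label variants with their strain of origin from a reference panel
#'
#' A variant receives the panel's strain label when the full
#' (chromosome, position, ref, alt) quadruple matches a panel record;
#' unmatched variants are labelled "unknown".
#'
#' @param variants A `variant_table`.
#' @param panel A `variant_table` carrying strain labels.
#' @return The variant table with the `strain` column filled in.
#' @export
label_strain <- function(variants, panel) {
  key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = "\r")
  i <- match(key(variants), key(panel))
  variants$strain <- ifelse(is.na(i), "unknown", panel$strain[i])
  variants
}

#' Variant counts per fixed genomic window
#'
#' Windows tile each chromosome without overlap (last window
#' truncated); a variant at 1-based position p belongs to window
#' `floor((p - 1) / window_size)`.  Variants beyond the chromosome end
#' are counted in the last window with a warning.
#'
#' @param variants A `variant_table`.
#' @param sizes Named vector of chromosome lengths (bp), e.g.
#'   [chrom_sizes()] of an annotation.
#' @param config A `scan_config`.
#' @param strain Optional strain label; when given only matching
#'   variants are counted.
#' @return data.frame of class `window_density`: chrom, start, end
#'   (0-based half-open), count.
#' @export
window_density <- function(variants, sizes, config = scan_config(),
                           strain = NULL) {
  w <- config$window_size
  if (!is.null(strain))
    variants <- variants[variants$strain == strain, , drop = FALSE]
  out <- lapply(names(sizes), function(cc) {
    len <- sizes[[cc]]
    nw <- max(1L, as.integer(ceiling(len / w)))
    starts <- (seq_len(nw) - 1) * w
    pos <- variants$pos[variants$chrom == cc]
    if (any(pos > len)) {
      warning(sum(pos > len), " variant(s) beyond the end of ", cc,
              "; counted in the last window")
    }
    idx <- pmin(floor((pos - 1) / w), nw - 1)
    data.frame(chrom = cc, start = starts,
               end = pmin(starts + w, len),
               count = tabulate(idx + 1, nbins = nw),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("window_density", "data.frame")
  out
}

#' Call contiguous high-density regions
#'
#' Within each chromosome, maximal runs of windows with
#' `count >= threshold`, allowing up to `merge_gap` consecutive
#' below-threshold windows to be bridged, are reported as regions when
#' they span at least `min_span` windows (bridged gaps included in the
#' span).  Regions never cross chromosomes and are aligned to window
#' boundaries.
#'
#' @param density A `window_density`.
#' @param config A `scan_config`.
#' @param variants Optional `variant_table` used to attach a majority
#'   strain label per region.
#' @return data.frame of class `region_call`: chrom, start, end,
#'   n_windows, n_hot, n_variants, mean_hot_density, strain.
#' @export
call_regions <- function(density, config = scan_config(),
                         variants = NULL) {
  res <- list()
  for (cc in unique(density$chrom)) {
    d <- density[density$chrom == cc, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    hot <- which(d$count >= config$threshold)
    if (length(hot) == 0) next
    run_start <- hot[1]; prev <- hot[1]
    runs <- list()
    for (h in hot[-1]) {
      if (h - prev - 1 > config$merge_gap) {
        runs[[length(runs) + 1]] <- c(run_start, prev)
        run_start <- h
      }
      prev <- h
    }
    runs[[length(runs) + 1]] <- c(run_start, prev)
    for (r in runs) {
      span <- r[2] - r[1] + 1
      if (span < config$min_span) next
      idx <- r[1]:r[2]
      is_hot <- d$count[idx] >= config$threshold
      strain <- NA_character_
      if (!is.null(variants)) {
        vv <- variants[variants$chrom == cc &
                         variants$pos > d$start[r[1]] &
                         variants$pos <= d$end[r[2]], , drop = FALSE]
        if (nrow(vv) > 0) {
          tb <- sort(table(vv$strain), decreasing = TRUE)
          strain <- names(tb)[1]
        }
      }
      res[[length(res) + 1]] <- data.frame(
        chrom = cc, start = d$start[r[1]], end = d$end[r[2]],
        n_windows = span, n_hot = sum(is_hot),
        n_variants = sum(d$count[idx]),
        mean_hot_density = mean(d$count[idx][is_hot]),
        strain = strain, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res) == 0) {
    data.frame(chrom = character(0), start = numeric(0),
               end = numeric(0), n_windows = integer(0),
               n_hot = integer(0), n_variants = numeric(0),
               mean_hot_density = numeric(0), strain = character(0),
               stringsAsFactors = FALSE)
  } else do.call(rbind, res)
  class(out) <- c("region_call", "data.frame")
  out
}

#' Write windows as BedGraph / regions as BED
#' @param density A `window_density`.
#' @param path Output path.
#' @export
write_density_bedgraph <- function(density, path) {
  write_bedgraph(data.frame(chrom = density$chrom,
                            start = density$start, end = density$end,
                            value = density$count), path)
}

#' @rdname write_density_bedgraph
#' @param regions A `region_call`.
#' @export
write_regions_bed <- function(regions, path) {
  data.table::fwrite(data.table::data.table(
    chrom = regions$chrom, start = format_coord(regions$start),
    end = format_coord(regions$end),
    name = ifelse(is.na(regions$strain), "region", regions$strain),
    score = regions$n_variants), path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Plot variant density along one chromosome
#'
#' Variants per window against window midpoint, with called regions
#' shaded — the standard view in which a donor-strain passenger region
#' shows up as a contiguous block of high-density windows.
#'
#' @param density A `window_density`.
#' @param chrom Chromosome to plot.
#' @param regions Optional `region_call` to shade.
#' @export
plot_window_density <- function(density, chrom, regions = NULL) {
  d <- density[density$chrom == chrom, , drop = FALSE]
  mid <- (d$start + d$end) / 2 / 1e6
  plot(mid, d$count, type = "h", xlab = paste(chrom, "position (Mb)"),
       ylab = sprintf("variants per %d kb window",
                      round((d$end - d$start)[1] / 1000)))
  if (!is.null(regions)) {
    rr <- regions[regions$chrom == chrom, , drop = FALSE]
    if (nrow(rr) > 0)
      graphics::rect(rr$start / 1e6, 0, rr$end / 1e6, max(d$count),
                     col = grDevices::adjustcolor("red", 0.15),
                     border = NA)
  }
  invisible(NULL)
}
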