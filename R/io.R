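# Readers and writers for the plain-text interchange formats the
# pipeline consumes and emits.  All writers are exact inverses of the
# corresponding readers (round-trip tested).

#' Write / read a count matrix as TSV
#'
#' Genes as rows, first column `gene`, remaining columns one per sample.
#' The sample-to-group mapping travels in a separate two-column TSV
#' (`sample`, `group`), see [write_groups_tsv()].
#'
#' @param cm A `count_matrix`.
#' @param path Output file.
#' @export
write_counts_tsv <- function(cm, path) {
  dt <- data.table::data.table(gene = rownames(cm$counts))
  for (s in colnames(cm$counts)) dt[[s]] <- cm$counts[, s]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_counts_tsv
#' @param groups_path Path of the groups TSV written by
#'   [write_groups_tsv()].
#' @return `read_counts_tsv` returns a `count_matrix`.
#' @export
read_counts_tsv <- function(path, groups_path) {
  dt <- data.table::fread(path, sep = "\t")
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1]]
  g <- data.table::fread(groups_path, sep = "\t")
  groups <- stats::setNames(as.character(g$group), g$sample)
  count_matrix(m, groups)
}

#' Write / read a sample-to-group mapping
#' @param groups Named vector (names = sample ids) of group labels.
#' @param path Output file.
#' @export
write_groups_tsv <- function(groups, path) {
  data.table::fwrite(data.table::data.table(sample = names(groups),
                                            group = as.character(groups)),
                     path, sep = "\t")
  invisible(path)
}

#' Write / read counts in MatrixMarket format
#'
#' The matrix goes to `<path>`, gene and sample ids to sidecar files
#' `<path>.genes` and `<path>.samples` (one id per line), and groups to
#' `<path>.groups` (two-column TSV).
#'
#' @param cm A `count_matrix`.
#' @param path Base path of the `.mtx` file.
#' @export
write_counts_mtx <- function(cm, path) {
  Matrix::writeMM(Matrix::Matrix(cm$counts, sparse = TRUE), path)
  writeLines(rownames(cm$counts), paste0(path, ".genes"))
  writeLines(colnames(cm$counts), paste0(path, ".samples"))
  write_groups_tsv(cm$groups, paste0(path, ".groups"))
  invisible(path)
}

#' @rdname write_counts_mtx
#' @return `read_counts_mtx` returns a `count_matrix`.
#' @export
read_counts_mtx <- function(path) {
  m <- as.matrix(Matrix::readMM(path))
  rownames(m) <- readLines(paste0(path, ".genes"))
  colnames(m) <- readLines(paste0(path, ".samples"))
  g <- data.table::fread(paste0(path, ".groups"), sep = "\t")
  count_matrix(m, stats::setNames(as.character(g$group), g$sample))
}

#' Write / read a gene annotation as BED6 plus an exon file
#'
#' Genes go to a BED6 file (0-based half-open, name = gene id, score 0).
#' Exon structure goes to a GTF-like TSV `<path>.exons` with columns
#' gene/start/end, and chromosome sizes to `<path>.chrom.sizes`.
#'
#' @param annotation A `gene_annotation`.
#' @param path Output BED path.
#' @export
write_annotation_bed <- function(annotation, path) {
  bed <- data.table::data.table(chrom = annotation$chrom,
                                start = format_coord(annotation$start),
                                end = format_coord(annotation$end),
                                name = annotation$gene, score = 0L,
                                strand = annotation$strand)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  ex <- attr(annotation, "exons")
  data.table::fwrite(data.table::data.table(gene = ex$gene,
                                            start = format_coord(ex$start),
                                            end = format_coord(ex$end)),
                     paste0(path, ".exons"), sep = "\t")
  sizes <- chrom_sizes(annotation)
  data.table::fwrite(data.table::data.table(chrom = names(sizes),
                                            size = format_coord(sizes)),
                     paste0(path, ".chrom.sizes"), sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' @rdname write_annotation_bed
#' @return `read_annotation_bed` returns a `gene_annotation`.
#' @export
read_annotation_bed <- function(path) {
  bed <- data.table::fread(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand"))
  ex <- data.table::fread(paste0(path, ".exons"), sep = "\t")
  cs <- data.table::fread(paste0(path, ".chrom.sizes"), sep = "\t",
                          header = FALSE, col.names = c("chrom", "size"))
  gene_annotation(bed$name, bed$chrom, bed$start, bed$end, bed$strand,
                  stats::setNames(cs$size, cs$chrom),
                  exons = as.data.frame(ex))
}

#' Write / read a variant table as VCF v4.x
#'
#' Only CHROM/POS/REF/ALT are consumed by the pipeline; the strain label
#' and coding flag are carried in the INFO field (`STRAIN=`, `CODING`)
#' so a written file reads back field-for-field.
#'
#' @param variants A `variant_table`.
#' @param path Output VCF path.
#' @export
write_vcf <- function(variants, path) {
  info <- paste0("STRAIN=", variants$strain,
                 ifelse(!is.na(variants$coding) & variants$coding,
                        ";CODING", ""))
  if (nrow(variants) == 0) info <- character(0)
  lines <- c("##fileformat=VCFv4.2",
             "##INFO=<ID=STRAIN,Number=1,Type=String,Description=\"Strain of origin\">",
             "##INFO=<ID=CODING,Number=0,Type=Flag,Description=\"Falls in a coding exon\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
             if (nrow(variants) > 0)
               paste(variants$chrom, format_coord(variants$pos), ".",
                     variants$ref, variants$alt, ".", "PASS", info,
                     sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_vcf
#' @return `read_vcf` returns a `variant_table`.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0)
    return(variant_table(character(0), numeric(0), character(0),
                         character(0)))
  f <- data.table::fread(text = body, sep = "\t", header = FALSE)
  info <- as.character(f[[8]])
  strain <- ifelse(grepl("STRAIN=", info),
                   sub(".*STRAIN=([^;]+).*", "\\1", info), "unknown")
  coding <- grepl("(^|;)CODING($|;)", info)
  variant_table(f[[1]], f[[2]], f[[4]], f[[5]], strain = strain,
                coding = coding)
}

#' Write / read a methylation profile
#'
#' Plain TSV with columns element_id/class/chrom/start/end/load.
#' @param profile A `methyl_profile`.
#' @param path Output path.
#' @export
write_methyl_tsv <- function(profile, path) {
  data.table::fwrite(as.data.frame(profile), path, sep = "\t")
  invisible(path)
}

#' @rdname write_methyl_tsv
#' @return `read_methyl_tsv` returns a `methyl_profile`.
#' @export
read_methyl_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  methyl_profile(dt$element_id, dt$class, dt$chrom, dt$start, dt$end,
                 dt$load)
}

#' Write / read coverage as BedGraph
#'
#' @param coverage data.frame with columns chrom/start/end/value
#'   (0-based half-open intervals).
#' @param path Output path.
#' @export
write_bedgraph <- function(coverage, path) {
  data.table::fwrite(data.table::data.table(
    chrom = coverage$chrom, start = format_coord(coverage$start),
    end = format_coord(coverage$end), value = coverage$value),
    path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_bedgraph
#' @return `read_bedgraph` returns the coverage data.frame.
#' @export
read_bedgraph <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "value"))
  as.data.frame(dt)
}

#' Read a gene set from a one-gene-per-line file
#' @param path File of gene identifiers, one per line; the set label is
#'   the file name without extension.
#' @return A `gene_set`.
#' @export
read_gene_set <- function(path) {
  members <- readLines(path)
  members <- members[nzchar(members)]
  gene_set(sub("\\.[^.]*$", "", basename(path)), members)
}

#' Write a gene set
#' @param set A `gene_set`.
#' @param dir Directory; the file is named `<label>.txt`.
#' @export
write_gene_set <- function(set, dir) {
  path <- file.path(dir, paste0(set$label, ".txt"))
  writeLines(set$members, path)
  invisible(path)
}
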