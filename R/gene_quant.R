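#' Read gene annotation from GFF3 or BED6
#'
#' GFF3 `gene`-type features (any feature type is accepted) are read with
#' their `ID` attribute and an optional `architecture` attribute; BED6 uses
#' column 4 as the gene id. Coordinates are returned 0-based half-open.
#'
#' @param path GFF3 (`.gff`/`.gff3`) or BED (`.bed`) file.
#' @return data.frame with gene_id, chrom, start, end, strand, biotype,
#'   architecture.
#' @export
read_annotation <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "gff3")
    id <- if (!is.null(gr$ID)) as.character(gr$ID) else
      sprintf("feature%04d", seq_along(gr))
    data.frame(
      gene_id = id,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      biotype = if (!is.null(gr$biotype)) as.character(gr$biotype) else
        as.character(gr$type),
      architecture = if (!is.null(gr$architecture))
        as.character(gr$architecture) else NA_character_,
      stringsAsFactors = FALSE)
  } else if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    b <- load_bed6(path)
    fields <- strsplit(readLines(path), "\t", fixed = TRUE)
    fields <- fields[lengths(fields) >= 6L]
    b$gene_id <- vapply(fields, `[[`, character(1), 4L)
    b$biotype <- "gene"
    b$architecture <- NA_character_
    b[, c("gene_id", "chrom", "start", "end", "strand", "biotype", "architecture")]
  } else stop("expected a .gff3 or .bed annotation: ", path, call. = FALSE)
}

#' Write a gene annotation as GFF3
#'
#' Features are written with type `gene`, an `ID` attribute and, when
#' present, an `architecture` attribute tagging the planted overlap type.
#'
#' @param annotation Annotation data.frame (as from [read_annotation()] or
#'   [plant_loci()]).
#' @param path Output path.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  ensure_parent_dir(path)
  if (!nrow(annotation)) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(annotation$start + 1L, annotation$end),
    strand = annotation$strand)
  gr$type <- "gene"
  gr$source <- "dcscan"
  gr$ID <- annotation$gene_id
  if (!is.null(annotation$biotype)) gr$biotype <- annotation$biotype
  if (!is.null(annotation$architecture) && !all(is.na(annotation$architecture)))
    gr$architecture <- annotation$architecture
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Count sense and antisense reads per gene
#'
#' A read is assigned to every gene whose interval contains the read's
#' midpoint, `floor((start + end) / 2)`; reads on the gene's strand count
#' as sense, opposite-strand reads as antisense. With `mode = "overlap"`
#' any base of overlap assigns the read instead. Reads hitting no gene are
#' tallied as intergenic (attribute `n_intergenic`).
#'
#' @param alignments Alignment data.frame.
#' @param annotation Annotation data.frame (see [read_annotation()]).
#' @param library_size RPM denominator (total aligned reads).
#' @param mode `"midpoint"` (default) or `"overlap"`.
#' @return data.frame with one row per gene: gene_id, chrom, start, end,
#'   strand, biotype, sense_reads, antisense_reads, sense_rpm,
#'   antisense_rpm; attribute `n_intergenic` counts unassigned reads.
#' @export
count_gene_reads <- function(alignments, annotation, library_size,
                             mode = c("midpoint", "overlap")) {
  mode <- match.arg(mode)
  check_alignments(alignments)
  if (nrow(alignments) &&
      length(setdiff(unique(alignments$chrom), unique(annotation$chrom))))
    stop("alignment chroms absent from annotation: ",
         paste(setdiff(unique(alignments$chrom), unique(annotation$chrom)),
               collapse = ", "), call. = FALSE)
  genes <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(annotation$start + 1L, annotation$end))
  if (mode == "midpoint") {
    mid <- floor((alignments$start + alignments$end) / 2)
    reads <- GenomicRanges::GRanges(alignments$chrom,
                                    IRanges::IRanges(mid + 1L, width = 1L))
  } else {
    reads <- GenomicRanges::GRanges(
      alignments$chrom,
      IRanges::IRanges(alignments$start + 1L, alignments$end))
  }
  hits <- GenomicRanges::findOverlaps(reads, genes)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  same <- alignments$strand[qh] == annotation$strand[sh]
  wt <- alignments$count[qh]
  sense <- tapply(wt[same], factor(sh[same], levels = seq_len(nrow(annotation))),
                  sum, default = 0)
  anti <- tapply(wt[!same], factor(sh[!same], levels = seq_len(nrow(annotation))),
                 sum, default = 0)
  out <- data.frame(
    gene_id = annotation$gene_id, chrom = annotation$chrom,
    start = annotation$start, end = annotation$end,
    strand = annotation$strand, biotype = annotation$biotype,
    sense_reads = as.numeric(sense), antisense_reads = as.numeric(anti),
    stringsAsFactors = FALSE)
  out$sense_rpm <- out$sense_reads * 1e6 / library_size
  out$antisense_rpm <- out$antisense_reads * 1e6 / library_size
  assigned <- unique(qh)
  attr(out, "n_intergenic") <-
    sum(alignments$count) - sum(alignments$count[assigned])
  out
}

#' Fraction of genes above RPM abundance thresholds
#'
#' Fraction of genes whose combined sense + antisense RPM reaches each
#' threshold; weakly decreasing in the threshold.
#'
#' @param counts Gene-count data.frame from [count_gene_reads()].
#' @param thresholds RPM thresholds (default `c(1, 100)`).
#' @return Named numeric vector mapping threshold to gene fraction.
#' @export
abundance_distribution <- function(counts, thresholds = c(1, 100)) {
  if (!nrow(counts)) stop("empty gene list", call. = FALSE)
  tot <- counts$sense_rpm + counts$antisense_rpm
  stats::setNames(vapply(thresholds, function(t) mean(tot >= t), numeric(1)),
                  as.character(thresholds))
}

#' Correlate per-gene counts between two libraries
#'
#' Joins two gene-count tables on `gene_id`, applies a log transform with a
#' pseudocount, and returns Pearson's r. Genes missing from either table
#' are dropped (count in attribute `n_dropped`).
#'
#' @param a,b Gene-count data.frames.
#' @param field_a,field_b Column to correlate in `a` and `b` (e.g.
#'   `"sense_reads"`, `"antisense_rpm"`).
#' @param transform Transformation applied to both sides before
#'   correlating; default `log10(x + 0.1)`.
#' @return list with `r`, `p_value`, `n` (shared genes used).
#' @export
correlate_counts <- function(a, b, field_a = "sense_reads",
                             field_b = "sense_reads",
                             transform = function(x) log10(x + 0.1)) {
  shared <- intersect(a$gene_id, b$gene_id)
  if (length(shared) < 3L) stop("fewer than 3 shared genes", call. = FALSE)
  x <- transform(a[[field_a]][match(shared, a$gene_id)])
  y <- transform(b[[field_b]][match(shared, b$gene_id)])
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance after transform", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  out <- list(r = unname(ct$estimate), p_value = ct$p.value, n = length(shared))
  attr(out, "n_dropped") <- (nrow(a) - length(shared)) + (nrow(b) - length(shared))
  out
}
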