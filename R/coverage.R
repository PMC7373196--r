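#' Build a strand-specific coverage track
#'
#' Every position `p` with `start <= p < end` of an alignment gains that
#' alignment's `count`. In `split` mode the plus and minus strands are kept
#' separately; in `combined` mode they are summed into one vector (the
#' representation used when comparing digestion profiles across samples).
#'
#' @param alignments Alignment data.frame (0-based half-open).
#' @param genome A [Biostrings::DNAStringSet] (defines reference lengths),
#'   or a named integer vector of reference lengths.
#' @param strand_mode `"split"` or `"combined"`.
#' @return A `coverage_track`: list with `chrom`, `values` (named list of
#'   per-position numeric vectors: `plus`/`minus` or `combined`), `scale`
#'   (`"raw"` or `"rpm"`) and `library_size`.
#' @export
build_coverage <- function(alignments, genome, strand_mode = c("split", "combined")) {
  strand_mode <- match.arg(strand_mode)
  check_alignments(alignments)
  lens <- if (is.numeric(genome)) genome else genome_lengths(genome)
  chrom <- names(lens)[1]
  if (length(lens) > 1L && nrow(alignments) &&
      !all(alignments$chrom %in% names(lens)))
    stop("alignments reference unknown chroms", call. = FALSE)
  a <- alignments[alignments$chrom == chrom, , drop = FALSE]
  glen <- lens[[chrom]]
  if (nrow(a) && (any(a$start < 0) || any(a$end > glen)))
    stop("alignment beyond reference bounds", call. = FALSE)
  cov_for <- function(sub) {
    if (!nrow(sub)) return(numeric(glen))
    r <- IRanges::coverage(IRanges::IRanges(sub$start + 1L, sub$end),
                           weight = as.numeric(sub$count), width = glen)
    as.numeric(r)
  }
  values <- if (strand_mode == "split") {
    list(plus = cov_for(a[a$strand == "+", , drop = FALSE]),
         minus = cov_for(a[a$strand == "-", , drop = FALSE]))
  } else {
    list(combined = cov_for(a))
  }
  structure(list(chrom = chrom, values = values, scale = "raw",
                 library_size = sum(alignments$count)),
            class = "coverage_track")
}

#' Scale a coverage track to reads per million (RPM)
#'
#' @param track A `coverage_track` with `scale == "raw"`.
#' @param library_size Total aligned read count used as the RPM
#'   denominator (>= 1); defaults to the library size recorded in the track.
#' @return The track with every value multiplied by `1e6 / library_size`
#'   and `scale` set to `"rpm"`. Scaling an already-scaled track is an
#'   error (no silent double scaling).
#' @export
rpm_scale <- function(track, library_size = track$library_size) {
  stopifnot(inherits(track, "coverage_track"))
  if (track$scale == "rpm") stop("track is already RPM-scaled", call. = FALSE)
  if (is.null(library_size) || library_size < 1)
    stop("library_size must be >= 1", call. = FALSE)
  track$values <- lapply(track$values, function(v) v * 1e6 / library_size)
  track$scale <- "rpm"
  track$library_size <- library_size
  track
}

#' Export a coverage track as bedGraph
#'
#' Writes 0-based half-open bedGraph with runs of equal value merged and
#' zero runs omitted; one file per strand (suffixes `.plus` / `.minus`
#' inserted before the extension) for split tracks, one file for combined
#' tracks. [import_bedgraph()] reproduces the track exactly.
#'
#' @param track A `coverage_track`.
#' @param path Output path (base name for split tracks).
#' @return Invisibly, the vector of files written.
#' @export
export_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  ensure_parent_dir(path)
  files <- character(0)
  for (nm in names(track$values)) {
    f <- if (nm == "combined") path else strand_suffixed(path, nm)
    gr <- run_granges(track$chrom, track$values[[nm]])
    rtracklayer::export(gr, f, format = "bedGraph")
    files <- c(files, f)
  }
  invisible(files)
}

strand_suffixed <- function(path, strand) {
  suff <- paste0(".", strand)
  if (grepl("\\.bedgraph$", path, ignore.case = TRUE))
    sub("(\\.[Bb]ed[Gg]raph)$", paste0(suff, "\\1"), path)
  else paste0(path, suff)
}

## Merge runs of equal nonzero value into a scored GRanges.
run_granges <- function(chrom, values) {
  r <- rle(values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0
  if (!any(keep)) return(GenomicRanges::GRanges(score = numeric(0)))
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(starts[keep], ends[keep]),
                         score = r$values[keep])
}

#' Import a bedGraph coverage file
#'
#' @param path bedGraph file (one strand or combined).
#' @param genome_length Reference length of the track's chromosome.
#' @param chrom Chromosome name; defaults to the one found in the file.
#' @return Per-position numeric vector of length `genome_length`.
#' @export
import_bedgraph <- function(path, genome_length, chrom = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  v <- numeric(genome_length)
  if (length(gr)) {
    if (is.null(chrom)) chrom <- as.character(GenomicRanges::seqnames(gr)[1])
    gr <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
    s <- GenomicRanges::start(gr); e <- GenomicRanges::end(gr)
    for (i in seq_along(gr)) v[s[i]:e[i]] <- gr$score[i]
  }
  v
}

#' Pearson correlation between two positional coverage profiles
#'
#' Combines strands position-wise within the region and computes Pearson's
#' r with a two-sided p-value from the t distribution on n - 2 degrees of
#' freedom. Used to compare digestion/capture profiles of the same
#' reference across samples.
#'
#' @param track_a,track_b `coverage_track` objects over the same reference.
#' @param region Numeric `c(start, end)`, 0-based half-open; `NULL` uses
#'   the whole track.
#' @return list with `r`, `p_value` and `n` (positions compared).
#' @export
compare_profiles <- function(track_a, track_b, region = NULL) {
  va <- combined_values(track_a)
  vb <- combined_values(track_b)
  if (is.null(region)) region <- c(0L, min(length(va), length(vb)))
  idx <- (region[1] + 1L):region[2]
  if (length(idx) < 3L) stop("region must cover at least 3 positions", call. = FALSE)
  x <- va[idx]; y <- vb[idx]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance in a profile", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(idx))
}

combined_values <- function(track) {
  stopifnot(inherits(track, "coverage_track"))
  if (!is.null(track$values$combined)) track$values$combined
  else track$values$plus + track$values$minus
}
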