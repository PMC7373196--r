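#' Collapse alignments into unique read records
#'
#' Identical placements (chrom, start, end, strand) are merged, counts
#' summed and RPM computed from the library size.
#'
#' @param alignments Alignment data.frame.
#' @param library_size RPM denominator.
#' @return data.frame with one row per unique placement: chrom, start,
#'   end, strand, length, count, rpm.
#' @export
collapse_unique <- function(alignments, library_size) {
  check_alignments(alignments)
  if (!nrow(alignments))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), length = integer(),
                      count = integer(), rpm = numeric(),
                      stringsAsFactors = FALSE))
  key <- paste(alignments$chrom, alignments$start, alignments$end,
               alignments$strand, sep = "\r")
  first <- !duplicated(key)
  out <- alignments[first, c("chrom", "start", "end", "strand"), drop = FALSE]
  cnt <- tapply(alignments$count, key, sum)
  out$length <- out$end - out$start
  out$count <- as.numeric(cnt[key[first]])
  out$rpm <- out$count * 1e6 / library_size
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find perfect-duplex RNase III cleavage signatures
#'
#' Emits a duplex site for every pair of unique reads consisting of a
#' plus-strand record at `[a, a + L)` and a minus-strand record at
#' `[a - 2, a + L - 2)` with the same length `L` in `lengths` and both
#' records at `rpm >= min_rpm`. The 2-nt offset puts a 2-nt 3' overhang at
#' both ends of the duplex — the cleavage signature of RNase III. Pairs
#' whose minus interval would start before the reference (`a - 2 < 0`) are
#' skipped and counted.
#'
#' @param records Unique read records from [collapse_unique()].
#' @param lengths Admissible duplex lengths (default `c(21, 22)`).
#' @param min_rpm Minimum RPM of each strand (default 1, inclusive;
#'   `strict = TRUE` switches the comparison to `>`).
#' @param require_equal_length If `FALSE`, also pair plus/minus records
#'   whose lengths differ by one (exploratory; the right-hand overhang is
#'   then 2 +- 1 nt).
#' @param strict Use a strict `> min_rpm` comparison instead of `>=`.
#' @return data.frame sorted by chrom and position, one row per duplex:
#'   chrom, plus_start, plus_end, minus_start, minus_end, length,
#'   paired_start, paired_end, plus_rpm, minus_rpm, plus_count,
#'   minus_count. Attributes: `per_length` (named duplex counts) and
#'   `n_skipped_off_reference`.
#' @export
find_duplexes <- function(records, lengths = c(21L, 22L), min_rpm = 1.0,
                          require_equal_length = TRUE, strict = FALSE) {
  stopifnot(all(lengths %in% 18:30))
  ok_rpm <- if (strict) records$rpm > min_rpm else records$rpm >= min_rpm
  ok <- ok_rpm & records$length %in% lengths
  plus <- records[ok & records$strand == "+", , drop = FALSE]
  minus <- records[ok & records$strand == "-", , drop = FALSE]
  empty <- data.frame(chrom = character(), plus_start = integer(),
                      plus_end = integer(), minus_start = integer(),
                      minus_end = integer(), length = integer(),
                      paired_start = integer(), paired_end = integer(),
                      plus_rpm = numeric(), minus_rpm = numeric(),
                      plus_count = numeric(), minus_count = numeric(),
                      stringsAsFactors = FALSE)
  n_skipped <- sum(plus$start - 2L < 0L)
  plus <- plus[plus$start - 2L >= 0L, , drop = FALSE]
  if (!nrow(plus) || !nrow(minus)) {
    attr(empty, "per_length") <- stats::setNames(integer(length(lengths)),
                                                 as.character(lengths))
    attr(empty, "n_skipped_off_reference") <- n_skipped
    return(empty)
  }
  offsets <- if (require_equal_length) 0L else c(-1L, 0L, 1L)
  out <- list()
  mkey <- paste(minus$chrom, minus$start, minus$end, sep = "\r")
  for (d in offsets) {
    ## partner of plus [a, a+L): minus [a-2, a+L-2+d) of length L+d
    want <- paste(plus$chrom, plus$start - 2L, plus$end - 2L + d, sep = "\r")
    hit <- match(want, mkey)
    sel <- !is.na(hit) & (plus$length + d) %in% lengths
    if (!any(sel)) next
    p <- plus[sel, , drop = FALSE]; m <- minus[hit[sel], , drop = FALSE]
    out[[length(out) + 1L]] <- data.frame(
      chrom = p$chrom, plus_start = p$start, plus_end = p$end,
      minus_start = m$start, minus_end = m$end, length = p$length,
      paired_start = p$start, paired_end = m$end,
      plus_rpm = p$rpm, minus_rpm = m$rpm,
      plus_count = p$count, minus_count = m$count,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    attr(empty, "per_length") <- stats::setNames(integer(length(lengths)),
                                                 as.character(lengths))
    attr(empty, "n_skipped_off_reference") <- n_skipped
    return(empty)
  }
  dup <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  dup <- dup[order(dup$chrom, dup$plus_start, dup$length), , drop = FALSE]
  rownames(dup) <- NULL
  attr(dup, "per_length") <- stats::setNames(
    vapply(lengths, function(L) sum(dup$length == L), integer(1)),
    as.character(lengths))
  attr(dup, "n_skipped_off_reference") <- n_skipped
  dup
}

#' Export the cleavage-site table
#'
#' One row per duplex with 1-based inclusive coordinates for both strands;
#' when a genome is supplied the two overhang dinucleotides (genomic plus
#' strand) are included.
#'
#' @param duplexes Duplex data.frame from [find_duplexes()].
#' @param path Output TSV path.
#' @param genome Optional [Biostrings::DNAStringSet] for overhang
#'   sequences.
#' @return Invisibly, `path`.
#' @export
export_cleavage_table <- function(duplexes, path, genome = NULL) {
  ensure_parent_dir(path)
  tab <- data.frame(
    chrom = duplexes$chrom,
    plus_start_1based = duplexes$plus_start + 1L,
    plus_end_1based = duplexes$plus_end,
    minus_start_1based = duplexes$minus_start + 1L,
    minus_end_1based = duplexes$minus_end,
    length = duplexes$length,
    plus_rpm = duplexes$plus_rpm,
    minus_rpm = duplexes$minus_rpm,
    stringsAsFactors = FALSE)
  if (!is.null(genome) && nrow(duplexes)) {
    gchar <- as.character(genome[[1]])
    tab$overhang_left <- substring(gchar, duplexes$minus_start + 1L,
                                   duplexes$minus_start + 2L)
    tab$overhang_right <- substring(gchar, duplexes$plus_end - 1L,
                                    duplexes$plus_end)
  }
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cleavage-site table written by [export_cleavage_table()]
#'
#' @param path TSV path.
#' @return Duplex data.frame in 0-based half-open coordinates.
#' @export
read_cleavage_table <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!nrow(tab))
    return(data.frame(chrom = character(), plus_start = integer(),
                      plus_end = integer(), minus_start = integer(),
                      minus_end = integer(), length = integer(),
                      plus_rpm = numeric(), minus_rpm = numeric(),
                      stringsAsFactors = FALSE))
  data.frame(chrom = tab$chrom,
             plus_start = tab$plus_start_1based - 1L,
             plus_end = tab$plus_end_1based,
             minus_start = tab$minus_start_1based - 1L,
             minus_end = tab$minus_end_1based,
             length = tab$length,
             plus_rpm = tab$plus_rpm, minus_rpm = tab$minus_rpm,
             stringsAsFactors = FALSE)
}
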