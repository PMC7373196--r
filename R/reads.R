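#' Read small-RNA sequencing reads from FASTA/FASTQ
#'
#' @param path FASTA or FASTQ file (optionally gzipped); the format is
#'   inferred from the extension.
#' @return Character vector of read sequences (names = read ids).
#' @export
read_reads <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
    "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  stats::setNames(as.character(x), names(x))
}

#' Trim a 3' adapter from reads by exact prefix matching
#'
#' Removes the read suffix starting at the leftmost position where the
#' remaining suffix is an exact match to the adapter's first `k >=
#' min_overlap` bases (a full adapter occurrence followed by extra bases is
#' also trimmed at its start). Reads shorter than `min_len` after trimming
#' are discarded; reads with no adapter match are kept unchanged and
#' flagged untrimmed.
#'
#' @param reads Character vector of read sequences.
#' @param adapter Adapter sequence (non-empty).
#' @param min_overlap Minimum adapter prefix length to accept a 3'-end
#'   match (default 3).
#' @param min_len Minimum read length after trimming (default 15).
#' @return list with `sequences` (kept reads), `trimmed` (logical flag per
#'   kept read), `n_discarded` (too short after trimming).
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 3L, min_len = 15L) {
  if (!is.character(adapter) || length(adapter) != 1L || !nzchar(adapter))
    stop("adapter must be a non-empty string", call. = FALSE)
  la <- nchar(adapter)
  trim_at <- vapply(reads, function(r) {
    n <- nchar(r)
    for (i in seq_len(n)) {
      seg_len <- min(n - i + 1L, la)
      if (seg_len >= min_overlap &&
          substr(r, i, i + seg_len - 1L) == substr(adapter, 1L, seg_len)) {
        ## accept only if the match runs to the read end or spans the full adapter
        if (i + seg_len - 1L == n || seg_len == la) return(i)
      }
    }
    0L
  }, integer(1), USE.NAMES = FALSE)
  trimmed <- trim_at > 0L
  out <- ifelse(trimmed, substr(reads, 1L, trim_at - 1L), reads)
  keep <- nchar(out) >= min_len
  list(sequences = out[keep], trimmed = trimmed[keep],
       n_discarded = sum(!keep))
}

#' Map reads to a genome by exact, unique matching
#'
#' A read is reported if and only if its sequence (or its reverse
#' complement) occurs exactly once in the genome, counting both
#' orientations jointly. A forward occurrence is reported on the plus
#' strand, a reverse-complement occurrence on the minus strand.
#' Multi-occurring reads, reads with zero occurrences and reads containing
#' non-ACGT characters are dropped; per-reason counts are attached as the
#' `drop_counts` attribute. Identical read sequences are collapsed before
#' matching and their multiplicity carried in `count`.
#'
#' @param reads Character vector of read sequences.
#' @param genome A [Biostrings::DNAStringSet].
#' @return data.frame of aligned reads (chrom, start, end, strand, length,
#'   sequence, count; 0-based half-open) with attribute `drop_counts`
#'   (named vector: multi, unmapped, invalid).
#' @export
map_exact <- function(reads, genome) {
  if (!length(reads)) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), length = integer(),
                      sequence = character(), count = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "drop_counts") <- c(multi = 0L, unmapped = 0L, invalid = 0L)
    return(out)
  }
  tab <- table(reads)
  uniq <- names(tab)
  mult <- as.integer(tab)
  valid <- !grepl("[^ACGT]", uniq)
  n_invalid <- sum(mult[!valid])
  uniq <- uniq[valid]; mult <- mult[valid]
  hits <- vector("list", length(uniq))
  n_occ <- integer(length(uniq))
  widths <- nchar(uniq)
  for (w in unique(widths)) {
    idx <- which(widths == w)
    pats <- Biostrings::DNAStringSet(uniq[idx])
    pd_f <- Biostrings::PDict(pats)
    pd_r <- Biostrings::PDict(Biostrings::reverseComplement(pats))
    for (ci in seq_along(genome)) {
      subj <- genome[[ci]]
      m_f <- Biostrings::matchPDict(pd_f, subj)
      m_r <- Biostrings::matchPDict(pd_r, subj)
      for (j in seq_along(idx)) {
        sf <- IRanges::start(m_f[[j]]); sr <- IRanges::start(m_r[[j]])
        k <- length(sf) + length(sr)
        if (k == 0L) next
        n_occ[idx[j]] <- n_occ[idx[j]] + k
        if (is.null(hits[[idx[j]]]) && k >= 1L) {
          if (length(sf))
            hits[[idx[j]]] <- list(chrom = names(genome)[ci],
                                   start = sf[1] - 1L, strand = "+")
          else
            hits[[idx[j]]] <- list(chrom = names(genome)[ci],
                                   start = sr[1] - 1L, strand = "-")
        }
      }
    }
  }
  unique_hit <- n_occ == 1L
  n_unmapped <- sum(mult[n_occ == 0L])
  n_multi <- sum(mult[n_occ > 1L])
  keep <- which(unique_hit)
  out <- data.frame(
    chrom = vapply(hits[keep], `[[`, character(1), "chrom"),
    start = vapply(hits[keep], `[[`, integer(1), "start"),
    strand = vapply(hits[keep], `[[`, character(1), "strand"),
    length = widths[keep],
    sequence = uniq[keep],
    count = mult[keep],
    stringsAsFactors = FALSE
  )
  out$end <- out$start + out$length
  out <- out[order(out$chrom, out$start, out$strand),
             c("chrom", "start", "end", "strand", "length", "sequence", "count")]
  rownames(out) <- NULL
  attr(out, "drop_counts") <- c(multi = n_multi, unmapped = n_unmapped,
                                invalid = n_invalid)
  out
}

#' Load pre-computed alignments from SAM or BED6
#'
#' SAM records that are unmapped (flag 0x4), secondary (0x100) or
#' supplementary (0x800) are skipped; coordinates are converted from SAM's
#' 1-based to the package's 0-based half-open convention. BED is taken as
#' 0-based half-open with strand in column 6.
#'
#' @param path SAM (with header) or BED6 file; format inferred from the
#'   extension (`.sam` vs `.bed`).
#' @return Alignment data.frame (chrom, start, end, strand, length, count).
#' @export
load_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) load_sam(path)
  else if (grepl("\\.bed$", path, ignore.case = TRUE)) load_bed6(path)
  else stop("expected a .sam or .bed file: ", path, call. = FALSE)
}

load_sam <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  p <- Rsamtools::ScanBamParam(flag = flags,
                               what = c("rname", "pos", "qwidth", "strand", "cigar"))
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  if (!length(rec$pos))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), length = integer(), count = integer(),
                      stringsAsFactors = FALSE))
  width <- GenomicAlignments_width(rec$cigar, rec$qwidth)
  data.frame(chrom = as.character(rec$rname),
             start = rec$pos - 1L,
             end = rec$pos - 1L + width,
             strand = as.character(rec$strand),
             length = width,
             count = 1L,
             stringsAsFactors = FALSE)
}

## Reference span of each record from the CIGAR; exact-match small-RNA
## alignments are plain '<n>M', for which the span equals the read length.
GenomicAlignments_width <- function(cigar, qwidth) {
  simple <- grepl("^[0-9]+M$", cigar)
  w <- integer(length(cigar))
  w[simple] <- as.integer(sub("M$", "", cigar[simple]))
  if (any(!simple)) {
    ops <- regmatches(cigar[!simple], gregexpr("[0-9]+[MIDNSHP=X]", cigar[!simple]))
    w[!simple] <- vapply(ops, function(o) {
      n <- as.integer(sub("[A-Z=]$", "", o))
      type <- sub("^[0-9]+", "", o)
      sum(n[type %in% c("M", "D", "N", "=", "X")])
    }, integer(1))
  }
  w
}

load_bed6 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), length = integer(), count = integer(),
                      stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L))
    stop("malformed BED6 record at line ", which(nf < 6L)[1], " of ", path,
         call. = FALSE)
  start <- as.integer(vapply(fields, `[[`, character(1), 2L))
  end <- as.integer(vapply(fields, `[[`, character(1), 3L))
  strand <- vapply(fields, `[[`, character(1), 6L)
  if (any(is.na(start)) || any(is.na(end)) || any(!strand %in% c("+", "-")))
    stop("malformed BED6 record at line ",
         which(is.na(start) | is.na(end) | !strand %in% c("+", "-"))[1],
         " of ", path, call. = FALSE)
  data.frame(chrom = vapply(fields, `[[`, character(1), 1L),
             start = start, end = end, strand = strand,
             length = end - start, count = 1L, stringsAsFactors = FALSE)
}

#' Read-length distribution
#'
#' @param x Character vector of read sequences, or an alignment data.frame
#'   (lengths weighted by `count`).
#' @return Named numeric vector mapping length to fraction (sums to 1).
#' @export
length_histogram <- function(x) {
  if (is.character(x)) {
    len <- nchar(x); wt <- rep(1, length(len))
  } else if (is_alignment_frame(x)) {
    len <- x$end - x$start; wt <- x$count
  } else stop("x must be read sequences or an alignment data.frame", call. = FALSE)
  if (!length(len)) stop("empty input", call. = FALSE)
  tot <- tapply(wt, len, sum)
  frac <- as.numeric(tot) / sum(wt)
  stats::setNames(frac, names(tot))
}
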