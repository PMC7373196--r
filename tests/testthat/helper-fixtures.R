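## Shared fixtures and independent brute-force oracles used across tests.

## Alignment data.frame constructor (0-based half-open).
aln <- function(chrom, start, end, strand, count = 1L) {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             strand = strand, length = as.integer(end - start),
             count = as.integer(count), stringsAsFactors = FALSE)
}

## Random alignment set on a single reference.
random_alignments <- function(n, glen, chrom = "chr", min_len = 18L,
                              max_len = 30L) {
  len <- sample(min_len:max_len, n, replace = TRUE)
  start <- vapply(len, function(l) sample.int(glen - l, 1L) - 1L, integer(1))
  aln(chrom, start, start + len, sample(c("+", "-"), n, replace = TRUE),
      count = sample(1:3, n, replace = TRUE))
}

## Brute-force per-base coverage oracle: loops over every alignment and
## every covered position.
coverage_oracle <- function(alignments, glen, strand = NULL) {
  v <- numeric(glen)
  for (i in seq_len(nrow(alignments))) {
    if (!is.null(strand) && alignments$strand[i] != strand) next
    for (p in alignments$start[i]:(alignments$end[i] - 1L))
      v[p + 1L] <- v[p + 1L] + alignments$count[i]
  }
  v
}

## Brute-force duplex oracle: all plus x minus pairs, checking the 2-nt
## offset geometry, equal length, admissible length and RPM directly.
duplex_oracle <- function(records, lengths = c(21L, 22L), min_rpm = 1.0) {
  plus <- records[records$strand == "+", , drop = FALSE]
  minus <- records[records$strand == "-", , drop = FALSE]
  found <- list()
  for (i in seq_len(nrow(plus))) for (j in seq_len(nrow(minus))) {
    p <- plus[i, ]; m <- minus[j, ]
    if (p$chrom != m$chrom) next
    if (m$start != p$start - 2L || m$end != p$end - 2L) next
    if (p$length != m$length || !(p$length %in% lengths)) next
    if (p$rpm < min_rpm || m$rpm < min_rpm) next
    if (p$start - 2L < 0L) next
    found[[length(found) + 1L]] <-
      data.frame(chrom = p$chrom, plus_start = p$start, plus_end = p$end,
                 length = p$length, stringsAsFactors = FALSE)
  }
  if (!length(found))
    return(data.frame(chrom = character(), plus_start = integer(),
                      plus_end = integer(), length = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, found)
  out <- out[order(out$chrom, out$plus_start, out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## All-pairs duplex oracle, vectorized over the full plus x minus cross
## product (same exhaustive check as duplex_oracle, usable at n ~ 2000).
duplex_oracle_fast <- function(records, lengths = c(21L, 22L), min_rpm = 1.0) {
  plus <- records[records$strand == "+", , drop = FALSE]
  minus <- records[records$strand == "-", , drop = FALSE]
  empty <- data.frame(chrom = character(), plus_start = integer(),
                      plus_end = integer(), length = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(plus) || !nrow(minus)) return(empty)
  ip <- rep(seq_len(nrow(plus)), each = nrow(minus))
  im <- rep(seq_len(nrow(minus)), times = nrow(plus))
  ok <- plus$chrom[ip] == minus$chrom[im] &
    minus$start[im] == plus$start[ip] - 2L &
    minus$end[im] == plus$end[ip] - 2L &
    plus$length[ip] == minus$length[im] &
    plus$length[ip] %in% lengths &
    plus$rpm[ip] >= min_rpm & minus$rpm[im] >= min_rpm &
    plus$start[ip] >= 2L
  if (!any(ok)) return(empty)
  out <- data.frame(chrom = plus$chrom[ip[ok]],
                    plus_start = plus$start[ip[ok]],
                    plus_end = plus$end[ip[ok]],
                    length = plus$length[ip[ok]], stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$plus_start, out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Random unique-read records, salted with plus/minus pairs at the duplex
## offset so the oracle has true positives to find.
random_records <- function(n, glen, n_planted = 10L, chrom = "chr") {
  len <- sample(c(20L, 21L, 22L, 23L), n, replace = TRUE)
  start <- vapply(len, function(l) sample.int(glen - l - 4L, 1L) + 2L, integer(1))
  rec <- data.frame(chrom = chrom, start = start, end = start + len,
                    strand = sample(c("+", "-"), n, replace = TRUE),
                    length = len,
                    rpm = round(stats::runif(n, 0.2, 5), 2),
                    count = 1L, stringsAsFactors = FALSE)
  if (n_planted > 0L) {
    L <- sample(c(21L, 22L), n_planted, replace = TRUE)
    a <- vapply(L, function(l) sample.int(glen - l - 4L, 1L) + 2L, integer(1))
    pairs <- rbind(
      data.frame(chrom = chrom, start = a, end = a + L, strand = "+",
                 length = L, rpm = round(stats::runif(n_planted, 0.2, 5), 2),
                 count = 1L, stringsAsFactors = FALSE),
      data.frame(chrom = chrom, start = a - 2L, end = a + L - 2L, strand = "-",
                 length = L, rpm = round(stats::runif(n_planted, 0.2, 5), 2),
                 count = 1L, stringsAsFactors = FALSE))
    rec <- rbind(rec, pairs)
  }
  ## collapse_unique semantics: one record per placement
  key <- paste(rec$chrom, rec$start, rec$end, rec$strand)
  rec[!duplicated(key), , drop = FALSE]
}

## Brute-force cluster oracle: enumerates every window offset explicitly
## and reports tight spans of 5' ends in maximal qualifying-window groups.
cluster_oracle <- function(alignments, window, min_reads) {
  p5 <- ifelse(alignments$strand == "+", alignments$start,
               alignments$end - 1L)
  wt <- alignments$count
  lo <- min(p5); hi <- max(p5)
  offs <- lo:hi
  counts <- vapply(offs, function(w) sum(wt[p5 >= w & p5 < w + window]),
                   numeric(1))
  qual <- offs[counts >= min_reads]
  if (!length(qual)) return(NULL)
  grp <- cumsum(c(1, diff(qual) > window))
  spans <- lapply(split(qual, grp), function(q) {
    sel <- p5 >= q[1] & p5 < q[length(q)] + window
    c(start = min(p5[sel]), end = max(p5[sel]) + 1L,
      total = sum(wt[sel]))
  })
  do.call(rbind, spans)
}

## Small simulation used by several suites: mixed architectures, zero
## noise, threshold scaled to the desk-size library.
small_sim_config <- function(seed = 42L, noise = 0L, n_each = 5L,
                             abundance = 60L, min_reads = 50L, ...) {
  plan <- data.frame(
    architecture = rep(c("divergent5", "convergent3", "full_overlap",
                         "novel_as"), each = n_each),
    overlap_length = 200L, abundance = abundance, stringsAsFactors = FALSE)
  ## each locus occupies overlap + 2*extension + spacing = 700 bases
  sim_config(genome_length = 4L * n_each * 700L + 2000L, locus_plan = plan,
             noise_read_count = noise, cluster_min_reads = min_reads,
             seed = seed, ...)
}
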