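#' Cluster-calling parameters
#'
#' A dsRNA read cluster is a genomic region containing at least
#' `min_reads` reads (both strands pooled) within some 200-bp window;
#' windows are considered at every base offset. Exactly one of `min_reads`
#' or `min_rpm` must be given; `min_rpm` is converted to a read threshold
#' with the library size at call time.
#'
#' @param window Window width in bases (default 200).
#' @param min_reads Read-count threshold (default 2000).
#' @param min_rpm RPM threshold (alternative to `min_reads`).
#' @param merge_gap Maximum genomic gap between qualifying windows merged
#'   into one cluster (default 0: windows must touch or overlap).
#' @return list of class `cluster_params`.
#' @export
cluster_params <- function(window = 200L, min_reads = 2000L, min_rpm = NULL,
                           merge_gap = 0L) {
  if (window < 1) stop("window must be >= 1", call. = FALSE)
  if (!is.null(min_rpm)) min_reads <- NULL
  if (is.null(min_reads) && is.null(min_rpm))
    stop("set exactly one of min_reads or min_rpm", call. = FALSE)
  structure(list(window = as.integer(window), min_reads = min_reads,
                 min_rpm = min_rpm, merge_gap = as.integer(merge_gap)),
            class = "cluster_params")
}

#' Call p19-captured dsRNA read clusters
#'
#' Reads are localized by their 5' end (start on the plus strand, `end - 1`
#' on the minus strand). A window offset `w` qualifies when the number of
#' 5' ends in `[w, w + window)` reaches the threshold; every maximal run of
#' qualifying windows whose intervals are separated by at most `merge_gap`
#' bases becomes one cluster. The reported cluster interval is the tight
#' span of the 5' ends assigned to the run's qualifying windows, which can
#' be much narrower than the window itself. Clusters are ordered by RPM
#' descending.
#'
#' @param alignments Alignment data.frame.
#' @param params A [cluster_params()].
#' @param library_size RPM denominator.
#' @return data.frame with one row per cluster: id, chrom, start, end
#'   (0-based half-open), total_reads, total_rpm, sense_reads,
#'   antisense_reads, peak_window_reads.
#' @export
call_clusters <- function(alignments, params = cluster_params(), library_size) {
  check_alignments(alignments)
  empty <- data.frame(id = character(), chrom = character(), start = integer(),
                      end = integer(), total_reads = numeric(),
                      total_rpm = numeric(), sense_reads = numeric(),
                      antisense_reads = numeric(), peak_window_reads = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(alignments)) return(empty)
  thr <- if (!is.null(params$min_reads)) params$min_reads
         else params$min_rpm * library_size / 1e6
  w <- params$window
  out <- list()
  for (chrom in unique(alignments$chrom)) {
    a <- alignments[alignments$chrom == chrom, , drop = FALSE]
    p5 <- five_prime_end(a)
    lo <- min(p5); hi <- max(p5)
    ## counts of 5' ends per position over [lo, hi]
    counts <- numeric(hi - lo + 1L)
    agg <- tapply(a$count, p5, sum)
    counts[as.integer(names(agg)) - lo + 1L] <- as.numeric(agg)
    ## window sums at every offset via cumulative sums (sweep form)
    cs <- c(0, cumsum(counts))
    n_off <- length(counts)  # offsets lo .. hi (window may extend past hi)
    wsum <- cs[pmin(seq_len(n_off) + w, length(cs))] - cs[seq_len(n_off)]
    qual <- which(wsum >= thr)  # 1-based offset index; genomic w0 = lo + qual - 1
    if (!length(qual)) next
    ## merge qualifying windows whose intervals are within merge_gap bases
    brk <- which(diff(qual) > w + params$merge_gap)
    run_start <- c(1L, brk + 1L)
    run_end <- c(brk, length(qual))
    for (k in seq_along(run_start)) {
      offs <- qual[run_start[k]:run_end[k]] + lo - 1L
      sel <- p5 >= offs[1] & p5 < offs[length(offs)] + w
      span <- range(p5[sel])
      sense <- sum(a$count[sel & a$strand == "+"])
      anti <- sum(a$count[sel & a$strand == "-"])
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = span[1], end = span[2] + 1L,
        total_reads = sense + anti,
        total_rpm = (sense + anti) * 1e6 / library_size,
        sense_reads = sense, antisense_reads = anti,
        peak_window_reads = max(wsum[qual[run_start[k]:run_end[k]]]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  cl <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  cl <- cl[order(-cl$total_rpm, cl$chrom, cl$start), , drop = FALSE]
  cl <- cbind(id = sprintf("C-%03d", seq_len(nrow(cl))), cl,
              stringsAsFactors = FALSE)
  rownames(cl) <- NULL
  cl
}

#' Assign clusters to abundance deciles
#'
#' Clusters sorted by `total_rpm` descending are split into 10 groups of
#' near-equal size (sizes differ by at most one member); decile 1 holds the
#' most abundant 10%. Ties in RPM are broken by genomic coordinate so the
#' assignment is deterministic.
#'
#' @param clusters Cluster data.frame from [call_clusters()].
#' @return Named integer vector mapping cluster id to decile 1..10.
#' @export
rank_deciles <- function(clusters) {
  n <- nrow(clusters)
  if (!n) stop("no clusters to rank", call. = FALSE)
  ord <- order(-clusters$total_rpm, clusters$chrom, clusters$start)
  sizes <- rep(n %/% 10L, 10L) + (seq_len(10L) <= n %% 10L)
  dec <- rep(1:10, sizes)
  stats::setNames(dec[order(ord)], clusters$id)[clusters$id]
}

#' Export clusters as BED6+ and a 1-based report table
#'
#' Writes `clusters.bed` (chrom, start, end, id, total_rpm, ".",
#' sense_reads, antisense_reads; 0-based half-open) and `clusters.tsv`
#' with 1-based inclusive genome coordinates as used in report tables.
#'
#' @param clusters Cluster data.frame.
#' @param dir Output directory.
#' @return Invisibly, the files written.
#' @export
export_clusters <- function(clusters, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bed <- file.path(dir, "clusters.bed")
  write.table(
    data.frame(clusters$chrom, clusters$start, clusters$end, clusters$id,
               round(clusters$total_rpm, 1), ".",
               clusters$sense_reads, clusters$antisense_reads),
    bed, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  tsv <- file.path(dir, "clusters.tsv")
  rep_tab <- data.frame(
    cluster = clusters$id, chrom = clusters$chrom,
    coord_start = clusters$start + 1L, coord_end = clusters$end,
    total_rpm = clusters$total_rpm, total_reads = clusters$total_reads,
    sense_reads = clusters$sense_reads,
    antisense_reads = clusters$antisense_reads,
    stringsAsFactors = FALSE)
  write.table(rep_tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(bed, tsv))
}
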