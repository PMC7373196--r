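#' Read an external feature set from BED or a TSS position list
#'
#' BED3/BED6 intervals are read 0-based half-open. A two-column TSV
#' (chrom, position; 1-based) is converted to 1-bp point features.
#'
#' @param path BED file or two-column TSV.
#' @param kind `"interval"` or `"point"`.
#' @param name Feature-set label.
#' @return data.frame with chrom, start, end (and strand when present)
#'   plus attributes `name` and `kind`.
#' @export
read_features <- function(path, kind = c("interval", "point"),
                          name = basename(path)) {
  kind <- match.arg(kind)
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    out <- data.frame(
      chrom = vapply(fields, `[[`, character(1), 1L),
      start = as.integer(vapply(fields, `[[`, character(1), 2L)),
      end = as.integer(vapply(fields, `[[`, character(1), 3L)),
      stringsAsFactors = FALSE)
    if (all(lengths(fields) >= 6L))
      out$strand <- vapply(fields, `[[`, character(1), 6L)
  } else {
    tab <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
    out <- data.frame(chrom = tab[[1]], start = as.integer(tab[[2]]) - 1L,
                      end = as.integer(tab[[2]]), stringsAsFactors = FALSE)
    kind <- "point"
  }
  if (kind == "point" && any(out$end - out$start != 1L))
    stop("point features must have width 1", call. = FALSE)
  attr(out, "name") <- name
  attr(out, "kind") <- kind
  out
}

#' Count clusters overlapping a feature set
#'
#' A cluster overlaps when it shares at least `min_overlap` bases with at
#' least one feature; strand is ignored.
#'
#' @param clusters Cluster data.frame from [call_clusters()].
#' @param features Feature data.frame (chrom, start, end; 0-based
#'   half-open).
#' @param min_overlap Minimum shared bases (default 1).
#' @return list with `n` (overlapping clusters) and `ids`.
#' @export
overlap_count <- function(clusters, features, min_overlap = 1L) {
  if (!nrow(clusters)) return(list(n = 0L, ids = character(0)))
  if (nrow(features) &&
      !any(features$chrom %in% clusters$chrom))
    stop("feature chroms do not match cluster chroms", call. = FALSE)
  cl <- GenomicRanges::GRanges(clusters$chrom,
                               IRanges::IRanges(clusters$start + 1L, clusters$end))
  ft <- GenomicRanges::GRanges(features$chrom,
                               IRanges::IRanges(features$start + 1L, features$end))
  hits <- GenomicRanges::findOverlaps(cl, ft, minoverlap = min_overlap)
  ids <- clusters$id[sort(unique(S4Vectors::queryHits(hits)))]
  list(n = length(ids), ids = ids)
}

#' Per-decile fraction of clusters overlapping a feature set
#'
#' @param clusters Cluster data.frame.
#' @param decile_map Named decile assignment from [rank_deciles()].
#' @param features Feature data.frame.
#' @param min_overlap Minimum shared bases.
#' @return Numeric vector of length 10: fraction of each decile's clusters
#'   overlapping the features; `NA` for deciles with no clusters.
#' @export
decile_overlap <- function(clusters, decile_map, features, min_overlap = 1L) {
  ov <- overlap_count(clusters, features, min_overlap)
  hit <- clusters$id %in% ov$ids
  dec <- decile_map[clusters$id]
  vapply(1:10, function(d) {
    sel <- dec == d
    if (!any(sel)) NA_real_ else mean(hit[sel])
  }, numeric(1))
}

#' Clusters containing a TSS within a flank of the cluster region
#'
#' A cluster counts when at least one TSS position `t` (0-based) satisfies
#' `start - flank <= t < end + flank`; strand is ignored.
#'
#' @param clusters Cluster data.frame.
#' @param tss Point feature data.frame (width-1 intervals).
#' @param flank Flank in bases on either side (default 50, >= 0).
#' @return list with `n` and `ids`.
#' @export
tss_proximity <- function(clusters, tss, flank = 50L) {
  if (flank < 0) stop("flank must be >= 0", call. = FALSE)
  if (!nrow(clusters)) return(list(n = 0L, ids = character(0)))
  hit <- vapply(seq_len(nrow(clusters)), function(i) {
    t <- tss$start[tss$chrom == clusters$chrom[i]]
    any(t >= clusters$start[i] - flank & t < clusters$end[i] + flank)
  }, logical(1))
  list(n = sum(hit), ids = clusters$id[hit])
}

## Reads-with-5'-end-inside counts for a set of intervals.
reads_in_intervals <- function(p5, counts, chrom_of_reads, intervals) {
  vapply(seq_len(nrow(intervals)), function(i) {
    sel <- chrom_of_reads == intervals$chrom[i] &
      p5 >= intervals$start[i] & p5 < intervals$end[i]
    sum(counts[sel])
  }, numeric(1))
}

#' Compare dsRNA read density between two interval groups
#'
#' Computes per-interval RPKM (reads with 5' end inside the interval,
#' scaled by `1e9 / (library_size * length)`) for a 5'-overlap group and a
#' 3'-overlap group, the fold change of their means (arithmetic headline;
#' geometric also reported), a two-sided Mann-Whitney U p-value between the
#' groups, and an empirical p-value for each group against
#' `n_control_sets` random interval sets with the identical length
#' multiset placed uniformly on the reference.
#'
#' @param alignments Alignment data.frame.
#' @param group5,group3 Interval data.frames (chrom, start, end), e.g. the
#'   5'-overlap regions of divergent operons and the 3'-overlap regions of
#'   convergent operons.
#' @param library_size RPM/RPKM denominator.
#' @param genome_lengths Named vector of reference lengths.
#' @param n_control_sets Number of matched random control sets per group.
#' @param seed Integer seed for control placement.
#' @return list with per-group results (`rpkm`, `mean_rpkm`,
#'   `geo_mean_rpkm`, `empirical_p`), `fold_change` (mean 5' / mean 3';
#'   `Inf` flagged via `fold_change_finite = FALSE` when group3 has zero
#'   density), `geo_fold_change`, `p_value` (Mann-Whitney), `n_control_sets`
#'   and `seed`.
#' @export
region_density_compare <- function(alignments, group5, group3, library_size,
                                   genome_lengths, n_control_sets = 100L,
                                   seed = 1L) {
  check_alignments(alignments)
  if (!nrow(group5) || !nrow(group3)) stop("both groups must be non-empty", call. = FALSE)
  for (g in list(group5, group3))
    if (any(g$end - g$start > genome_lengths[g$chrom]))
      stop("interval longer than its reference", call. = FALSE)
  p5 <- five_prime_end(alignments)
  rpkm_of <- function(intervals) {
    n <- reads_in_intervals(p5, alignments$count, alignments$chrom, intervals)
    n * 1e9 / (library_size * (intervals$end - intervals$start))
  }
  r5 <- rpkm_of(group5); r3 <- rpkm_of(group3)
  geo <- function(x) exp(mean(log(x + 0.1))) - 0.1
  control_means <- function(intervals, k) {
    lens <- intervals$end - intervals$start
    vapply(seq_len(n_control_sets), function(s) {
      ctrl <- place_random_intervals(lens, genome_lengths)
      mean(rpkm_of(ctrl))
    }, numeric(1))
  }
  with_seed(seed, {
    cm5 <- control_means(group5, 1L)
    cm3 <- control_means(group3, 2L)
  })
  emp_p <- function(obs, ctrl) (1 + sum(ctrl >= obs)) / (length(ctrl) + 1)
  mw <- suppressWarnings(stats::wilcox.test(r5, r3, alternative = "two.sided",
                                            exact = FALSE))
  fold <- mean(r5) / mean(r3)
  list(
    group5 = list(rpkm = r5, mean_rpkm = mean(r5), geo_mean_rpkm = geo(r5),
                  empirical_p = emp_p(mean(r5), cm5), control_means = cm5),
    group3 = list(rpkm = r3, mean_rpkm = mean(r3), geo_mean_rpkm = geo(r3),
                  empirical_p = emp_p(mean(r3), cm3), control_means = cm3),
    fold_change = fold,
    fold_change_finite = is.finite(fold),
    geo_fold_change = (geo(r5) + 0.1) / (geo(r3) + 0.1),
    p_value = mw$p.value,
    n_control_sets = n_control_sets,
    seed = seed
  )
}

## Uniformly placed intervals with a given length multiset; chromosomes
## sampled proportionally to the number of admissible start positions.
place_random_intervals <- function(lens, genome_lengths) {
  chroms <- names(genome_lengths)
  out <- data.frame(chrom = character(length(lens)),
                    start = integer(length(lens)),
                    end = integer(length(lens)), stringsAsFactors = FALSE)
  for (i in seq_along(lens)) {
    slots <- pmax(genome_lengths - lens[i] + 1, 0)
    if (all(slots == 0)) stop("interval longer than every reference", call. = FALSE)
    ci <- if (length(chroms) == 1L) 1L else
      sample.int(length(chroms), 1L, prob = slots)
    s <- sample.int(slots[ci], 1L) - 1L
    out$chrom[i] <- chroms[ci]; out$start[i] <- s; out$end[i] <- s + lens[i]
  }
  out
}
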