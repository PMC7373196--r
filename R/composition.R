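#' Positional composition parameters for fixed-length duplex reads
#'
#' Defines the region map used when the RNase III double-cleavage geometry
#' is modeled onto a read of length `L` with `flank`-nt genomic flanks.
#' Read positions are 1-based (`1..L`); flank positions are negative
#' (upstream) or `> L` (downstream); there is no position 0. Regions:
#'
#' * `body`: positions `4..L-5` (4..17 for L = 22, 4..16 for L = 21), the
#'   central duplex section where p19 shows its GC preference.
#' * `overhang_partner`: positions `-2, -1` — the partner strand's 2-nt 3'
#'   overhang, upstream of the read on its own strand.
#' * `overhang_this`: positions `L-1, L` — this strand's 3' overhang.
#' * `cleavage_flank`: four 3-nt windows immediately inside/outside the
#'   two modeled scissile positions: `-5..-3`, `1..3`, `L-4..L-2`,
#'   `L+1..L+3`.
#' * `background`: the remaining flank positions.
#'
#' The regions partition positions `-flank..L+flank` exactly.
#'
#' @param read_length Read length `L` (21 or 22).
#' @param flank Genomic flank length in nt (default 10).
#' @return list of class `composition_params` with `L`, `flank`,
#'   `positions` (ordered position vector) and `region` (factor parallel to
#'   `positions`).
#' @export
composition_params <- function(read_length = 22L, flank = 10L) {
  L <- as.integer(read_length)
  F <- as.integer(flank)
  stopifnot(L %in% 18:30, F >= 6L)
  positions <- c(seq(-F, -1L), seq_len(L), seq(L + 1L, L + F))
  region <- character(length(positions))
  assign_region <- function(pos, label) {
    region[match(pos, positions)] <<- label
  }
  assign_region(seq(4L, L - 5L), "body")
  assign_region(c(-2L, -1L), "overhang_partner")
  assign_region(c(L - 1L, L), "overhang_this")
  assign_region(c(-5L:-3L, 1L:3L, (L - 4L):(L - 2L), (L + 1L):(L + 3L)),
                "cleavage_flank")
  region[region == ""] <- "background"
  structure(list(L = L, flank = F, positions = positions,
                 region = factor(region, levels = c("body", "overhang_partner",
                                                    "overhang_this",
                                                    "cleavage_flank",
                                                    "background"))),
            class = "composition_params")
}

## Character matrix (sequences x positions) of reads plus flanks, in read
## orientation: minus-strand records are reverse-complemented so that
## position 1 is the read's own 5' end. Records whose flanks would run off
## the reference are dropped (count returned in attribute).
flanked_base_matrix <- function(records, genome, params) {
  L <- params$L; F <- params$flank
  glen <- stats::setNames(Biostrings::width(genome), names(genome))
  ok <- records$start - F >= 0L & records$end + F <= glen[records$chrom]
  n_skipped <- sum(!ok)
  rec <- records[ok, , drop = FALSE]
  if (!nrow(rec)) stop("no usable sequences for the profile", call. = FALSE)
  gchar <- lapply(seq_along(genome), function(i) as.character(genome[[i]]))
  names(gchar) <- names(genome)
  seqs <- vapply(seq_len(nrow(rec)), function(i) {
    substring(gchar[[rec$chrom[i]]], rec$start[i] - F + 1L, rec$end[i] + F)
  }, character(1))
  ds <- Biostrings::DNAStringSet(seqs)
  minus <- rec$strand == "-"
  if (any(minus)) ds[minus] <- Biostrings::reverseComplement(ds[minus])
  m <- as.matrix(ds)
  attr(m, "records") <- rec
  attr(m, "n_skipped") <- n_skipped
  m
}

#' Positional GC profile of fixed-length reads with genomic flanks
#'
#' Computes the per-position GC fraction across all included read records
#' at positions `-flank..L+flank`, with flanks taken on the read's own
#' strand (reverse-complemented for minus-strand records) so that position
#' semantics match the cleavage geometry. Records below `min_rpm` and
#' records whose flanks fall outside the reference are excluded (the
#' latter counted in attribute `n_skipped`).
#'
#' @param records Unique read records (all of length `params$L`) from
#'   [collapse_unique()], or any alignment frame with an `rpm` column
#'   (absent `rpm` is treated as passing).
#' @param genome A [Biostrings::DNAStringSet].
#' @param params A [composition_params()].
#' @param weighting `"unique"` (each unique sequence weight 1) or
#'   `"abundance"` (weight = read count).
#' @param min_rpm Exclude records below this RPM (default 0 = keep all).
#' @return data.frame of class `composition_profile`: position,
#'   gc_fraction, region, n (sequences used), with attributes `L`,
#'   `weighting`, `body_gc` (per-sequence body GC fractions, for
#'   downstream tests) and `n_skipped`.
#' @export
positional_gc <- function(records, genome, params = composition_params(),
                          weighting = c("unique", "abundance"), min_rpm = 0) {
  weighting <- match.arg(weighting)
  if (!nrow(records)) stop("no records", call. = FALSE)
  if (!all(records$end - records$start == params$L))
    stop("all records must have length ", params$L, call. = FALSE)
  if (!is.null(records$rpm)) records <- records[records$rpm >= min_rpm, , drop = FALSE]
  if (!nrow(records)) stop("no records at rpm >= ", min_rpm, call. = FALSE)
  m <- flanked_base_matrix(records, genome, params)
  rec <- attr(m, "records")
  w <- if (weighting == "abundance" && !is.null(rec$count)) rec$count
       else rep(1, nrow(m))
  gc <- (m == "G" | m == "C") * 1
  frac <- colSums(gc * w) / sum(w)
  body_cols <- which(params$region == "body")
  out <- data.frame(position = params$positions,
                    gc_fraction = unname(frac),
                    region = params$region,
                    n = nrow(m))
  class(out) <- c("composition_profile", class(out))
  attr(out, "L") <- params$L
  attr(out, "weighting") <- weighting
  attr(out, "body_gc") <- rowMeans(gc[, body_cols, drop = FALSE])
  attr(out, "n_skipped") <- attr(m, "n_skipped")
  out
}

#' Mean GC per composition region
#'
#' @param profile A `composition_profile` from [positional_gc()].
#' @return Named numeric vector of mean GC fraction per region (body,
#'   overhang_partner, overhang_this, cleavage_flank, background) plus
#'   `overhang` (both overhang regions pooled).
#' @export
region_summary <- function(profile) {
  oh <- profile$region %in% c("overhang_partner", "overhang_this")
  out <- vapply(levels(profile$region),
                function(r) mean(profile$gc_fraction[profile$region == r]),
                numeric(1))
  c(out, overhang = mean(profile$gc_fraction[oh]))
}

#' Compare duplex-body GC between two read sets
#'
#' Computes each sequence's GC fraction over the body region (positions
#' `4..L-5`) and compares the two sets with a two-sided Mann-Whitney U
#' test. Directionally, p19-captured products are expected to be GC-richer
#' in the body than the pre-capture digestion pool.
#'
#' @param records_a,records_b Read record frames (length `params$L`).
#' @param genome A [Biostrings::DNAStringSet].
#' @param params A [composition_params()].
#' @return list with `delta_mean` (mean body GC of a minus b), `p_value`,
#'   `n_a`, `n_b`.
#' @export
compare_body_gc <- function(records_a, records_b, genome,
                            params = composition_params()) {
  if (nrow(records_a) < 2L || nrow(records_b) < 2L)
    stop("each set needs at least 2 sequences", call. = FALSE)
  body_of <- function(records) {
    m <- flanked_base_matrix(records, genome, params)
    gc <- (m == "G" | m == "C") * 1
    rowMeans(gc[, params$region == "body", drop = FALSE])
  }
  a <- body_of(records_a); b <- body_of(records_b)
  p <- if (stats::sd(c(a, b)) == 0) 1 else  # fully tied: no evidence at all
    suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided",
                                        exact = FALSE, correct = TRUE))$p.value
  list(delta_mean = mean(a) - mean(b), p_value = p,
       n_a = length(a), n_b = length(b))
}
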