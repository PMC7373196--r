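#' @keywords internal
"_PACKAGE"

#' @import methods
#' @importFrom stats rnorm rpois runif cor.test wilcox.test qbinom setNames
#' @importFrom utils write.table read.table head tail
NULL

## Run `code` under a fixed RNG seed without clobbering the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

## Deterministic per-stage seed fan-out from one user-facing seed.
## Stage index k is a small integer; keeps the result inside 32-bit range.
derive_seed <- function(seed, k) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(k)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single non-missing number", name), call. = FALSE)
}

## Named vector of reference lengths from a DNAStringSet genome.
genome_lengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}

is_alignment_frame <- function(x) {
  is.data.frame(x) &&
    all(c("chrom", "start", "end", "strand", "count") %in% names(x))
}

check_alignments <- function(alignments) {
  if (!is_alignment_frame(alignments))
    stop("alignments must be a data.frame with columns chrom, start, end, strand, count",
         call. = FALSE)
  if (nrow(alignments) && any(alignments$start >= alignments$end))
    stop("alignment intervals must satisfy start < end (0-based half-open)",
         call. = FALSE)
  invisible(alignments)
}

## 5' end of each alignment in 0-based genomic coordinates:
## start for plus-strand reads, end - 1 for minus-strand reads.
five_prime_end <- function(alignments) {
  ifelse(alignments$strand == "+", alignments$start, alignments$end - 1L)
}

## Tiny helper used by several exporters.
ensure_parent_dir <- function(path) {
  d <- dirname(path)
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  invisible(path)
}
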