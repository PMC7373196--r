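#' Generate a random genome sequence
#'
#' Draws a single-record genome with independent bases at a given GC
#' fraction: P(G) = P(C) = gc/2 and P(A) = P(T) = (1 - gc)/2. Used by the
#' synthetic-data generator as the reference sequence that overlapping
#' sense/antisense loci are planted into.
#'
#' @param length Genome length in bases (>= 1).
#' @param gc GC fraction in `[0, 1]`.
#' @param seed Integer seed; a fixed seed gives an identical genome.
#' @param name Sequence name of the single record.
#' @return A [Biostrings::DNAStringSet] with one named record.
#' @examples
#' g <- generate_genome(1000, 0.5, seed = 1)
#' Biostrings::letterFrequency(g[[1]], "GC", as.prob = TRUE)
#' @export
generate_genome <- function(length, gc, seed = NULL, name = "synth") {
  stopifnot_scalar_number(length, "length")
  stopifnot_scalar_number(gc, "gc")
  if (length < 1) stop("genome length must be >= 1", call. = FALSE)
  if (gc < 0 || gc > 1) stop("gc must lie in [0, 1]", call. = FALSE)
  bases <- with_seed(seed, sample(c("A", "C", "G", "T"), size = length,
                                  replace = TRUE,
                                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)))
  genome <- Biostrings::DNAStringSet(paste0(bases, collapse = ""))
  names(genome) <- name
  genome
}

#' Read a reference genome from FASTA
#'
#' @param path FASTA file (optionally gzipped).
#' @return A [Biostrings::DNAStringSet]; record names are truncated at the
#'   first whitespace, matching common aligner behaviour.
#' @export
read_genome <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (!length(genome)) stop("no sequences in ", path, call. = FALSE)
  genome
}

#' Write a genome to FASTA
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param path Output path.
#' @export
write_genome <- function(genome, path) {
  ensure_parent_dir(path)
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}
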