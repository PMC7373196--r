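#' Simulation configuration for synthetic p19-capture data
#'
#' Builds the configuration object consumed by [plant_loci()],
#' [digest_duplexes()], [p19_capture()] and [emit_reads()]. The generator
#' emulates the statistical structure the downstream analysis assumes:
#' overlapping sense/antisense transcript pairs form long perfect duplexes
#' over their overlap, RNase III digests those duplexes into short products
#' with 2-nt 3' overhangs and a local sequence preference (AU-rich flanks
#' around the scissile bonds, GC-rich overhangs), and p19 retains products
#' by length (mass on 21-22 bp) with a mild preference for GC-rich duplex
#' bodies. Per-sequence cloning strand bias and uniform single-stranded
#' background reads are modeled at the read-emission step.
#'
#' @param genome_length Genome length in bases.
#' @param genome_gc Genome GC fraction (default 0.508, the E. coli value).
#' @param locus_plan data.frame with columns `architecture` (one of
#'   `"divergent5"`, `"convergent3"`, `"full_overlap"`, `"novel_as"`),
#'   `overlap_length` (bases) and `abundance` (expected duplex molecule
#'   count entering digestion).
#' @param digestion_mode `"mg"` (Mg2+, ~14-bp products) or `"mn"`
#'   (Mn2+, ~21-bp products). Sets the default `product_length_mean`.
#' @param product_length_mean Mean inter-cut spacing in bases; `NULL`
#'   selects 14 (`mg`) or 21 (`mn`).
#' @param product_length_sd SD of the inter-cut spacing.
#' @param beta_site Strength of the cleavage-site sequence preference
#'   (0 = uniform cutting among candidate offsets).
#' @param p19_length_weights Named numeric vector mapping product length to
#'   a retention weight; lengths absent from the map get weight 0.
#' @param beta_body Strength of the p19 preference for GC-rich duplex
#'   bodies (positions 4..L-5 of the plus-strand product).
#' @param strand_bias_sd SD of the per-sequence log-scale cloning strand
#'   bias applied at read emission.
#' @param noise_read_count Number of uniformly placed single-stranded
#'   background reads (lengths 18-30).
#' @param overhang 3' overhang length of digestion products in nt; 2 is the
#'   RNase III signature, 0 produces blunt products (negative control).
#' @param extension Length of the non-overlapping transcript extension on
#'   each side of a planted overlap.
#' @param spacing Gap between consecutive planted loci.
#' @param cluster_min_reads Read threshold used when tabulating expected
#'   clusters in the emitted ground truth.
#' @param seed Integer seed; an identical config (including seed) yields
#'   byte-identical outputs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 100000,
                       genome_gc = 0.508,
                       locus_plan = default_locus_plan(),
                       digestion_mode = c("mn", "mg"),
                       product_length_mean = NULL,
                       product_length_sd = 2,
                       beta_site = 2,
                       p19_length_weights = c("21" = 1, "22" = 1),
                       beta_body = 1,
                       strand_bias_sd = 0.25,
                       noise_read_count = 500,
                       overhang = 2,
                       extension = 100,
                       spacing = 300,
                       cluster_min_reads = 2000,
                       seed = 1) {
  digestion_mode <- match.arg(digestion_mode)
  if (is.null(product_length_mean))
    product_length_mean <- if (digestion_mode == "mg") 14 else 21
  if (genome_gc < 0 || genome_gc > 1) stop("genome_gc must lie in [0, 1]", call. = FALSE)
  if (product_length_mean < 6) stop("product_length_mean must be >= 6", call. = FALSE)
  if (beta_site < 0) stop("beta_site must be nonnegative", call. = FALSE)
  if (!is.data.frame(locus_plan) ||
      !all(c("architecture", "overlap_length", "abundance") %in% names(locus_plan)))
    stop("locus_plan needs columns architecture, overlap_length, abundance", call. = FALSE)
  bad <- !locus_plan$architecture %in%
    c("divergent5", "convergent3", "full_overlap", "novel_as")
  if (any(bad))
    stop("unknown architecture: ", paste(unique(locus_plan$architecture[bad]),
                                         collapse = ", "), call. = FALSE)
  if (any(locus_plan$overlap_length < product_length_mean + 4))
    stop("every overlap_length must be >= product_length_mean + 4", call. = FALSE)
  if (any(locus_plan$abundance < 0) || noise_read_count < 0)
    stop("counts must be >= 0", call. = FALSE)
  structure(list(
    genome_length = as.integer(genome_length),
    genome_gc = genome_gc,
    locus_plan = locus_plan,
    digestion_mode = digestion_mode,
    product_length_mean = product_length_mean,
    product_length_sd = product_length_sd,
    beta_site = beta_site,
    p19_length_weights = p19_length_weights,
    beta_body = beta_body,
    strand_bias_sd = strand_bias_sd,
    noise_read_count = as.integer(noise_read_count),
    overhang = as.integer(overhang),
    extension = as.integer(extension),
    spacing = as.integer(spacing),
    cluster_min_reads = as.integer(cluster_min_reads),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default locus plan: one locus of each overlap architecture
#' @return data.frame usable as `locus_plan` in [sim_config()].
#' @export
default_locus_plan <- function() {
  data.frame(
    architecture = c("divergent5", "convergent3", "full_overlap", "novel_as"),
    overlap_length = c(300L, 300L, 225L, 250L),
    abundance = c(100L, 100L, 100L, 100L),
    stringsAsFactors = FALSE
  )
}

#' Plant overlapping sense/antisense transcript pairs into a genome
#'
#' Lays out each planned locus left to right with a fixed inter-locus gap.
#' Every architecture produces a sense transcript and an antisense
#' transcript on opposite strands whose intersection is exactly
#' `overlap_length` bases: at the 5' ends of both transcripts
#' (`divergent5`), at the 3' ends (`convergent3`), or with the antisense
#' transcript fully contained in the sense transcript (`full_overlap`;
#' `novel_as` is the same geometry but the antisense partner is left out of
#' the gene annotation, emulating an unannotated asRNA).
#'
#' @param genome A [Biostrings::DNAStringSet] (the first record is used).
#' @param config A [sim_config()].
#' @return list with `annotation` (data.frame: gene_id, chrom, start, end,
#'   strand, biotype, architecture; 0-based half-open) and `truth` (a
#'   `sim_truth` list whose `loci` component records the full geometry and
#'   planned abundance of every locus, annotated or not).
#' @export
plant_loci <- function(genome, config) {
  chrom <- names(genome)[1]
  glen <- Biostrings::width(genome)[1]
  plan <- config$locus_plan
  ext <- config$extension
  margin <- 50L  # keeps composition flanks and overhangs inside the reference
  cursor <- margin
  loci <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    ov <- as.integer(plan$overlap_length[i])
    arch <- plan$architecture[i]
    footprint <- ov + 2L * ext
    if (cursor + footprint > glen - margin)
      stop(sprintf("locus %d (%s) does not fit in the genome without collision",
                   i, arch), call. = FALSE)
    o_start <- cursor + ext
    o_end <- o_start + ov
    if (arch == "divergent5") {
      sense <- c(o_start, o_end + ext); anti <- c(cursor, o_end)
    } else if (arch == "convergent3") {
      sense <- c(cursor, o_end); anti <- c(o_start, o_end + ext)
    } else {  # full_overlap, novel_as
      sense <- c(cursor, cursor + footprint); anti <- c(o_start, o_end)
    }
    loci[[i]] <- data.frame(
      locus_id = sprintf("locus%03d", i), architecture = arch, chrom = chrom,
      sense_start = sense[1], sense_end = sense[2], sense_strand = "+",
      anti_start = anti[1], anti_end = anti[2], anti_strand = "-",
      overlap_start = o_start, overlap_end = o_end,
      abundance = as.integer(plan$abundance[i]),
      stringsAsFactors = FALSE
    )
    cursor <- cursor + footprint + config$spacing
  }
  if (length(loci)) {
    loci <- do.call(rbind, c(loci, list(make.row.names = FALSE)))
  } else {
    loci <- data.frame(locus_id = character(), architecture = character(),
                       chrom = character(), sense_start = integer(),
                       sense_end = integer(), sense_strand = character(),
                       anti_start = integer(), anti_end = integer(),
                       anti_strand = character(), overlap_start = integer(),
                       overlap_end = integer(), abundance = integer(),
                       stringsAsFactors = FALSE)
  }
  annotation <- locus_annotation(loci)
  truth <- structure(list(loci = loci, cleavage_events = NULL,
                          captured_products = NULL, reads = NULL,
                          expected_clusters = NULL, chrom = chrom),
                     class = "sim_truth")
  list(annotation = annotation, truth = truth)
}

## Gene-style annotation rows for planted loci; the antisense partner of a
## novel_as locus is deliberately unannotated.
locus_annotation <- function(loci) {
  rows <- list()
  for (i in seq_len(nrow(loci))) {
    l <- loci[i, ]
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = paste0(l$locus_id, "_sense"), chrom = l$chrom,
      start = l$sense_start, end = l$sense_end, strand = l$sense_strand,
      biotype = "gene", architecture = l$architecture, stringsAsFactors = FALSE)
    if (l$architecture != "novel_as")
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = paste0(l$locus_id, "_antisense"), chrom = l$chrom,
        start = l$anti_start, end = l$anti_end, strand = l$anti_strand,
        biotype = "antisense", architecture = l$architecture,
        stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      biotype = character(), architecture = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

## Sequence preference score of every candidate cut position c (0-based;
## the plus-strand bond is severed between c-1 and c, the minus-strand bond
## `overhang` bases further left, so the 2-nt overhang occupies genomic
## [c-2, c)): AU fraction of the two 3-nt windows flanking the scissile
## bonds plus GC fraction of the overhang. Computed as one vector over the
## genome via running sums; positions too close to the ends get NA.
cut_site_scores <- function(is_gc, overhang) {
  n <- length(is_gc)
  cs_gc <- c(0, cumsum(is_gc))
  win_gc <- function(a, b) {  # GC count in 0-based genomic [a, b), vectorized
    ifelse(a >= 0L & b <= n & b > a, cs_gc[pmin(pmax(b, 0L), n) + 1L] -
             cs_gc[pmin(pmax(a, 0L), n) + 1L], NA_real_)
  }
  c_all <- seq_len(n) - 1L
  au_left <- 3 - win_gc(c_all - overhang - 3L, c_all - overhang)
  au_right <- 3 - win_gc(c_all, c_all + 3L)
  gc_oh <- if (overhang > 0L) win_gc(c_all - overhang, c_all) / overhang else 0
  (au_left + au_right) / 6 + gc_oh
}

#' Digest planted duplexes into short products with 3' overhangs
#'
#' For every duplex molecule (locus `abundance` copies of the overlap
#' region) walks 5' to 3' along the plus strand placing successive cuts.
#' Inter-cut spacing is `round(Normal(product_length_mean,
#' product_length_sd))` clamped to >= 6; the realized cut is chosen among
#' candidate offsets within +-3 of the sampled spacing with probability
#' proportional to `exp(beta_site * score)`, where the score rewards AU in
#' the 3 nt on each side of the scissile bonds and GC in the 2-nt overhang.
#' Each cut severs the two strands offset by `overhang` nt, so every
#' internal product is a perfect duplex whose minus-strand interval equals
#' the plus-strand interval shifted left by `overhang`. The two terminal
#' fragments of each molecule carry only one cut end and are flagged
#' non-duplex.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param truth A `sim_truth` from [plant_loci()].
#' @param config A [sim_config()].
#' @return `truth` with `cleavage_events`: a data.frame with one row per
#'   fragment per molecule (locus_id, molecule, chrom, plus_start,
#'   plus_end, minus_start, minus_end, length, is_duplex; 0-based
#'   half-open).
#' @export
digest_duplexes <- function(genome, truth, config) {
  stopifnot(inherits(truth, "sim_truth"))
  seq_chars <- strsplit(as.character(genome[[1]]), "", fixed = TRUE)[[1]]
  is_gc <- seq_chars == "G" | seq_chars == "C"
  oh <- config$overhang
  mu <- config$product_length_mean
  sd <- config$product_length_sd
  beta <- config$beta_site
  site_w <- if (beta > 0) {
    sc <- cut_site_scores(is_gc, oh)
    sc[is.na(sc)] <- 0
    exp(beta * sc)
  } else rep(1, length(is_gc))
  events <- list()
  with_seed(derive_seed(config$seed, 2L), {
    for (i in seq_len(nrow(truth$loci))) {
      l <- truth$loci[i, ]
      for (m in seq_len(l$abundance)) {
        cuts <- integer(0)
        pos <- l$overlap_start
        repeat {
          sp <- max(6L, as.integer(round(rnorm(1, mu, sd))))
          cand <- pos + sp + (-3L:3L)
          cand <- cand[cand - pos >= 6L & cand <= l$overlap_end]
          if (!length(cand)) break
          c_sel <- cand[sample.int(length(cand), 1L, prob = site_w[cand + 1L])]
          cuts <- c(cuts, c_sel)
          pos <- c_sel
        }
        bounds <- c(l$overlap_start, cuts, l$overlap_end)
        nfrag <- length(bounds) - 1L
        if (nfrag < 1L) next
        events[[length(events) + 1L]] <- data.frame(
          locus_id = l$locus_id, molecule = m, chrom = l$chrom,
          plus_start = bounds[-length(bounds)], plus_end = bounds[-1],
          minus_start = bounds[-length(bounds)] - oh,
          minus_end = bounds[-1] - oh,
          length = diff(bounds),
          is_duplex = seq_len(nfrag) > 1L & seq_len(nfrag) < nfrag,
          stringsAsFactors = FALSE)
      }
    }
  })
  truth$cleavage_events <- if (length(events))
    do.call(rbind, c(events, list(make.row.names = FALSE)))
  else
    data.frame(locus_id = character(), molecule = integer(), chrom = character(),
               plus_start = integer(), plus_end = integer(),
               minus_start = integer(), minus_end = integer(),
               length = integer(), is_duplex = logical(),
               stringsAsFactors = FALSE)
  truth
}

## GC fraction of the duplex body (plus-strand positions 4..L-5, i.e.
## genomic [plus_start+3, plus_end-5)) for each row of a fragment frame.
body_gc_of_products <- function(is_gc, plus_start, plus_end) {
  vapply(seq_along(plus_start), function(i) {
    a <- plus_start[i] + 3L; b <- plus_end[i] - 5L
    if (b <= a) return(NA_real_)
    mean(is_gc[(a + 1L):b])
  }, numeric(1))
}

#' Apply p19 capture selection to digestion products
#'
#' Each internal (duplex) digestion product is retained independently with
#' probability proportional to `p19_length_weights[L] * exp(beta_body *
#' bodyGC)`, where bodyGC is the GC fraction of plus-strand positions
#' 4..L-5. Probabilities are normalized by the maximum attainable weight so
#' the most-preferred product class is retained with probability 1; only
#' relative retention rates are meaningful. Terminal (non-duplex) fragments
#' are never retained. Product lengths absent from the weight map get
#' weight 0 and are dropped silently (their number is recorded in the
#' `dropped_lengths` attribute).
#'
#' @inheritParams digest_duplexes
#' @return `truth` with `captured_products`: one row per retained molecule
#'   aggregated by placement (chrom, plus_start, plus_end, minus_start,
#'   minus_end, length, body_gc, count).
#' @export
p19_capture <- function(genome, truth, config) {
  ev <- truth$cleavage_events
  if (is.null(ev)) stop("run digest_duplexes() first", call. = FALSE)
  seq_chars <- strsplit(as.character(genome[[1]]), "", fixed = TRUE)[[1]]
  is_gc <- seq_chars == "G" | seq_chars == "C"
  dup <- ev[ev$is_duplex, , drop = FALSE]
  w_len <- config$p19_length_weights
  wl <- unname(w_len[as.character(dup$length)])
  wl[is.na(wl)] <- 0
  n_dropped <- sum(wl == 0)
  body <- body_gc_of_products(is_gc, dup$plus_start, dup$plus_end)
  body[is.na(body)] <- 0
  wmax <- max(w_len) * exp(max(config$beta_body, 0))
  prob <- wl * exp(config$beta_body * body) / wmax
  keep <- with_seed(derive_seed(config$seed, 3L),
                    runif(nrow(dup)) < prob)
  cap <- dup[keep, , drop = FALSE]
  if (nrow(cap)) {
    key <- paste(cap$chrom, cap$plus_start, cap$plus_end, sep = ":")
    agg <- cap[!duplicated(key), c("chrom", "plus_start", "plus_end",
                                   "minus_start", "minus_end", "length")]
    agg$body_gc <- body[keep][!duplicated(key)]
    agg$count <- as.integer(table(key)[paste(agg$chrom, agg$plus_start,
                                             agg$plus_end, sep = ":")])
    agg <- agg[order(agg$plus_start), , drop = FALSE]
    rownames(agg) <- NULL
  } else {
    agg <- data.frame(chrom = character(), plus_start = integer(),
                      plus_end = integer(), minus_start = integer(),
                      minus_end = integer(), length = integer(),
                      body_gc = numeric(), count = integer(),
                      stringsAsFactors = FALSE)
  }
  truth$captured_products <- agg
  attr(truth$captured_products, "dropped_lengths") <- n_dropped
  truth
}

#' Emit sequencing reads for captured duplexes
#'
#' For each captured duplex placement with molecule count `m`, a
#' per-sequence cloning bias `b` with `log(b) ~ Normal(0, strand_bias_sd)`
#' is drawn, and the plus- and minus-strand read counts are
#' `Poisson(m * b)` and `Poisson(m / b)`. Read sequences are exact genomic
#' substrings (reverse-complemented for the minus strand). In addition,
#' `noise_read_count` single-stranded background reads of lengths 18-30 are
#' placed uniformly on either strand. Reads are written as FASTQ with a
#' constant Q40 quality, together with the ground-truth cleavage-site table
#' and expected-cluster intervals.
#'
#' @inheritParams digest_duplexes
#' @param out_dir Output directory; created if missing. Files written:
#'   `reads.fastq`, `cleavage_sites.tsv`, `expected_clusters.bed`.
#' @return `truth` with `reads` (data.frame chrom, start, end, strand,
#'   sequence, origin) and `expected_clusters` (data.frame chrom, start,
#'   end, n_reads) filled in.
#' @export
emit_reads <- function(genome, truth, config, out_dir) {
  cap <- truth$captured_products
  if (is.null(cap)) stop("run p19_capture() first", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  chrom <- truth$chrom
  glen <- Biostrings::width(genome)[1]
  gseq <- genome[[1]]
  reads <- with_seed(derive_seed(config$seed, 4L), {
    out <- list()
    if (nrow(cap)) {
      b <- exp(rnorm(nrow(cap), 0, config$strand_bias_sd))
      n_plus <- rpois(nrow(cap), cap$count * b)
      n_minus <- rpois(nrow(cap), cap$count / b)
      for (i in seq_len(nrow(cap))) {
        if (n_plus[i] > 0)
          out[[length(out) + 1L]] <- data.frame(
            chrom = chrom, start = cap$plus_start[i], end = cap$plus_end[i],
            strand = "+", n = n_plus[i], origin = sprintf("duplex%04d", i),
            stringsAsFactors = FALSE)
        if (n_minus[i] > 0)
          out[[length(out) + 1L]] <- data.frame(
            chrom = chrom, start = cap$minus_start[i], end = cap$minus_end[i],
            strand = "-", n = n_minus[i], origin = sprintf("duplex%04d", i),
            stringsAsFactors = FALSE)
      }
    }
    if (config$noise_read_count > 0) {
      len <- sample(18:30, config$noise_read_count, replace = TRUE)
      start <- vapply(len, function(l) sample.int(glen - l + 1L, 1L) - 1L,
                      integer(1))
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = start, end = start + len,
        strand = sample(c("+", "-"), config$noise_read_count, replace = TRUE),
        n = 1L, origin = "noise", stringsAsFactors = FALSE)
    }
    if (!length(out))
      return(data.frame(chrom = character(), start = integer(),
                        end = integer(), strand = character(), n = integer(),
                        origin = character(), stringsAsFactors = FALSE))
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  })
  ## expand multiplicities to one row per read
  reads <- reads[rep(seq_len(nrow(reads)), reads$n),
                 c("chrom", "start", "end", "strand", "origin"), drop = FALSE]
  rownames(reads) <- NULL
  if (nrow(reads)) {
    seqs <- Biostrings::DNAStringSet(
      substring(as.character(gseq), reads$start + 1L, reads$end))
    minus <- reads$strand == "-"
    if (any(minus))
      seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
    reads$sequence <- as.character(seqs)
    names(seqs) <- sprintf("read%06d_%s", seq_len(nrow(reads)), reads$origin)
    quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(seqs)))
    Biostrings::writeXStringSet(seqs, file.path(out_dir, "reads.fastq"),
                                format = "fastq", qualities = quals)
  } else {
    reads$sequence <- character(0)
    writeLines(character(0), file.path(out_dir, "reads.fastq"))
  }
  truth$reads <- reads
  truth$expected_clusters <- expected_clusters_from_reads(
    reads, truth$loci, min_reads = config$cluster_min_reads, window = 200L)
  ## ground-truth tables
  write.table(cap, file.path(out_dir, "cleavage_sites.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  ec <- truth$expected_clusters
  if (nrow(ec)) {
    write.table(data.frame(ec$chrom, ec$start, ec$end,
                           sprintf("expected%03d", seq_len(nrow(ec))),
                           ec$n_reads, "."),
                file.path(out_dir, "expected_clusters.bed"),
                sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    writeLines(character(0), file.path(out_dir, "expected_clusters.bed"))
  }
  truth
}

## Ground-truth cluster intervals: per planted locus, enumerate every
## 200-bp window offset over the locus footprint and record the tight span
## of read 5' ends assigned to qualifying windows. Deliberately a direct
## per-offset enumeration, independent of the caller's sweep.
expected_clusters_from_reads <- function(reads, loci, min_reads, window = 200L) {
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      n_reads = integer(), stringsAsFactors = FALSE)
  if (!nrow(reads) || !nrow(loci)) return(empty)
  p5 <- five_prime_end(reads)
  out <- list()
  for (i in seq_len(nrow(loci))) {
    l <- loci[i, ]
    lo <- min(l$sense_start, l$anti_start) - window
    hi <- max(l$sense_end, l$anti_end) + window
    offs <- lo:(hi - window)
    counts <- vapply(offs, function(w) sum(p5 >= w & p5 < w + window), integer(1))
    qual <- offs[counts >= min_reads]
    if (!length(qual)) next
    sel <- p5 >= qual[1] & p5 < qual[length(qual)] + window
    out[[length(out) + 1L]] <- data.frame(
      chrom = l$chrom, start = min(p5[sel]), end = max(p5[sel]) + 1L,
      n_reads = sum(sel), stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Run the full synthetic-data generator
#'
#' Convenience wrapper: genome, locus planting, digestion, capture and read
#' emission under a single configuration.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory for FASTQ and ground-truth files.
#' @return list with `genome`, `annotation` and `truth` (all stages filled).
#' @export
simulate_dataset <- function(config, out_dir) {
  genome <- generate_genome(config$genome_length, config$genome_gc,
                            seed = derive_seed(config$seed, 1L))
  planted <- plant_loci(genome, config)
  truth <- digest_duplexes(genome, planted$truth, config)
  truth <- p19_capture(genome, truth, config)
  truth <- emit_reads(genome, truth, config, out_dir)
  write_genome(genome, file.path(out_dir, "genome.fasta"))
  write_annotation_gff3(planted$annotation, file.path(out_dir, "annotation.gff3"))
  list(genome = genome, annotation = planted$annotation, truth = truth)
}

#' Simulate reads with planted positional composition
#'
#' Builds a genome in which `n` read placements of length `L` are embedded,
#' each with its 10-nt flanks, and every position is drawn from a planted
#' per-region base composition: GC probability `overhang_gc` at the four
#' modeled overhang positions, GC probability `1 - flank_au` in the four
#' 3-nt cleavage-flank windows, and `background_gc` elsewhere. Used to
#' verify that the composition profiler recovers planted region-level GC.
#'
#' @param n Number of read placements.
#' @param L Read length (21 or 22).
#' @param overhang_gc Planted GC probability at overhang positions.
#' @param flank_au Planted AU probability in cleavage-flank windows.
#' @param background_gc GC probability everywhere else.
#' @param seed Integer seed.
#' @return list with `genome` (DNAStringSet) and `records` (data.frame of
#'   unique read records: chrom, start, end, strand, length, count, rpm).
#' @export
simulate_planted_composition <- function(n, L = 22L, overhang_gc = 0.6,
                                         flank_au = 0.6, background_gc = 0.508,
                                         seed = 1) {
  F <- 10L
  unit <- L + 2L * F + 5L
  glen <- n * unit + 2L * F
  ## per-unit offsets relative to the read start a (0-based genomic):
  ## overhangs at a-2,a-1 (partner) and a+L-2,a+L-1 (this strand);
  ## cleavage flanks at a-5..a-3, a..a+2, a+L-5..a+L-3, a+L..a+L+2.
  rel_oh <- c(-2L, -1L, L - 2L, L - 1L)
  rel_fl <- c(-5L:-3L, 0L:2L, (L - 5L):(L - 3L), L:(L + 2L))
  p_gc <- rep(background_gc, glen)
  starts <- F + (seq_len(n) - 1L) * unit + F  # read start a of each unit
  for (d in rel_oh) p_gc[starts + d + 1L] <- overhang_gc
  for (d in rel_fl) p_gc[starts + d + 1L] <- 1 - flank_au
  bases <- with_seed(seed, {
    gc <- runif(glen) < p_gc
    b <- character(glen)
    half <- runif(glen) < 0.5
    b[gc & half] <- "G"; b[gc & !half] <- "C"
    b[!gc & half] <- "A"; b[!gc & !half] <- "T"
    b
  })
  genome <- Biostrings::DNAStringSet(paste0(bases, collapse = ""))
  names(genome) <- "planted"
  records <- data.frame(chrom = "planted", start = starts, end = starts + L,
                        strand = "+", length = L, count = 1L, rpm = 1,
                        stringsAsFactors = FALSE)
  list(genome = genome, records = records)
}
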