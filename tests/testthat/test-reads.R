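test_that("adapter trimming removes 3' adapter matches of decreasing length", {
  adapter <- "AGATCGGAAG"
  ## full adapter appended
  tr <- trim_adapter(paste0("ACGTACGTACGTACGT", adapter), adapter)
  expect_equal(tr$sequences, "ACGTACGTACGTACGT")
  expect_true(tr$trimmed)
  ## 3-base adapter prefix at the read end (hand-traced leftmost match)
  tr <- trim_adapter("ACGTACGTACGTACGTAGA", adapter, min_overlap = 3)
  expect_equal(tr$sequences, "ACGTACGTACGTACGT")
  ## no adapter: kept, flagged untrimmed
  tr <- trim_adapter("ACGTACGTACGTACGTT", adapter)
  expect_equal(tr$sequences, "ACGTACGTACGTACGTT")
  expect_false(tr$trimmed)
  ## too short after trimming: discarded
  tr <- trim_adapter(paste0("ACGTACG", adapter), adapter, min_len = 15)
  expect_equal(length(tr$sequences), 0L)
  expect_equal(tr$n_discarded, 1L)
  expect_error(trim_adapter("ACGT", ""), "adapter")
})

test_that("exact mapping reports unique forward and reverse-complement hits", {
  set.seed(21)
  g <- generate_genome(5000, 0.5, seed = 21)
  gchar <- as.character(g[[1]])
  fwd <- substr(gchar, 101, 122)  # genome[100:122) 0-based
  rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(gchar, 99, 120))))  # genome[98:120)
  out <- map_exact(c(fwd, rev), g)
  plus <- out[out$strand == "+", ]
  minus <- out[out$strand == "-", ]
  expect_equal(c(plus$start, plus$end), c(100L, 122L))
  expect_equal(c(minus$start, minus$end), c(98L, 120L))
  ## read with non-ACGT characters is dropped and counted
  out2 <- map_exact(c(fwd, "ACGTNNACGTACGTACGTACGT"), g)
  expect_equal(unname(attr(out2, "drop_counts")["invalid"]), 1L)
})

test_that("multi-occurring reads are dropped and counted", {
  ## construct a genome with an exact 25-bp tandem repeat
  set.seed(22)
  unit <- paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE), collapse = "")
  filler <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE), collapse = "")
  g <- Biostrings::DNAStringSet(paste0(filler, unit, filler, unit))
  names(g) <- "rep"
  out <- map_exact(unit, g)
  expect_equal(nrow(out), 0L)
  expect_equal(unname(attr(out, "drop_counts")["multi"]), 1L)
})

test_that("exact mapping agrees with a brute-force full-scan matcher", {
  set.seed(23)
  g <- generate_genome(50000, 0.5, seed = 23)
  gchar <- as.character(g[[1]])
  rcchar <- as.character(Biostrings::reverseComplement(g[[1]]))
  glen <- nchar(gchar)
  ## 1000 reads: mostly genomic substrings (either strand), some random
  n <- 1000L
  reads <- character(n)
  for (i in seq_len(n)) {
    L <- sample(18:26, 1)
    if (i %% 10 == 0) {
      reads[i] <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                        collapse = "")
    } else {
      s <- sample.int(glen - L, 1)
      src <- if (i %% 2 == 0) gchar else rcchar
      reads[i] <- substr(src, s, s + L - 1L)
    }
  }
  out <- map_exact(reads, g)
  ## oracle: count occurrences by scanning every genomic offset (fixed() to
  ## avoid regex; overlapping hits via gregexpr with lookahead-free loop)
  scan_count <- function(pat, subject) {
    hits <- 0L; from <- 1L
    repeat {
      p <- regexpr(pat, substr(subject, from, nchar(subject)), fixed = TRUE)
      if (p == -1L) break
      hits <- hits + 1L
      from <- from + p  # advance one position past the match start
    }
    hits
  }
  uniq <- unique(reads)
  for (r in sample(uniq, 200)) {  # spot-check a subsample for runtime
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(r)))
    n_occ <- scan_count(r, gchar) + scan_count(rc, gchar)
    in_out <- r %in% out$sequence
    expect_equal(in_out, n_occ == 1L, info = r)
  }
  ## every reported hit is a true genomic match at the reported placement
  for (i in sample(nrow(out), 100)) {
    seg <- substr(gchar, out$start[i] + 1L, out$end[i])
    expected <- if (out$strand[i] == "+") out$sequence[i]
      else as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(out$sequence[i])))
    expect_equal(seg, expected)
  }
})

test_that("alignment loading converts SAM and BED coordinates correctly", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t98\t120\tr1\t0\t-", bed)
  a <- load_alignments(bed)
  expect_equal(a[1, c("start", "end", "strand")],
               data.frame(start = 98L, end = 120L, strand = "-"),
               ignore_attr = TRUE)

  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chr1\tLN:1000",
    paste("r1", 0, "chr1", 101, 60, "22M", "*", 0, 0,
          strrep("A", 22), strrep("I", 22), sep = "\t"),
    paste("r2", 4, "*", 0, 0, "*", "*", 0, 0,
          strrep("A", 22), strrep("I", 22), sep = "\t")
  ), sam)
  a <- load_alignments(sam)
  expect_equal(nrow(a), 1L)  # unmapped record skipped
  expect_equal(a[1, c("start", "end", "strand")],
               data.frame(start = 100L, end = 122L, strand = "+"),
               ignore_attr = TRUE)

  bad <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t98\t120\tr1\t0\t-", "chr1\tnope"), bad)
  expect_error(load_alignments(bad), "line 2")
})

test_that("length histogram weights by count and sums to one", {
  expect_equal(length_histogram(c(strrep("A", 21), strrep("C", 21),
                                  strrep("G", 21), strrep("T", 22))),
               c("21" = 0.75, "22" = 0.25))
  a <- rbind(aln("c", 0, 21, "+", count = 2000L),
             aln("c", 50, 64, "+", count = 8000L))
  h <- length_histogram(a)
  expect_equal(sum(h), 1, tolerance = 1e-9)
  expect_equal(names(which.max(h)), "14")
  expect_error(length_histogram(character(0)), "empty")
})
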