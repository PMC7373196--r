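test_that("the region map partitions positions and matches duplex-body bounds", {
  for (L in c(21L, 22L)) {
    p <- composition_params(L)
    expect_equal(length(p$positions), L + 20L)
    expect_false(any(p$positions == 0L))
    expect_false(any(duplicated(p$positions)))
    body <- p$positions[p$region == "body"]
    expect_equal(range(body), c(4L, L - 5L))  # 4..17 for 22-nt, 4..16 for 21-nt
    oh <- p$positions[p$region %in% c("overhang_partner", "overhang_this")]
    expect_setequal(oh, c(-2L, -1L, L - 1L, L))
    fl <- p$positions[p$region == "cleavage_flank"]
    expect_setequal(fl, c(-5L:-3L, 1L:3L, (L - 4L):(L - 2L), (L + 1L):(L + 3L)))
    ## every position is labeled (partition, no gaps)
    expect_false(any(is.na(p$region)))
  }
})

test_that("an all-GC genome gives a flat profile of 1", {
  g <- Biostrings::DNAStringSet(strrep("GC", 200))
  names(g) <- "gc"
  rec <- data.frame(chrom = "gc", start = c(50L, 120L), end = c(72L, 142L),
                    strand = "+", length = 22L, count = 1L, rpm = 1,
                    stringsAsFactors = FALSE)
  prof <- positional_gc(rec, g, composition_params(22L))
  expect_true(all(prof$gc_fraction == 1))
  expect_equal(unique(prof$n), 2L)
})

test_that("hand-constructed sequences give hand-counted positional fractions", {
  ## two 22-mers with flanks; sequence built so per-position GC is known:
  ## record 1 all-G in read and flanks, record 2 all-A except positions 1-2
  ## of the read (0-based offsets 0-1), which are C.
  r1 <- strrep("G", 42)
  r2 <- paste0(strrep("A", 10), "CC", strrep("A", 30))
  g <- Biostrings::DNAStringSet(paste0(r1, strrep("T", 8), r2))
  names(g) <- "chr"
  rec <- data.frame(chrom = "chr", start = c(10L, 60L), end = c(32L, 82L),
                    strand = "+", length = 22L, count = c(1L, 3L), rpm = 1,
                    stringsAsFactors = FALSE)
  p <- composition_params(22L)
  prof_u <- positional_gc(rec, g, p, weighting = "unique")
  ## unique weighting: position 1 and 2 GC in both records -> 1.0; all other
  ## positions only record 1 -> 0.5
  expect_equal(prof_u$gc_fraction[prof_u$position %in% c(1, 2)], c(1, 1))
  expect_equal(unique(prof_u$gc_fraction[!prof_u$position %in% c(1, 2)]), 0.5)
  ## abundance weighting: record 2 weight 3 -> others drop to 1/4
  prof_a <- positional_gc(rec, g, p, weighting = "abundance")
  expect_equal(unique(prof_a$gc_fraction[!prof_a$position %in% c(1, 2)]), 0.25)
})

test_that("minus-strand records are profiled in their own 5'->3' orientation", {
  set.seed(71)
  g <- generate_genome(500, 0.5, seed = 71)
  ## a plus record and the minus record of the same duplex window see
  ## reverse-complementary sequence; GC is strand-symmetric, so a profile of
  ## plus records at [a, a+22) equals the profile of minus records at the
  ## same interval reversed
  rec_p <- data.frame(chrom = "synth", start = 100L, end = 122L, strand = "+",
                      length = 22L, count = 1L, rpm = 1, stringsAsFactors = FALSE)
  rec_m <- rec_p; rec_m$strand <- "-"
  p <- composition_params(22L)
  prof_p <- positional_gc(rec_p, g, p)
  prof_m <- positional_gc(rec_m, g, p)
  expect_equal(prof_m$gc_fraction, rev(prof_p$gc_fraction))
})

test_that("profiles are invariant to record order and to set duplication", {
  set.seed(72)
  g <- generate_genome(4000, 0.5, seed = 72)
  starts <- sample(50:3900, 40)
  rec <- data.frame(chrom = "synth", start = starts, end = starts + 22L,
                    strand = sample(c("+", "-"), 40, TRUE), length = 22L,
                    count = 1L, rpm = 1, stringsAsFactors = FALSE)
  p <- composition_params(22L)
  a <- positional_gc(rec, g, p)
  b <- positional_gc(rec[sample(1:40), ], g, p)
  expect_equal(a$gc_fraction, b$gc_fraction)
  dup <- positional_gc(rbind(rec, rec), g, p, weighting = "unique")
  expect_equal(dup$gc_fraction, a$gc_fraction)
})

test_that("region summary averages the profile within each region", {
  g <- Biostrings::DNAStringSet(strrep("AT", 300))
  names(g) <- "at"
  rec <- data.frame(chrom = "at", start = 100L, end = 122L, strand = "+",
                    length = 22L, count = 1L, rpm = 1, stringsAsFactors = FALSE)
  prof <- positional_gc(rec, g, composition_params(22L))
  rs <- region_summary(prof)
  expect_true(all(rs == 0))  # AT-only genome: every region 0
})

test_that("body-GC comparison separates extreme sets with a tiny p-value", {
  ## set A: 20 all-GC reads; set B: 20 all-AT reads (same genome)
  g <- Biostrings::DNAStringSet(paste0(strrep("GC", 300), strrep("AT", 300)))
  names(g) <- "mix"
  sa <- seq(20L, by = 25L, length.out = 20L)
  sb <- 600L + seq(20L, by = 25L, length.out = 20L)
  mk <- function(s) data.frame(chrom = "mix", start = s, end = s + 22L,
                               strand = "+", length = 22L, count = 1L, rpm = 1,
                               stringsAsFactors = FALSE)
  out <- compare_body_gc(mk(sa), mk(sb), g)
  expect_equal(out$delta_mean, 1.0)
  expect_lt(out$p_value, 1e-6)
  ## identical sets: delta 0, p ~ 1 under tie handling
  out2 <- compare_body_gc(mk(sa), mk(sa), g)
  expect_equal(out2$delta_mean, 0)
  expect_gte(out2$p_value, 0.99)
})

test_that("planted region composition is recovered by the profiler", {
  ps <- simulate_planted_composition(3000, L = 22L, overhang_gc = 0.6,
                                     flank_au = 0.6, seed = 73)
  prof <- positional_gc(ps$records, ps$genome, composition_params(22L))
  rs <- region_summary(prof)
  expect_lt(abs(rs[["overhang"]] - 0.6), 0.03)
  expect_lt(abs(rs[["cleavage_flank"]] - 0.4), 0.03)
  expect_lt(abs(rs[["background"]] - 0.508), 0.03)
})
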