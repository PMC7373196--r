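test_that("planted loci have the requested overlap geometry per architecture", {
  g <- generate_genome(5000, 0.5, seed = 1)
  for (arch in c("divergent5", "convergent3", "full_overlap", "novel_as")) {
    cfg <- sim_config(genome_length = 5000,
                      locus_plan = data.frame(architecture = arch,
                                              overlap_length = 100L,
                                              abundance = 10L),
                      seed = 1)
    l <- plant_loci(g, cfg)$truth$loci
    ## intersection of the two transcript intervals equals the overlap
    inter <- c(max(l$sense_start, l$anti_start), min(l$sense_end, l$anti_end))
    expect_equal(inter, c(l$overlap_start, l$overlap_end))
    expect_equal(l$overlap_end - l$overlap_start, 100L)
    if (arch == "divergent5") {
      ## overlap sits at the 5' end of both transcripts
      expect_equal(l$overlap_start, l$sense_start)
      expect_equal(l$overlap_end, l$anti_end)
    }
    if (arch == "convergent3") {
      expect_equal(l$overlap_end, l$sense_end)
      expect_equal(l$overlap_start, l$anti_start)
    }
    if (arch %in% c("full_overlap", "novel_as")) {
      expect_true(l$anti_start >= l$sense_start && l$anti_end <= l$sense_end)
      expect_equal(c(l$overlap_start, l$overlap_end),
                   c(l$anti_start, l$anti_end))
    }
  }
})

test_that("a 225-nt antisense RNA inside a 300-nt sense transcript overlaps exactly itself", {
  g <- generate_genome(2000, 0.5, seed = 4)
  cfg <- sim_config(genome_length = 2000,
                    locus_plan = data.frame(architecture = "full_overlap",
                                            overlap_length = 225L,
                                            abundance = 5L),
                    extension = 38L, seed = 4)  # sense length 225 + 2*38 ~ 300
  l <- plant_loci(g, cfg)$truth$loci
  expect_equal(l$anti_end - l$anti_start, 225L)
  expect_equal(c(l$overlap_start, l$overlap_end), c(l$anti_start, l$anti_end))
  expect_equal(l$sense_end - l$sense_start, 301L)
})

test_that("an empty locus plan yields empty annotation and truth", {
  g <- generate_genome(2000, 0.5, seed = 1)
  cfg <- sim_config(genome_length = 2000,
                    locus_plan = data.frame(architecture = character(),
                                            overlap_length = integer(),
                                            abundance = integer()),
                    seed = 1)
  out <- plant_loci(g, cfg)
  expect_equal(nrow(out$annotation), 0L)
  expect_equal(nrow(out$truth$loci), 0L)
})

test_that("an unplaceable plan raises a placement error naming the locus", {
  g <- generate_genome(900, 0.5, seed = 1)
  cfg <- sim_config(genome_length = 5000,
                    locus_plan = data.frame(architecture = c("divergent5",
                                                             "divergent5"),
                                            overlap_length = 200L,
                                            abundance = 5L),
                    seed = 1)
  expect_error(plant_loci(g, cfg), "locus 2")
})

test_that("digestion products obey the 3' 2-nt overhang geometry exhaustively", {
  cfg <- small_sim_config(seed = 5, n_each = 2L, abundance = 20L)
  g <- generate_genome(cfg$genome_length, cfg$genome_gc, seed = 50)
  truth <- digest_duplexes(g, plant_loci(g, cfg)$truth, cfg)
  ev <- truth$cleavage_events
  expect_gt(nrow(ev), 0)
  expect_true(all(ev$minus_start == ev$plus_start - 2L))
  expect_true(all(ev$minus_end == ev$plus_end - 2L))
  ## terminal fragments of each molecule are flagged non-duplex
  first_last <- unlist(tapply(seq_len(nrow(ev)),
                              paste(ev$locus_id, ev$molecule),
                              function(i) c(i[1], i[length(i)])))
  expect_true(all(!ev$is_duplex[first_last]))
})

test_that("unbiased digestion recovers the configured product length mean", {
  cfg <- small_sim_config(seed = 6, n_each = 3L, abundance = 50L,
                          beta_site = 0)
  g <- generate_genome(cfg$genome_length, cfg$genome_gc, seed = 60)
  truth <- digest_duplexes(g, plant_loci(g, cfg)$truth, cfg)
  lens <- truth$cleavage_events$length[truth$cleavage_events$is_duplex]
  se <- sd(lens) / sqrt(length(lens))
  expect_lt(abs(mean(lens) - cfg$product_length_mean), 3 * se + 1e-9)
})

test_that("Mg2+ and Mn2+ digestion modes produce ~14 vs ~21 bp modal products", {
  modal_len <- function(mode, seed) {
    cfg <- small_sim_config(seed = seed, n_each = 3L, abundance = 60L,
                            digestion_mode = mode)
    g <- generate_genome(cfg$genome_length, cfg$genome_gc, seed = 70)
    truth <- digest_duplexes(g, plant_loci(g, cfg)$truth, cfg)
    lens <- truth$cleavage_events$length[truth$cleavage_events$is_duplex]
    as.integer(names(which.max(table(lens))))
  }
  expect_equal(modal_len("mg", 7), 14L)
  expect_equal(modal_len("mn", 7), 21L)
})

test_that("sequence-biased cutting enriches AU next to realized cut sites", {
  flank_au_at_cuts <- function(beta, seed) {
    cfg <- small_sim_config(seed = seed, n_each = 5L, abundance = 80L,
                            beta_site = beta)
    g <- generate_genome(cfg$genome_length, cfg$genome_gc, seed = 80)
    truth <- digest_duplexes(g, plant_loci(g, cfg)$truth, cfg)
    ev <- truth$cleavage_events
    cuts <- ev$plus_start[ev$is_duplex]  # every internal cut, >= 5000 draws
    expect_gt(length(cuts), 5000)
    chars <- strsplit(as.character(g[[1]]), "")[[1]]
    is_au <- chars %in% c("A", "T")
    ## 3-nt windows flanking the scissile bonds at cut c: [c-5,c-2) and [c,c+3)
    mean(vapply(cuts, function(c) {
      mean(is_au[c(seq(c - 4L, c - 2L), seq(c + 1L, c + 3L))])
    }, numeric(1)))
  }
  expect_gt(flank_au_at_cuts(3, 8), flank_au_at_cuts(0, 8))
})

test_that("p19 capture retains only lengths with nonzero weight", {
  cfg <- small_sim_config(seed = 9, n_each = 3L, abundance = 40L,
                          p19_length_weights = c("21" = 1, "22" = 1),
                          beta_body = 0)
  g <- generate_genome(cfg$genome_length, cfg$genome_gc, seed = 90)
  truth <- p19_capture(g, digest_duplexes(g, plant_loci(g, cfg)$truth, cfg), cfg)
  expect_true(all(truth$captured_products$length %in% c(21L, 22L)))
})

test_that("p19 body-GC preference raises mean body GC of the captured pool", {
  cfg <- small_sim_config(seed = 10, n_each = 5L, abundance = 60L,
                          beta_body = 4)
  g <- generate_genome(cfg$genome_length, cfg$genome_gc, seed = 100)
  truth <- digest_duplexes(g, plant_loci(g, cfg)$truth, cfg)
  pool <- truth$cleavage_events
  pool <- pool[pool$is_duplex & pool$length %in% c(21L, 22L), ]
  chars <- strsplit(as.character(g[[1]]), "")[[1]]
  is_gc <- chars %in% c("G", "C")
  body_gc <- function(s, e) mean(is_gc[(s + 4L):(e - 5L)])
  pool_gc <- mapply(body_gc, pool$plus_start, pool$plus_end)
  cap <- p19_capture(g, truth, cfg)$captured_products
  cap_gc <- rep(mapply(body_gc, cap$plus_start, cap$plus_end), cap$count)
  expect_gt(mean(cap_gc), mean(pool_gc))
})

test_that("empty cleavage set gives an empty captured set", {
  cfg <- sim_config(genome_length = 2000,
                    locus_plan = data.frame(architecture = character(),
                                            overlap_length = integer(),
                                            abundance = integer()),
                    seed = 1)
  g <- generate_genome(2000, 0.5, seed = 1)
  truth <- p19_capture(g, digest_duplexes(g, plant_loci(g, cfg)$truth, cfg), cfg)
  expect_equal(nrow(truth$captured_products), 0L)
})

test_that("without strand bias the sense:antisense read ratio is near 1", {
  cfg <- small_sim_config(seed = 12, n_each = 5L, abundance = 200L,
                          strand_bias_sd = 0)
  out <- simulate_dataset(cfg, withr::local_tempdir())
  reads <- out$truth$reads
  n_plus <- sum(reads$strand == "+"); n_minus <- sum(reads$strand == "-")
  ## Poisson SE of the two totals
  se <- sqrt(n_plus + n_minus)
  expect_lt(abs(n_plus - n_minus), 3 * se)
})

test_that("with zero noise every read lies inside a captured duplex", {
  cfg <- small_sim_config(seed = 13, n_each = 1L, abundance = 30L)
  out <- simulate_dataset(cfg, withr::local_tempdir())
  cap <- out$truth$captured_products
  reads <- out$truth$reads
  inside <- vapply(seq_len(nrow(reads)), function(i) {
    any((reads$start[i] == cap$plus_start & reads$end[i] == cap$plus_end) |
        (reads$start[i] == cap$minus_start & reads$end[i] == cap$minus_end))
  }, logical(1))
  expect_true(all(inside))
})

test_that("identical configs give byte-identical FASTQ output", {
  cfg <- small_sim_config(seed = 14, n_each = 1L, abundance = 20L, noise = 50L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  expect_identical(readLines(file.path(d1, "reads.fastq")),
                   readLines(file.path(d2, "reads.fastq")))
  expect_identical(tools::md5sum(file.path(d1, "reads.fastq"))[[1]],
                   tools::md5sum(file.path(d2, "reads.fastq"))[[1]])
})

test_that("planted-composition simulator returns well-formed records", {
  ps <- simulate_planted_composition(50, L = 22L, seed = 3)
  expect_equal(nrow(ps$records), 50L)
  expect_true(all(ps$records$end - ps$records$start == 22L))
  expect_true(all(ps$records$start - 10L >= 0))
  expect_true(all(ps$records$end + 10L <= Biostrings::width(ps$genome)[1]))
})
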