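#' Load a pipeline run configuration from YAML or JSON
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file mirroring the argument
#'   structure of [run_pipeline()].
#' @return Configuration list.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

validate_run_config <- function(config) {
  if (is.null(config$mode) || !config$mode %in% c("simulate", "analyze"))
    stop("config validation: 'mode' must be \"simulate\" or \"analyze\"",
         call. = FALSE)
  if (is.null(config$out_dir))
    stop("config validation: missing field 'out_dir'", call. = FALSE)
  if (config$mode == "analyze") {
    if (is.null(config$genome))
      stop("config validation: missing field 'genome' (analyze mode)",
           call. = FALSE)
    if (is.null(config$reads) && is.null(config$alignments))
      stop("config validation: analyze mode needs 'reads' or 'alignments'",
           call. = FALSE)
    for (f in c("genome", "reads", "alignments", "annotation"))
      if (!is.null(config[[f]]) && !file.exists(config[[f]]))
        stop("config validation: path for '", f, "' does not exist: ",
             config[[f]], call. = FALSE)
  }
  invisible(config)
}

config_sim <- function(config) {
  sim <- config$sim
  if (is.null(sim)) sim <- list()
  if (!is.null(sim$locus_plan)) sim$locus_plan <- as.data.frame(sim$locus_plan)
  if (!is.null(sim$p19_length_weights))
    sim$p19_length_weights <- unlist(sim$p19_length_weights)
  if (is.null(sim$seed) && !is.null(config$seed)) sim$seed <- config$seed
  do.call(sim_config, sim)
}

#' Run the end-to-end dsRNA analysis pipeline
#'
#' In `simulate` mode a synthetic dataset (genome, annotation, reads,
#' ground truth) is generated under the run's seed and then analyzed; in
#' `analyze` mode the configured genome and reads (or pre-computed
#' alignments) are used. The analysis stages are: optional 3' adapter
#' trimming, exact unique mapping, strand-specific coverage with bedGraph
#' export, cluster calling, duplex (cleavage-site) detection, positional
#' GC profiling of 21- and 22-nt unique reads, optional per-gene
#' sense/antisense counting, and a reproducibility manifest
#' (`manifest.json`: seed, configuration hash, input checksums and stage
#' counts). An identical configuration, including the seed, reproduces
#' identical manifest counts.
#'
#' @param config Configuration list (or a path readable by
#'   [read_run_config()]). Recognized fields: `mode`, `out_dir`, `seed`,
#'   `genome`, `reads`, `alignments`, `annotation`, `adapter`, `sim`
#'   (fields of [sim_config()]), `cluster` (fields of [cluster_params()]),
#'   `duplex` (`lengths`, `min_rpm`), `composition` (`flank`, `weighting`,
#'   `min_rpm`).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  counts <- list()
  inputs <- character(0)

  if (config$mode == "simulate") {
    sim <- config_sim(config)
    sim_dir <- file.path(out_dir, "sim")
    simdat <- simulate_dataset(sim, sim_dir)
    genome <- simdat$genome
    annotation <- simdat$annotation
    reads_path <- file.path(sim_dir, "reads.fastq")
    counts$simulated_duplex_placements <- nrow(simdat$truth$captured_products)
  } else {
    genome <- read_genome(config$genome)
    annotation <- if (!is.null(config$annotation))
      read_annotation(config$annotation) else NULL
    reads_path <- config$reads
    inputs <- c(inputs, config$genome, config$reads, config$alignments,
                config$annotation)
  }

  if (!is.null(config$alignments) && config$mode == "analyze") {
    alignments <- load_alignments(config$alignments)
    counts$reads_in <- sum(alignments$count)
    counts$trimmed <- counts$reads_in
    counts$mapped <- sum(alignments$count)
    counts$multi_mapped <- 0L
  } else {
    reads <- read_reads(reads_path)
    counts$reads_in <- length(reads)
    if (!is.null(config$adapter)) {
      tr <- trim_adapter(reads, config$adapter)
      reads <- tr$sequences
    }
    counts$trimmed <- length(reads)
    alignments <- map_exact(reads, genome)
    drops <- attr(alignments, "drop_counts")
    counts$mapped <- sum(alignments$count)
    counts$multi_mapped <- unname(drops["multi"])
    counts$unmapped <- unname(drops["unmapped"])
  }
  library_size <- sum(alignments$count)

  track <- build_coverage(alignments, genome, strand_mode = "split")
  export_bedgraph(track, file.path(out_dir, "coverage.bedgraph"))
  export_bedgraph(rpm_scale(track, library_size),
                  file.path(out_dir, "coverage.rpm.bedgraph"))

  cl_par <- do.call(cluster_params,
                    if (is.null(config$cluster)) list() else config$cluster)
  clusters <- call_clusters(alignments, cl_par, library_size)
  export_clusters(clusters, out_dir)
  counts$clusters <- nrow(clusters)

  records <- collapse_unique(alignments, library_size)
  dx <- config$duplex
  duplexes <- find_duplexes(records,
                            lengths = if (is.null(dx$lengths)) c(21L, 22L)
                                      else as.integer(dx$lengths),
                            min_rpm = if (is.null(dx$min_rpm)) 1.0 else dx$min_rpm)
  export_cleavage_table(duplexes, file.path(out_dir, "cleavage_sites.tsv"),
                        genome = genome)
  per_len <- attr(duplexes, "per_length")
  for (L in names(per_len))
    counts[[paste0("duplexes_", L, "bp")]] <- unname(per_len[[L]])

  comp <- config$composition
  comp_flank <- if (is.null(comp$flank)) 10L else as.integer(comp$flank)
  comp_weight <- if (is.null(comp$weighting)) "unique" else comp$weighting
  comp_min_rpm <- if (is.null(comp$min_rpm)) 1.0 else comp$min_rpm
  for (L in c(21L, 22L)) {
    recL <- records[records$length == L, , drop = FALSE]
    prof <- tryCatch(
      positional_gc(recL, genome, composition_params(L, comp_flank),
                    weighting = comp_weight, min_rpm = comp_min_rpm),
      error = function(e) NULL)
    if (!is.null(prof))
      write.table(prof, file.path(out_dir, sprintf("composition_%dnt.tsv", L)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (!is.null(annotation) && nrow(annotation)) {
    gc_tab <- count_gene_reads(alignments, annotation, library_size)
    write.table(gc_tab, file.path(out_dir, "gene_counts.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    counts$genes <- nrow(gc_tab)
  }

  manifest <- list(
    mode = config$mode,
    seed = seed,
    config_hash = hash_object(config[setdiff(names(config), "out_dir")]),
    library_size = library_size,
    input_checksums = as.list(tools::md5sum(inputs[!is.na(inputs)])),
    counts = counts
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

## Stable md5 of an R object via its canonical JSON serialization.
hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}
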