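#' Run the full analysis pipeline from a YAML configuration
#'
#' Orchestrates counting, fitness scoring and (optionally) codon-adaptation
#' analysis from a single config, writing a versioned output tree:
#' `counts.tsv`, `fitness.tsv`, `thresholds.json`, `codon_report/`,
#' `resolved_config.yaml` and `run.log` (JSON lines with stage timings and
#' counts). All randomness flows from the single `seed` entry.
#'
#' Config keys (see the packaged example in the vignette): `manifest`,
#' `gene_map`, flank settings (`flank_up`, `flank_down`, `barcode_length`,
#' `max_flank_mismatches`), `min_barcodes` (default 3), `pseudocount`
#' (default 0), `n_boot` (default 1000), `k_sd` (default 3), `seed`
#' (default 1); optionally `counts` (precomputed counts TSV, skipping the
#' FASTQ stage) and a `codon` block (`phage_fasta`, `phage_gff`,
#' `host_fasta`, `host_gff`, `trna_table`, `exclude_stops`).
#'
#' @param config Path to a YAML file or an equivalent named list.
#' @param output_dir Directory for outputs (created if needed).
#' @return Invisibly, a list with the `barseq_fit` and (if run) the codon
#'   results.
#' @export
run_pipeline <- function(config, output_dir) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- config
  cfg$min_barcodes <- cfg$min_barcodes %||% 3L
  cfg$pseudocount <- cfg$pseudocount %||% 0
  cfg$n_boot <- cfg$n_boot %||% 1000L
  cfg$k_sd <- cfg$k_sd %||% 3
  cfg$seed <- cfg$seed %||% 1L
  if (is.null(cfg$manifest) || is.null(cfg$gene_map))
    stop_("config must name 'manifest' and 'gene_map' files")

  # fail on missing inputs before any computation starts
  inputs <- c(manifest = cfg$manifest, gene_map = cfg$gene_map,
              counts = cfg$counts,
              unlist(cfg$codon[c("phage_fasta", "phage_gff", "host_fasta",
                                 "host_gff", "trna_table")]))
  for (nm in names(inputs))
    if (!file.exists(inputs[[nm]]))
      stop_("input '", nm, "' does not exist: ", inputs[[nm]])

  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(output_dir, "run.log")
  unlink(log_path)
  log_stage <- function(stage, ...) {
    rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  stage = stage), list(...))
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
        file = log_path, append = TRUE)
  }

  manifest <- read_manifest(cfg$manifest)
  gene_map <- read_gene_map(cfg$gene_map)
  yaml::write_yaml(cfg, file.path(output_dir, "resolved_config.yaml"))

  t0 <- Sys.time()
  if (!is.null(cfg$counts)) {
    counts <- read_counts(cfg$counts)
    log_stage("count", source = "precomputed", n_barcodes = nrow(counts))
  } else {
    if (is.null(cfg$flank_up) || is.null(cfg$flank_down))
      stop_("config must give flank_up/flank_down when counting from FASTQ")
    spec <- flank_spec(cfg$flank_up, cfg$flank_down,
                       cfg$barcode_length %||% 20L,
                       cfg$max_flank_mismatches %||% 0L)
    counts <- count_barcodes(manifest, spec)
    rl <- attr(counts, "run_log")
    log_stage("count", n_barcodes = nrow(counts),
              n_reads = sum(rl$n_reads), n_discarded = sum(rl$n_discarded),
              seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 2))
    write_counts(counts, file.path(output_dir, "counts.tsv"))
  }

  t1 <- Sys.time()
  fit <- barseq_fitness(counts, manifest, gene_map,
                        min_barcodes = cfg$min_barcodes,
                        pseudocount = cfg$pseudocount,
                        n_boot = cfg$n_boot, k_sd = cfg$k_sd,
                        seed = cfg$seed)
  write_fitness(fit, file.path(output_dir, "fitness.tsv"),
                file.path(output_dir, "thresholds.json"))
  log_stage("fitness", n_genes = nrow(fit$results),
            n_resistant = sum(fit$results$significant == "resistant"),
            n_sensitive = sum(fit$results$significant == "sensitive"),
            n_filtered = fit$n_genes_filtered, seed = cfg$seed,
            seconds = round(as.numeric(Sys.time() - t1, units = "secs"), 2))

  codon_out <- NULL
  if (!is.null(cfg$codon)) {
    t2 <- Sys.time()
    codon_out <- .run_codon_stage(cfg$codon,
                                  file.path(output_dir, "codon_report"))
    log_stage("codon", r = codon_out$correlation$r,
              enrichment_p = codon_out$enrichment$p_value,
              seconds = round(as.numeric(Sys.time() - t2, units = "secs"), 2))
  }

  invisible(list(fit = fit, codon = codon_out))
}

.run_codon_stage <- function(cc, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  phage_cds <- extract_cds(cc$phage_fasta, cc$phage_gff)
  host_cds <- extract_cds(cc$host_fasta, cc$host_gff)
  excl <- isTRUE(cc$exclude_stops)
  phage <- codon_usage(phage_cds, exclude_stops = excl)
  host <- codon_usage(host_cds, exclude_stops = excl)
  trna <- parse_trnascan(cc$trna_table)
  alt <- if (isTRUE(cc$one_sided)) "greater" else "two.sided"
  enr <- trna_enrichment_test(phage, trna$codon_set, alternative = alt)
  corr <- codon_usage_correlation(phage, host)

  prof <- data.frame(codon = names(phage$frequency),
                     phage_count = as.integer(phage$counts),
                     phage_frequency = as.numeric(phage$frequency),
                     host_frequency = as.numeric(host$frequency),
                     has_trna = names(phage$frequency) %in% trna$codon_set)
  write.table(prof, file.path(out_dir, "codon_profile.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(trna_enrichment = unclass(enr),
         correlation = unclass(corr),
         n_trna_records = nrow(trna$records),
         n_unique_anticodons = length(unique(trna$records$anticodon))),
    file.path(out_dir, "codon_report.json"), auto_unbox = TRUE, digits = NA)
  list(phage_profile = phage, host_profile = host, trna = trna,
       enrichment = enr, correlation = corr)
}
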