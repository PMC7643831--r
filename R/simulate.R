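#' Simulate a barcoded transposon library under phage selection
#'
#' Generates the 3 x 3 (condition x replicate) barcode count structure the
#' fitness analysis consumes, together with its ground truth. The
#' generative model:
#' \enumerate{
#'   \item each gene carries `max(1, Poisson(barcodes_per_gene_mean))`
#'     unique barcodes;
#'   \item initial barcode abundances are LogNormal(0, `abundance_sigma`),
#'     normalized to proportions;
#'   \item expected post-growth proportions are proportional to abundance
#'     times multiplicative log-normal replicate growth noise (CV
#'     `growth_noise_cv`, drawn fresh per barcode per grown replicate),
#'     and, under phage, times a survival factor: `survival_factor` for the
#'     planted resistant genes, 1 otherwise;
#'   \item each of the 9 samples draws counts from
#'     Multinomial(`depth`, its proportions), so per-sample totals equal
#'     `depth` exactly.
#' }
#' Initial samples are aliquots of the unselected library: they get
#' multinomial sampling but no growth noise.
#'
#' @param n_genes Number of genes (default 1000).
#' @param barcodes_per_gene_mean Poisson mean barcodes per gene (default 8).
#' @param n_resistant Number of planted phage-resistant genes (default 0).
#' @param survival_factor Relative survival of resistant mutants under
#'   phage, >= 1 (default 1 = no planted effect).
#' @param growth_noise_cv Coefficient of variation of the per-barcode
#'   multiplicative replicate noise (default 0.1).
#' @param depth Reads per sample (default 5e5).
#' @param abundance_sigma Log-normal sigma of initial abundances
#'   (default 1).
#' @param n_replicates Replicates per condition (default 3).
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @return List with `counts` (integer matrix, barcodes x 9 samples),
#'   `manifest` (`sample_manifest`), `gene_map`, and `truth` (list:
#'   `resistant_gene_ids`, `expected_proportions` per condition —
#'   noise-free — and `barcode_abundance`).
#' @export
simulate_library <- function(n_genes = 1000L, barcodes_per_gene_mean = 8,
                             n_resistant = 0L, survival_factor = 1,
                             growth_noise_cv = 0.1, depth = 5e5,
                             abundance_sigma = 1, n_replicates = 3L,
                             seed = 1L) {
  if (n_resistant > n_genes) stop_("n_resistant cannot exceed n_genes")
  if (survival_factor < 1) stop_("survival_factor must be >= 1")
  if (growth_noise_cv < 0) stop_("growth_noise_cv must be >= 0")
  if (depth <= 0 || barcodes_per_gene_mean <= 0 || n_genes <= 0)
    stop_("n_genes, barcodes_per_gene_mean and depth must be positive")
  with_seed(seed, {
    gene_ids <- sprintf("gene%04d", seq_len(n_genes))
    k <- pmax(1L, rpois(n_genes, barcodes_per_gene_mean))
    n_bc <- sum(k)
    barcodes <- .random_barcodes(n_bc)
    gene_map <- data.frame(barcode = barcodes,
                           gene_id = rep(gene_ids, k),
                           insertion_pos = seq_len(n_bc))

    resistant <- sort(sample(gene_ids, n_resistant))
    s_bc <- ifelse(gene_map$gene_id %in% resistant, survival_factor, 1)

    a <- stats::rlnorm(n_bc, meanlog = 0, sdlog = abundance_sigma)
    a <- a / sum(a)

    # log-normal multiplicative noise with the requested CV
    sdlog <- sqrt(log(1 + growth_noise_cv^2))
    noise <- function() if (sdlog == 0) rep(1, n_bc) else
      stats::rlnorm(n_bc, meanlog = -sdlog^2 / 2, sdlog = sdlog)

    conds <- c("initial", "no_phage", "phage")
    sample_ids <- as.vector(t(outer(c("I", "N", "P"), seq_len(n_replicates),
                                    paste0)))
    manifest <- as_manifest(data.frame(
      sample_id = sample_ids,
      condition = rep(conds, each = n_replicates),
      replicate = rep(seq_len(n_replicates), times = 3L)))

    counts <- matrix(0L, nrow = n_bc, ncol = length(sample_ids),
                     dimnames = list(barcodes, sample_ids))
    for (j in seq_along(sample_ids)) {
      cond <- manifest$condition[j]
      p <- switch(cond,
                  initial = a,
                  no_phage = a * noise(),
                  phage = a * noise() * s_bc)
      p <- p / sum(p)
      counts[, j] <- as.integer(rmultinom(1L, size = depth, prob = p))
    }

    p_phage <- a * s_bc / sum(a * s_bc)
    truth <- list(resistant_gene_ids = resistant,
                  expected_proportions = list(initial = setNames(a, barcodes),
                                              no_phage = setNames(a, barcodes),
                                              phage = setNames(p_phage, barcodes)),
                  barcode_abundance = setNames(a, barcodes))
    list(counts = counts, manifest = manifest, gene_map = gene_map,
         truth = truth)
  })
}

.random_barcodes <- function(n, length = 20L) {
  repeat {
    bc <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
            collapse = ""), "")
    if (!anyDuplicated(bc)) return(bc)
  }
}

#' Write simulated amplicon reads for a barcode count table
#'
#' Emits one FASTQ file per sample with one read per count: a short random
#' pad, the upstream flank, the barcode, the downstream flank and another
#' random pad, with independent per-base substitution errors at
#' `error_rate`. At `error_rate = 0`, running [count_barcodes()] on the
#' output recovers the input table exactly.
#'
#' @param counts Integer count matrix (rows = barcodes, columns = samples).
#' @param spec A [flank_spec()].
#' @param dir Output directory for the FASTQ files (created if needed).
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param max_pad Maximum random pad length on either side (default 8).
#' @param seed Integer seed.
#' @param gzip Write gzip-compressed FASTQ (default `FALSE`).
#' @return A `sample_manifest`-style data.frame with `sample_id` and
#'   `fastq_path` for each sample (conditions/replicates not inferred).
#' @export
simulate_reads <- function(counts, spec, dir, error_rate = 0, max_pad = 8L,
                           seed = 1L, gzip = FALSE) {
  stopifnot(inherits(spec, "flank_spec"))
  if (error_rate < 0 || error_rate >= 1) stop_("error_rate must be in [0,1)")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    paths <- character(ncol(counts))
    for (j in seq_len(ncol(counts))) {
      sid <- colnames(counts)[j]
      cnt <- counts[, j]
      bc <- rep(rownames(counts), cnt)
      n <- length(bc)
      path <- file.path(dir, paste0(sid, ".fastq", if (gzip) ".gz"))
      if (n == 0L) {
        con <- if (gzip) gzfile(path, "wt") else file(path, "wt")
        close(con)
        paths[j] <- path
        next
      }
      pad1 <- vapply(sample.int(max_pad + 1L, n, replace = TRUE) - 1L,
                     function(k) paste(sample(bases, k, replace = TRUE),
                                       collapse = ""), "")
      pad2 <- vapply(sample.int(max_pad + 1L, n, replace = TRUE) - 1L,
                     function(k) paste(sample(bases, k, replace = TRUE),
                                       collapse = ""), "")
      seqs <- paste0(pad1, spec$upstream, bc, spec$downstream, pad2)
      if (error_rate > 0) seqs <- .mutate_seqs(seqs, error_rate, bases)
      qual <- vapply(nchar(seqs), function(w)
        paste(rep("I", w), collapse = ""), "")
      rec <- paste0("@", sid, "_r", seq_len(n), "\n", seqs, "\n+\n", qual)
      con <- if (gzip) gzfile(path, "wt") else file(path, "wt")
      writeLines(rec, con)
      close(con)
      paths[j] <- path
    }
    data.frame(sample_id = colnames(counts), fastq_path = paths)
  })
}

# independent per-base substitutions to a uniformly chosen different base
.mutate_seqs <- function(seqs, rate, bases) {
  vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    hit <- runif(length(ch)) < rate
    if (any(hit)) {
      ch[hit] <- vapply(ch[hit], function(b)
        sample(setdiff(bases, b), 1L), "")
    }
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Simulate coding sequences from a codon usage profile
#'
#' Each simulated gene is `codons_per_gene` i.i.d. codon draws from the
#' generating profile, so the pooled codon usage of the output converges to
#' the generating profile as the total codon count grows.
#'
#' @param generating_profile Named numeric vector of codon probabilities
#'   (subset of the 64 codons; normalized internally) or a
#'   `codon_profile`.
#' @param n_genes Number of genes to simulate.
#' @param codons_per_gene Codons per gene.
#' @param seed Integer seed.
#' @return A `DNAStringSet` of CDS, each of length `3 * codons_per_gene`.
#' @export
simulate_cds <- function(generating_profile, n_genes = 100L,
                         codons_per_gene = 100L, seed = 1L) {
  if (inherits(generating_profile, "codon_profile"))
    generating_profile <- generating_profile$frequency
  p <- generating_profile[generating_profile > 0]
  if (is.null(names(p)) || any(!names(p) %in% all_codons()))
    stop_("generating profile must be named by codons")
  p <- p / sum(p)
  with_seed(seed, {
    draws <- sample(names(p), n_genes * codons_per_gene, replace = TRUE,
                    prob = p)
    genes <- vapply(split(draws, rep(seq_len(n_genes),
                                     each = codons_per_gene)),
                    paste, "", collapse = "")
    out <- Biostrings::DNAStringSet(unname(genes))
    names(out) <- sprintf("simgene%04d", seq_len(n_genes))
    out
  })
}
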