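#' Read a barcode-to-gene map
#'
#' TSV with columns `barcode`, `gene_id` and optionally `insertion_pos`
#' (1-based genome coordinate of the transposon insertion). Each barcode may
#' map to at most one gene; all insertion positions within a gene are used,
#' with no central-region filter.
#'
#' @param path Path to the gene map TSV.
#' @return A data.frame with columns `barcode`, `gene_id`, `insertion_pos`.
#' @export
read_gene_map <- function(path) {
  if (!file.exists(path)) stop_("gene map not found: ", path)
  gm <- read.delim(path, stringsAsFactors = FALSE)
  as_gene_map(gm)
}

#' @rdname read_gene_map
#' @param gm Data.frame with at least `barcode` and `gene_id` columns.
#' @export
as_gene_map <- function(gm) {
  miss <- setdiff(c("barcode", "gene_id"), names(gm))
  if (length(miss))
    stop_("gene map lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(gm$barcode))
    stop_("gene map assigns some barcode to more than one gene")
  if (any(!nzchar(gm$gene_id)))
    stop_("gene map contains empty gene_ids")
  if (is.null(gm$insertion_pos))
    gm$insertion_pos <- rep(NA_integer_, nrow(gm))
  gm[c("barcode", "gene_id", "insertion_pos")]
}

#' Average RPM over the replicates of each condition
#'
#' For each condition in the manifest, takes the arithmetic mean of each
#' barcode's RPM over that condition's replicate samples. A barcode absent
#' from a given sample contributes 0 for that sample (it simply was not
#' sequenced there).
#'
#' @param rpm RPM matrix from [normalize_rpm()] (rows = barcodes, columns =
#'   samples).
#' @param manifest A `sample_manifest`; its `sample_id`s must appear among
#'   the columns of `rpm`.
#' @return Numeric matrix, rows = barcodes, one column per condition.
#' @export
mean_over_replicates <- function(rpm, manifest) {
  manifest <- as_manifest(as.data.frame(manifest))
  conds <- unique(manifest$condition)
  out <- matrix(0, nrow = nrow(rpm), ncol = length(conds),
                dimnames = list(rownames(rpm), conds))
  for (cc in conds) {
    ids <- manifest$sample_id[manifest$condition == cc]
    missing <- setdiff(ids, colnames(rpm))
    if (length(missing))
      stop_("condition '", cc, "' has sample(s) absent from the RPM table: ",
            paste(missing, collapse = ", "))
    out[, cc] <- rowMeans(rpm[, ids, drop = FALSE])
  }
  out
}

#' Pool observed barcodes by gene and apply the coverage filter
#'
#' Groups the observed barcodes by the gene their insertion overlaps and
#' drops genes represented by fewer than `min_barcodes` barcodes (default 3),
#' since such genes are more susceptible to experimental noise. Barcodes not
#' present in the gene map (intergenic or unmapped insertions) are excluded.
#'
#' @param barcodes Character vector of observed barcodes (typically
#'   `rownames(counts)`).
#' @param gene_map Gene map data.frame (see [read_gene_map()]).
#' @param min_barcodes Minimum number of observed barcodes for a gene to be
#'   retained (default 3).
#' @return Named list of character vectors: observed barcodes per retained
#'   gene. Attribute `n_unmapped` counts observed barcodes without a gene.
#' @export
group_and_filter <- function(barcodes, gene_map, min_barcodes = 3L) {
  gene_map <- as_gene_map(gene_map)
  if (nrow(gene_map) == 0L) {
    warning("empty gene map: no genes to analyse", call. = FALSE)
    out <- list()
    attr(out, "n_unmapped") <- length(barcodes)
    return(out)
  }
  hit <- match(barcodes, gene_map$barcode)
  mapped <- !is.na(hit)
  groups <- split(barcodes[mapped], gene_map$gene_id[hit[mapped]])
  groups <- groups[lengths(groups) >= min_barcodes]
  attr(groups, "n_unmapped") <- sum(!mapped)
  groups
}

#' Per-gene enrichment: post-treatment over initial abundance
#'
#' The enrichment of a gene under a treatment is the ratio of the summed
#' (replicate-averaged, RPM-normalized) abundance of its barcodes after
#' treatment to the same sum before treatment:
#' \deqn{E = \frac{\sum_b \mathrm{post}(b) + c}{\sum_b \mathrm{init}(b) + c}}
#' with pseudocount \eqn{c} (default 0) added to both sums. With the default
#' pseudocount a zero initial sum is an error rather than a silent infinity.
#'
#' @param barcodes Barcodes of one gene group.
#' @param post_means,initial_means Named numeric vectors (or single columns
#'   of the matrix from [mean_over_replicates()]) of replicate-averaged RPM.
#' @param pseudocount Non-negative value added to numerator and denominator
#'   sums; default 0. A value of 1 (RPM) is a reasonable choice for sparse
#'   libraries.
#' @return Non-negative scalar enrichment.
#' @export
gene_enrichment <- function(barcodes, post_means, initial_means,
                            pseudocount = 0) {
  if (length(barcodes) == 0L) stop_("empty gene group")
  if (pseudocount < 0) stop_("pseudocount must be non-negative")
  post <- sum(post_means[barcodes], na.rm = TRUE)
  init <- sum(initial_means[barcodes], na.rm = TRUE)
  den <- init + pseudocount
  if (den == 0)
    stop_("zero initial abundance for a gene group; set pseudocount > 0 ",
          "to analyse genes unobserved in the initial samples")
  (post + pseudocount) / den
}

#' Log2 fitness score from the two treatment enrichments
#'
#' \deqn{\mathrm{fitness} = \log_2(E_\mathrm{phage} / E_\mathrm{no\,phage})}
#' Positive scores indicate that disrupting the gene makes the mutant more
#' abundant under phage challenge than without it, i.e. phage resistance.
#'
#' @param enr_phage,enr_no_phage Positive enrichments of the same gene under
#'   the phage and no-phage treatments.
#' @return Fitness score in log2 units.
#' @export
fitness_score <- function(enr_phage, enr_no_phage) {
  if (any(enr_phage <= 0) || any(enr_no_phage <= 0))
    stop_("enrichments must be strictly positive")
  log2(enr_phage / enr_no_phage)
}

#' Bootstrap the fitness-score significance thresholds
#'
#' Resamples the observed fitness scores with replacement `n_boot` times
#' (resample size equal to the number of scores) and anchors the
#' significance band at the bootstrapped mean `m*` (the mean of the resample
#' means). The half-width of the band is `k_sd` standard deviations, by
#' default the sample SD of the observed scores (`sd_method = "observed"`);
#' `sd_method = "bootstrap"` instead uses the SD of the bootstrap
#' distribution of the mean (a much narrower band, the standard error of the
#' mean).
#'
#' @param scores Numeric vector of at least 2 fitness scores.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param k_sd Number of SDs for the band (default 3).
#' @param seed Integer seed; required so thresholds are reproducible.
#' @param sd_method `"observed"` (default) or `"bootstrap"`.
#' @return List of class `fitness_thresholds` with elements `m_star`, `s`,
#'   `lower`, `upper`, `k_sd`, `n_boot`, `seed`, `sd_method`.
#' @export
bootstrap_threshold <- function(scores, n_boot = 1000L, k_sd = 3,
                                seed, sd_method = c("observed", "bootstrap")) {
  sd_method <- match.arg(sd_method)
  scores <- scores[is.finite(scores)]
  n <- length(scores)
  if (n < 2L) stop_("need at least 2 finite fitness scores")
  if (missing(seed) || is.null(seed)) stop_("a seed is required")
  if (!is_count(n_boot) || n_boot < 1) stop_("n_boot must be >= 1")
  boot_means <- with_seed(seed, {
    vapply(seq_len(n_boot),
           function(i) mean(scores[sample.int(n, n, replace = TRUE)]),
           numeric(1))
  })
  m_star <- mean(boot_means)
  s <- if (sd_method == "observed") sd(scores) else sd(boot_means)
  structure(list(m_star = m_star, s = s,
                 lower = m_star - k_sd * s, upper = m_star + k_sd * s,
                 k_sd = k_sd, n_boot = as.integer(n_boot),
                 seed = as.integer(seed), sd_method = sd_method),
            class = "fitness_thresholds")
}

#' Flag genes beyond the significance thresholds
#'
#' A gene is called `resistant` if its fitness score is strictly greater
#' than the upper threshold, `sensitive` if strictly less than the lower
#' one, and `none` otherwise (scores exactly at a threshold are not
#' flagged).
#'
#' @param fitness Numeric vector of fitness scores (may contain `Inf` for
#'   genes unobserved in one treatment).
#' @param thresholds A `fitness_thresholds` object.
#' @return Factor with levels `resistant`, `sensitive`, `none`.
#' @export
call_significance <- function(fitness, thresholds) {
  stopifnot(inherits(thresholds, "fitness_thresholds"))
  out <- rep("none", length(fitness))
  out[!is.na(fitness) & fitness > thresholds$upper] <- "resistant"
  out[!is.na(fitness) & fitness < thresholds$lower] <- "sensitive"
  factor(out, levels = c("resistant", "sensitive", "none"))
}

#' Fit per-gene phage-selection fitness from a BarSeq count matrix
#'
#' The central model of the package. Starting from raw barcode counts over
#' the 3 x 3 design (initial, no-phage and phage conditions in triplicate),
#' the pipeline (i) normalizes each sample to reads per million, (ii)
#' averages replicates within each condition, (iii) pools barcodes by the
#' gene their insertion disrupts, dropping genes with fewer than
#' `min_barcodes` barcodes, (iv) computes each gene's enrichment under both
#' treatments relative to the initial library, (v) scores fitness as
#' `log2(enrichment_phage / enrichment_no_phage)`, and (vi) calls genes
#' significant when their score lies strictly outside a band of `k_sd`
#' standard deviations around the bootstrapped mean fitness score.
#'
#' Genes whose barcodes are entirely unobserved in exactly one treatment
#' get an infinite score (at pseudocount 0); such scores are excluded from
#' the bootstrap but still compared against the thresholds.
#'
#' @param counts Integer matrix of barcode counts (rows = barcodes, columns
#'   = samples), e.g. from [count_barcodes()] or [simulate_library()].
#' @param manifest A `sample_manifest` covering conditions `initial`,
#'   `no_phage` and `phage`.
#' @param gene_map Barcode-to-gene map (see [read_gene_map()]).
#' @param min_barcodes Coverage filter (default 3).
#' @param pseudocount Added to enrichment numerator and denominator sums
#'   (default 0; see [gene_enrichment()]).
#' @param n_boot,k_sd,seed,sd_method Passed to [bootstrap_threshold()].
#' @return An object of class `barseq_fit`: a list with `results` (per-gene
#'   data.frame sorted by fitness, descending), `thresholds`, `n_unmapped`,
#'   `n_genes_filtered`, and `call`.
#' @seealso [coef.barseq_fit()], [plot.barseq_fit()], [simulate_library()]
#' @export
barseq_fitness <- function(counts, manifest, gene_map, min_barcodes = 3L,
                           pseudocount = 0, n_boot = 1000L, k_sd = 3,
                           seed = 1L, sd_method = c("observed", "bootstrap")) {
  cl <- match.call()
  sd_method <- match.arg(sd_method)
  manifest <- as_manifest(as.data.frame(manifest))
  need <- c("initial", "no_phage", "phage")
  miss <- setdiff(need, unique(manifest$condition))
  if (length(miss))
    stop_("manifest lacks condition(s): ", paste(miss, collapse = ", "))
  gene_map <- as_gene_map(gene_map)

  rpm <- normalize_rpm(counts)
  means <- mean_over_replicates(rpm, manifest)
  groups <- group_and_filter(rownames(counts), gene_map, min_barcodes)
  n_total_genes <- length(unique(gene_map$gene_id))

  if (length(groups) == 0L) {
    warning("no gene passed the coverage filter", call. = FALSE)
    res <- data.frame(gene_id = character(), n_barcodes = integer(),
                      enrichment_no_phage = numeric(),
                      enrichment_phage = numeric(), fitness = numeric(),
                      significant = factor(character(),
                        levels = c("resistant", "sensitive", "none")))
    return(structure(list(results = res, thresholds = NULL,
                          n_unmapped = attr(groups, "n_unmapped"),
                          n_genes_filtered = n_total_genes,
                          min_barcodes = as.integer(min_barcodes),
                          call = cl),
                     class = "barseq_fit"))
  }

  # pooled gene sums in one pass; equivalent to gene_enrichment() per group
  bc <- unlist(groups, use.names = FALSE)
  grp <- rep(names(groups), lengths(groups))
  sums <- rowsum(means[bc, , drop = FALSE], grp)
  sums <- sums[names(groups), , drop = FALSE]
  init <- sums[, "initial"] + pseudocount
  if (any(init == 0))
    stop_("zero initial abundance for gene(s) ",
          paste(head(names(groups)[init == 0], 5), collapse = ", "),
          "; set pseudocount > 0")
  e_np <- (sums[, "no_phage"] + pseudocount) / init
  e_ph <- (sums[, "phage"] + pseudocount) / init
  # log2 of a zero enrichment is -Inf: the gene vanished from that
  # treatment; keep it in the table but outside the bootstrap.
  fitness <- suppressWarnings(log2(e_ph / e_np))

  thr <- bootstrap_threshold(fitness, n_boot = n_boot, k_sd = k_sd,
                             seed = seed, sd_method = sd_method)
  sig <- call_significance(fitness, thr)

  res <- data.frame(gene_id = names(groups),
                    n_barcodes = lengths(groups),
                    enrichment_no_phage = unname(e_np),
                    enrichment_phage = unname(e_ph),
                    fitness = unname(fitness),
                    significant = sig,
                    row.names = NULL)
  res <- res[order(-res$fitness), , drop = FALSE]
  rownames(res) <- NULL

  structure(list(results = res, thresholds = thr,
                 n_unmapped = attr(groups, "n_unmapped"),
                 n_genes_filtered = n_total_genes - length(groups),
                 min_barcodes = as.integer(min_barcodes), call = cl),
            class = "barseq_fit")
}
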