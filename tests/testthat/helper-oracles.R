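# Fixtures and independent oracles shared across the test files.
# Oracles are deliberately written as plain loops over the defining
# formulas, independent of the package's vectorized implementation.

toy_spec <- function(mismatches = 0L)
  flank_spec("GATGTCCACGAGGTCTCT", "CGTACGCTGCAGGTCGAC",
             barcode_length = 20L, max_flank_mismatches = mismatches)

# Hand-built 5-gene / 20-barcode count table over the 3x3 design.
# Sample totals differ on purpose so RPM normalization matters.
toy_fixture <- function() {
  barcodes <- sprintf("BC%02d", 1:20)  # count tables accept any row names
  gene_map <- data.frame(barcode = barcodes,
                         gene_id = rep(sprintf("g%d", 1:5), each = 4),
                         insertion_pos = seq_len(20))
  manifest <- as_manifest(data.frame(
    sample_id = c("I1", "I2", "I3", "N1", "N2", "N3", "P1", "P2", "P3"),
    condition = rep(c("initial", "no_phage", "phage"), each = 3),
    replicate = rep(1:3, times = 3)))
  base <- c(120, 80, 200, 40, 160, 90, 110, 70, 55, 145,
            95, 105, 60, 140, 85, 115, 75, 130, 50, 100)
  set <- function(mult, shift)
    pmax(1L, as.integer(round(base * mult + shift)))
  counts <- cbind(I1 = set(1.0, 0), I2 = set(1.1, 3), I3 = set(0.9, -2),
                  N1 = set(1.2, 5), N2 = set(1.0, -4), N3 = set(1.3, 2),
                  # phage: genes 1-2 (barcodes 1-8) strongly enriched
                  P1 = set(c(rep(4, 8), rep(0.5, 12)), 1),
                  P2 = set(c(rep(3.5, 8), rep(0.6, 12)), -1),
                  P3 = set(c(rep(4.5, 8), rep(0.4, 12)), 2))
  rownames(counts) <- barcodes
  list(counts = counts, manifest = manifest, gene_map = gene_map)
}

# Brute-force evaluation of the two published equations straight from the
# raw count matrix, with explicit loops.
oracle_fitness <- function(counts, manifest, gene_map, min_barcodes = 3) {
  rpm <- counts
  for (j in seq_len(ncol(counts)))
    rpm[, j] <- counts[, j] / sum(counts[, j]) * 1e6
  cond_mean <- function(bc, cond) {
    ids <- manifest$sample_id[manifest$condition == cond]
    v <- 0
    for (s in ids) v <- v + rpm[bc, s]
    v / length(ids)
  }
  genes <- unique(gene_map$gene_id)
  out <- list()
  for (g in genes) {
    bcs <- gene_map$barcode[gene_map$gene_id == g]
    bcs <- bcs[bcs %in% rownames(counts)]
    if (length(bcs) < min_barcodes) next
    s_init <- 0; s_np <- 0; s_ph <- 0
    for (b in bcs) {
      s_init <- s_init + cond_mean(b, "initial")
      s_np <- s_np + cond_mean(b, "no_phage")
      s_ph <- s_ph + cond_mean(b, "phage")
    }
    out[[g]] <- c(enr_no_phage = s_np / s_init, enr_phage = s_ph / s_init,
                  fitness = log2((s_ph / s_init) / (s_np / s_init)))
  }
  do.call(rbind, out)
}

# Plain substring-search barcode extraction (exact flanks only).
oracle_extract <- function(seq, up, dn, bl) {
  pos <- 1L
  repeat {
    hit <- regexpr(up, substring(seq, pos), fixed = TRUE)
    if (hit < 0) return(NA_character_)
    start <- pos + as.integer(hit) - 1L
    bc_start <- start + nchar(up)
    dn_start <- bc_start + bl
    if (dn_start + nchar(dn) - 1L <= nchar(seq) &&
        substring(seq, dn_start, dn_start + nchar(dn) - 1L) == dn) {
      bc <- substring(seq, bc_start, bc_start + bl - 1L)
      if (!grepl("[^ACGT]", bc)) return(bc)
    }
    pos <- start + 1L
  }
}

# Full-enumeration two-sided rank-sum p-value over all group assignments.
oracle_ranksum_p <- function(x, y) {
  rk <- rank(c(x, y))
  n1 <- length(x)
  w_obs <- sum(rk[seq_len(n1)])
  subsets <- utils::combn(length(rk), n1)
  ws <- apply(subsets, 2, function(ii) sum(rk[ii]))
  lo <- mean(ws <= w_obs + 1e-9)
  hi <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

random_barcode_counts <- function(barcodes, samples, lambda = 50) {
  if (is.numeric(barcodes)) barcodes <- sprintf("B%03d", seq_len(barcodes))
  matrix(rpois(length(barcodes) * length(samples), lambda) + 1L,
         nrow = length(barcodes), dimnames = list(barcodes, samples))
}

write_fastq_lines <- function(path, seqs) {
  qual <- vapply(nchar(seqs), function(w) strrep("I", w), "")
  writeLines(paste0("@r", seq_along(seqs), "\n", seqs, "\n+\n", qual), path)
  path
}

# Minimal genome FASTA + GFF3 pair for CDS extraction tests.
write_toy_genome <- function(dir) {
  genome <- paste0(
    "AATT",
    "ATGAAACCCGGGTAA",        # plus-strand CDS at 5..19
    "GG",
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString("ATGTTTGCACTGTGA"))),  # minus-strand CDS 22..36
    "CCAA")
  fa <- file.path(dir, "toy.fasta")
  writeLines(c(">chr1 toy", genome), fa)
  gff <- file.path(dir, "toy.gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tCDS\t5\t19\t.\t+\t0\tID=cds1",
    "chr1\ttest\tCDS\t22\t36\t.\t-\t0\tID=cds2"), gff)
  list(fasta = fa, gff = gff)
}
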