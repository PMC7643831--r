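#' Read a single-end FASTQ file
#'
#' Reads amplicon reads from a FASTQ file (plain or gzip-compressed) into a
#' [Biostrings::DNAStringSet]. Base qualities are not retained: the barcode
#' extraction stage ignores them. Malformed files (truncated records,
#' quality/sequence length mismatches) raise an error naming the offending
#' record.
#'
#' @param path Path to a FASTQ file; `.gz` accepted.
#' @return A `DNAStringSet`, one element per read, named by read id.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop_("FASTQ file not found: ", path)
  # readLines transparently decompresses .gz input
  lines <- readLines(path, warn = FALSE)
  n <- length(lines)
  if (n == 0L) return(Biostrings::DNAStringSet())
  fail <- function(line)
    stop_("malformed FASTQ in '", path, "' at line ", line)
  if (n %% 4L != 0L) fail(n)
  heads <- seq.int(1L, n, by = 4L)
  bad <- which(!startsWith(lines[heads], "@"))
  if (length(bad)) fail(heads[bad[1L]])
  bad <- which(!startsWith(lines[heads + 2L], "+"))
  if (length(bad)) fail(heads[bad[1L]] + 2L)
  bad <- which(nchar(lines[heads + 1L]) != nchar(lines[heads + 3L]))
  if (length(bad)) fail(heads[bad[1L]] + 3L)
  reads <- Biostrings::DNAStringSet(lines[heads + 1L])
  names(reads) <- sub("^@", "", sub("\\s.*$", "", lines[heads]))
  reads
}

#' Specify the sequences flanking the random barcode
#'
#' A barcode is located in a read as the fixed-length window immediately
#' between an upstream and a downstream flank (the constant amplicon sequence
#' on either side of the random tag). Flanks are required configuration: they
#' are primer-design specific and carry no universal default.
#'
#' @param upstream,downstream Non-empty DNA strings flanking the barcode.
#' @param barcode_length Barcode length in nt (default 20, the usual
#'   RB-TnSeq library tag length).
#' @param max_flank_mismatches Maximum Hamming mismatches tolerated per flank
#'   (default 0).
#' @return An object of class `flank_spec`.
#' @export
flank_spec <- function(upstream, downstream, barcode_length = 20L,
                       max_flank_mismatches = 0L) {
  up <- toupper(as.character(upstream))
  dn <- toupper(as.character(downstream))
  if (nchar(up) == 0L || nchar(dn) == 0L)
    stop_("flank sequences must be non-empty")
  if (grepl("[^ACGT]", up) || grepl("[^ACGT]", dn))
    stop_("flank sequences must be over the A/C/G/T alphabet")
  if (!is_count(barcode_length) || barcode_length <= 0)
    stop_("barcode_length must be a positive integer")
  if (!is_count(max_flank_mismatches) || max_flank_mismatches < 0)
    stop_("max_flank_mismatches must be a non-negative integer")
  structure(list(upstream = up, downstream = dn,
                 barcode_length = as.integer(barcode_length),
                 max_flank_mismatches = as.integer(max_flank_mismatches)),
            class = "flank_spec")
}

#' Extract barcodes from reads
#'
#' For each read, finds the leftmost occurrence of the upstream flank
#' (allowing at most `spec$max_flank_mismatches` Hamming mismatches) whose
#' placement validates in full: the fixed-length barcode window fits inside
#' the read, the downstream flank matches at the expected offset within the
#' same mismatch budget, and the barcode contains no N. Reads with no valid
#' placement yield `NA` and are counted by the caller as discards.
#'
#' @param reads A `DNAStringSet` or character vector of read sequences.
#' @param spec A [flank_spec()].
#' @return Character vector of barcodes, `NA` where extraction failed.
#' @export
extract_barcodes <- function(reads, spec) {
  stopifnot(inherits(spec, "flank_spec"))
  if (is.character(reads)) reads <- Biostrings::DNAStringSet(reads)
  n <- length(reads)
  out <- rep(NA_character_, n)
  if (n == 0L) return(out)

  mm <- spec$max_flank_mismatches
  bl <- spec$barcode_length
  up_len <- nchar(spec$upstream)
  dn_len <- nchar(spec$downstream)

  hits <- Biostrings::vmatchPattern(spec$upstream, reads, max.mismatch = mm)
  starts <- Biostrings::startIndex(hits)
  n_hits <- lengths(starts)
  idx <- rep.int(seq_len(n), n_hits)
  up_start <- unlist(starts, use.names = FALSE)
  if (length(idx) == 0L) return(out)

  bc_start <- up_start + up_len
  dn_start <- bc_start + bl
  keep <- dn_start + dn_len - 1L <= Biostrings::width(reads)[idx]
  idx <- idx[keep]; bc_start <- bc_start[keep]; dn_start <- dn_start[keep]
  if (length(idx) == 0L) return(out)

  # order candidates so the leftmost placement per read is examined first
  o <- order(idx, bc_start)
  idx <- idx[o]; bc_start <- bc_start[o]; dn_start <- dn_start[o]

  dn_win <- as.character(Biostrings::subseq(
    reads[idx], start = dn_start, width = dn_len))
  ok_dn <- .hamming_to(dn_win, spec$downstream) <= mm
  idx <- idx[ok_dn]; bc_start <- bc_start[ok_dn]
  if (length(idx) == 0L) return(out)

  bc <- as.character(Biostrings::subseq(
    reads[idx], start = bc_start, width = bl))
  ok_bc <- !grepl("[^ACGT]", bc)
  idx <- idx[ok_bc]; bc <- bc[ok_bc]
  if (length(idx) == 0L) return(out)

  first <- !duplicated(idx)
  out[idx[first]] <- bc[first]
  out
}

# Hamming distance of each fixed-width string to a single pattern.
.hamming_to <- function(strings, pattern) {
  if (length(strings) == 0L) return(integer(0))
  pat <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  m <- matrix(unlist(strsplit(strings, "", fixed = TRUE), use.names = FALSE),
              nrow = length(pat))
  as.integer(colSums(m != pat))
}

#' Read a sample manifest
#'
#' The manifest is a TSV with header columns `sample_id`, `condition`,
#' `replicate`, `fastq_path` describing the 3 conditions x 3 replicates
#' design: `initial` (library before selection), `no_phage` (grown without
#' phage) and `phage` (grown under phage challenge).
#'
#' @param path Path to the manifest TSV.
#' @return A validated data.frame of class `sample_manifest`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_("manifest not found: ", path)
  m <- read.delim(path, stringsAsFactors = FALSE)
  as_manifest(m)
}

#' Validate a sample manifest data.frame
#'
#' @param m A data.frame with columns `sample_id`, `condition`, `replicate`
#'   and optionally `fastq_path`.
#' @return `m` with class `sample_manifest` prepended.
#' @export
as_manifest <- function(m) {
  need <- c("sample_id", "condition", "replicate")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop_("manifest lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(m$sample_id))
    stop_("manifest sample_ids are not unique")
  bad <- setdiff(unique(m$condition), c("initial", "no_phage", "phage"))
  if (length(bad))
    stop_("unknown condition(s) in manifest: ", paste(bad, collapse = ", "))
  m$replicate <- as.integer(m$replicate)
  class(m) <- unique(c("sample_manifest", class(m)))
  m
}

#' Count barcodes per sample
#'
#' Runs barcode extraction over every FASTQ in the manifest and tallies the
#' extracted barcodes into a counts matrix (rows = barcodes, columns =
#' samples), the central object of the fitness analysis. Reads from which no
#' barcode could be extracted are tallied per sample in the `run_log`
#' attribute.
#'
#' @param manifest A `sample_manifest` with readable `fastq_path`s.
#' @param spec A [flank_spec()].
#' @return Integer matrix of counts with attribute `run_log`, a data.frame of
#'   per-sample read totals and discards.
#' @export
count_barcodes <- function(manifest, spec) {
  manifest <- as.data.frame(manifest)
  if (is.null(manifest$sample_id) || is.null(manifest$fastq_path))
    stop_("manifest needs sample_id and fastq_path columns")
  if (anyDuplicated(manifest$sample_id))
    stop_("manifest sample_ids are not unique")
  per_sample <- vector("list", nrow(manifest))
  log <- data.frame(sample_id = manifest$sample_id, n_reads = 0L,
                    n_counted = 0L, n_discarded = 0L)
  for (i in seq_len(nrow(manifest))) {
    path <- manifest$fastq_path[i]
    if (!file.exists(path))
      stop_("cannot read FASTQ for sample '", manifest$sample_id[i],
            "': ", path)
    reads <- read_fastq(path)
    bc <- extract_barcodes(reads, spec)
    log$n_reads[i] <- length(bc)
    log$n_counted[i] <- sum(!is.na(bc))
    log$n_discarded[i] <- sum(is.na(bc))
    if (log$n_counted[i] == 0L && log$n_reads[i] > 0L)
      warning("sample '", manifest$sample_id[i],
              "': no read matched the flanks", call. = FALSE)
    per_sample[[i]] <- table(bc[!is.na(bc)])
  }
  all_bc <- sort(unique(unlist(lapply(per_sample, names))))
  counts <- matrix(0L, nrow = length(all_bc), ncol = nrow(manifest),
                   dimnames = list(all_bc, manifest$sample_id))
  for (i in seq_len(nrow(manifest))) {
    tb <- per_sample[[i]]
    if (length(tb)) counts[names(tb), i] <- as.integer(tb)
  }
  attr(counts, "run_log") <- log
  counts
}

#' Normalize a count matrix to reads per million
#'
#' Scales each sample (column) so its counts sum to 1e6, removing sequencing
#' depth differences between samples.
#'
#' @param counts Non-negative numeric matrix, rows = barcodes, columns =
#'   samples.
#' @return Numeric matrix of RPM values with the same dimnames.
#' @export
normalize_rpm <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop_("counts must be non-negative")
  totals <- colSums(counts)
  zero <- totals == 0
  if (any(zero))
    stop_("sample(s) with zero total counts: ",
          paste(colnames(counts)[zero], collapse = ", "))
  sweep(counts, 2L, totals, "/") * 1e6
}

#' Read or write a barcode count matrix as TSV
#'
#' The on-disk format is a TSV with a `barcode` column followed by one
#' integer column per sample.
#'
#' @param path File path.
#' @return For `read_counts`, an integer matrix (rows = barcodes).
#' @export
read_counts <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1L] != "barcode") stop_("counts TSV must start with a 'barcode' column")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$barcode
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_counts
#' @param counts Count matrix as produced by [count_barcodes()].
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(barcode = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
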