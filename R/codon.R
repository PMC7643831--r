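#' The 64 codons, in alphabetical order
#'
#' Order matches `Biostrings::oligonucleotideFrequency(width = 3)`.
#' @return Character vector of length 64.
#' @export
all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Extract coding sequences from a genome and its annotation
#'
#' Splices each CDS feature of a GFF3 annotation out of the genome: parts
#' of a joined (multi-range) CDS are concatenated in ascending coordinate
#' order, and minus-strand features are reverse-complemented so every
#' returned sequence is the sense strand from start to stop codon. CDS
#' whose length is not a multiple of 3, or which contain ambiguous bases,
#' are dropped with a warning.
#'
#' @param genome A `DNAStringSet` (e.g. `Biostrings::readDNAStringSet`) or
#'   path to a genome FASTA.
#' @param annotation A `GRanges` of features or path to a GFF3 file; only
#'   features with `type == "CDS"` are used. Parts of one CDS are grouped
#'   by their `ID` attribute (falling back to `Parent`, then to one feature
#'   per range).
#' @return A `DNAStringSet` of coding sequences.
#' @export
extract_cds <- function(genome, annotation) {
  if (is.character(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  # strip FASTA description lines down to the record identifier
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (is.character(annotation))
    annotation <- rtracklayer::import(annotation)
  feats <- annotation[S4Vectors::mcols(annotation)$type %in% "CDS"]
  if (length(feats) == 0L) stop_("annotation contains no CDS features")

  mc <- S4Vectors::mcols(feats)
  ids <- if (!is.null(mc$ID) && !all(is.na(mc$ID))) as.character(mc$ID)
         else if (!is.null(mc$Parent) && any(lengths(mc$Parent) > 0))
           vapply(mc$Parent, function(p) if (length(p)) p[[1L]] else NA_character_, "")
         else paste0("cds_", seq_along(feats))
  ids[is.na(ids)] <- paste0("cds_", which(is.na(ids)))

  bad_seq <- setdiff(unique(as.character(GenomicRanges::seqnames(feats))),
                     names(genome))
  if (length(bad_seq))
    stop_("annotation references sequence(s) missing from the genome: ",
          paste(bad_seq, collapse = ", "))

  parts <- split(seq_along(feats), ids)
  seqs <- vapply(parts, function(ii) {
    ii <- ii[order(GenomicRanges::start(feats)[ii])]
    chunks <- vapply(ii, function(i) {
      as.character(Biostrings::subseq(
        genome[[as.character(GenomicRanges::seqnames(feats)[i])]],
        start = GenomicRanges::start(feats)[i],
        end = GenomicRanges::end(feats)[i]))
    }, "")
    s <- paste(chunks, collapse = "")
    if (as.character(GenomicRanges::strand(feats)[ii[1L]]) == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }, "")

  len_ok <- nchar(seqs) %% 3L == 0L
  if (any(!len_ok))
    warning(sum(!len_ok), " CDS dropped: length not a multiple of 3",
            call. = FALSE)
  seqs <- seqs[len_ok]
  clean <- !grepl("[^ACGT]", seqs)
  if (any(!clean))
    warning(sum(!clean), " CDS dropped: ambiguous bases", call. = FALSE)
  Biostrings::DNAStringSet(seqs[clean])
}

#' Count in-frame codons over a CDS set
#'
#' Reads each coding sequence in frame 0 as non-overlapping triplets and
#' pools the counts genome-wide.
#'
#' @param cds A `DNAStringSet` or character vector of coding sequences,
#'   each of length divisible by 3.
#' @return Named integer vector over the 64 codons.
#' @export
count_codons <- function(cds) {
  if (is.character(cds)) cds <- Biostrings::DNAStringSet(cds)
  if (length(cds) == 0L) return(setNames(integer(64), all_codons()))
  if (any(Biostrings::width(cds) %% 3L != 0L))
    stop_("all CDS lengths must be multiples of 3")
  freq <- Biostrings::oligonucleotideFrequency(cds, width = 3L, step = 3L)
  counts <- if (is.matrix(freq)) colSums(freq) else freq
  out <- setNames(as.integer(counts[all_codons()]), all_codons())
  out
}

#' Codon usage profile of a CDS set
#'
#' Frequencies of the 64 codons pooled over all coding sequences of a
#' genome (counts summed genome-wide, then normalized). Optionally the
#' three stop codons can be excluded before normalization.
#'
#' @param cds A `DNAStringSet`/character vector of CDS, or a named numeric
#'   vector of codon counts as returned by [count_codons()].
#' @param exclude_stops If `TRUE`, restrict to the 61 sense codons.
#' @return Object of class `codon_profile`: list with `counts`, `frequency`
#'   (sums to 1), `total_codons`.
#' @export
codon_usage <- function(cds, exclude_stops = FALSE) {
  counts <- if (is.numeric(cds)) {
    if (is.null(names(cds)) || !all(all_codons() %in% names(cds)))
      stop_("codon count vector must be named by all 64 codons")
    cds[all_codons()]
  } else count_codons(cds)
  if (exclude_stops) counts <- counts[setdiff(names(counts), STOP_CODONS)]
  total <- sum(counts)
  if (total == 0) stop_("no codons counted")
  structure(list(counts = counts, frequency = counts / total,
                 total_codons = as.integer(total),
                 exclude_stops = exclude_stops),
            class = "codon_profile")
}

#' @export
print.codon_profile <- function(x, ...) {
  cat(sprintf("Codon usage profile: %d codons over %d codon types%s\n",
              x$total_codons, length(x$frequency),
              if (x$exclude_stops) " (stops excluded)" else ""))
  top <- sort(x$frequency, decreasing = TRUE)[1:5]
  cat("Most frequent:",
      paste(sprintf("%s=%.3f", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Codon decoded by a tRNA anticodon
#'
#' Watson-Crick reverse complement of the anticodon in the DNA alphabet
#' (U read as T); wobble pairing is not expanded, so one anticodon maps to
#' exactly one codon. The map is an involution: applying it twice returns
#' the input.
#'
#' @param anticodon Character vector of 3-mers over A/C/G/T/U.
#' @return Character vector of codons (DNA alphabet).
#' @export
anticodon_to_codon <- function(anticodon) {
  ac <- toupper(chartr("U", "T", anticodon))
  if (any(nchar(ac) != 3L) || any(grepl("[^ACGT]", ac)))
    stop_("anticodons must be 3-mers over A/C/G/T/U")
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(ac)))
}

#' Parse tRNAscan-SE 2.0 tabular output
#'
#' Reads the tab-delimited output of tRNAscan-SE (two header lines plus a
#' dashed separator, then one row per predicted tRNA) and derives the set
#' of codons decoded by the annotated anticodons. Rows flagged as possible
#' pseudogenes are retained in the record table and marked in the `pseudo`
#' column; they are included in the codon set.
#'
#' @param path Path to a tRNAscan-SE tabular output file.
#' @return List with `records` (data.frame: `aa`, `anticodon`, `pseudo`)
#'   and `codon_set` (unique decoded codons).
#' @export
parse_trnascan <- function(path) {
  if (!file.exists(path)) stop_("tRNAscan output not found: ", path)
  lines <- readLines(path, warn = FALSE)
  dash <- grep("^-{2,}", lines)
  body_start <- if (length(dash)) dash[1L] + 1L else 1L
  body <- lines[seq.int(body_start, length.out = max(0L, length(lines) - body_start + 1L))]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) {
    warning("tRNAscan output has no tRNA rows", call. = FALSE)
    return(list(records = data.frame(aa = character(),
                                     anticodon = character(),
                                     pseudo = logical()),
                codon_set = character()))
  }
  fields <- strsplit(body, "\t|\\s{1,}")
  recs <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]][nzchar(fields[[i]])]
    if (length(f) < 6L)
      stop_("malformed tRNAscan row at line ", body_start + i - 1L)
    ac <- toupper(f[6L])
    if (nchar(ac) != 3L || grepl("[^ACGTU]", ac))
      stop_("invalid anticodon '", ac, "' at line ", body_start + i - 1L)
    data.frame(aa = f[5L], anticodon = ac,
               pseudo = any(grepl("pseudo", f, ignore.case = TRUE)))
  })
  records <- do.call(rbind, recs)
  codon_set <- unique(anticodon_to_codon(records$anticodon))
  list(records = records, codon_set = codon_set)
}

#' Test enrichment of tRNA-matched codons in a codon usage profile
#'
#' Splits the profile's codon frequencies into codons decoded by a
#' genome-encoded tRNA versus the rest, and compares the two groups with a
#' two-sample Wilcoxon rank-sum test. When full enumeration of the group
#' assignments is feasible (at most 20,000 combinations, which covers all
#' splits with both groups of size 8 or less) the p-value is computed by
#' exact, tie-aware enumeration of the observed ranks; for larger groups
#' the tie-corrected normal approximation is used. The reported statistic
#' is the rank sum of the tRNA-matched group.
#'
#' @param profile A `codon_profile` (see [codon_usage()]).
#' @param trna_codons Character vector of codons with a matching tRNA gene
#'   (e.g. `parse_trnascan(path)$codon_set`).
#' @param alternative `"two.sided"` (default), `"greater"` (tRNA-matched
#'   codons used more) or `"less"`.
#' @return List of class `trna_enrichment` with `statistic`, `p_value`,
#'   `n_with_trna`, `n_without`, `direction`, `method`.
#' @export
trna_enrichment_test <- function(profile, trna_codons,
                                 alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(profile, "codon_profile"))
  codons <- names(profile$frequency)
  trna_codons <- unique(toupper(trna_codons))
  unknown <- setdiff(trna_codons, all_codons())
  if (length(unknown))
    stop_("invalid codon(s): ", paste(unknown, collapse = ", "))
  with_grp <- intersect(codons, trna_codons)
  without_grp <- setdiff(codons, trna_codons)
  if (length(with_grp) == 0L || length(without_grp) == 0L)
    stop_("both codon groups must be non-empty")
  x <- unname(profile$frequency[with_grp])
  y <- unname(profile$frequency[without_grp])

  rk <- rank(c(x, y))
  w <- sum(rk[seq_along(x)])
  if (choose(length(x) + length(y), length(x)) <= 20000) {
    p <- .exact_ranksum_p(rk, length(x), alternative)
    method <- "exact enumeration"
  } else {
    wt <- wilcox.test(x, y, alternative = alternative, exact = FALSE,
                      correct = FALSE)
    p <- wt$p.value
    method <- "tie-corrected normal approximation"
  }
  dir <- if (median(x) > median(y)) "with>without"
         else if (median(x) < median(y)) "with<without" else "none"
  structure(list(statistic = w, p_value = p,
                 n_with_trna = length(x), n_without = length(y),
                 direction = dir, alternative = alternative,
                 method = method),
            class = "trna_enrichment")
}

# Exact two-sided rank-sum p by enumerating every C(n, n1) assignment of
# the observed ranks (handles ties, since tied midranks are enumerated as
# observed). Two-sided p doubles the smaller tail, capped at 1.
.exact_ranksum_p <- function(ranks, n1, alternative) {
  n <- length(ranks)
  sets <- combn(n, n1)
  sums <- colSums(matrix(ranks[sets], nrow = n1))
  w <- sum(ranks[seq_len(n1)])
  eps <- 1e-9
  p_ge <- mean(sums >= w - eps)
  p_le <- mean(sums <= w + eps)
  switch(alternative,
         greater = p_ge,
         less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

#' @export
print.trna_enrichment <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum (%s), %s\n", x$alternative, x$method))
  cat(sprintf("rank sum of %d tRNA-matched codons vs %d others: W = %g, p = %.4g (%s)\n",
              x$n_with_trna, x$n_without, x$statistic, x$p_value,
              x$direction))
  invisible(x)
}

#' Correlate two codon usage profiles
#'
#' Pearson product-moment correlation of the paired codon frequencies of
#' two genomes (e.g. phage versus candidate host), with the p-value from
#' the t-distribution on n - 2 degrees of freedom.
#'
#' @param profile_a,profile_b `codon_profile` objects over the same codon
#'   set.
#' @return List of class `codon_correlation` with `r`, `p_value`, `n`.
#' @export
codon_usage_correlation <- function(profile_a, profile_b) {
  stopifnot(inherits(profile_a, "codon_profile"),
            inherits(profile_b, "codon_profile"))
  a <- profile_a$frequency
  b <- profile_b$frequency
  if (!identical(names(a), names(b)))
    stop_("profiles are not over the same codon set")
  if (sd(a) == 0 || sd(b) == 0)
    stop_("zero-variance codon profile")
  ct <- cor.test(a, b, method = "pearson")
  structure(list(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(a)),
            class = "codon_correlation")
}

#' @export
print.codon_correlation <- function(x, ...) {
  cat(sprintf("Pearson codon-usage correlation: r = %.3f, p = %.4g (n = %d codons)\n",
              x$r, x$p_value, x$n))
  invisible(x)
}
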