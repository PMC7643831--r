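test_that("CDS extraction splices, orients and validates features", {
  dir <- withr::local_tempdir()
  toy <- write_toy_genome(dir)
  cds <- extract_cds(toy$fasta, toy$gff)
  expect_length(cds, 2L)
  expect_setequal(as.character(cds), c("ATGAAACCCGGGTAA", "ATGTTTGCACTGTGA"))

  # joined (two-part) CDS on the minus strand: parts are concatenated in
  # coordinate order, then the whole sequence reverse-complemented
  gff2 <- file.path(dir, "join.gff3")
  writeLines(c("##gff-version 3",
               "chr1\ttest\tCDS\t5\t10\t.\t-\t0\tID=j1",
               "chr1\ttest\tCDS\t14\t19\t.\t-\t0\tID=j1"), gff2)
  genome <- Biostrings::readDNAStringSet(toy$fasta)
  joined <- extract_cds(toy$fasta, gff2)
  manual <- Biostrings::reverseComplement(Biostrings::DNAString(
    paste0(substr(as.character(genome[[1]]), 5, 10),
           substr(as.character(genome[[1]]), 14, 19))))
  expect_equal(as.character(joined[[1]]), as.character(manual))

  # CDS whose length is not a multiple of 3 is dropped with a warning
  gff3 <- file.path(dir, "bad.gff3")
  writeLines(c("##gff-version 3",
               "chr1\ttest\tCDS\t5\t11\t.\t+\t0\tID=bad",
               "chr1\ttest\tCDS\t5\t19\t.\t+\t0\tID=ok"), gff3)
  expect_warning(kept <- extract_cds(toy$fasta, gff3), "multiple of 3")
  expect_length(kept, 1L)

  gff4 <- file.path(dir, "missing.gff3")
  writeLines(c("##gff-version 3",
               "chrX\ttest\tCDS\t1\t6\t.\t+\t0\tID=x"), gff4)
  expect_error(extract_cds(toy$fasta, gff4), "chrX")
})

test_that("codon counting reads non-overlapping in-frame triplets", {
  cnt <- count_codons("ATGTAA")
  expect_equal(unname(cnt["ATG"]), 1L)
  expect_equal(unname(cnt["TAA"]), 1L)
  expect_equal(sum(cnt), 2L)
  expect_equal(unname(count_codons("ATGATG")["ATG"]), 2L)

  # additivity: counting two CDS equals counting them in one set
  a <- "ATGAAACCC"; b <- "GGGTTTTAA"
  expect_equal(count_codons(c(a, b)), count_codons(a) + count_codons(b))
  expect_error(count_codons("ATGA"), "multiples of 3")
})

test_that("usage frequencies normalize counts and can exclude stops", {
  prof <- codon_usage(c("ATGTAA", "ATGTAA"))
  expect_equal(unname(prof$frequency["ATG"]), 0.5)
  expect_equal(unname(prof$frequency["TAA"]), 0.5)
  expect_equal(sum(prof$frequency), 1, tolerance = 1e-12)
  expect_equal(prof$total_codons, 4L)

  sense <- codon_usage(c("ATGTAA", "ATGTAA"), exclude_stops = TRUE)
  expect_length(sense$frequency, 61L)
  expect_equal(unname(sense$frequency["ATG"]), 1)

  counts <- setNames(rep(0L, 64), all_codons())
  expect_error(codon_usage(counts), "no codons")
})

test_that("anticodons decode to their Watson-Crick codon", {
  expect_equal(anticodon_to_codon("CAT"), "ATG")   # Met
  expect_equal(anticodon_to_codon("UUU"), "AAA")
  expect_equal(anticodon_to_codon(c("GCC", "tgg")), c("GGC", "CCA"))
  # the map is an involution
  withr::local_seed(8)
  acs <- replicate(25, paste(sample(c("A", "C", "G", "T"), 3,
                                    replace = TRUE), collapse = ""))
  expect_equal(anticodon_to_codon(anticodon_to_codon(acs)), acs)
  expect_error(anticodon_to_codon("AXG"), "3-mers")
  expect_error(anticodon_to_codon("ACGT"), "3-mers")
})

test_that("tRNAscan tables parse into a decoded codon set", {
  dir <- withr::local_tempdir()
  # 32 tRNA rows with 28 unique anticodons, like a typical phage genome
  withr::local_seed(14)
  acs <- sample(setdiff(all_codons(), "AAA"), 28)
  all_ac <- c(acs, acs[1:4])
  rows <- sprintf("phage\t%d\t%d\t%d\t%s\t%s\t0\t0\t%.1f",
                  seq_along(all_ac), seq_along(all_ac) * 100,
                  seq_along(all_ac) * 100 + 75, "Xxx",
                  all_ac, 60 + seq_along(all_ac) / 10)
  rows[5] <- paste0(rows[5], "\tpseudo")
  path <- file.path(dir, "trnascan.tsv")
  writeLines(c("Sequence\ttRNA\tBounds\t", "Name\t#\tBegin\tEnd\tType\tCodon\tBegin\tEnd\tScore",
               strrep("-", 60), rows), path)
  trna <- parse_trnascan(path)
  expect_equal(nrow(trna$records), 32L)
  expect_length(trna$codon_set, 28L)
  expect_setequal(trna$codon_set, anticodon_to_codon(acs))
  expect_equal(sum(trna$records$pseudo), 1L)

  # empty body warns and returns an empty set
  empty <- file.path(dir, "empty.tsv")
  writeLines(c("Name\t#\tBegin\tEnd\tType\tCodon", strrep("-", 40)), empty)
  expect_warning(et <- parse_trnascan(empty), "no tRNA rows")
  expect_length(et$codon_set, 0L)

  bad <- file.path(dir, "bad.tsv")
  writeLines(c(strrep("-", 40), "phage\t1\t100"), bad)
  expect_error(parse_trnascan(bad), "line 2")
})

make_profile <- function(freqs) {
  counts <- round(freqs / sum(freqs) * 1e6)
  codon_usage(setNames(as.numeric(counts), names(freqs))[all_codons()])
}

test_that("the rank-sum test matches the spec'd 3-vs-3 example", {
  f <- setNames(numeric(64), all_codons())
  f[c("AAA", "AAC", "AAG")] <- c(0.04, 0.05, 0.06)
  f[c("CCC", "CCG", "CCT")] <- c(0.01, 0.02, 0.03)
  prof <- codon_usage(setNames(round(f * 1e5), names(f)))
  six <- c("AAA", "AAC", "AAG", "CCC", "CCG", "CCT")
  prof$frequency <- prof$frequency[six]
  prof$counts <- prof$counts[six]
  res <- trna_enrichment_test(prof, c("AAA", "AAC", "AAG"))
  expect_equal(res$statistic, 15)
  expect_equal(res$p_value, 0.1)
  expect_equal(res$direction, "with>without")
  expect_equal(res$n_with_trna, 3L)
  expect_equal(res$n_without, 3L)
})

test_that("rank-sum p is label-symmetric and matches full enumeration", {
  withr::local_seed(40)
  for (i in 1:20) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x <- round(runif(n1), 2)   # rounding forces occasional ties
    y <- round(runif(n2), 2)
    f <- setNames(numeric(64), all_codons())
    f[seq_len(n1 + n2)] <- c(x, y) + 0.001
    prof <- codon_usage(setNames(round(f * 1e5), names(f)))
    with_set <- all_codons()[seq_len(n1)]
    without_set <- all_codons()[n1 + seq_len(n2)]
    # restrict the comparison to the codons actually in play
    sub <- prof
    sub$frequency <- prof$frequency[c(with_set, without_set)]
    sub$counts <- prof$counts[c(with_set, without_set)]
    res <- trna_enrichment_test(sub, with_set)
    expect_equal(res$p_value,
                 oracle_ranksum_p(sub$frequency[with_set],
                                  sub$frequency[without_set]))
    # swapping the group labels preserves the two-sided p exactly
    res_swap <- trna_enrichment_test(sub, without_set)
    expect_equal(res_swap$p_value, res$p_value)
  }
})

test_that("rank-sum null p-values are uniform under identical groups", {
  withr::local_seed(55)
  ps <- replicate(2000, {
    f <- setNames(rlnorm(64), all_codons())
    prof <- make_profile(f)
    trna_enrichment_test(prof, sample(all_codons(), 28))$p_value
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("codon usage correlation behaves on exact and reflected profiles", {
  withr::local_seed(23)
  prof <- make_profile(setNames(rlnorm(64), all_codons()))
  self <- codon_usage_correlation(prof, prof)
  expect_equal(self$r, 1, tolerance = 1e-12)
  expect_equal(self$n, 64L)

  # affine anti-correlation: reflected frequencies give r = -1
  refl <- prof
  refl$frequency <- max(prof$frequency) - prof$frequency
  expect_equal(codon_usage_correlation(prof, refl)$r, -1,
               tolerance = 1e-12)

  # exact linear relation across profiles built from proportional counts
  a <- make_profile(setNames(1:64, all_codons()))
  b <- make_profile(setNames(2 * (1:64), all_codons()))
  expect_equal(codon_usage_correlation(a, b)$r, 1, tolerance = 1e-9)

  # permuting codons identically in both profiles leaves r unchanged
  perm <- sample(64)
  pa <- prof; pb <- refl
  pa$frequency <- pa$frequency[perm]
  pb$frequency <- pb$frequency[perm]
  expect_equal(codon_usage_correlation(pa, pb)$r,
               codon_usage_correlation(prof, refl)$r)

  flat <- prof
  flat$frequency[] <- 1 / 64
  expect_error(codon_usage_correlation(prof, flat), "zero-variance")
  mis <- prof
  names(mis$frequency)[1] <- "XXX"
  expect_error(codon_usage_correlation(prof, mis), "same codon set")
})
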