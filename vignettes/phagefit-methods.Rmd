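---
title: "Scoring phage-resistance fitness from barcoded transposon libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring phage-resistance fitness from barcoded transposon libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagefit)
```

## The experiment phagefit models

In an RB-TnSeq (BarSeq) screen, a pooled library of transposon insertion
mutants — each mutant tagged with a unique random DNA barcode — is grown
with and without a selective agent, here a lytic bacteriophage. Sequencing
a short amplicon spanning the barcode measures each mutant's relative
abundance. Mutants whose disrupted gene is required for phage infection
(for example, receptor biogenesis genes) survive the challenge and their
barcodes rise in frequency; comparing abundances across conditions turns
the pool into a genome-wide reverse-genetic screen.

The design phagefit consumes has nine samples: three replicate aliquots of
the unselected library (`initial`), three replicate cultures grown without
phage (`no_phage`) and three grown under phage challenge (`phage`).

## The fitness model

For each sample, barcode counts are normalized to reads per million (RPM)
to remove depth differences. RPM values are then averaged over the three
replicates of each condition, and barcodes are pooled by the gene their
insertion disrupts. Genes represented by fewer than 3 barcodes are
discarded, as their scores are dominated by the sampling noise of one or
two insertion mutants.

For a gene $g$ with barcode set $B_g$, the enrichment under a treatment is

$$E_g(\text{treatment}) =
  \frac{\sum_{b \in B_g} \overline{\text{RPM}}_b(\text{post-treatment})}
       {\sum_{b \in B_g} \overline{\text{RPM}}_b(\text{initial})}$$

and the fitness score is the log ratio of the two treatments,

$$F_g = \log_2 \frac{E_g(\text{phage})}{E_g(\text{no phage})}.$$

Positive $F_g$ means disrupting $g$ confers a survival advantage under
phage — the gene contributes to susceptibility (e.g. encodes part of the
receptor). The initial-sample denominator cancels algebraically in $F_g$,
but both enrichments are reported because each is interpretable on its
own (growth effects without phage; survival under phage).

Two consequences of the formulas are checked as exact invariants by the
test suite: swapping the `phage` and `no_phage` labels negates every
score, and rescaling any single sample's raw counts (a pure depth change)
leaves every score unchanged.

### Order of operations

Normalization happens per sample, then replicate averaging, then summation
over a gene's barcodes. Sum-then-average over replicates would give the
same result (both are linear), but computing per-barcode ratios and then
averaging would not; the pipeline fixes the ratio-of-sums form shown
above, which is robust to individual low-count barcodes.

### Pseudocount

The default pseudocount is 0, so the equations above are applied exactly
as written; a gene whose barcodes are entirely absent from the initial
samples is then a hard error rather than a silently infinite enrichment.
For sparse libraries a pseudocount of 1 RPM (added to numerator and
denominator sums) is available via the `pseudocount` argument. A gene
unobserved in exactly one treatment yields an infinite score at
pseudocount 0; such genes are kept in the output table, flagged by sign,
and excluded from threshold estimation.

## Significance threshold

Significance is declared against a band of $k$ standard deviations
(default $k = 3$) around the bootstrapped mean fitness score: the observed
per-gene scores are resampled with replacement `n_boot` times (default
1000), the resample means are averaged into $m^*$, and the band is
$m^* \pm k \cdot s$. Genes strictly above the band are called `resistant`,
strictly below `sensitive`; ties at the boundary are conservatively not
flagged.

The dispersion $s$ is, by default, the sample standard deviation of the
observed scores (`sd_method = "observed"`). An alternative reading
attaches the SD to the bootstrap distribution of the mean
(`sd_method = "bootstrap"`); that quantity is the standard error of the
mean, shrinks as $1/\sqrt{n_\text{genes}}$, and would flag a large
fraction of genes in any genome-scale screen, so the observed-scores SD is
the default and the bootstrap variant is provided for comparison only.
Thresholds are deterministic given the `seed` argument, which is required.

### Calibration under abundance heterogeneity

If every gene's score had the same sampling variance and scores were
normal, a 3-SD two-tail band would flag about 0.27% of null genes. In
realistic libraries initial barcode abundances span an order of magnitude
or more, so low-abundance genes have systematically noisier scores; the
pooled score distribution is then a variance mixture with heavier tails
than normal. On the package's null simulations (log-normal abundance
spread $\sigma = 1$, no planted effects) the 3-SD rule flags roughly
0.6–0.8% of genes. This is a property of any pooled fixed-SD threshold,
not of the implementation; it is worth keeping in mind when interpreting
hit counts near the band. Planted resistant effects of realistic size
(survival factors of ~100) sit far outside the band and are recovered
with sensitivity ≥ 0.99 and essentially zero false positives in the
package's recovery simulations.

## Codon adaptation analyses

Phage genomes often carry their own tRNA genes and drift toward host-like
codon usage; both signals are evidence of adaptation to a host. The
package provides:

* **Codon usage profiles** (`codon_usage`): counts of in-frame,
  non-overlapping triplets pooled over all coding sequences of a genome,
  normalized to frequencies over the 64 codons. Pooling is genome-wide
  (no per-gene averaging), matching the usual "codon usage frequency"
  definition. Stop codons are included by default; `exclude_stops = TRUE`
  restricts to the 61 sense codons.
* **tRNA-matched codon enrichment** (`trna_enrichment_test`): codons are
  dichotomized by whether the genome encodes a tRNA whose anticodon
  decodes them under strict Watson–Crick pairing (one anticodon, one
  codon; wobble is deliberately not expanded, so the "matched" set is
  conservative). The two groups' frequencies are compared with a
  two-sample Wilcoxon rank-sum test: exact, tie-aware enumeration of all
  group assignments when that is feasible (up to 20,000 combinations),
  otherwise the tie-corrected normal approximation. Two-sided by default,
  since a direction should be concluded from the data, not assumed.
* **Codon usage correlation** (`codon_usage_correlation`): Pearson
  correlation of two genomes' paired codon frequencies, untransformed,
  with the usual $t$-based p-value on $n - 2$ degrees of freedom.

CDS extraction consumes a FASTA genome plus GFF3 annotation
(`extract_cds`): multi-part CDS are spliced in coordinate order,
minus-strand features reverse-complemented, and sequences that are not a
multiple of 3 or contain ambiguous bases are dropped with a warning. tRNA
annotations are consumed as tRNAscan-SE 2.0 tabular output
(`parse_trnascan`); rows flagged as possible pseudogenes are retained and
marked, and duplicate anticodons collapse when forming the decoded codon
set.

## The synthetic-data generator

`simulate_library` generates the full 3 × 3 count structure with known
ground truth so every pipeline stage can be tested without external data:

1. each gene receives $\max(1, \mathrm{Poisson}(\lambda))$ unique
   barcodes, $\lambda = 8$ by default (about 10 in the deeper recovery
   simulations);
2. initial abundances are log-normal with $\sigma = 1$, reflecting the
   wide, right-skewed barcode abundance spread of real transposon
   libraries (roughly a 10-fold central range);
3. grown conditions multiply each barcode's abundance by log-normal
   replicate noise with coefficient of variation 0.10 — a typical
   between-replicate variation for pooled growth assays — and, under
   phage, by a survival factor ($\ge 1$) for planted resistant genes;
4. every sample draws counts from a multinomial at fixed depth, so
   per-sample totals are exact and RPM normalization is exercised
   honestly.

Default scale is 1,000 genes × ~8 barcodes at depth $5 \times 10^5$
reads per sample, which runs in about a second while leaving nearly all
genes above the 3-barcode filter. The generator emulates the count
structure the analysis consumes — it does not model phage population
dynamics, adsorption kinetics, barcode PCR bias, chimeras, or positional
effects within genes. Passing recovery tests on these simulations
therefore demonstrates correctness of the scoring pipeline under its own
statistical assumptions, not robustness to every artifact of real
sequencing data.

`simulate_reads` renders a count table into per-sample FASTQ (random pad +
upstream flank + barcode + downstream flank + random pad, optional
per-base substitution errors); at error rate 0 counting the reads
reproduces the table exactly, which is the round-trip identity the tests
assert. `simulate_cds` draws i.i.d. codons from a generating profile, so
pooled usage converges to that profile by the law of large numbers.

## Numerical and design choices

* Barcode extraction takes the leftmost upstream-flank match whose whole
  placement validates (barcode window fits, downstream flank matches at
  the expected offset within the same per-flank Hamming budget, no N in
  the barcode). This equals plain substring search at zero mismatches and
  is robust to spurious flank-like sequence in the pad.
* Flank sequences are required configuration with no default: they are
  primer-design specific. The barcode length defaults to 20 nt, the usual
  RB-TnSeq tag length.
* Only the forward read is processed, in fixed orientation; no
  reverse-complement scan.
* Barcodes containing N are discarded, not error-corrected, and
  near-identical barcodes are not clustered.
* Base qualities are ignored throughout.
* Problem sizes in the shipped tests (up to 3,000 genes × ~10 barcodes at
  depth $2 \times 10^6$, five seeds) were chosen so the whole suite
  completes in about a minute while keeping per-gene counts in the range
  where the asymptotic behaviour is visible.

## Limitations

* The score is a simple ratio statistic; it does not model count
  overdispersion or weight barcodes by abundance, so very low-abundance
  genes are noisy (see the calibration note above). The 3-barcode filter
  is the only guard.
* The pooled 3-SD band assumes a common score dispersion across genes;
  with strong abundance heterogeneity it is mildly anticonservative.
* The tRNA-matched codon set uses strict Watson–Crick anticodon pairing;
  wobble decoding would enlarge the matched set and is not modelled.
* GenBank flat files are not parsed; supply FASTA + GFF3.
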