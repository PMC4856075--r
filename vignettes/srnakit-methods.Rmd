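---
title: "srnakit: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{srnakit: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

# The pipeline and its assumptions

`srnakit` analyses bulk small RNA libraries of the kind produced from
*C. elegans*: single-end reads consisting of a library barcode, an RNA
insert of roughly gel-window size, and a 3' sequencing adapter. The
cloning chemistry it assumes performs a single ligation to the RNA 3' end,
so species are recovered regardless of 5'-end structure — miRNAs
(5' monophosphate), piRNAs, and triphosphorylated secondary endo-siRNAs
alike. Nothing in the pipeline uses base qualities.

The stages are deliberately simple, explicit contracts rather than wrappers
around external tools, so each can be checked against an independent
oracle:

1. **Trimming.** An adapter segment of length $L$ matches with at most
   $\lfloor e \cdot L \rfloor$ errors (substitutions and indels),
   $e = 0.25$ by default. Among allowed candidates the best match has the
   **most matched bases** ($L - \text{errors}$), then the fewest errors,
   then the leftmost start; the 3' adapter may be truncated at the read
   end (minimum overlap 3 nt). We deliberately rank by matched bases
   rather than raw error count: under a fewest-errors-first rule a
   coincidental 3 nt perfect end-overlap would outrank a full 20 nt
   adapter occurrence carrying allowed errors and trim at the wrong
   position. Reads in which no adapter is found are *retained* and flagged
   (`keep_untrimmed = FALSE` discards them instead); the analysis this
   package models does not state either behaviour, so both are exposed.
2. **Demultiplexing** is exact-prefix matching — no mismatch allowance is
   granted because none is documented; barcodes land in an `undetermined`
   bin otherwise, and every input read is accounted for in exactly one bin
   (assigned / undetermined / discarded-short / discarded-empty).
3. **Length filter** at 16 nt, applied to the insert after barcode
   removal.
4. **Collapsing** of identical sequences with deterministic ordering
   (descending count, then lexicographic).

# Alignment: the best-stratum contract

A read is placed at every genomic offset, on both strands, whose Hamming
distance to the reference equals the minimum achievable distance $d^*$,
and only if $d^* \le 3$. Alignment is ungapped; indels are out of
contract, mirroring `-v`-style alignment of the short-read aligners this
emulates. Internally the search has two tiers — a hashed window table that
resolves the 0-mismatch stratum exactly, and a Biostrings scan for reads
with no exact placement — but the implementation's contract is equality
with an exhaustive scan over every offset, which the test suite enforces
on hundreds of reads against toy genomes.

The length-dependent mismatch filter then accepts an alignment of a read
of length $\ell$ with $m$ mismatches iff $m \le$ 0, 1, 2, 3 for
$\ell \in$ 16–17, 18–19, 20–24, $\ge 25$ respectively. The stratum is
computed **before** filtering and the filter applied to surviving stratum
members; reads failing at one locus are not re-stratified to a worse
stratum elsewhere (a declared choice — the source analysis does not say).

# Classification rules

- **miRNA (±5 window).** A read is assigned to a mature miRNA arm iff some
  surviving alignment lies on the arm's strand and its 5' end (`start0` on
  `+`, `end0 − 1` on `−`) falls within ±5 nt of the annotated mature 5'
  position. Sense-only assignment is a design choice (D1): mature miRNAs
  are single-stranded and the guide/passenger (g/p) arm labels only make
  sense in transcript orientation. Ties across overlapping anchors go to
  the nearest anchor, then guide over passenger.
- **Containment (D2).** "Mapped within the annotated region" is read as
  full containment of the alignment interval, not mere overlap; a read
  straddling a boundary is not assigned to the feature. The alternative
  (any-overlap) is not exposed because containment is the stricter reading
  and the simulator only emits contained reads — a green truth-recovery
  test would not distinguish them.
- **endo-siRNA.** A read counts toward gene $G$ iff some surviving
  alignment is antisense to and contained in a 5'UTR, coding exon or 3'UTR
  of $G$. Sense-contained reads flow to the `gene_sense` ("other") class.
- **Multi-mappers (D3).** A read with $n$ surviving alignments contributes
  weight $\text{count}/n$ to each hit (`count_mode = "fractional"`);
  `"all"` gives integer counting for sensitivity analysis.
- **Single-label summary (D4).** For the read-distribution summary each
  read gets one label by precedence miRNA > rRNA > tRNA > piRNA(sense) >
  transposon > gene-antisense (endo-siRNA) > gene-sense > unannotated,
  with sense beating antisense within a class. Structural RNAs outrank
  ambiguous hits; antisense gene reads are endo-siRNAs. Antisense hits to
  piRNA loci fall through (21U biology is sense-stranded).

# Differential expression

The normalization and test re-implement the standard two-group count
workflow for small replicate numbers:

- **TMM factors.** The reference library is the one whose upper-quartile
  count fraction is closest to the mean. For library $j$ vs the reference,
  $M$ and $A$ values are computed on features nonzero in both; the top and
  bottom 30% of $M$ and 5% of $A$ are rank-trimmed; the factor is
  $2^{\sum w M / \sum w}$ with delta-method weights
  $w^{-1} = \frac{N_j - y_j}{N_j y_j} + \frac{N_r - y_r}{N_r y_r}$;
  factors are rescaled to geometric mean 1.
- **qCML common dispersion.** Counts are mapped to pseudo-counts at the
  geometric-mean effective library size by a moderated quantile match (the
  average of a normal- and a gamma-approximation quantile transform), and
  a single dispersion maximizes the summed conditional log-likelihood
  given per-group pseudo-totals, searched on the log scale over
  $[10^{-6}, 10]$ to tolerance $10^{-6}$, alternating with re-equalization
  until stable. No tagwise shrinkage is attempted (a non-goal).
- **Exact test.** Conditional on a feature's pseudo-total $s$, the split
  between groups follows the convolution of per-group negative binomials;
  because both groups share the NB success probability, the conditional
  distribution depends only on the group sizes and the dispersion. The
  two-sided p-value doubles the smaller tail (capping at 1). Group
  pseudo-sums are rounded to the nearest integer before enumeration —
  sub-integer agreement with any particular external implementation is a
  non-goal; the binding oracle is exhaustive conditional enumeration,
  which the tests apply for every total $\le 30$ at $10^{-10}$.
- **logFC** uses normalized group mean rates with a proportional prior
  count of 0.125 per library; **FDR** is Benjamini–Hochberg; the
  `direction` call uses FDR < `alpha` (0.05 — the significance convention
  assumed wherever "significantly changed" counts are reproduced).
- **Low-abundance filter.** Features below 1 CPM in fewer than
  (smallest group size) libraries are *flagged* and not tested; both
  thresholds are arguments and may be 0. The filter is visible in the
  output rather than silent.

**On scale invariance.** No stage of this workflow is exactly invariant to
multiplying one library's counts by a constant $c$: TMM's inverse-variance
weights mix a term that scales as $1/c$ with an unscaled reference term,
and the exact test conditions on pseudo-totals whose magnitude — the
information content of the data — scales with depth (the equalized common
size scales as $c^{1/n}$). Measured effects are small (median
$|\Delta p| \approx 4\times10^{-3}$ at $c = 3$ with 6 libraries, log2-CPM
perturbation $\sim 10^{-3}$), and the reference implementations of this
workflow behave identically, but a $10^{-9}$-level invariance claim would
be false for the method family; the tests therefore assert CPM stability
at 0.02 on the log2 scale and leave p-value invariance undocumented as an
exact property.

# Phenotype statistics

Penetrance comparisons (adult alae categories, ASE neuron marker) use the
Pearson chi-square statistic $\sum (O-E)^2/E$ without continuity
correction, $df = (r-1)(c-1)$, on raw animal counts only — non-integer
cells are refused because the statistic is not invariant under row
scaling. Seam cell counts use the two-tailed t test; Welch's
unequal-variance form with Welch–Satterthwaite degrees of freedom is the
default because the source analyses do not state an equal-variance
assumption (`pooled = TRUE` restores the classical test). Stars map to
p < 0.05 / 0.01 / 0.001.

# What the simulator emulates — and what it does not

`build_genome()` packs non-overlapping features with random gaps onto
uniform-random chromosomes (defaults: 2 × 30 kb; 30 miRNA hairpins of
70 nt with guide/passenger mature 5' anchors at offsets +2 and +40; 30
piRNA loci of 30 nt with a forced genomic T at the sense 5' end; 10 tRNA,
5 rRNA, 10 transposon loci; 40 genes of 5'UTR(100) + exon(200) +
intron(50) + exon(200) + 3'UTR(100)). `simulate_libraries()` draws each
library's reads from a multinomial over sampling units whose weights
combine the class proportions, a fixed log-normal per-feature abundance
skew (shared across libraries), and the spike table in mutant libraries.

Stated-world defaults: 3 replicates per group; class proportions 45%
miRNA, 25% endo-siRNA, 8% piRNA, 8% tRNA, 6% rRNA, 4% transposon, 2%
gene-sense, 2% intergenic — a miRNA-dominant library with a substantial
antisense siRNA fraction, chosen as a qualitative caricature of real read
distributions, not a quantitative claim. Insert lengths live in the
18–26 nt gel-selection window (miRNA peak at 22, piRNA exactly 21,
endo-siRNA peak 22); miRNA 5' ends are drawn at offsets −2..+2 around the
mature anchor (probabilities 0.05/0.15/0.60/0.15/0.05) so the ±5
window rule is exercised inside its acceptance region, while boundary
offsets are covered by direct unit tests; antisense reads prefer a 5' G
(22G-style) by rejection sampling. Barcodes are 4 nt at pairwise Hamming
distance ≥ 2, prepended 5' of the insert — the barcode design of the
emulated experiment is unpublished, so the convention is declared in the
output metadata rather than inferred. The substitution error rate defaults
to 0.001/base; quality strings are constant. The default read length of
50 nt leaves the 3' adapter complete for the largest default insert;
shorter read lengths truncate it, which the trimmer handles.

Not modelled: ligation bias, PCR duplication, indel sequencing errors,
expression correlation between features, and any quantitative match to a
real deposit's read-count spectrum. Consequently a green end-to-end test
establishes that the pipeline's *rules* are implemented exactly (class
recovery is checked for equality against ground truth at zero error rate
under unique mapping), not that it is robust to artefacts real libraries
contain.

# Numerical and degenerate-input choices

- Same seed ⇒ byte-identical FASTA/GFF3/FASTQ output; gzip output carries
  a fixed timestamp, so even compressed bytes reproduce.
- N bases count as mismatches everywhere and never match adapters or
  barcodes; reads of non-ACGTN symbols are input errors.
- Alignment output ordering is (chromosome, start, strand); collapse
  ordering is (count desc, sequence); DE output ordering is (FDR,
  feature). Ties in miRNA assignment break as described above.
- Zero-read libraries are valid (warning, empty FASTQ); all-zero features
  get p = 1, logFC = 0, and a flag; zero-total libraries and tables with a
  zero column total are errors naming the offender.
- The dispersion search bound $[10^{-6}, 10]$ is also the reporting range:
  Poisson-like data pins the estimate to the lower bound.

# Known limitations

- The aligner's window tables hold all genome substrings of each read
  length in memory; fine for desk-scale references (tens of kb to a few
  Mb), not for a real genome — there the same contract would be served by
  an FM-index-backed tool emitting the identical stratum.
- The approximate-trimming dynamic program is quadratic per read and runs
  in R; it is reached only by reads without a perfect full-adapter
  occurrence, which is rare at realistic error rates.
- Fractional multi-mapper weights make count tables non-integer; the exact
  test rounds pseudo-sums, which is the documented behaviour, not an
  accident.
- `chisq_penetrance` warns (via `low_expected`) but does not switch to an
  exact test when expected cells fall below 5, matching the emulated
  analyses.
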