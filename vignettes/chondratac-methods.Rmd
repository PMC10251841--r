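---
title: "Methods: consensus open chromatin, GWAS enrichment and TF footprints"
author: "chondratac"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus open chromatin, GWAS enrichment and TF footprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chondratac)
```

chondratac re-implements, as one tested package, the integration analysis
typically run over bulk ATAC-seq of a proliferating cell population (here
modelled on fetal bovine chondrocytes) together with matched RNA-seq: QC of
the Tn5 fragment signal, peak calling, replicate-consensus peak
construction, genomic feature annotation, over-representation analysis,
GWAS-SNP enrichment, motif/footprint analysis, and expression filtering.
This vignette documents the models, the parameters that matter, the
numerical choices, and what the synthetic data do and do not establish.

## Coordinates and containers

All on-disk interval formats are BED: 0-based, half-open. In memory the
package uses `GRanges` (1-based, closed) — the container the R genomics
stack is built on — and converts only at the I/O boundary. The half-open
semantics survive the conversion: abutting intervals overlap 0 bp, and a
SNP at a peak's `end` coordinate is outside the peak. We chose `GRanges`
over a bespoke half-open record because every interval operation here
(overlap search, union, coverage, disjoint segmentation) is an
industrial-strength one-liner on it, and a second interval convention
inside the package would be a standing source of off-by-one bugs.

## Signal model and QC

**Cut-site correction.** Tn5 inserts as a dimer and duplicates 9 bp of
target sequence; the transposition centre sits +4/−5 bp from the read 5′
ends. `tn5_shift()` applies exactly that: +4 on "+", −5 on "−", clamping
at position 0 with a warning. Both ends of every fragment are corrected
cut sites.

**Fragment classes and periodicity.** Fragments are binned as
nucleosome-free (< 100 bp), mono (150–250), di (350–450), tri (550–650)
or other. The ladder period is estimated as the argmax, over lags 100–300
bp, of the normalized autocorrelation of the 1-bp fragment-length
histogram, after three deliberate pre-processing steps:

* only fragments ≥ 100 bp enter the histogram — the sub-nucleosomal mode
  otherwise cross-correlates with the mono-nucleosome peak and produces a
  spurious ~145 bp period;
* the histogram is trimmed to its occupied support before mean-centering —
  flat zero flanks bias the argmax upward by ~8–9 bp;
* a 5-bp running mean suppresses bin noise.

A distribution is called periodic when the maximum autocorrelation
reaches 0.2. Uniform-length noise stays below 0.05 after smoothing and a
genuine 200/400/600 ladder scores ~0.5, so the threshold sits well away
from both; a single repeated length or an empty nucleosomal range is
flagged aperiodic.

**TSS enrichment.** Cut density in ± 100 bp of the TSS divided by the
density in the outermost 100 bp tails of a strand-oriented ± 2 kb window,
aggregated over all genes. Empty tails yield an infinite score with an
explicit flag rather than an error.

## Peak calling

The caller mirrors the shift/extsize parametrization common for ATAC
(`shift = −100`, `extsize = 200`: a 200 bp window centred on each cut)
with a deliberately simple background: one genome-wide Poisson rate
λ = total pileup mass / genome length. For every covered position with
pileup k the upper-tail p-value P(X ≥ k) is computed, BH correction is
applied across covered positions only (uncovered genome would inflate the
correction denominator without carrying information), significant
positions (q < 0.05) are merged across gaps < 30 bp, and merged regions
shorter than `extsize` are discarded; the summit is the leftmost pileup
maximum. Merge gap and minimum length are conventional defaults exposed
as arguments. Because p is monotone in k, BH reduces to a pileup
threshold; the implementation works on run-length encodings, and its
weighted BH is tested against `p.adjust` on the expanded vector.

There is no local background, duplicate filtering, or model building:
the consensus rule downstream is the analysis's own contribution and is
independent of which caller produced the replicate peak sets.

## Replicate consensus

A replicate peak is retained iff some other replicate contains a peak
whose overlap exceeds 50 % *of both peaks' lengths* (reciprocal, strict
`>`); with `min_replicates = 2` that is "present in at least two
replicates". Retained peaks overlapping across replicates are unioned
transitively, and the consensus interval spans their outer bounds. The
reciprocal reading is the stricter, symmetric interpretation of an
overlap criterion stated "in the two replicates"; strictness follows the
wording "more than 50 %". One boundary case is resolved pragmatically: a
complete overlap (fraction exactly 1, e.g. identical intervals) passes
any threshold, including 1, where literal strictness would reject a
perfect reproduction. Each replicate set must be internally
non-overlapping (`merge_intervals()` pre-merges); the output is sorted,
non-overlapping, and carries the supporting replicate set.

## Annotation

Feature tracks derive from the gene models: promoter = TSS ± 3000 bp
(strand-aware TSS, window inclusive of both endpoints), 5′/3′ UTRs as the
exonic sequence outside the CDS split by transcription direction, exon as
the coding exon bodies (whole exons for non-coding genes), intron as gene
span minus exons, downstream as 3000 bp past the 3′ end. A peak takes the
highest-priority category it overlaps by ≥ 1 bp, in the order promoter >
5′UTR > 3′UTR > exon > intron > downstream, else distal intergenic.
Downstream and distal intergenic are placed after intron — the two
categories the priority list leaves open — matching the convention of
annotation tools that report them last. The ≥ 1 bp rule (rather than
midpoint containment) is what makes a priority necessary at all: a peak
may overlap several features.

Nearest genes are assigned by |peak midpoint − TSS| with lexicographic
gene-id tie-break, and the signed distance is negative upstream in gene
orientation. The ORA layer is a plain hypergeometric upper tail over any
user-supplied term map with BH adjustment (significant at p ≤ 0.01);
curated GO/KEGG content is out of scope because term-level results are
database-version-dependent.

## GWAS-SNP permutation enrichment

The statistic is the candidates' in-peak proportion. Each of `n_perm`
(default 10,000) permutations draws the *same number* of SNPs from the
panel without replacement; fold = observed / mean(null), and the
one-tailed empirical p uses the add-one correction
(1 + #{null ≥ obs}) / (1 + n_perm), so p is never 0 and the test is
valid at finite permutation counts. Size-matched draws are a deliberate
choice: letting the draw size itself vary randomly would make the null a
mixture over sample sizes and the fold ill-defined. Draws are
without-replacement by default (`replace = TRUE` available); the panel is
canonically sorted first so results are invariant to input row order.

The resampling panel is an explicit argument. With real data the
candidates are a p-value-selected subset of the panel, and the
contaminated null this implies is the price of the design. In the
synthetic fold-recovery experiments the candidates are *planted* at a
known fold over an independent background panel; there the background
panel alone is the null, because including 20,000 fold-3 candidates in a
50,000-SNP panel would shift the null in-peak rate enough that the
planted fold is no longer the estimand. The pipeline's demo stage keeps
candidates in the panel (the real-data contract) and its report says the
fold is diluted accordingly.

## Motif scanning and footprints

PWMs are 4 × L probability matrices (A,C,G,T rows; columns sum to 1)
with a pseudocount (default 0.01) applied before log2-odds scoring
against a uniform background (configurable). Both strands are scanned;
windows containing N are skipped; minus-strand hits are reported at
their forward-strand window start. Motif enrichment counts sequences
with ≥ 1 hit at 80 % of the motif's maximum score in target vs background
sets and applies a one-tailed hypergeometric test, BH-adjusted across the
motif library.

Footprints are aggregate profiles: cut counts per base offset in ± 100 bp
frames around motif centres, strand-oriented. The depth score is the mean
count over the outermost 20 bp flanks divided by the mean over the motif
span, with the denominator floored at one count so a perfectly protected
(all-zero) centre yields a large finite score rather than a division by
zero. A TF is called active when depth ≥ 1.5 *and* the global minimum of
the 5-bp-smoothed profile falls inside the motif span — the formalization
of "a clean centred dip" as opposed to a disordered curve that happens to
have high variance; profiles from fewer than 50 sites are indeterminate.
This transparent classifier deliberately replaces HMM-based footprinters
with sequence-bias correction; Tn5 sequence bias is out of scope, and the
depth+shape criterion captures exactly the visual evidence the
active/inactive distinction rests on. Activity calls are cross-checked
against RNA-seq: a TF whose gene has mean TPM > 2 is expressed, and
active ∧ expressed (or inactive ∧ silent) is concordant.

## Expression

TPM divides counts by gene length in kb and rescales each sample to 10⁶
(column sums conserved to < 10⁻³; all-zero samples stay zero and are
flagged). The expressed-gene filter is strict mean TPM > 2; a gene at
exactly 2 is excluded. Replicate correlation is Pearson on log2(TPM + 1)
— the scale on which RNA-seq replicate agreement is conventionally
quoted; the raw scale is available via `log = FALSE`. Gene lengths
default to exon-length sums from the gene model when not supplied.

## The synthetic-data module

The generators produce every input with ground truth attached, at the
study's structure and desk scale: a 3 × 1 Mb genome with 100
non-overlapping genes; 200 true peaks of mean length 572 bp, half planted
in promoter windows and half explicitly avoiding them; three replicate
peak sets with dropout 0.2 and ± 10 % boundary jitter (the jitter bounds
reciprocal overlap of two observations of one peak below at 2/3, so
replicate agreement is governed by dropout alone); 100,000 fragments from
a 0.50/0.30/0.13/0.07 NFR/mono/di/tri mixture with 10× cut enrichment in
peaks and at TSSs; a 50,000-SNP background panel with fold-3 candidates;
motif sites placed one aggregation frame apart inside peaks, half
footprint-protected at depletion 0.5; and negative-binomial counts for 3
replicates.

Two generator parameters were calibrated once and frozen. The NB
dispersion is 2, chosen by sweeping dispersion against the mean
log-scale replicate correlation and targeting the ~0.8 replicate
agreement typical of the assay (the sweep gave r ≈ 0.99 at 0.05, 0.79 at
2, 0.47 at 5); with only 100 genes spanning five orders of magnitude of
TPM, the log-signal variance is large and a correspondingly large
dispersion is needed to pull correlation down to realistic levels.
Expression targets are drawn on the TPM scale directly — sub-threshold
genes at Uniform(0.05, 1.5), expressed genes sharing the remaining 10⁶
budget log-uniformly — so the TPM > 2 ground truth is well defined.

Every generator derives its RNG stream from the master seed plus a stage
tag, so outputs are byte-reproducible and independent of call order.

What the synthetic data do *not* emulate: genome sequence (motif
sequences are generated separately for the scanning stages), Tn5
sequence bias, GC/mappability structure, linkage disequilibrium between
SNPs, inter-gene correlation in expression, and library-specific
artefacts (duplicates, mitochondrial reads, adapter chimeras). Passing
tests therefore establish that the *statistics* behave as designed —
calibrated type-I error, unbiased fold recovery, oracle-exact interval
logic — not that the defaults are tuned for any particular real library.

## Problem sizes and runtime envelopes

The test suite exercises the statistical guarantees at sizes chosen to
make Monte-Carlo bounds tight while keeping the whole suite in minutes on
one core: 200 random 3-replicate instances (≤ 100 intervals each) for
exact consensus-oracle equivalence; 1,000 simulated null datasets at
1,000 permutations each for type-I calibration (rejection rate within
[0.03, 0.07]); 20 seeds of 50,000 cuts with planted 10× regions for
base-pair recall/precision ≥ 0.9; 20 seeds of 500 motif sites at
depletion 0.5 for depth ∈ [1.8, 2.2] (protected) vs [0.9, 1.1]
(unprotected); and the full pipeline twice at one seed for byte-identical
reports.

## Known limitations

* The Poisson caller's single global λ over-calls on genomes with strong
  coverage heterogeneity; it is a stand-in whose outputs feed a
  caller-agnostic consensus rule, not a MACS2 replacement.
* The footprint classifier has no Tn5 bias model; on real data, bias can
  fake or mask dips that the synthetic construction cannot produce.
* The permutation test treats SNPs as exchangeable points; LD blocks
  violate that and would need block-aware resampling.
* Nearest-gene assignment uses TSS-to-midpoint distance only; it does not
  consider gene bodies or expression weighting.
* `run_pipeline()`'s user-data mode expects pre-loaded R objects in the
  package's standard containers; alignment-level inputs (FASTQ/BAM) are
  out of scope, with fragment BED as the entry format.
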