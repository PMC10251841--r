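# chondratac

Consensus open-chromatin analysis for bulk ATAC-seq with GWAS enrichment,
TF footprinting and RNA-seq crosschecks — built around the regulatory
landscape of proliferating fetal bovine chondrocytes, and usable on any
small genome with replicate peak sets, fragments, SNPs, motifs and counts.

The package is aimed at analysts who have replicate-level ATAC-seq peak
and fragment data (plus optional GWAS summary statistics and RNA-seq
counts) and want a transparent, fully tested re-implementation of the
standard integration steps, together with a synthetic-data module that
generates every input *with ground truth* so each step's statistical
behaviour can be verified at desk scale.

## What it computes

- **Tn5 cut-site correction.** Read 5′ ends are shifted +4 bp on the +
  strand and −5 bp on the − strand to the transposition centre; both
  fragment ends contribute a cut site.
- **Signal QC.** Fragment classes (NFR < 100 bp, mono ≈ 200, di ≈ 400,
  tri ≈ 600 bp), the ~200 bp periodicity of the fragment-length histogram
  (autocorrelation over lags 100–300 bp), and a TSS enrichment score
  (cut density at TSS ± 100 bp over the outer tails of a ± 2 kb window).
- **Peak calling.** A sliding-window Poisson caller: each cut extended to
  `[pos − 100, pos + 100)`, per-bp pileup tested against a single
  genome-wide Poisson rate λ (upper tail, P(X ≥ k)), Benjamini–Hochberg
  over covered positions, significant stretches merged (< 30 bp gaps) and
  length-filtered (≥ 200 bp).
- **Replicate consensus.** A peak is retained iff it has a partner with
  *reciprocal* overlap > 50 % in at least one other replicate (≥ 2
  replicates total); retained peaks are unioned transitively across
  replicates into consensus peaks.
- **Annotation.** Single-category assignment by the priority
  promoter > 5′UTR > 3′UTR > exon > intron > downstream > distal
  intergenic, with promoter = TSS ± 3 kb (strand-aware) and nearest-gene
  assignment by TSS-to-midpoint distance.
- **ORA.** Hypergeometric over-representation P(X ≥ k | N, K, n) over a
  user-supplied gene–term map, BH-adjusted, significant at p ≤ 0.01.
- **GWAS enrichment.** Observed in-peak proportion of candidate SNPs vs
  10,000 size-matched draws from the SNP panel;
  fold = observed / mean(null); one-tailed empirical
  p = (1 + #{null ≥ obs}) / (1 + n_perm).
- **Motif & footprint.** Log-odds PWM scanning on both strands, one-tailed
  hypergeometric target-vs-background motif enrichment, aggregate cut
  profiles in ± 100 bp frames around motif centres, and an
  active/inactive call from footprint depth (flank mean / motif-span
  mean ≥ 1.5) plus a centred-trough shape criterion — verified against
  expression (mean TPM > 2) of the TF's gene.
- **Expression.** TPM (per-sample columns sum to 10⁶), the strict
  mean-TPM > 2 expressed-gene filter, and replicate Pearson correlation on
  log2(TPM + 1).

## Worked example

The numbered drivers under `analysis/` run the whole study on synthetic
data (seed 7), writing tables under `results/synthetic/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_signal_qc.R
Rscript analysis/03_peaks_consensus.R
# ... through analysis/07_expression.R
```

Stage 1 plants the ground truth:

```
genome: 3 chromosomes x 1e+06 bp, 100 genes
true peaks: 200 (mean 563 bp, 3.8% of genome), 99 in promoters
replicate peak sets: 165 / 154 / 159
```

Stage 2 recovers the ATAC hallmarks — the nucleosome ladder
(`period 199 bp`) and TSS-concentrated cuts:

```
fragment-length periodicity: detected (period 199 bp, max acf 0.25)
TSS enrichment score: 4.01 (center 36.8905 vs tail 9.1900 cuts/bp)
```

Stage 3 reproduces the consensus construction; with per-replicate dropout
0.2 the expected recovery of a true peak in ≥ 2 of 3 replicates is
0.896, and the run observes:

```
consensus: 171 peaks, mean length 609 bp, 3.47% of genome
true-peak recovery: 0.855 (binomial expectation with dropout 0.2: 0.896)
```

Stage 5 tests the planted fold-3 SNP enrichment
(`fold: 2.744, one-tailed empirical p: 9.999e-05` — slightly diluted
because the candidates are themselves part of the resampled panel), and
stage 6 separates the protected from the unprotected motif sites
(`footprint depth: protected 1.91 (active), unprotected 1.01 (inactive)`)
and confirms both calls against expression.

The same workflow is available as one call:

```r
library(chondratac)
report <- run_pipeline(run_config(sim = simulation_config(seed = 7)))
report$stages$consensus
```

Identical seed and configuration produce a byte-identical
`report.json`.

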