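#!/usr/bin/env Rscript
## Stage 3 -- peak calling and replicate consensus.
##
## Calls peaks on the pooled corrected cut sites with the sliding-window
## Poisson caller (shift -100, extsize 200), then builds the consensus peak
## set: peaks present in >= 2 replicates with > 50% reciprocal overlap,
## unioned across replicates.

suppressPackageStartupMessages({
  library(chondratac)
  library(GenomicRanges)
})

out <- "results/synthetic"
cl <- setNames(rep(1e6, 3), paste0("chr", 1:3))
frags <- read_bed(file.path(out, "fragments.bed"))
truth <- read_bed(file.path(out, "true_peaks.bed"))
cuts <- fragment_cut_sites(frags)

called <- call_peaks(cuts, cl)
write_narrowpeak(called, file.path(out, "called_peaks.narrowPeak"))
rp <- bp_recall_precision(called, truth)
cat(sprintf("Poisson caller: %d peaks (mean %.0f bp); vs planted peaks recall %.3f, precision %.3f\n",
            length(called), mean(width(called)), rp$recall, rp$precision))
cat("  (precision vs planted peaks is an underestimate: TSS windows are\n")
cat("   cut-enriched too and get called, as they should be)\n")

reps <- lapply(paste0("peaks_rep", 1:3), function(nm) {
  read_bed(file.path(out, paste0(nm, ".bed")))
})
names(reps) <- paste0("rep", 1:3)
cons <- consensus_peaks(reps, min_replicates = 2, threshold = 0.5)
write_bed(cons, file.path(out, "consensus_peaks.bed"))

recov <- mean(countOverlaps(truth, cons) > 0)
cat(sprintf("consensus: %d peaks, mean length %.0f bp, %.2f%% of genome\n",
            length(cons), mean(width(cons)),
            100 * genome_fraction(cons, cl)))
cat(sprintf("true-peak recovery: %.3f (binomial expectation with dropout 0.2: %.3f)\n",
            recov, choose(3, 2) * 0.8^2 * 0.2 + 0.8^3))
print(table(support = cons$support))
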