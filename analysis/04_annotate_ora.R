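#!/usr/bin/env Rscript
## Stage 4 -- genomic feature annotation and over-representation analysis.
##
## Assigns each consensus peak a single category by the priority
## promoter > 5'UTR > 3'UTR > exon > intron > downstream > distal
## intergenic (promoter = TSS +/- 3 kb), attaches the nearest gene, and
## tests the promoter-peak genes for term over-representation against a
## synthetic term map carrying one planted enriched term.

suppressPackageStartupMessages({
  library(chondratac)
  library(GenomicRanges)
})

out <- "results/synthetic"
cl <- setNames(rep(1e6, 3), paste0("chr", 1:3))
genes <- read_gene_table(file.path(out, "genes.tsv"))
cons <- read_bed(file.path(out, "consensus_peaks.bed"))

tracks <- feature_tracks(genes, cl)
ann <- annotate_peaks(cons, tracks, genes)
write_annotation(ann, file.path(out, "peak_annotation.tsv"))
summ <- annotation_summary(ann)
write.table(summ, file.path(out, "annotation_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("peak category distribution (%):\n")
print(summ, row.names = FALSE)

promoter_genes <- unique(na.omit(ann$nearest_gene[ann$category == "promoter"]))
term_map <- simulate_term_map(genes$gene_id, enriched_genes = promoter_genes,
                              seed = 7)
ora <- ora_test(promoter_genes, term_map, genes$gene_id)
write.table(ora, file.path(out, "ora_results.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("\nORA over %d promoter-peak genes, %d terms; %d significant at BH p <= 0.01\n",
            length(promoter_genes), nrow(ora), sum(ora$significant)))
print(head(ora, 3), row.names = FALSE)
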