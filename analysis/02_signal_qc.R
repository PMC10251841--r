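#!/usr/bin/env Rscript
## Stage 2 -- fragment-level and TSS-level signal QC.
##
## Checks the two ATAC hallmarks: the nucleosome-ladder periodicity of the
## fragment-length distribution (~200 bp) and the concentration of Tn5 cut
## sites at transcription start sites.

suppressPackageStartupMessages({
  library(chondratac)
  library(GenomicRanges)
})

out <- "results/synthetic"
frags <- read_bed(file.path(out, "fragments.bed"))
genes <- read_gene_table(file.path(out, "genes.tsv"))
cuts <- fragment_cut_sites(frags)

cls <- table(fragment_class(width(frags)))
cls_pct <- round(100 * cls / sum(cls), 2)
write.table(data.frame(class = names(cls), count = as.integer(cls),
                       percent = as.numeric(cls_pct)),
            file.path(out, "fragment_classes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

per <- fragment_periodicity(width(frags))
te <- tss_enrichment(cuts, genes)
write.table(data.frame(offset = names(te$profile), count = te$profile),
            file.path(out, "tss_profile.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
export_bedgraph(cuts, file.path(out, "cut_sites.bedgraph"),
                chrom_lengths = setNames(rep(1e6, 3), paste0("chr", 1:3)))

cat("fragment classes (%):\n")
print(cls_pct)
cat(sprintf("fragment-length periodicity: %s (period %s bp, max acf %.2f)\n",
            if (per$periodic) "detected" else "absent",
            format(per$period), max(per$acf)))
cat(sprintf("TSS enrichment score: %.2f (center %.4f vs tail %.4f cuts/bp)\n",
            te$score, te$center_density, te$tail_density))
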