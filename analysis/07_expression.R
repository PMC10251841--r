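#!/usr/bin/env Rscript
## Stage 7 -- RNA-seq TPM normalization, expressed-gene filter and
## replicate-correlation QC.

suppressPackageStartupMessages(library(chondratac))

out <- "results/synthetic"
counts <- read_counts(file.path(out, "counts.tsv"))
lens <- read.table(file.path(out, "gene_lengths.tsv"),
                   col.names = c("gene_id", "length"))
tpm <- compute_tpm(counts, setNames(lens$length, lens$gene_id))
write.table(data.frame(gene_id = rownames(tpm), round(tpm, 4),
                       check.names = FALSE),
            file.path(out, "tpm.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

expr <- expressed_genes(tpm, threshold = 2)
writeLines(expr, file.path(out, "expressed_genes.txt"))
rc <- replicate_correlation(tpm)
write.table(round(rc, 4), file.path(out, "replicate_correlation.tsv"),
            sep = "\t", quote = FALSE)

cat(sprintf("TPM column sums: %s (per-million budget conserved)\n",
            paste(format(colSums(tpm), big.mark = ","), collapse = " / ")))
cat(sprintf("expressed genes (mean TPM > 2): %d of %d\n",
            length(expr), nrow(tpm)))
cat("replicate Pearson correlation on log2(TPM + 1):\n")
print(round(rc, 3))
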