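#!/usr/bin/env Rscript
## Stage 1 -- generate the synthetic study data.
##
## Emulates the structure of a 3-replicate fetal chondrocyte ATAC-seq +
## RNA-seq experiment on a 3 x 1 Mb genome: 200 true open-chromatin peaks
## (mean 572 bp, half in +/-3 kb promoter windows), a nucleosome-ladder
## fragment mixture with 10x cut enrichment in peaks and at TSSs, a
## 50,000-SNP panel with fold-3 peak-enriched candidates, footprint-
## protected motif sites, and negative-binomial counts for 3 replicates.
## All observables plus their ground truth land under results/synthetic/.

suppressPackageStartupMessages({
  library(chondratac)
  library(GenomicRanges)
})

out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
cfg <- simulation_config(seed = 7)

genome <- make_genome(cfg)
write_gene_table(genome$genes, file.path(out, "genes.tsv"))

pk <- simulate_replicate_peaks(genome, cfg)
write_bed(pk$true_peaks, file.path(out, "true_peaks.bed"))
for (nm in names(pk$replicates)) {
  write_bed(pk$replicates[[nm]], file.path(out, paste0("peaks_", nm, ".bed")))
}

fr <- simulate_fragments(genome, pk$true_peaks, cfg)
write_bed(fr$fragments, file.path(out, "fragments.bed"))

sn <- simulate_snps(genome, pk$true_peaks, cfg)
write_snp_table(sn$background, file.path(out, "snps_background.tsv"))
write_snp_table(sn$candidates, file.path(out, "snps_candidates.tsv"))

pwm <- consensus_pwm("TGACTCAG", name = "TF1")
write_pwm(pwm, file.path(out, "motif.pwm"))
fp <- simulate_footprint_sites(genome, pk$true_peaks, pwm, cfg)
sites_out <- fp$sites
mcols(sites_out)$name <- ifelse(sites_out$bound, "bound", "unbound")
mcols(sites_out)$bound <- NULL
write_bed(sites_out, file.path(out, "motif_sites.bed"))
write_bed(fp$cut_sites, file.path(out, "footprint_cuts.bed"))

cnt <- simulate_counts(genome, cfg)
write_counts(cnt$counts, file.path(out, "counts.tsv"))
writeLines(paste(names(cnt$gene_lengths), cnt$gene_lengths, sep = "\t"),
           file.path(out, "gene_lengths.tsv"))

seqs <- simulate_motif_sequences(pwm, seed = cfg$seed)
write_fasta(setNames(seqs$target, sprintf("target_%03d", seq_along(seqs$target))),
            file.path(out, "target_sequences.fa"))
write_fasta(setNames(seqs$background,
                     sprintf("background_%03d", seq_along(seqs$background))),
            file.path(out, "background_sequences.fa"))

jsonlite::write_json(unclass(cfg), file.path(out, "config.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat(sprintf("genome: %d chromosomes x %g bp, %d genes\n",
            cfg$n_chroms, cfg$chrom_length, nrow(genome$genes)))
cat(sprintf("true peaks: %d (mean %.0f bp, %.1f%% of genome), %d in promoters\n",
            length(pk$true_peaks), mean(width(pk$true_peaks)),
            100 * genome_fraction(pk$true_peaks, genome$chrom_lengths),
            sum(pk$true_peaks$in_promoter)))
cat(sprintf("replicate peak sets: %s\n",
            paste(lengths(pk$replicates), collapse = " / ")))
cat(sprintf("fragments: %d; SNP panel: %d background + %d candidates\n",
            length(fr$fragments), nrow(sn$background), nrow(sn$candidates)))
cat(sprintf("motif sites: %d (%d footprint-protected); genes with counts: %d\n",
            length(fp$sites), sum(fp$sites$bound), nrow(cnt$counts)))
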