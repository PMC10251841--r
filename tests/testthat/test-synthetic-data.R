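test_that("simulation_config validates its inputs", {
  expect_s3_class(simulation_config(), "simulation_config")
  expect_error(simulation_config(fragment_mixture = c(0.5, 0.5, 0.1, 0)),
               "sum to 1")
  expect_error(simulation_config(replicate_dropout = 1.2), "\\[0, 1\\]")
  expect_error(simulation_config(n_genes = -1), ">= 0")
})

test_that("make_genome places valid, reproducible gene models", {
  cfg <- simulation_config(seed = 3)
  g <- make_genome(cfg)
  expect_equal(nrow(g$genes), cfg$n_genes)
  expect_false(any(duplicated(g$genes$gene_id)))
  expect_true(all(g$genes$start >= 1))
  expect_true(all(g$genes$end <= g$chrom_lengths[g$genes$chrom]))
  ## genes non-overlapping within each chromosome
  for (cn in names(g$chrom_lengths)) {
    gs <- g$genes[g$genes$chrom == cn, ]
    gs <- gs[order(gs$start), ]
    if (nrow(gs) > 1) {
      expect_true(all(gs$start[-1] > gs$end[-nrow(gs)]))
    }
  }
  ## exons sorted, within span; CDS within span
  for (i in seq_len(nrow(g$genes))) {
    ex <- g$genes$exons[[i]]
    expect_true(all(diff(ex[, 1]) > 0))
    expect_true(all(ex[, 2] >= ex[, 1]))
    expect_gte(ex[1, 1], g$genes$start[i])
    expect_lte(ex[nrow(ex), 2], g$genes$end[i])
    if (!is.na(g$genes$cds_start[i])) {
      expect_gte(g$genes$cds_start[i], g$genes$start[i])
      expect_lte(g$genes$cds_end[i], g$genes$end[i])
    }
  }
  expect_identical(g, make_genome(cfg))
  g0 <- make_genome(simulation_config(n_genes = 0L))
  expect_equal(nrow(g0$genes), 0)
  expect_error(make_genome(simulation_config(n_chroms = 1L,
                                             chrom_length = 5e4,
                                             n_genes = 50L)),
               "without overlap")
})

test_that("gene table round-trips through TSV", {
  g <- make_genome(simulation_config(seed = 5, n_genes = 20L))
  tf <- tempfile(fileext = ".tsv")
  write_gene_table(g$genes, tf)
  back <- read_gene_table(tf)
  expect_equal(back$gene_id, g$genes$gene_id)
  expect_equal(back$cds_start, g$genes$cds_start)
  expect_equal(back$exons, g$genes$exons, ignore_attr = TRUE)
})

test_that("replicate peak sets follow the dropout model", {
  cfg0 <- simulation_config(seed = 2, replicate_dropout = 0)
  g <- make_genome(cfg0)
  pk0 <- simulate_replicate_peaks(g, cfg0)
  for (r in pk0$replicates) expect_length(r, cfg0$n_true_peaks)

  cfg1 <- simulation_config(seed = 2, replicate_dropout = 1)
  pk1 <- simulate_replicate_peaks(g, cfg1)
  for (r in pk1$replicates) expect_length(r, 0)

  ## replicate sets are internally non-overlapping (pre-merged)
  for (r in pk0$replicates) {
    expect_equal(length(merge_intervals(r)), length(r))
  }
})

test_that("consensus recovery of true peaks matches the binomial closed form", {
  ## P(present in >= 2 of 3 replicates) with dropout 0.2:
  ## choose(3,2)*.8^2*.2 + .8^3 = 0.896
  p_expect <- choose(3, 2) * 0.8^2 * 0.2 + 0.8^3
  se <- sqrt(p_expect * (1 - p_expect) / 200)
  cfg <- simulation_config(seed = 17, replicate_dropout = 0.2,
                           n_true_peaks = 200L)
  g <- make_genome(cfg)
  pk <- simulate_replicate_peaks(g, cfg)
  cons <- consensus_peaks(pk$replicates)
  recovered <- mean(countOverlaps(pk$true_peaks, cons) > 0)
  expect_lt(abs(recovered - p_expect), 3 * se)
})

test_that("fragment lengths follow the configured mixture", {
  cfg <- simulation_config(seed = 4, n_fragments = 20000L,
                           fragment_mixture = c(nfr = 1, mono = 0, di = 0,
                                                tri = 0))
  g <- make_genome(cfg)
  pk <- simulate_replicate_peaks(g, cfg)
  fr <- simulate_fragments(g, pk$true_peaks, cfg)
  expect_true(all(width(fr$fragments) < 100))

  cfg2 <- simulation_config(seed = 4, n_fragments = 10000L,
                            fragment_mixture = c(nfr = 0, mono = 1 / 3,
                                                 di = 1 / 3, tri = 1 / 3))
  fr2 <- simulate_fragments(g, pk$true_peaks, cfg2)
  lens <- width(fr2$fragments)
  h <- tabulate(lens)
  for (mode in c(200, 400, 600)) {
    window <- (mode - 50):(mode + 50)
    expect_gt(sum(h[window]) / length(lens), 0.25)
    local_mode <- window[which.max(h[window])]
    expect_lt(abs(local_mode - mode), 30)
  }
})

test_that("cut density inside peaks matches the configured enrichment", {
  cfg <- simulation_config(seed = 6, n_fragments = 50000L,
                           n_true_peaks = 50L, peak_length_mean = 2000,
                           peak_cut_enrichment = 10, tss_cut_enrichment = 1,
                           fragment_mixture = c(nfr = 1, mono = 0, di = 0,
                                                tri = 0))
  g <- make_genome(cfg)
  pk <- simulate_replicate_peaks(g, cfg)
  fr <- simulate_fragments(g, pk$true_peaks, cfg)
  cuts <- fr$cut_sites
  peak_bp <- sum(as.numeric(width(pk$true_peaks)))
  genome_bp <- sum(as.numeric(g$chrom_lengths))
  n_in <- sum(countOverlaps(cuts, pk$true_peaks) > 0)
  dens_in <- n_in / peak_bp
  dens_out <- (length(cuts) - n_in) / (genome_bp - peak_bp)
  expect_gt(dens_in / dens_out, 8)
  expect_lt(dens_in / dens_out, 12)
})

test_that("candidate SNPs hit peaks at the configured fold", {
  cfg <- simulation_config(seed = 8, snp_enrichment_fold = 1)
  g <- make_genome(cfg)
  pk <- simulate_replicate_peaks(g, cfg)
  sn <- simulate_snps(g, pk$true_peaks, cfg)
  pf <- genome_fraction(pk$true_peaks, g$chrom_lengths)
  se <- sqrt(pf * (1 - pf) / cfg$candidate_snp_count)
  expect_lt(abs(mean(sn$candidates$in_peak) - pf), 3 * se)

  cfg3 <- simulation_config(seed = 8, snp_enrichment_fold = 3,
                            candidate_snp_count = 50000L)
  sn3 <- simulate_snps(g, pk$true_peaks, cfg3)
  target <- 3 * pf
  se3 <- sqrt(target * (1 - target) / 50000)
  expect_lt(abs(mean(sn3$candidates$in_peak) - target), 3 * se3)

  expect_warning(
    simulate_snps(g, pk$true_peaks,
                  simulation_config(seed = 8, snp_enrichment_fold = 1000,
                                    candidate_snp_count = 500L)),
    "capped")
})

test_that("SNP positions use 0-based coordinates inside chromosome bounds", {
  cfg <- simulation_config(seed = 9, snp_count = 2000L,
                           candidate_snp_count = 500L)
  g <- make_genome(cfg)
  pk <- simulate_replicate_peaks(g, cfg)
  sn <- simulate_snps(g, pk$true_peaks, cfg)
  for (tab in sn) {
    expect_true(all(tab$pos >= 0))
    expect_true(all(tab$pos < g$chrom_lengths[tab$chrom]))
  }
  ## in_peak truth agrees with the interval test
  chk <- snp_in_peaks(sn$candidates, merge_intervals(pk$true_peaks))
  expect_equal(chk$in_peak, sn$candidates$in_peak)
})

test_that("count matrix honours the planted expressed fraction", {
  cfg <- simulation_config(seed = 12, n_genes = 1000L, chrom_length = 1e7,
                           low_expr_fraction = 0.3)
  g <- make_genome(cfg)
  cnt <- simulate_counts(g, cfg)
  expect_equal(dim(cnt$counts), c(1000L, 3L))
  tpm <- compute_tpm(cnt$counts, cnt$gene_lengths)
  expressed <- expressed_genes(tpm)
  se <- sqrt(1000 * 0.3 * 0.7)
  expect_lt(abs(length(expressed) - 700), 3 * se)
  ## ground-truth flags broadly agree with the realized filter
  expect_gt(mean((rownames(tpm) %in% expressed) == cnt$expressed_truth), 0.9)
})

test_that("generators are byte-deterministic under a fixed seed", {
  cfg <- simulation_config(seed = 21, n_fragments = 5000L,
                           snp_count = 2000L, candidate_snp_count = 300L)
  g <- make_genome(cfg)
  pk <- simulate_replicate_peaks(g, cfg)
  run <- function() {
    list(pk = simulate_replicate_peaks(g, cfg),
         fr = simulate_fragments(g, pk$true_peaks, cfg),
         sn = simulate_snps(g, pk$true_peaks, cfg),
         fp = simulate_footprint_sites(g, pk$true_peaks,
                                       consensus_pwm("ACGTACGT"), cfg),
         cnt = simulate_counts(g, cfg))
  }
  expect_identical(run(), run())
})
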