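make_simple_gene <- function(chrom = "chr1", strand = "+", start = 10001,
                             end = 20000, exons = NULL, cds = NULL) {
  if (is.null(exons)) exons <- cbind(start = start, end = end)
  g <- data.frame(gene_id = "G0001", chrom = chrom, strand = strand,
                  start = start, end = end,
                  cds_start = if (is.null(cds)) NA_integer_ else cds[1],
                  cds_end = if (is.null(cds)) NA_integer_ else cds[2],
                  stringsAsFactors = FALSE)
  g$exons <- list(exons)
  g
}

test_that("promoter windows are strand-aware and centred on the TSS", {
  cl <- c(chr1 = 100000)
  gp <- make_simple_gene(strand = "+", start = 10001, end = 20000)
  tr <- feature_tracks(gp, cl)
  expect_equal(start(tr$promoter), 10001 - 3000)
  expect_equal(end(tr$promoter), 10001 + 3000)

  gm <- make_simple_gene(strand = "-", start = 40001, end = 50000)
  trm <- feature_tracks(gm, cl)
  expect_equal(start(trm$promoter), 50000 - 3000)
  expect_equal(end(trm$promoter), 50000 + 3000)
  ## downstream flanks the 3' end on the correct side
  expect_equal(start(trm$downstream), 40001 - 3000)
  expect_equal(end(trm$downstream), 40000)
})

test_that("UTR/exon/intron tracks derive from exon-CDS structure", {
  cl <- c(chr1 = 100000)
  ex <- cbind(start = c(10001, 13001, 16001), end = c(11000, 14000, 20000))
  g <- make_simple_gene(exons = ex, cds = c(10501, 18000))
  tr <- feature_tracks(g, cl)
  expect_equal(start(tr$`5'UTR`), 10001)
  expect_equal(end(tr$`5'UTR`), 10500)
  expect_equal(start(tr$`3'UTR`), 18001)
  expect_equal(end(tr$`3'UTR`), 20000)
  expect_equal(length(tr$intron), 2)
  ## coding exon bodies lie within the CDS
  expect_true(all(start(tr$exon) >= 10501 & end(tr$exon) <= 18000))

  single <- make_simple_gene(cds = c(12000, 18000))
  expect_length(feature_tracks(single, cl)$intron, 0)

  noncoding <- make_simple_gene()
  trn <- feature_tracks(noncoding, cl)
  expect_length(trn$`5'UTR`, 0)
  expect_length(trn$`3'UTR`, 0)
  expect_gt(length(trn$exon), 0)
})

test_that("priority resolves multi-category peaks and default is intergenic", {
  cl <- c(chr1 = 100000)
  g <- make_simple_gene(cds = c(12000, 18000))
  tr <- feature_tracks(g, cl)
  ## overlaps the promoter window and the exon body
  both <- GRanges("chr1", IRanges(12500, 13500))
  ann <- annotate_peaks(both, tr, g)
  expect_equal(as.character(ann$category), "promoter")

  nowhere <- GRanges("chr1", IRanges(80001, 80500))
  ann2 <- annotate_peaks(nowhere, tr, g)
  expect_equal(as.character(ann2$category), "distal_intergenic")
  expect_equal(ann2$nearest_gene, "G0001")
})

test_that("peak categories equal the per-base priority oracle", {
  set.seed(61)
  for (inst in 1:8) {
    cfg <- simulation_config(seed = 100 + inst, n_genes = 15L,
                             n_chroms = 1L, chrom_length = 3e5)
    g <- make_genome(cfg)
    tr <- feature_tracks(g$genes, g$chrom_lengths)
    starts <- sample.int(295000, 25)
    peaks_df <- data.frame(chrom = "chr1", start = starts,
                           end = starts + sample(50:300, 25, replace = TRUE))
    ann <- annotate_peaks(df_to_gr(peaks_df), tr, g$genes)
    tr_df <- tracks_to_df(tr)
    for (i in seq_len(nrow(peaks_df))) {
      expect_equal(as.character(ann$category[i]),
                   oracle_annotate(peaks_df[i, ], tr_df),
                   info = sprintf("instance %d peak %d", inst, i))
    }
  }
})

test_that("nearest-gene distance is signed by gene orientation", {
  cl <- c(chr1 = 100000)
  gp <- make_simple_gene(strand = "+", start = 50001, end = 60000)
  tr <- feature_tracks(gp, cl)
  up <- GRanges("chr1", IRanges(48001, 48200))    # upstream of + TSS
  ann <- annotate_peaks(up, tr, gp)
  expect_lt(ann$distance_to_tss, 0)
  gm <- make_simple_gene(strand = "-", start = 50001, end = 60000)
  upm <- GRanges("chr1", IRanges(61001, 61200))   # upstream of - TSS
  annm <- annotate_peaks(upm, feature_tracks(gm, cl), gm)
  expect_lt(annm$distance_to_tss, 0)
})

test_that("annotation summary percentages always total 100", {
  cfg <- simulation_config(seed = 23)
  g <- make_genome(cfg)
  pk <- simulate_replicate_peaks(g, cfg)
  tr <- feature_tracks(g$genes, g$chrom_lengths)
  ann <- annotate_peaks(pk$true_peaks, tr, g$genes)
  summ <- annotation_summary(ann)
  expect_equal(sum(summ$percent), 100, tolerance = 1e-4)
  expect_error(annotation_summary(ann[0, ]), "no annotations")
})

test_that("hypergeometric ORA matches the pmf-sum oracle", {
  universe <- sprintf("g%03d", 1:100)
  term_map <- data.frame(term_id = "T1", gene_id = universe[1:10])
  gene_set <- universe[c(1:5, 50:54)]       # k = 5, n = 10, K = 10, N = 100
  res <- ora_test(gene_set, term_map, universe)
  expect_equal(res$k, 5)
  expect_equal(res$p_value, oracle_hyper_upper(5, 100, 10, 10),
               tolerance = 1e-14)

  ## k = 0 and whole-universe terms give p = 1
  res0 <- ora_test(universe[50:59],
                   data.frame(term_id = "T1", gene_id = universe[1:10]),
                   universe)
  expect_equal(res0$p_value, 1)
  resU <- ora_test(universe[1:10],
                   data.frame(term_id = "ALL", gene_id = universe), universe)
  expect_equal(resU$p_value, 1)
  expect_error(ora_test(character(), term_map, character()), "empty")
})

test_that("ORA p-value agrees with a resampling estimate of the null", {
  universe <- sprintf("g%03d", 1:60)
  term_genes <- universe[1:12]
  gene_set <- universe[c(1:6, 30:35)]       # k = 6 of n = 12
  res <- ora_test(gene_set,
                  data.frame(term_id = "T", gene_id = term_genes), universe)
  set.seed(67)
  B <- 10000
  null_k <- replicate(B, sum(sample(universe, length(gene_set)) %in% term_genes))
  p_mc <- mean(null_k >= res$k)
  expect_lt(abs(res$p_value - p_mc), 3 * sqrt(p_mc * (1 - p_mc) / B) + 1e-6)
})

test_that("BH adjustment is monotone and bounded by construction", {
  set.seed(71)
  universe <- sprintf("g%03d", 1:80)
  term_map <- do.call(rbind, lapply(1:15, function(i) {
    data.frame(term_id = paste0("T", i),
               gene_id = sample(universe, sample(5:20, 1)))
  }))
  res <- ora_test(sample(universe, 25), term_map, universe,
                  sig_threshold = 0.05)
  expect_true(all(res$adjusted_p >= res$p_value - 1e-15))
  expect_true(all(diff(res$adjusted_p) >= -1e-15))  # sorted by adjusted p
  expect_equal(res$adjusted_p, oracle_bh(res$p_value), tolerance = 1e-12)
})
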