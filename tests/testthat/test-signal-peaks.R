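test_that("tn5_shift applies the +4/-5 correction", {
  expect_equal(tn5_shift(100, "+"), 104L)
  expect_equal(tn5_shift(200, "-"), 195L)
  expect_warning(out <- tn5_shift(2, "-"), "clamped")
  expect_equal(out, 0L)
  expect_error(tn5_shift(10, "*"), "strand")
})

test_that("fragment ends become corrected cut sites", {
  frag <- GRanges("chr1", IRanges(101, 300))   # BED [100, 300)
  cs <- fragment_cut_sites(frag)
  expect_length(cs, 2)
  ## + cut at 100+4 = 104 (0-based) -> 105; - cut at 299-5 = 294 -> 295
  expect_setequal(start(cs), c(105L, 295L))
  expect_setequal(as.character(strand(cs)), c("+", "-"))
})

test_that("fragment classes follow the nucleosome-ladder bins", {
  expect_equal(as.character(fragment_class(c(80, 200, 120, 400, 600, 700))),
               c("NFR", "mono", "other", "di", "tri", "other"))
  expect_equal(as.character(fragment_class(c(99, 100, 150, 249, 250))),
               c("NFR", "other", "mono", "mono", "other"))
  expect_error(fragment_class(0))
})

test_that("periodicity detects the nucleosome ladder and flags noise", {
  set.seed(31)
  ladder <- c(round(rnorm(4000, 200, 25)), round(rnorm(3000, 400, 35)),
              round(rnorm(3000, 600, 45)))
  p <- fragment_periodicity(ladder)
  expect_true(p$periodic)
  expect_gte(p$period, 190)
  expect_lte(p$period, 210)

  expect_false(fragment_periodicity(round(runif(10000, 50, 700)))$periodic)
  expect_false(fragment_periodicity(rep(180L, 2000))$periodic)
  expect_error(fragment_periodicity(rep(200L, 10)), "1,000")
})

test_that("TSS enrichment is ~1 for uniform cuts and flags empty tails", {
  g <- make_genome(simulation_config(seed = 14, n_genes = 30L))
  set.seed(14)
  n <- 200000
  cuts <- GRanges(sample(names(g$chrom_lengths), n, replace = TRUE),
                  IRanges(sample.int(1e6, n, replace = TRUE), width = 1))
  te <- tss_enrichment(cuts, g$genes)
  ## null score 1; SE from Poisson counts in center vs tails
  n_tss <- nrow(g$genes)
  lam <- n / 3e6
  se <- sqrt(1 / (201 * n_tss * lam) + 1 / (200 * n_tss * lam))
  expect_lt(abs(te$score - 1), 3 * se)
  expect_false(te$flagged)

  tss1 <- gene_tss(g$genes)[1]
  near <- GRanges(g$genes$chrom[1], IRanges(tss1 + seq(-50, 50), width = 1))
  te2 <- tss_enrichment(near, g$genes)
  expect_true(te2$flagged)
  expect_equal(te2$score, Inf)
})

test_that("pileup conserves total extended mass and matches Poisson oracle", {
  set.seed(41)
  cl <- c(chr1 = 100000)
  pos <- sort(sample.int(99000, 2000, replace = TRUE))
  cuts <- GRanges("chr1", IRanges(pos, width = 1))
  peaks <- call_peaks(cuts, cl, q_threshold = 0.2)
  ## conservation: coverage mass equals sum of clipped window widths
  s0 <- pmax(0, (pos - 1) - 100)
  e0 <- pmin(100000, (pos - 1) - 100 + 200)
  mass <- sum(e0 - s0)
  cov <- coverage(GRanges("chr1", IRanges(s0 + 1, e0)), width = list(chr1 = 1e5))
  expect_equal(sum(as.numeric(cov$chr1)), mass)
  lambda <- mass / 1e5
  if (length(peaks)) {
    ## per-position Poisson p at the summit equals the closed-form tail
    k <- mcols(peaks)$pileup
    oracle <- 1 - sapply(k, function(kk) sum(dpois(0:(kk - 1), lambda)))
    expect_equal(mcols(peaks)$p_value, oracle, tolerance = 1e-9)
  }
  expect_length(call_peaks(GRanges(), cl), 0)
})

test_that("call_peaks is invariant to cut-site input order", {
  set.seed(43)
  cl <- c(chr1 = 50000, chr2 = 50000)
  gr <- GRanges(sample(c("chr1", "chr2"), 3000, TRUE),
                IRanges(sample.int(49000, 3000, TRUE), width = 1))
  a <- call_peaks(gr, cl, q_threshold = 0.5)
  b <- call_peaks(gr[sample(length(gr))], cl, q_threshold = 0.5)
  expect_equal(a, b)
})

test_that("a planted high-density region is recovered at base-pair level", {
  set.seed(47)
  cl <- c(chr1 = 1000000)
  truth <- GRanges("chr1", IRanges(400001, 402000))
  w <- rep(1, 1e6); w[400001:402000] <- 10
  pos <- sample.int(1e6, 50000, replace = TRUE, prob = w)
  cuts <- GRanges("chr1", IRanges(pos, width = 1))
  called <- call_peaks(cuts, cl)
  rp <- bp_recall_precision(called, truth)
  expect_gte(rp$recall, 0.9)
  expect_gte(rp$precision, 0.9)
})

test_that("weighted BH equals p.adjust on the expanded vector", {
  set.seed(53)
  for (i in 1:20) {
    p <- runif(sample(3:20, 1))
    n <- sample(1:50, length(p), replace = TRUE)
    expect_equal(bh_adjust_weighted(p, n),
                 p.adjust(rep(p, n), "BH")[cumsum(n)],
                 tolerance = 1e-12)
  }
})

test_that("bedGraph export merges runs and round-trips coverage", {
  tf <- tempfile(fileext = ".bedgraph")
  export_bedgraph(RleList(chr1 = Rle(0L, 10)), tf)
  expect_equal(readLines(tf), "track type=bedGraph")

  export_bedgraph(RleList(chr1 = Rle(3L, 100)), tf)
  expect_equal(readLines(tf)[-1], "chr1\t0\t100\t3")

  set.seed(59)
  cl <- c(chr1 = 5000)
  cuts <- sort(GRanges("chr1", IRanges(sample.int(4999, 500, TRUE), width = 1)))
  export_bedgraph(cuts, tf, chrom_lengths = cl)
  df <- read.table(tf, skip = 1, sep = "\t",
                   col.names = c("chrom", "start", "end", "value"))
  rebuilt <- integer(5000)
  for (i in seq_len(nrow(df))) {
    rebuilt[(df$start[i] + 1):df$end[i]] <- df$value[i]
  }
  expect_equal(rebuilt, as.integer(coverage(cuts, width = list(chr1 = 5000))$chr1))
  expect_error(export_bedgraph(rev(cuts), tf, chrom_lengths = cl), "sorted")
})
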