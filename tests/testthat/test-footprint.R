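test_that("PWM construction, validation and file round-trip", {
  pwm <- consensus_pwm("TGACTCAG", p = 0.9)
  expect_equal(pwm_consensus(pwm), "TGACTCAG")
  expect_equal(colSums(pwm$mat), rep(1, 8), ignore_attr = TRUE)
  tf <- tempfile(fileext = ".pwm")
  write_pwm(pwm, tf)
  back <- read_pwm(tf)
  expect_equal(back$mat, pwm$mat, tolerance = 1e-9)
  expect_equal(back$name, "TGACTCAG")
  bad <- matrix(0.3, 4, 6)
  expect_error(new_pwm("x", bad), "sum to 1")
})

test_that("an exact-motif PWM finds its single planted occurrence", {
  set.seed(91)
  pwm <- consensus_pwm("TGACTCAG", p = 0.97)
  bg <- paste(sample(c("A", "C"), 200, replace = TRUE), collapse = "")
  seqfwd <- paste0(substr(bg, 1, 100), "TGACTCAG", substr(bg, 101, 200))
  hits <- pwm_scan(seqfwd, pwm, pwm_max_score(pwm))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$pos, 101)
  expect_equal(hits$strand, "+")

  hits_rc <- pwm_scan(revcomp(seqfwd), pwm, pwm_max_score(pwm))
  expect_equal(nrow(hits_rc), 1)
  expect_equal(hits_rc$strand, "-")
  ## motif longer than sequence -> empty
  expect_equal(nrow(pwm_scan("ACGT", pwm, 0)), 0)
  ## N windows skipped
  withN <- paste0(substr(seqfwd, 1, 104), "N", substr(seqfwd, 106, 208))
  expect_equal(nrow(pwm_scan(withN, pwm, pwm_max_score(pwm))), 0)
})

test_that("pwm_scan equals brute-force per-window rescoring", {
  set.seed(97)
  for (i in 1:15) {
    L <- sample(4:10, 1)
    mat <- matrix(rgamma(4 * L, 1), 4)
    mat <- sweep(mat, 2, colSums(mat), "/")
    pwm <- new_pwm("rand", mat)
    seq <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
    thr <- 0.5 * pwm_max_score(pwm)
    hits <- pwm_scan(seq, pwm, thr)
    ## brute force: rescore every window on both strands
    chars <- strsplit(seq, "")[[1]]
    pr <- (mat + pwm$pseudocount) / (1 + 4 * pwm$pseudocount)
    score1 <- function(win, m) {
      sum(log2(m[cbind(match(win, c("A", "C", "G", "T")), seq_along(win))] / 0.25))
    }
    prr <- pr[4:1, L:1]
    brute <- do.call(rbind, lapply(seq_len(500 - L + 1), function(s) {
      win <- chars[s:(s + L - 1)]
      rbind(data.frame(pos = s, strand = "+", score = score1(win, pr)),
            data.frame(pos = s, strand = "-", score = score1(win, prr)))
    }))
    brute <- brute[brute$score >= thr, ]
    brute <- brute[order(brute$pos, brute$strand), ]
    rownames(brute) <- NULL
    expect_equal(hits, brute, tolerance = 1e-10)
  }
})

test_that("motif enrichment separates planted from null motifs", {
  pwm <- consensus_pwm("TGACTCAG")
  seqs <- simulate_motif_sequences(pwm, n_target = 200, n_background = 800,
                                   planted_target = 0.8,
                                   planted_background = 0.05, seed = 7)
  res <- motif_enrichment(seqs$target, seqs$background, pwm)
  expect_lt(res$p_value, 1e-10)

  ## same hit rates -> no signal; no hits anywhere -> p = 1
  null_res <- motif_enrichment(seqs$background[1:200], seqs$background[201:800],
                               pwm)
  expect_gt(null_res$p_value, 0.01)
  none <- motif_enrichment(c("AAAA", "CCCC"), c("GGGG", "TTTT"),
                           consensus_pwm("TGCATGCA", p = 0.97),
                           threshold_frac = 1)
  expect_equal(none$p_value, 1)
  expect_error(motif_enrichment(character(), c("AAAA"), pwm), "target")
  expect_error(motif_enrichment(c("AAAA"), character(), pwm), "background")
})

test_that("aggregate footprint conserves counts and scores depletion", {
  cfg <- simulation_config(seed = 37, n_true_peaks = 300L,
                           n_motif_sites = 300L, bound_motif_fraction = 1,
                           footprint_depletion = 0.5, footprint_cut_rate = 2)
  g <- make_genome(cfg)
  pk <- simulate_replicate_peaks(g, cfg)
  pwm <- consensus_pwm("TGACTCAG")
  fp <- simulate_footprint_sites(g, pk$true_peaks, pwm, cfg)
  prof <- aggregate_footprint(fp$cut_sites, fp$sites)
  expect_equal(sum(prof$counts), length(fp$cut_sites))
  expect_gt(prof$depth_score, 1.8)
  expect_lt(prof$depth_score, 2.2)
  expect_equal(classify_active(prof), "active")

  cfg0 <- simulation_config(seed = 37, n_true_peaks = 300L,
                            n_motif_sites = 300L, bound_motif_fraction = 0,
                            footprint_cut_rate = 2)
  fp0 <- simulate_footprint_sites(g, pk$true_peaks, pwm, cfg0)
  prof0 <- aggregate_footprint(fp0$cut_sites, fp0$sites)
  expect_gt(prof0$depth_score, 0.9)
  expect_lt(prof0$depth_score, 1.1)
  expect_equal(classify_active(prof0), "inactive")
})

test_that("total depletion empties the motif span yet stays classifiable", {
  cfg <- simulation_config(seed = 41, n_true_peaks = 200L,
                           n_motif_sites = 200L, bound_motif_fraction = 1,
                           footprint_depletion = 0, footprint_cut_rate = 2)
  g <- make_genome(cfg)
  pk <- simulate_replicate_peaks(g, cfg)
  pwm <- consensus_pwm("TGACTCAG")
  fp <- simulate_footprint_sites(g, pk$true_peaks, pwm, cfg)
  prof <- aggregate_footprint(fp$cut_sites, fp$sites)
  motif_offs <- as.character(-3:4)
  expect_true(all(prof$counts[motif_offs] == 0))
  expect_gt(prof$depth_score, 100)     # floored denominator, huge depth
  expect_equal(classify_active(prof), "active")
})

test_that("classification respects site-count and shape requirements", {
  flat <- structure(list(tf_name = "x", window = 100L,
                         counts = setNames(rep(10, 201), -100:100),
                         n_sites = 500L, motif_width = 8L,
                         depth_score = 1.0), class = "footprint_profile")
  expect_equal(classify_active(flat), "inactive")
  few <- flat; few$n_sites <- 10L
  expect_equal(classify_active(few), "indeterminate")
  ## deep but off-centre trough is not a footprint
  off <- flat
  off$counts[as.character(60:70)] <- 0
  off$depth_score <- 2.5
  expect_equal(classify_active(off), "inactive")
})

test_that("deepening the depletion never flips active to inactive", {
  pwm <- consensus_pwm("TGACTCAG")
  calls <- sapply(c(0.7, 0.5, 0.3, 0.1, 0), function(dep) {
    cfg <- simulation_config(seed = 43, n_true_peaks = 200L,
                             n_motif_sites = 200L, bound_motif_fraction = 1,
                             footprint_depletion = dep,
                             footprint_cut_rate = 2)
    g <- make_genome(cfg)
    pk <- simulate_replicate_peaks(g, cfg)
    fp <- simulate_footprint_sites(g, pk$true_peaks, pwm, cfg)
    classify_active(aggregate_footprint(fp$cut_sites, fp$sites))
  })
  first_active <- match("active", calls)
  expect_false(is.na(first_active))
  expect_true(all(calls[first_active:length(calls)] == "active"))
})

test_that("expression crosscheck joins calls, TPM and mapping", {
  tpm <- matrix(c(50, 52, 48, 0.1, 0.2, 0.1), nrow = 2, byrow = TRUE,
                dimnames = list(c("gHigh", "gLow"), paste0("rep", 1:3)))
  calls <- data.frame(tf = c("TFa", "TFb", "TFc"),
                      call = c("active", "active", "inactive"))
  map <- data.frame(tf = c("TFa", "TFb"), gene_id = c("gHigh", "gLow"))
  res <- crosscheck_expression(calls, tpm, map)
  expect_true(res$concordant[1])           # active & expressed
  expect_false(res$concordant[2])          # active & silent
  expect_false(res$mapped[3])              # unmapped kept, flagged
  expect_true(is.na(res$concordant[3]))
})
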