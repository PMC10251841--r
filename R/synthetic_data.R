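## Synthetic-data generators.  Every observable the workflow consumes
## (replicate peak sets, fragments, SNPs, motif sites, count matrices) is
## produced here together with its ground truth, so downstream stages can be
## tested for recovery rather than merely for not crashing.

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generators, validated once.
#' Defaults emulate the study conditions of a 3-replicate chondrocyte
#' ATAC-seq + RNA-seq experiment at desk scale: a 3 x 1 Mb genome with 100
#' genes, 200 true open-chromatin peaks of mean length 572 bp (half placed
#' in +/-3 kb promoter windows), a nucleosome-ladder fragment mixture, a
#' 50,000-SNP panel with fold-3 enriched candidate SNPs, and
#' negative-binomial counts for 3 replicates with dispersion calibrated to
#' an inter-replicate correlation near 0.8.
#'
#' @param seed integer master seed; each generator derives its own stream
#'   from it, so generators are reproducible independently of call order.
#' @param n_replicates biological replicates for peaks and counts.
#' @param n_chroms,chrom_length genome shape (chromosomes x bp).
#' @param n_genes genes to place, non-overlapping.
#' @param gene_span_range min/max gene span (bp).
#' @param coding_fraction fraction of genes given a CDS (hence UTR tracks).
#' @param n_true_peaks,peak_length_mean true open-chromatin peaks and their
#'   mean length (bp).
#' @param promoter_peak_fraction probability a true peak is planted inside a
#'   +/-3 kb promoter window (the remainder avoid all promoter windows).
#' @param replicate_dropout probability a true peak is absent from a given
#'   replicate's peak set.
#' @param jitter_frac per-end uniform boundary jitter for replicate peaks,
#'   as a fraction of peak length.
#' @param n_fragments Tn5 fragments to simulate.
#' @param fragment_mixture weights over the (<100, ~200, ~400, ~600 bp)
#'   fragment-length components; must sum to 1.
#' @param peak_cut_enrichment,tss_cut_enrichment per-bp cut-density
#'   multiplier inside peaks / inside +/-100 bp TSS windows.
#' @param snp_count background panel size; `candidate_snp_count` candidate
#'   SNPs placed at `snp_enrichment_fold` times the background in-peak rate
#'   (capped at 1 with a warning).
#' @param candidate_snp_count,snp_enrichment_fold see above.
#' @param n_motif_sites,bound_motif_fraction motif occurrences inside peaks
#'   and the fraction carrying footprint protection.
#' @param footprint_depletion multiplicative cut-rate suppression over the
#'   motif span at bound sites (0 = complete protection).
#' @param footprint_cut_rate expected cuts per bp per site in the flanks.
#' @param footprint_window half-window (bp) of simulated cut coverage
#'   around each motif center.
#' @param low_expr_fraction fraction of genes given a sub-threshold
#'   (mean TPM <= 2) expression level.
#' @param count_dispersion negative-binomial dispersion (1/size) shared by
#'   all genes; the default is calibrated so that log-scale replicate
#'   correlation lands near 0.8.
#' @param lib_size expected reads per replicate for the count simulator.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_replicates = 3L,
                              n_chroms = 3L,
                              chrom_length = 1e6,
                              n_genes = 100L,
                              gene_span_range = c(3000, 15000),
                              coding_fraction = 0.9,
                              n_true_peaks = 200L,
                              peak_length_mean = 572,
                              promoter_peak_fraction = 0.5,
                              replicate_dropout = 0.2,
                              jitter_frac = 0.1,
                              n_fragments = 100000L,
                              fragment_mixture = c(nfr = 0.50, mono = 0.30,
                                                   di = 0.13, tri = 0.07),
                              peak_cut_enrichment = 10,
                              tss_cut_enrichment = 10,
                              snp_count = 50000L,
                              candidate_snp_count = 2000L,
                              snp_enrichment_fold = 3,
                              n_motif_sites = 200L,
                              bound_motif_fraction = 0.5,
                              footprint_depletion = 0.5,
                              footprint_cut_rate = 1,
                              footprint_window = 100L,
                              low_expr_fraction = 0.3,
                              count_dispersion = 2,
                              lib_size = 2e6) {
  cfg <- as.list(environment())
  probs <- c(promoter_peak_fraction, replicate_dropout, jitter_frac,
             bound_motif_fraction, low_expr_fraction, coding_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(fragment_mixture) - 1) > 1e-9) {
    stop("fragment_mixture weights must sum to 1")
  }
  if (any(fragment_mixture < 0)) stop("fragment_mixture weights must be >= 0")
  counts <- c(n_replicates, n_chroms, n_genes, n_true_peaks, n_fragments,
              snp_count, candidate_snp_count, n_motif_sites)
  if (any(counts < 0)) stop("counts must be >= 0")
  if (chrom_length <= 0) stop("chrom_length must be > 0")
  if (snp_enrichment_fold < 0) stop("snp_enrichment_fold must be >= 0")
  if (footprint_depletion < 0) stop("footprint_depletion must be >= 0")
  if (count_dispersion < 0) stop("count_dispersion must be >= 0")
  structure(cfg, class = "simulation_config")
}

## Give a GRanges the full set of genome seqlevels so later concatenation
## and coverage calls see a consistent universe.
with_seqlevels <- function(gr, chrom_lengths) {
  GenomeInfoDb::seqlevels(gr) <- names(chrom_lengths)
  GenomeInfoDb::seqlengths(gr) <- unname(chrom_lengths)
  gr
}

## Derive an independent, reproducible RNG state per generator stage.
stage_seed <- function(seed, stage) {
  s <- (as.numeric(seed) * 7919 + sum(utf8ToInt(stage)) * 131) %%
    (.Machine$integer.max - 1)
  as.integer(s) + 1L
}

#' Generate a synthetic genome with non-overlapping gene models
#'
#' Chromosomes `chr1..chrN` of equal length; genes are placed without
#' overlap (either strand), each with 1-8 exons and, for coding genes, a CDS
#' leaving non-empty 5' and 3' UTR portions in the terminal exons.  TSS is
#' strand-aware: the leftmost coordinate on "+", the rightmost on "-".
#'
#' @param config a [simulation_config()].
#' @return list of class `synthetic_genome` with elements `chrom_lengths`
#'   (named vector), `genes` (data.frame: gene_id, chrom, strand, start,
#'   end, cds_start, cds_end, 1-based inclusive; `exons` list-column of
#'   2-column start/end matrices) and `seed`.
#' @export
make_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(stage_seed(config$seed, "genome"))
  chrom_lengths <- stats::setNames(rep(config$chrom_length, config$n_chroms),
                                   paste0("chr", seq_len(config$n_chroms)))
  genes <- make_gene_models(chrom_lengths, config)
  structure(list(chrom_lengths = chrom_lengths, genes = genes,
                 seed = config$seed),
            class = "synthetic_genome")
}

make_gene_models <- function(chrom_lengths, config) {
  n <- config$n_genes
  empty <- data.frame(gene_id = character(), chrom = character(),
                      strand = character(), start = integer(),
                      end = integer(), cds_start = integer(),
                      cds_end = integer(), stringsAsFactors = FALSE)
  empty$exons <- list()
  if (n == 0L) return(empty)
  chrom <- sort(sample(names(chrom_lengths), n, replace = TRUE))
  spans <- round(stats::runif(n, config$gene_span_range[1],
                              config$gene_span_range[2]))
  rows <- vector("list", n)
  idx <- 1L
  for (cn in unique(chrom)) {
    ii <- which(chrom == cn)
    L <- chrom_lengths[[cn]]
    ## keep a margin so +/-3 kb promoter windows stay on-chromosome
    margin <- 4000
    slack <- (L - 2 * margin) - sum(spans[ii]) - (length(ii) - 1) * 200
    if (slack <= 0) {
      stop("cannot place ", length(ii), " genes of total span ",
           sum(spans[ii]), " bp on ", cn, " (", L,
           " bp) without overlap; reduce n_genes or gene spans")
    }
    cuts <- sort(stats::runif(length(ii), 0, slack))
    gaps <- diff(c(0, cuts))
    start <- margin + cumsum(gaps + 200) - 200 +
      c(0, cumsum(spans[ii])[-length(ii)]) + 1
    for (k in seq_along(ii)) {
      g <- ii[k]
      s <- round(start[k]); e <- s + spans[g] - 1
      strand <- sample(c("+", "-"), 1L)
      ex <- make_exons(s, e)
      coding <- stats::runif(1) < config$coding_fraction
      if (coding) {
        first <- ex[1, ]; last <- ex[nrow(ex), ]
        cds_start <- first[1] + max(1L, floor((first[2] - first[1]) / 2))
        cds_end <- last[2] - max(1L, floor((last[2] - last[1]) / 2))
        if (cds_end <= cds_start) { cds_start <- NA_integer_; cds_end <- NA_integer_ }
      } else {
        cds_start <- NA_integer_; cds_end <- NA_integer_
      }
      rows[[idx]] <- list(gene_id = sprintf("G%04d", g), chrom = cn,
                          strand = strand, start = as.integer(s),
                          end = as.integer(e),
                          cds_start = as.integer(cds_start),
                          cds_end = as.integer(cds_end), exons = ex)
      idx <- idx + 1L
    }
  }
  rows <- rows[seq_len(idx - 1L)]
  out <- data.frame(gene_id = vapply(rows, `[[`, "", "gene_id"),
                    chrom = vapply(rows, `[[`, "", "chrom"),
                    strand = vapply(rows, `[[`, "", "strand"),
                    start = vapply(rows, `[[`, 1L, "start"),
                    end = vapply(rows, `[[`, 1L, "end"),
                    cds_start = vapply(rows, `[[`, 1L, "cds_start"),
                    cds_end = vapply(rows, `[[`, 1L, "cds_end"),
                    stringsAsFactors = FALSE)
  out$exons <- lapply(rows, `[[`, "exons")
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

## Partition a gene span [s, e] into alternating exon/intron blocks.
make_exons <- function(s, e) {
  span <- e - s + 1
  n_ex <- sample(1:8, 1L)
  min_ex <- 100; min_in <- 50
  while (n_ex > 1 && n_ex * min_ex + (n_ex - 1) * min_in > span) {
    n_ex <- n_ex - 1L
  }
  if (n_ex == 1L) {
    return(matrix(c(s, e), 1, 2, dimnames = list(NULL, c("start", "end"))))
  }
  n_blocks <- 2L * n_ex - 1L
  mins <- ifelse(seq_len(n_blocks) %% 2 == 1, min_ex, min_in)
  extra <- span - sum(mins)
  w <- stats::runif(n_blocks)
  widths <- mins + floor(extra * w / sum(w))
  widths[1] <- widths[1] + (span - sum(widths))
  ends <- s - 1 + cumsum(widths)
  starts <- c(s, ends[-n_blocks] + 1)
  ex_idx <- seq(1, n_blocks, by = 2)
  cbind(start = as.integer(starts[ex_idx]), end = as.integer(ends[ex_idx]))
}

#' Strand-aware transcription start sites of a gene table
#' @param genes gene data.frame as in [make_genome()].
#' @return integer vector of TSS positions (1-based).
#' @export
gene_tss <- function(genes) {
  ifelse(genes$strand == "+", genes$start, genes$end)
}

#' Simulate per-replicate peak sets around true open-chromatin peaks
#'
#' True peaks are placed non-overlapping with generous spacing; a fraction
#' (`promoter_peak_fraction`) is planted inside +/-3 kb promoter windows and
#' the rest avoid all promoter windows.  Each replicate observes a true peak
#' with probability `1 - replicate_dropout`, with each boundary jittered
#' independently by Uniform(+/- `jitter_frac` x length); the jitter keeps
#' reciprocal overlap of two observations of the same peak above 2/3, so
#' replicate agreement is governed purely by dropout.
#'
#' @param genome a [make_genome()] result.
#' @param config a [simulation_config()].
#' @return list with `true_peaks` (GRanges; metadata `in_promoter`) and
#'   `replicates` (named list of internally non-overlapping GRanges with a
#'   `true_id` metadata column).
#' @export
simulate_replicate_peaks <- function(genome, config) {
  stopifnot(config$n_replicates >= 1L)
  set.seed(stage_seed(config$seed, "peaks"))
  cl <- genome$chrom_lengths
  tss <- gene_tss(genome$genes)
  prom <- if (nrow(genome$genes)) {
    merge_intervals(GenomicRanges::GRanges(
      genome$genes$chrom,
      IRanges::IRanges(pmax(1L, tss - 3000L),
                       pmin(cl[genome$genes$chrom], tss + 3000L))))
  } else GenomicRanges::GRanges()

  n <- config$n_true_peaks
  lens <- pmax(150, round(stats::rnorm(n, config$peak_length_mean,
                                       0.2 * config$peak_length_mean)))
  in_prom <- stats::runif(n) < config$promoter_peak_fraction &
    length(prom) > 0
  prom_chrom <- as.character(GenomeInfoDb::seqnames(prom))
  prom_start <- BiocGenerics::start(prom)
  prom_end <- BiocGenerics::end(prom)
  p_chrom <- character(0); p_start <- numeric(0); p_end <- numeric(0)
  chroms <- character(n); starts <- integer(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(10000L)) {
      if (in_prom[i]) {
        g <- sample.int(nrow(genome$genes), 1L)
        center <- tss[g] + round(stats::runif(1, -2500, 2500))
        chrom <- genome$genes$chrom[g]
      } else {
        chrom <- sample(names(cl), 1L)
        center <- round(stats::runif(1, lens[i], cl[[chrom]] - lens[i]))
      }
      s <- max(1L, as.integer(center - lens[i] %/% 2))
      e <- min(as.integer(cl[[chrom]]), as.integer(s + lens[i] - 1L))
      ## pad by 25% of length so jittered copies of distinct peaks stay
      ## disjoint within a replicate
      pad <- ceiling(0.25 * lens[i])
      same <- p_chrom == chrom
      if (any(same & p_start <= e + pad & p_end >= s - pad)) next
      if (!in_prom[i] && length(prom) &&
          any(prom_chrom == chrom & prom_start <= e & prom_end >= s)) next
      p_chrom <- c(p_chrom, chrom)
      p_start <- c(p_start, s - pad); p_end <- c(p_end, e + pad)
      chroms[i] <- chrom; starts[i] <- s
      ok <- TRUE
      break
    }
    if (!ok) stop("could not place true peak ", i,
                  " without overlap; genome too crowded")
  }
  true_peaks <- GenomicRanges::GRanges(chroms,
                                       IRanges::IRanges(starts,
                                                        starts + lens - 1L))
  S4Vectors::mcols(true_peaks)$in_promoter <- in_prom
  S4Vectors::mcols(true_peaks)$true_id <- seq_len(n)

  replicates <- lapply(seq_len(config$n_replicates), function(r) {
    present <- which(stats::runif(n) < 1 - config$replicate_dropout)
    if (!length(present)) return(GenomicRanges::GRanges())
    l <- lens[present]
    j1 <- round(stats::runif(length(present), -config$jitter_frac * l,
                             config$jitter_frac * l))
    j2 <- round(stats::runif(length(present), -config$jitter_frac * l,
                             config$jitter_frac * l))
    s <- pmax(1L, as.integer(starts[present] + j1))
    e <- pmin(as.integer(cl[chroms[present]]),
              as.integer(starts[present] + l - 1L + j2))
    gr <- with_seqlevels(GenomicRanges::GRanges(chroms[present],
                                                IRanges::IRanges(s, e)), cl)
    S4Vectors::mcols(gr)$true_id <- present
    GenomicRanges::sort(gr)
  })
  names(replicates) <- paste0("rep", seq_len(config$n_replicates))
  list(true_peaks = GenomicRanges::sort(with_seqlevels(true_peaks, cl)),
       replicates = replicates)
}

#' Simulate Tn5 fragments with a nucleosome-ladder length mixture
#'
#' Fragment centers are drawn from a per-bp density of 1 over background,
#' multiplied by `peak_cut_enrichment` inside peaks and
#' `tss_cut_enrichment` inside +/-100 bp TSS windows.  Lengths come from the
#' 4-component mixture: sub-nucleosomal Uniform(20, 99) and Gaussian
#' nucleosome multiples at 200 +/- 25, 400 +/- 35 and 600 +/- 45 bp.  Cut
#' sites are the fragment ends after the +4/-5 Tn5 correction.
#'
#' @param genome a [make_genome()] result.
#' @param peaks GRanges of open regions to enrich (may be empty).
#' @param config a [simulation_config()].
#' @return list with `fragments` (GRanges) and `cut_sites` (stranded
#'   width-1 GRanges from [fragment_cut_sites()]).
#' @export
simulate_fragments <- function(genome, peaks, config) {
  set.seed(stage_seed(config$seed, "fragments"))
  cl <- genome$chrom_lengths
  n <- config$n_fragments
  comp <- sample.int(4L, n, replace = TRUE, prob = config$fragment_mixture)
  lens <- integer(n)
  lens[comp == 1L] <- round(stats::runif(sum(comp == 1L), 20, 99))
  lens[comp == 2L] <- round(stats::rnorm(sum(comp == 2L), 200, 25))
  lens[comp == 3L] <- round(stats::rnorm(sum(comp == 3L), 400, 35))
  lens[comp == 4L] <- round(stats::rnorm(sum(comp == 4L), 600, 45))
  lens <- pmax(10L, as.integer(lens))

  weights <- list()
  if (length(peaks)) {
    p <- merge_intervals(peaks)
    S4Vectors::mcols(p)$w <- config$peak_cut_enrichment - 1
    weights <- c(weights, list(p))
  }
  if (nrow(genome$genes) && config$tss_cut_enrichment > 1) {
    tss <- gene_tss(genome$genes)
    tw <- GenomicRanges::GRanges(
      genome$genes$chrom,
      IRanges::IRanges(pmax(1L, tss - 100L),
                       pmin(cl[genome$genes$chrom], tss + 100L)))
    tw <- merge_intervals(tw)
    S4Vectors::mcols(tw)$w <- config$tss_cut_enrichment - 1
    weights <- c(weights, list(tw))
  }
  centers <- sample_weighted_positions(n, cl, weights)
  s <- centers$pos - lens %/% 2L
  chrom_len <- cl[centers$chrom]
  s <- pmax(1L, pmin(as.integer(chrom_len - lens + 1L), as.integer(s)))
  frags <- with_seqlevels(GenomicRanges::GRanges(centers$chrom,
                                                 IRanges::IRanges(s, s + lens - 1L)),
                          cl)
  list(fragments = frags, cut_sites = fragment_cut_sites(frags))
}

## Draw n positions from a piecewise-constant density: baseline 1 per bp,
## plus the `w` metadata of each GRanges in `extra` added over its span.
sample_weighted_positions <- function(n, chrom_lengths, extra = list()) {
  segs <- data.frame(chrom = names(chrom_lengths), start = 1,
                     end = as.numeric(chrom_lengths), w = 1)
  for (gr in extra) {
    if (!length(gr)) next
    add <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                      start = BiocGenerics::start(gr),
                      end = BiocGenerics::end(gr),
                      w = S4Vectors::mcols(gr)$w)
    segs <- rbind(segs, add)
  }
  ## disjoin into flat segments with summed weights
  all_gr <- GenomicRanges::GRanges(segs$chrom,
                                   IRanges::IRanges(segs$start, segs$end))
  dj <- GenomicRanges::disjoin(all_gr)
  ov <- GenomicRanges::findOverlaps(dj, all_gr)
  wsum <- tapply(segs$w[S4Vectors::subjectHits(ov)],
                 S4Vectors::queryHits(ov), sum)
  w <- numeric(length(dj))
  w[as.integer(names(wsum))] <- as.numeric(wsum)
  mass <- w * BiocGenerics::width(dj)
  cum <- cumsum(mass)
  u <- stats::runif(n) * cum[length(cum)]
  seg <- findInterval(u, cum) + 1L
  within <- u - c(0, cum)[seg]
  pos <- BiocGenerics::start(dj)[seg] +
    pmin(BiocGenerics::width(dj)[seg] - 1L,
         as.integer(floor(within / w[seg])))
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(dj))[seg],
             pos = pos, stringsAsFactors = FALSE)
}

#' Simulate a background SNP panel and peak-enriched candidate SNPs
#'
#' Background SNPs are uniform over the genome with Uniform(0,1) p-values.
#' Each candidate SNP falls inside a peak with probability
#' `min(1, snp_enrichment_fold x peak genome fraction)` (capped with a
#' warning), otherwise uniformly outside peaks.
#'
#' @param genome a [make_genome()] result.
#' @param peaks GRanges of open regions.
#' @param config a [simulation_config()].
#' @return list with `background` and `candidates`, data.frames of
#'   `chrom`, `pos` (0-based) and `p`; candidates carry `in_peak` truth.
#' @export
simulate_snps <- function(genome, peaks, config) {
  set.seed(stage_seed(config$seed, "snps"))
  cl <- genome$chrom_lengths
  bg <- sample_weighted_positions(config$snp_count, cl)
  background <- data.frame(chrom = bg$chrom, pos = bg$pos - 1L,
                           p = stats::runif(config$snp_count))
  peaks <- merge_intervals(peaks)
  pf <- genome_fraction(peaks, cl)
  p_in <- config$snp_enrichment_fold * pf
  if (p_in > 1) {
    warning("requested in-peak SNP proportion ", signif(p_in, 3),
            " exceeds 1; capped")
    p_in <- 1
  }
  n <- config$candidate_snp_count
  inside <- stats::runif(n) < p_in
  pos <- integer(n); chrom <- character(n)
  if (any(inside)) {
    pk <- sample.int(length(peaks), sum(inside), replace = TRUE,
                     prob = BiocGenerics::width(peaks))
    chrom[inside] <- as.character(GenomeInfoDb::seqnames(peaks))[pk]
    pos[inside] <- BiocGenerics::start(peaks)[pk] +
      floor(stats::runif(sum(inside)) * BiocGenerics::width(peaks)[pk])
  }
  n_out <- sum(!inside)
  if (n_out) {
    got <- 0L; och <- character(n_out); opos <- integer(n_out)
    while (got < n_out) {
      draw <- sample_weighted_positions(2L * (n_out - got), cl)
      gr <- GenomicRanges::GRanges(draw$chrom,
                                   IRanges::IRanges(draw$pos, draw$pos))
      keep <- which(GenomicRanges::countOverlaps(gr, peaks) == 0L)
      take <- keep[seq_len(min(length(keep), n_out - got))]
      if (length(take)) {
        och[got + seq_along(take)] <- draw$chrom[take]
        opos[got + seq_along(take)] <- draw$pos[take]
        got <- got + length(take)
      }
    }
    chrom[!inside] <- och; pos[!inside] <- opos
  }
  candidates <- data.frame(chrom = chrom, pos = pos - 1L,
                           p = stats::runif(n) * 1e-4,
                           in_peak = inside)
  list(background = background, candidates = candidates)
}

## Offsets (relative to the aggregation center) covered by a motif of a
## given width; shared by the simulator and the footprint aggregator.
motif_center_offsets <- function(width) {
  left <- -((width - 1L) %/% 2L)
  seq(left, left + width - 1L)
}

#' Simulate motif sites with and without footprint protection
#'
#' Motif centers are placed inside peaks (uniformly, width-weighted) with
#' at least one full aggregation frame of spacing between sites, with
#' random strand; a `bound_motif_fraction` of sites is flagged bound.  Cut
#' counts are Poisson with rate `footprint_cut_rate` per bp per site over a
#' +/-`footprint_window` bp window, suppressed by `footprint_depletion`
#' over the motif span at bound sites.
#'
#' @param genome a [make_genome()] result.
#' @param peaks GRanges of open regions (must be non-empty).
#' @param pwm a PWM as returned by [consensus_pwm()] or [read_pwm()]; only
#'   its width is used here.
#' @param config a [simulation_config()].
#' @return list with `sites` (stranded GRanges of motif spans; metadata
#'   `bound`) and `cut_sites` (width-1 GRanges).
#' @export
simulate_footprint_sites <- function(genome, peaks, pwm, config) {
  stopifnot(length(peaks) > 0)
  set.seed(stage_seed(config$seed, "footprint"))
  cl <- genome$chrom_lengths
  w <- pwm_width(pwm)
  win <- config$footprint_window
  n <- config$n_motif_sites
  peaks <- merge_intervals(peaks)
  ## centers keep at least one full frame of separation so the +/-window
  ## frames of distinct sites never overlap and each site's depletion
  ## construction stays clean
  min_space <- 2L * win + w + 1L
  centers <- integer(n); chrom <- character(n)
  got <- 0L; tries <- 0L
  pw <- BiocGenerics::width(peaks)
  pchr <- as.character(GenomeInfoDb::seqnames(peaks))
  pstart <- BiocGenerics::start(peaks)
  while (got < n) {
    tries <- tries + 1L
    if (tries > 200L * n) {
      stop("could not place ", n, " motif sites with ", min_space,
           " bp spacing inside the peak set; reduce n_motif_sites")
    }
    i <- sample.int(length(peaks), 1L, prob = pw)
    cand <- pstart[i] + floor(stats::runif(1) * pw[i])
    cand <- max(win + w + 1, min(as.integer(cl[[pchr[i]]] - win - w), cand))
    same <- chrom[seq_len(got)] == pchr[i]
    if (any(same & abs(centers[seq_len(got)] - cand) < min_space)) next
    got <- got + 1L
    centers[got] <- as.integer(cand); chrom[got] <- pchr[i]
  }
  strand <- sample(c("+", "-"), n, replace = TRUE)
  bound <- stats::runif(n) < config$bound_motif_fraction

  offs <- seq(-win, win)
  motif_offs <- motif_center_offsets(w)
  rate <- matrix(config$footprint_cut_rate, nrow = n, ncol = length(offs))
  rate[bound, offs %in% motif_offs] <-
    config$footprint_cut_rate * config$footprint_depletion
  counts <- matrix(stats::rpois(length(rate), rate), nrow = n)
  site_idx <- rep(seq_len(n), times = rowSums(counts))
  off_idx <- unlist(lapply(seq_len(n), function(i) {
    rep(offs, times = counts[i, ])
  }))
  sign <- ifelse(strand[site_idx] == "+", 1L, -1L)
  pos <- centers[site_idx] + sign * off_idx
  cut_sites <- GenomicRanges::GRanges(chrom[site_idx],
                                      IRanges::IRanges(pos, pos))
  left <- centers + min(motif_offs)
  sites <- GenomicRanges::GRanges(chrom,
                                  IRanges::IRanges(left, left + w - 1L),
                                  strand = strand)
  S4Vectors::mcols(sites)$bound <- bound
  list(sites = with_seqlevels(sites, cl),
       cut_sites = GenomicRanges::sort(with_seqlevels(cut_sites, cl)))
}

#' Simulate a negative-binomial RNA-seq count matrix
#'
#' Gene-level expected TPM values are drawn once and shared across
#' replicates: a `low_expr_fraction` of genes gets Uniform(0.05, 1.5) TPM
#' (below the TPM > 2 filter), the rest log-uniform on \[5, 500\].  Expected
#' counts are proportional to TPM x length, scaled to `lib_size` per
#' replicate, and observed counts are negative binomial with shared
#' dispersion.
#'
#' @param genome a [make_genome()] result (gene lengths = exon span sums).
#' @param config a [simulation_config()].
#' @return list with `counts` (gene x replicate integer matrix),
#'   `gene_lengths` (named, bp), `expressed_truth` (logical: gene drawn
#'   from the expressed component) and `target_tpm`.
#' @export
simulate_counts <- function(genome, config) {
  stopifnot(nrow(genome$genes) >= 1)
  set.seed(stage_seed(config$seed, "counts"))
  genes <- genome$genes
  lens <- vapply(genes$exons, function(ex) sum(ex[, 2] - ex[, 1] + 1), 0)
  names(lens) <- genes$gene_id
  n <- nrow(genes)
  low <- stats::runif(n) < config$low_expr_fraction
  if (all(low)) stop("all genes drawn sub-threshold; lower low_expr_fraction")
  ## targets live on the TPM scale directly: sub-threshold genes get
  ## Uniform(0.05, 1.5) TPM and the expressed genes share the remaining
  ## mass of the 1e6 budget in log-uniform proportions
  tpm <- numeric(n)
  tpm[low] <- stats::runif(sum(low), 0.05, 1.5)
  raw <- exp(stats::runif(sum(!low), log(5), log(500)))
  tpm[!low] <- raw / sum(raw) * (1e6 - sum(tpm[low]))
  rate <- tpm * lens / 1000
  mu <- rate / sum(rate) * config$lib_size
  counts <- sapply(seq_len(config$n_replicates), function(r) {
    if (config$count_dispersion == 0) {
      stats::rpois(n, mu)
    } else {
      stats::rnbinom(n, mu = mu, size = 1 / config$count_dispersion)
    }
  })
  counts <- matrix(as.integer(counts), nrow = n,
                   dimnames = list(genes$gene_id,
                                   paste0("rep", seq_len(config$n_replicates))))
  list(counts = counts, gene_lengths = lens,
       expressed_truth = !low, target_tpm = stats::setNames(tpm, genes$gene_id))
}

#' Simulate a gene-to-term map with one planted enriched term
#'
#' Random term memberships over the gene universe, plus (optionally) a term
#' whose members are drawn preferentially from a designated gene set -- the
#' positive control for over-representation testing.
#'
#' @param gene_ids character vector, the gene universe.
#' @param n_terms number of random background terms.
#' @param term_size_range min/max genes per term.
#' @param enriched_genes optional character vector; when given, a term
#'   `TERM_planted` containing a sample of these genes is added.
#' @param seed integer seed.
#' @return data.frame with columns `term_id`, `gene_id`.
#' @export
simulate_term_map <- function(gene_ids, n_terms = 20L,
                              term_size_range = c(5L, 30L),
                              enriched_genes = NULL, seed = 1L) {
  set.seed(stage_seed(seed, "terms"))
  maps <- lapply(seq_len(n_terms), function(i) {
    k <- sample(seq(term_size_range[1], min(term_size_range[2],
                                            length(gene_ids))), 1L)
    data.frame(term_id = sprintf("TERM_%03d", i),
               gene_id = sample(gene_ids, k))
  })
  out <- do.call(rbind, maps)
  if (!is.null(enriched_genes) && length(enriched_genes)) {
    k <- min(length(enriched_genes),
             max(term_size_range[1], length(enriched_genes) %/% 2))
    out <- rbind(out, data.frame(term_id = "TERM_planted",
                                 gene_id = sample(enriched_genes, k)))
  }
  out
}

#' Simulate target/background sequence sets with planted motif occurrences
#'
#' Random uniform ACGT sequences; a configurable fraction of each set gets
#' one copy of the PWM consensus planted at a random offset (forward or
#' reverse strand).  Used to exercise motif scanning and target-vs-background
#' motif enrichment with known truth.
#'
#' @param pwm a PWM (see [consensus_pwm()]).
#' @param n_target,n_background sequence counts.
#' @param planted_target,planted_background planting probabilities.
#' @param length sequence length (bp).
#' @param seed integer seed.
#' @return list with character vectors `target`, `background` and logical
#'   truth vectors `target_planted`, `background_planted`.
#' @export
simulate_motif_sequences <- function(pwm, n_target = 200L,
                                     n_background = 800L,
                                     planted_target = 0.8,
                                     planted_background = 0.05,
                                     length = 300L, seed = 1L) {
  set.seed(stage_seed(seed, "sequences"))
  consensus <- pwm_consensus(pwm)
  gen <- function(n, p_plant) {
    planted <- stats::runif(n) < p_plant
    seqs <- vapply(seq_len(n), function(i) {
      s <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
      if (planted[i]) {
        off <- sample.int(length - nchar(consensus) + 1L, 1L)
        ins <- strsplit(if (stats::runif(1) < 0.5) consensus else
          revcomp(consensus), "")[[1]]
        s[off:(off + nchar(consensus) - 1L)] <- ins
      }
      paste(s, collapse = "")
    }, "")
    list(seqs = seqs, planted = planted)
  }
  tg <- gen(n_target, planted_target)
  bg <- gen(n_background, planted_background)
  list(target = tg$seqs, background = bg$seqs,
       target_planted = tg$planted, background_planted = bg$planted)
}

## ---- plain-text writers/readers for the fixture formats ----

#' Read/write the gene-model table
#'
#' Tab-separated, one row per gene: `gene_id`, `chrom`, `strand`, `start`,
#' `end` (1-based inclusive), `exons` as comma-separated `start-end` blocks,
#' `cds_start`, `cds_end` (`NA` for non-coding genes).
#'
#' @param genes gene data.frame as produced by [make_genome()].
#' @param path file path.
#' @return `write_gene_table`: `path`, invisibly.  `read_gene_table`: the
#'   gene data.frame.
#' @export
write_gene_table <- function(genes, path) {
  out <- genes
  out$exons <- vapply(genes$exons, function(ex) {
    paste(paste0(ex[, 1], "-", ex[, 2]), collapse = ",")
  }, "")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_table
#' @export
read_gene_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  df$exons <- lapply(strsplit(df$exons, ",", fixed = TRUE), function(blocks) {
    m <- do.call(rbind, strsplit(blocks, "-", fixed = TRUE))
    cbind(start = as.integer(m[, 1]), end = as.integer(m[, 2]))
  })
  df
}

#' Read/write a SNP table (chrom, 0-based pos, p-value)
#' @param snps data.frame with `chrom`, `pos`, optionally `p`.
#' @param path file path.
#' @return `write_snp_table`: `path`, invisibly; `read_snp_table`: the
#'   data.frame.
#' @export
write_snp_table <- function(snps, path) {
  utils::write.table(snps[, intersect(c("chrom", "pos", "p"), names(snps))],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_snp_table
#' @export
read_snp_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Read/write a gene x sample count matrix as TSV
#' @param counts integer matrix with gene rownames and sample colnames.
#' @param path file path.
#' @return `write_counts`: `path`, invisibly; `read_counts`: the matrix.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}
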