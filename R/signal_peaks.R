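## Tn5 cut-site handling, fragment-level QC and a transparent Poisson peak
## caller parametrized like the study's shift/extsize sliding-window call
## (shift -100, extsize 200, single global background rate).

#' Tn5 insertion-site correction (+4 / -5 bp)
#'
#' Shifts read 5' positions to the Tn5 transposition center: +4 bp on the
#' "+" strand, -5 bp on the "-" strand.  Positions are 0-based; negative
#' results are clamped to 0 with a warning.
#'
#' @param pos integer vector of 0-based read 5' positions.
#' @param strand character vector of "+"/"-", recycled.
#' @return integer vector of corrected 0-based cut positions.
#' @export
#' @examples
#' tn5_shift(100, "+")  # 104
#' tn5_shift(200, "-")  # 195
tn5_shift <- function(pos, strand) {
  stopifnot(all(pos >= 0))
  n <- max(length(pos), length(strand))
  pos <- rep_len(as.integer(pos), n)
  strand <- rep_len(as.character(strand), n)
  if (!all(strand %in% c("+", "-"))) {
    stop("unknown strand value: ", paste(unique(setdiff(strand, c("+", "-"))),
                                         collapse = ", "))
  }
  out <- pos + ifelse(strand == "+", 4L, -5L)
  if (any(out < 0L)) {
    warning(sum(out < 0L), " corrected position(s) below 0 clamped to 0")
    out <- pmax(out, 0L)
  }
  out
}

#' Corrected Tn5 cut sites from paired-end fragments
#'
#' Each fragment contributes two insertion events: the "+"-strand read 5'
#' end at the fragment start and the "-"-strand read 5' end at the last
#' fragment base, both corrected by [tn5_shift()].
#'
#' @param fragments GRanges of fragments.
#' @return stranded width-1 GRanges of cut sites, sorted.
#' @export
fragment_cut_sites <- function(fragments) {
  if (!length(fragments)) return(GenomicRanges::GRanges())
  s0 <- BiocGenerics::start(fragments) - 1L
  e0 <- BiocGenerics::end(fragments)          # half-open end
  plus <- tn5_shift(s0, "+")
  minus <- tn5_shift(e0 - 1L, "-")
  chrom <- as.character(GenomeInfoDb::seqnames(fragments))
  gr <- GenomicRanges::GRanges(
    rep(chrom, 2L),
    IRanges::IRanges(c(plus, minus) + 1L, c(plus, minus) + 1L),
    strand = rep(c("+", "-"), each = length(fragments)))
  gr <- GenomeInfoDb::sortSeqlevels(gr)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Nucleosome-ladder class of a fragment length
#'
#' `<100` bp: nucleosome-free (NFR); `[150, 250)`: mono-nucleosome;
#' `[350, 450)`: di; `[550, 650)`: tri; anything else: other.
#'
#' @param length integer vector of fragment lengths (bp), all > 0.
#' @return factor with levels NFR, mono, di, tri, other.
#' @export
fragment_class <- function(length) {
  stopifnot(all(length > 0))
  cls <- rep("other", length(length))
  cls[length < 100] <- "NFR"
  cls[length >= 150 & length < 250] <- "mono"
  cls[length >= 350 & length < 450] <- "di"
  cls[length >= 550 & length < 650] <- "tri"
  factor(cls, levels = c("NFR", "mono", "di", "tri", "other"))
}

#' Dominant period of the fragment-length distribution
#'
#' Bins lengths at 1 bp, smooths with a 5-bp running mean, and takes the
#' normalized autocorrelation of the mean-centered histogram over lags
#' 100-300 bp.  Only the nucleosomal part of the distribution
#' (`lengths >= min_length`, default 100 bp) enters the histogram, so the
#' sub-nucleosomal mode cannot masquerade as a period.  The period is the
#' argmax lag; when the autocorrelation never exceeds `min_acf` the
#' distribution is flagged aperiodic (`periodic = FALSE`, period `NA`).
#'
#' @param lengths integer vector of fragment lengths; at least 1,000.
#' @param lag_range lags (bp) searched for the period.
#' @param min_length fragments below this length are excluded from the
#'   periodicity histogram (default 100 bp, the nucleosome-free cutoff).
#' @param min_acf minimum normalized autocorrelation (default 0.2) for a
#'   lag to count as a genuine periodicity peak.
#' @return list with `period` (bp or NA), `periodic` (logical), `acf`
#'   (named vector over lags).
#' @export
fragment_periodicity <- function(lengths, lag_range = c(100L, 300L),
                                 min_length = 100L, min_acf = 0.2) {
  if (length(lengths) < 1000L) {
    stop("need at least 1,000 fragments to estimate periodicity, got ",
         length(lengths))
  }
  stopifnot(all(lengths > 0))
  h <- tabulate(as.integer(lengths))
  if (min_length > 1L && length(h) >= min_length) {
    h[seq_len(min_length - 1L)] <- 0
  }
  ## trim to the occupied support: flat zero flanks bias the
  ## mean-centered autocorrelation toward longer lags
  nz <- which(h > 0)
  if (!length(nz)) {
    return(list(period = NA_integer_, periodic = FALSE,
                acf = stats::setNames(numeric(0), integer(0))))
  }
  h <- h[nz[1]:nz[length(nz)]]
  k <- 5L
  if (length(h) > k) {
    h <- as.numeric(stats::filter(h, rep(1 / k, k), sides = 2))
    h[is.na(h)] <- 0
  }
  hc <- h - mean(h)
  denom <- sum(hc^2)
  L <- length(hc)
  lags <- seq(lag_range[1], min(lag_range[2], L - 1L))
  if (!length(lags) || denom == 0) {
    return(list(period = NA_integer_, periodic = FALSE,
                acf = stats::setNames(numeric(0), integer(0))))
  }
  ac <- vapply(lags, function(l) {
    sum(hc[seq_len(L - l)] * hc[seq_len(L - l) + l]) / denom
  }, 0)
  names(ac) <- lags
  if (max(ac) < min_acf) {
    return(list(period = NA_integer_, periodic = FALSE, acf = ac))
  }
  list(period = as.integer(lags[which.max(ac)]), periodic = TRUE, acf = ac)
}

#' TSS enrichment score of ATAC cut sites
#'
#' Cut sites are aggregated in strand-oriented windows of +/- `window` bp
#' around every TSS.  The score is the mean per-bp cut density within
#' +/-100 bp of the TSS divided by the mean density in the outermost
#' 100 bp tails of the window.
#'
#' @param cut_sites width-1 GRanges of corrected cut sites.
#' @param genes gene data.frame (see [make_genome()]).
#' @param window half-window size in bp (default 2000).
#' @return list with `score` (ratio; `Inf` when the tails are empty, with
#'   `flagged = TRUE`), `center_density`, `tail_density`, `profile`
#'   (counts by offset) and `flagged`.
#' @export
tss_enrichment <- function(cut_sites, genes, window = 2000L) {
  stopifnot(nrow(genes) >= 1)
  tss <- gene_tss(genes)
  win <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(pmax(1L, tss - window),
                                                 tss + window))
  ov <- GenomicRanges::findOverlaps(cut_sites, win, ignore.strand = TRUE)
  g <- S4Vectors::subjectHits(ov)
  pos <- BiocGenerics::start(cut_sites)[S4Vectors::queryHits(ov)]
  offset <- ifelse(genes$strand[g] == "+", pos - tss[g], tss[g] - pos)
  offset <- offset[abs(offset) <= window]
  profile <- table(factor(offset, levels = seq(-window, window)))
  counts <- as.numeric(profile)
  offs <- seq(-window, window)
  center <- abs(offs) <= 100
  tails <- abs(offs) > window - 100
  center_density <- sum(counts[center]) / sum(center)
  tail_density <- sum(counts[tails]) / sum(tails)
  flagged <- tail_density == 0
  score <- if (flagged) Inf else center_density / tail_density
  list(score = score, center_density = center_density,
       tail_density = tail_density,
       profile = stats::setNames(counts, offs), flagged = flagged)
}

#' Sliding-window Poisson peak caller
#'
#' Each corrected cut site is extended to the interval
#' `[pos + shift, pos + shift + extsize)` (0-based, clipped to the
#' chromosome); per-bp pileup is the number of covering intervals.  Every
#' covered position is tested against a single genome-wide Poisson
#' background with rate `lambda` = total pileup mass / genome length
#' (upper tail, `P(X >= k)`), with Benjamini-Hochberg correction across
#' covered positions.  Significant positions (`q < q_threshold`) are
#' merged when separated by fewer than `merge_gap` bp, and merged regions
#' shorter than `extsize` are discarded.  The summit is the leftmost
#' pileup maximum.
#'
#' @param cut_sites width-1 GRanges of cut sites (strand ignored).
#' @param chrom_lengths named vector of chromosome lengths.
#' @param shift,extsize window placement parameters (default -100 / 200,
#'   centering a 200 bp window on each cut).
#' @param q_threshold BH-adjusted significance threshold (default 0.05).
#' @param merge_gap maximum gap (exclusive, bp) across which significant
#'   stretches are joined; default 30.
#' @return GRanges of peaks with metadata `summit` (1-based position),
#'   `pileup`, `p_value`, `q_value`, plus attribute-free empty GRanges for
#'   empty input.
#' @export
call_peaks <- function(cut_sites, chrom_lengths, shift = -100L,
                       extsize = 200L, q_threshold = 0.05,
                       merge_gap = 30L) {
  stopifnot(extsize > 0)
  if (!length(cut_sites)) return(GenomicRanges::GRanges())
  pos0 <- BiocGenerics::start(cut_sites) - 1L
  chrom <- as.character(GenomeInfoDb::seqnames(cut_sites))
  L <- chrom_lengths[chrom]
  s0 <- pmax(0, pos0 + shift)
  e0 <- pmin(as.numeric(L), pos0 + shift + extsize)
  keep <- e0 > s0
  ext <- GenomicRanges::GRanges(chrom[keep],
                                IRanges::IRanges(s0[keep] + 1L, e0[keep]))
  GenomeInfoDb::seqlevels(ext) <- names(chrom_lengths)
  cov <- GenomicRanges::coverage(ext, width = as.list(chrom_lengths))

  total_mass <- sum(vapply(cov, function(r) sum(as.numeric(S4Vectors::runValue(r)) *
                                                  S4Vectors::runLength(r)), 0))
  lambda <- total_mass / sum(as.numeric(chrom_lengths))

  vals <- unlist(lapply(cov, S4Vectors::runValue), use.names = FALSE)
  lens <- unlist(lapply(cov, S4Vectors::runLength), use.names = FALSE)
  nz <- vals > 0
  tab <- rowsum(as.numeric(lens[nz]), vals[nz])
  v <- as.integer(rownames(tab))
  n_at <- as.numeric(tab[, 1])
  p_at <- stats::ppois(v - 1L, lambda, lower.tail = FALSE)
  q_at <- bh_adjust_weighted(p_at, n_at)
  sig <- v[q_at < q_threshold]
  if (!length(sig)) return(GenomicRanges::GRanges())
  thr <- min(sig)
  p_by_v <- stats::setNames(p_at, v)
  q_by_v <- stats::setNames(q_at, v)

  out <- GenomicRanges::GRanges()
  for (cn in names(cov)) {
    r <- cov[[cn]]
    reg <- IRanges::slice(r, lower = thr, rangesOnly = TRUE)
    if (!length(reg)) next
    reg <- IRanges::reduce(reg, min.gapwidth = merge_gap)
    reg <- reg[BiocGenerics::width(reg) >= extsize]
    if (!length(reg)) next
    vw <- IRanges::Views(r, reg)
    summit <- BiocGenerics::start(reg) +
      vapply(vw, which.max, 0L) - 1L
    pk <- as.integer(IRanges::viewMaxs(vw))
    gr <- GenomicRanges::GRanges(factor(cn, levels = names(cov)), reg)
    S4Vectors::mcols(gr)$summit <- summit
    S4Vectors::mcols(gr)$pileup <- pk
    S4Vectors::mcols(gr)$p_value <- unname(p_by_v[as.character(pk)])
    S4Vectors::mcols(gr)$q_value <- unname(q_by_v[as.character(pk)])
    out <- c(out, gr)
  }
  GenomicRanges::sort(out)
}

#' Benjamini-Hochberg adjustment for run-length encoded p-values
#'
#' Equivalent to `p.adjust(rep(p, n), "BH")` on the expanded vector, but
#' computed on the unique values with multiplicities -- the form needed
#' when millions of genome positions share a handful of pileup values.
#'
#' @param p numeric vector of distinct p-values.
#' @param n positive multiplicities, parallel to `p`.
#' @return adjusted p-values, parallel to `p`.
#' @export
bh_adjust_weighted <- function(p, n) {
  stopifnot(length(p) == length(n), all(n > 0))
  o <- order(p)
  N <- sum(n)
  ranks <- cumsum(n[o])            # highest rank within each tied block
  adj <- p[o] * N / ranks
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(length(p))
  out[o] <- adj
  out
}

#' Per-replicate peak pileup as bedGraph text
#'
#' Writes 4-column bedGraph (0-based half-open) from a coverage RleList or
#' from cut sites (converted to width-1 coverage).  Adjacent equal-value
#' runs are merged; zero-coverage runs are omitted.
#'
#' @param x an RleList of per-chromosome coverage, or a sorted width-1
#'   GRanges of cut sites.
#' @param path output path.
#' @param chrom_lengths required when `x` is a GRanges.
#' @return `path`, invisibly.
#' @export
export_bedgraph <- function(x, path, chrom_lengths = NULL) {
  if (methods::is(x, "GRanges")) {
    if (length(x) > 1L &&
        is.unsorted(order(as.character(GenomeInfoDb::seqnames(x)),
                          BiocGenerics::start(x)))) {
      stop("cut sites must be sorted before bedGraph export")
    }
    if (is.null(chrom_lengths)) stop("chrom_lengths required for GRanges input")
    x <- GenomicRanges::coverage(x, width = as.list(chrom_lengths))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("track type=bedGraph", con)
  for (cn in names(x)) {
    r <- x[[cn]]
    v <- S4Vectors::runValue(r)
    l <- S4Vectors::runLength(r)
    ends <- cumsum(as.numeric(l))
    starts <- ends - as.numeric(l)        # 0-based
    keep <- v != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%g", cn, as.integer(starts[keep]),
                       as.integer(ends[keep]), v[keep]), con)
  }
  invisible(path)
}

#' Write peaks in narrowPeak-style BED6+4
#'
#' Columns: chrom, start, end, name, score (pileup), strand, signalValue
#' (pileup), -log10 p, -log10 q, summit offset from peak start.
#'
#' @param peaks GRanges from [call_peaks()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  if (!length(peaks)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  md <- S4Vectors::mcols(peaks)
  out <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(peaks)),
                    start = BiocGenerics::start(peaks) - 1L,
                    end = BiocGenerics::end(peaks),
                    name = sprintf("peak_%d", seq_along(peaks)),
                    score = md$pileup,
                    strand = ".",
                    signal = md$pileup,
                    neglog10p = round(-log10(pmax(md$p_value, 1e-300)), 4),
                    neglog10q = round(-log10(pmax(md$q_value, 1e-300)), 4),
                    summit = md$summit - BiocGenerics::start(peaks))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
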