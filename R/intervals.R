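#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits Rle runValue runLength
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqlevels<- seqnames
#' @importFrom methods is
NULL

## All on-disk interval formats are BED: 0-based, half-open.  In memory the
## package uses GRanges (1-based, closed); the two helpers below are the only
## place the conversion happens.

#' Convert a 0-based half-open interval table to GRanges
#'
#' @param df data.frame with columns `chrom`, `start`, `end` (BED convention)
#'   and optionally `name`, `score`, `strand`.
#' @return A [GenomicRanges::GRanges] carrying any extra columns as metadata.
#' @keywords internal
bed_to_granges <- function(df) {
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end),
                               strand = strand)
  extra <- setdiff(names(df), c("chrom", "start", "end", "strand"))
  for (nm in extra) S4Vectors::mcols(gr)[[nm]] <- df[[nm]]
  gr
}

#' Convert GRanges to a 0-based half-open interval table
#' @param gr a GRanges.
#' @return data.frame with `chrom`, `start`, `end` in BED convention plus any
#'   metadata columns and, when informative, `strand`.
#' @keywords internal
granges_to_bed <- function(gr) {
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = BiocGenerics::start(gr) - 1L,
                   end   = BiocGenerics::end(gr),
                   stringsAsFactors = FALSE)
  md <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(md)) df <- cbind(df, md)
  st <- as.character(BiocGenerics::strand(gr))
  if (any(st != "*")) df$strand <- st
  df
}

#' Read a BED file of genomic intervals
#'
#' Reads BED3/BED6 (tab-separated, 0-based half-open).  Input order is
#' preserved; empty intervals (`start >= end`) and malformed lines are
#' rejected with the offending line number.
#'
#' @param path file path.
#' @return GRanges in file order; columns 4-6, when present, become `name`,
#'   `score` and strand.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".bed")
#' writeLines("chr1\t0\t100\tpk1\t5\t+", tf)
#' read_bed(tf)
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  if (!length(lines)) {
    return(GenomicRanges::GRanges())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("malformed BED line ", which(nf < 3L)[1L], ": fewer than 3 fields")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end   <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | chrom == "")
  if (length(bad)) stop("malformed BED line ", bad[1L], ": non-numeric coordinates")
  bad <- which(start < 0L | start >= end)
  if (length(bad)) {
    stop("invalid interval at BED line ", bad[1L],
         ": need 0 <= start < end, got [", start[bad[1L]], ", ", end[bad[1L]], ")")
  }
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  if (all(nf >= 4L)) df$name <- vapply(fields, `[[`, "", 4L)
  if (all(nf >= 5L)) df$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  if (all(nf >= 6L)) df$strand <- vapply(fields, `[[`, "", 6L)
  bed_to_granges(df)
}

#' Write intervals to a BED file
#'
#' Writes BED3, or BED6 when `name`/`score`/strand information is present.
#' Coordinates are emitted 0-based half-open so that
#' `read_bed(write_bed(x))` round-trips exactly.
#'
#' @param gr GRanges to write.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  df <- granges_to_bed(gr)
  has6 <- any(c("name", "score", "strand") %in% names(df))
  if (has6) {
    out <- data.frame(df$chrom, df$start, df$end,
                      name   = if (is.null(df$name)) "." else df$name,
                      score  = if (is.null(df$score)) 0 else df$score,
                      strand = if (is.null(df$strand)) "*" else df$strand)
  } else {
    out <- df[, c("chrom", "start", "end")]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Overlap in base pairs between paired intervals
#'
#' Element-wise overlap of two equal-length GRanges (or one interval against
#' another).  Abutting intervals overlap 0 bp; different chromosomes 0 bp.
#'
#' @param a,b GRanges of equal length (or length 1, recycled).
#' @return integer vector of overlap widths in bp.
#' @export
overlap_bp <- function(a, b) {
  n <- max(length(a), length(b))
  if (length(a) == 1L) a <- rep(a, n)
  if (length(b) == 1L) b <- rep(b, n)
  stopifnot(length(a) == length(b))
  ov <- pmin(BiocGenerics::end(a), BiocGenerics::end(b)) -
    pmax(BiocGenerics::start(a), BiocGenerics::start(b)) + 1L
  ov[as.character(GenomeInfoDb::seqnames(a)) !=
       as.character(GenomeInfoDb::seqnames(b))] <- 0L
  pmax(ov, 0L)
}

#' Reciprocal-overlap test for a peak pair
#'
#' TRUE when the shared span exceeds `threshold` of *each* interval's length
#' (strict inequality), the rule used to call two replicate peaks the same
#' peak.
#'
#' @param a,b GRanges, element-wise pairs.
#' @param threshold required overlap fraction in (0, 1]; default 0.5.
#' @return logical vector.
#' @export
reciprocal_overlap_pass <- function(a, b, threshold = 0.5) {
  stopifnot(threshold > 0, threshold <= 1)
  ov <- overlap_bp(a, b)
  wa <- BiocGenerics::width(if (length(a) == 1L) rep(a, length(ov)) else a)
  wb <- BiocGenerics::width(if (length(b) == 1L) rep(b, length(ov)) else b)
  ## a complete overlap (fraction exactly 1) passes any threshold
  pass_a <- ov / wa > threshold | ov == wa
  pass_b <- ov / wb > threshold | ov == wb
  pass_a & pass_b & ov > 0L
}

#' Merge overlapping intervals within one set
#'
#' Union of overlapping intervals; abutting (0 bp overlap) intervals are kept
#' separate, respecting the half-open convention.
#'
#' @param gr GRanges.
#' @return reduced GRanges sorted by position.
#' @export
merge_intervals <- function(gr) {
  GenomicRanges::reduce(GenomicRanges::sort(gr), min.gapwidth = 0L)
}

#' Replicate-consensus peak construction
#'
#' A replicate peak is *retained* when at least `min_replicates - 1` other
#' replicates each contain a peak whose reciprocal overlap with it exceeds
#' `threshold` (strictly).  Retained peaks that overlap across replicates are
#' then unioned transitively into a single consensus peak spanning their
#' outer bounds.
#'
#' @param replicate_sets list of GRanges, one per biological replicate; each
#'   must be internally non-overlapping (pre-merge with [merge_intervals()]).
#' @param min_replicates minimum number of supporting replicates (default 2).
#' @param threshold reciprocal overlap fraction, strict (default 0.5).
#' @return GRanges sorted by position with metadata columns `support`
#'   (number of contributing replicates) and `name`
#'   (comma-separated replicate identifiers).  No two output intervals
#'   overlap.
#' @export
consensus_peaks <- function(replicate_sets, min_replicates = 2L,
                            threshold = 0.5) {
  n_rep <- length(replicate_sets)
  if (min_replicates > n_rep) {
    stop("min_replicates (", min_replicates, ") exceeds number of replicate sets (",
         n_rep, ")")
  }
  if (is.null(names(replicate_sets))) {
    names(replicate_sets) <- paste0("rep", seq_len(n_rep))
  }
  for (i in seq_len(n_rep)) {
    gr <- replicate_sets[[i]]
    if (length(gr) > 1L && length(merge_intervals(gr)) != length(gr)) {
      stop("replicate set ", names(replicate_sets)[i],
           " contains internally overlapping intervals; pre-merge first")
    }
  }
  all_levels <- unique(unlist(lapply(replicate_sets, GenomeInfoDb::seqlevels)))
  pooled <- do.call(c, lapply(seq_len(n_rep), function(i) {
    gr <- replicate_sets[[i]]
    S4Vectors::mcols(gr) <- NULL
    GenomeInfoDb::seqlevels(gr) <- all_levels
    if (length(gr)) S4Vectors::mcols(gr)$replicate <- names(replicate_sets)[i]
    gr
  }))
  if (!length(pooled)) return(GenomicRanges::GRanges())

  ## count, for each pooled peak, in how many OTHER replicates it has a
  ## reciprocal-overlap partner
  hits <- GenomicRanges::findOverlaps(pooled, pooled, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  keep <- qh != sh &
    S4Vectors::mcols(pooled)$replicate[qh] != S4Vectors::mcols(pooled)$replicate[sh]
  qh <- qh[keep]; sh <- sh[keep]
  pass <- reciprocal_overlap_pass(pooled[qh], pooled[sh], threshold)
  qh <- qh[pass]; sh <- sh[pass]
  n_other <- integer(length(pooled))
  if (length(qh)) {
    tab <- unique(data.frame(q = qh, rep = S4Vectors::mcols(pooled)$replicate[sh]))
    cnt <- table(tab$q)
    n_other[as.integer(names(cnt))] <- as.integer(cnt)
  }
  retained <- pooled[n_other >= min_replicates - 1L]
  if (!length(retained)) return(GenomicRanges::GRanges())

  merged <- merge_intervals(retained)
  ov <- GenomicRanges::findOverlaps(merged, retained, ignore.strand = TRUE)
  reps <- split(S4Vectors::mcols(retained)$replicate[S4Vectors::subjectHits(ov)],
                S4Vectors::queryHits(ov))
  support_sets <- lapply(reps, function(r) sort(unique(r)))
  S4Vectors::mcols(merged)$support <- unname(lengths(support_sets))
  S4Vectors::mcols(merged)$name <-
    unname(vapply(support_sets, paste, "", collapse = ","))
  merged
}

#' Fraction of the genome covered by a set of intervals
#'
#' Non-redundant covered bases divided by total genome length; overlapping
#' inputs are counted once.
#'
#' @param gr GRanges.
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @return scalar fraction in \[0, 1\].
#' @export
genome_fraction <- function(gr, chrom_lengths) {
  stopifnot(length(chrom_lengths) > 0, all(chrom_lengths > 0))
  if (length(gr)) {
    chr <- as.character(GenomeInfoDb::seqnames(gr))
    if (!all(chr %in% names(chrom_lengths))) {
      stop("interval on chromosome absent from chrom_lengths")
    }
    if (any(BiocGenerics::end(gr) > chrom_lengths[chr]) ||
        any(BiocGenerics::start(gr) < 1L)) {
      stop("interval extends beyond chromosome bounds")
    }
  }
  covered <- sum(as.numeric(BiocGenerics::width(merge_intervals(gr))))
  covered / sum(as.numeric(chrom_lengths))
}
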