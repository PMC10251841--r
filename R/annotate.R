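## Priority-ordered genomic feature annotation of peaks, plus a generic
## hypergeometric over-representation test over user-supplied term maps.

#' Category priority used throughout annotation
#' @keywords internal
ANNOTATION_CATEGORIES <- c("promoter", "5'UTR", "3'UTR", "exon", "intron",
                           "downstream", "distal_intergenic")

#' Derive feature tracks from gene models
#'
#' Builds one interval set per genomic feature category: `promoter`
#' (TSS +/- `promoter_flank`, strand-aware center), `5'UTR` / `3'UTR`
#' (exonic sequence outside the CDS, split by transcription direction;
#' absent for non-coding genes), `exon` (coding exon bodies, or whole exons
#' of non-coding genes), `intron` (gene span minus exons) and `downstream`
#' (`downstream_flank` bp past the 3' gene end).  All tracks are clipped to
#' the chromosome.
#'
#' @param genes gene data.frame (see [make_genome()] / [read_gene_table()]).
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param promoter_flank promoter half-window around the TSS (default
#'   3000 bp).
#' @param downstream_flank extent of the downstream track (default 3000 bp).
#' @return named list of GRanges, one per category except
#'   `distal_intergenic` (implicit complement).
#' @export
feature_tracks <- function(genes, chrom_lengths, promoter_flank = 3000L,
                           downstream_flank = 3000L) {
  lvls <- names(chrom_lengths)
  mk <- function(chrom, start, end) {
    keep <- !is.na(start) & !is.na(end) & end >= start
    chrom <- chrom[keep]; start <- start[keep]; end <- end[keep]
    start <- pmax(1, start)
    end <- pmin(as.numeric(chrom_lengths[chrom]), end)
    keep <- end >= start
    GenomicRanges::GRanges(factor(chrom[keep], levels = lvls),
                           IRanges::IRanges(as.integer(start[keep]),
                                            as.integer(end[keep])))
  }
  tss <- gene_tss(genes)
  promoter <- mk(genes$chrom, tss - promoter_flank, tss + promoter_flank)

  exon_list <- vector("list", nrow(genes))
  utr5_list <- vector("list", nrow(genes))
  utr3_list <- vector("list", nrow(genes))
  intron_list <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    ex <- IRanges::IRanges(genes$exons[[i]][, 1], genes$exons[[i]][, 2])
    gene_span <- IRanges::IRanges(genes$start[i], genes$end[i])
    introns <- BiocGenerics::setdiff(gene_span, ex)
    coding <- !is.na(genes$cds_start[i])
    if (coding) {
      cds <- IRanges::IRanges(genes$cds_start[i], genes$cds_end[i])
      pre <- if (genes$cds_start[i] > genes$start[i]) {
        IRanges::IRanges(genes$start[i], genes$cds_start[i] - 1L)
      } else IRanges::IRanges()
      post <- if (genes$cds_end[i] < genes$end[i]) {
        IRanges::IRanges(genes$cds_end[i] + 1L, genes$end[i])
      } else IRanges::IRanges()
      if (genes$strand[i] == "+") {
        utr5 <- BiocGenerics::intersect(ex, pre)
        utr3 <- BiocGenerics::intersect(ex, post)
      } else {
        utr5 <- BiocGenerics::intersect(ex, post)
        utr3 <- BiocGenerics::intersect(ex, pre)
      }
      exon_body <- BiocGenerics::intersect(ex, cds)
    } else {
      utr5 <- IRanges::IRanges()
      utr3 <- IRanges::IRanges()
      exon_body <- ex
    }
    wrap <- function(ir) {
      GenomicRanges::GRanges(factor(rep(genes$chrom[i], length(ir)),
                                    levels = lvls), ir)
    }
    exon_list[[i]] <- wrap(exon_body)
    utr5_list[[i]] <- wrap(utr5)
    utr3_list[[i]] <- wrap(utr3)
    intron_list[[i]] <- wrap(introns)
  }
  cat_gr <- function(lst) {
    if (!length(lst)) {
      return(GenomicRanges::GRanges(seqnames = factor(levels = lvls)))
    }
    do.call(c, lst)
  }
  down_start <- ifelse(genes$strand == "+", genes$end + 1,
                       genes$start - downstream_flank)
  down_end <- ifelse(genes$strand == "+", genes$end + downstream_flank,
                     genes$start - 1)
  downstream <- mk(genes$chrom, down_start, down_end)

  clip <- function(gr) {
    if (!length(gr)) return(gr)
    chrom <- as.character(GenomeInfoDb::seqnames(gr))
    GenomicRanges::GRanges(chrom,
                           IRanges::IRanges(pmax(1L, BiocGenerics::start(gr)),
                                            pmin(as.integer(chrom_lengths[chrom]),
                                                 BiocGenerics::end(gr))))
  }
  list(promoter = promoter,
       `5'UTR` = clip(cat_gr(utr5_list)),
       `3'UTR` = clip(cat_gr(utr3_list)),
       exon = clip(cat_gr(exon_list)),
       intron = clip(cat_gr(intron_list)),
       downstream = downstream)
}

#' Annotate peaks with a single prioritized feature category
#'
#' Each peak takes the highest-priority category whose track it overlaps by
#' at least 1 bp, in the order promoter > 5'UTR > 3'UTR > exon > intron >
#' downstream; peaks overlapping nothing are `distal_intergenic`.  Each
#' peak is also assigned its nearest gene by distance from the peak
#' midpoint to the TSS (ties broken by lexicographically smaller gene id),
#' with a signed distance that is negative upstream of the TSS in gene
#' orientation.
#'
#' @param peaks GRanges of peaks.
#' @param tracks feature tracks from [feature_tracks()].
#' @param genes gene data.frame the tracks were built from.
#' @return data.frame with one row per peak: `chrom`, `start`, `end`
#'   (0-based half-open), `category` (factor over the seven categories),
#'   `nearest_gene`, `distance_to_tss`.
#' @export
annotate_peaks <- function(peaks, tracks, genes) {
  n <- length(peaks)
  category <- rep("distal_intergenic", n)
  unassigned <- rep(TRUE, n)
  for (cat in names(tracks)) {
    if (!any(unassigned)) break
    if (!length(tracks[[cat]])) next
    hit <- GenomicRanges::countOverlaps(peaks, tracks[[cat]],
                                        ignore.strand = TRUE) > 0
    take <- unassigned & hit
    category[take] <- cat
    unassigned[take] <- FALSE
  }
  nearest_gene <- rep(NA_character_, n)
  distance <- rep(NA_real_, n)
  if (nrow(genes)) {
    tss <- gene_tss(genes)
    mid <- BiocGenerics::start(peaks) +
      (BiocGenerics::end(peaks) - BiocGenerics::start(peaks)) %/% 2L
    pchrom <- as.character(GenomeInfoDb::seqnames(peaks))
    ord <- order(genes$gene_id)      # lexicographic tie-break
    for (i in seq_len(n)) {
      cand <- ord[genes$chrom[ord] == pchrom[i]]
      if (!length(cand)) next
      d <- abs(mid[i] - tss[cand])
      j <- cand[which.min(d)]
      nearest_gene[i] <- genes$gene_id[j]
      distance[i] <- if (genes$strand[j] == "+") mid[i] - tss[j] else
        tss[j] - mid[i]
    }
  }
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(peaks)),
             start = BiocGenerics::start(peaks) - 1L,
             end = BiocGenerics::end(peaks),
             category = factor(category, levels = ANNOTATION_CATEGORIES),
             nearest_gene = nearest_gene,
             distance_to_tss = distance,
             stringsAsFactors = FALSE)
}

#' Category percentage table of a peak annotation
#'
#' @param annotations data.frame from [annotate_peaks()].
#' @return data.frame with `category`, `count`, `percent`; percentages over
#'   all peaks, summing to 100 within 0.01.
#' @export
annotation_summary <- function(annotations) {
  if (!nrow(annotations)) stop("no annotations to summarize")
  counts <- table(annotations$category)
  data.frame(category = names(counts),
             count = as.integer(counts),
             percent = as.numeric(counts) / nrow(annotations) * 100,
             stringsAsFactors = FALSE)
}

#' Hypergeometric over-representation test
#'
#' For each term with K genes in the universe, tests whether the k hits in
#' an n-gene set exceed expectation under hypergeometric sampling:
#' upper-tail `P(X >= k)` given (N, K, n).  P-values are BH-adjusted
#' across all tested terms and flagged significant at adjusted p <= 0.01.
#'
#' @param gene_set character vector, must be a subset of `universe`.
#' @param term_map data.frame with columns `term_id`, `gene_id`.
#' @param universe character vector of all genes considered.
#' @param sig_threshold adjusted-p significance cutoff (default 0.01).
#' @return data.frame sorted by adjusted p: `term_id`, `k`, `n`, `K`, `N`,
#'   `p_value`, `adjusted_p`, `significant`.
#' @export
ora_test <- function(gene_set, term_map, universe, sig_threshold = 0.01) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty gene universe")
  gene_set <- unique(gene_set)
  if (!all(gene_set %in% universe)) {
    stop("gene_set contains genes absent from the universe")
  }
  term_map <- term_map[term_map$gene_id %in% universe, , drop = FALSE]
  terms <- split(unique(term_map[c("term_id", "gene_id")])$gene_id,
                 unique(term_map[c("term_id", "gene_id")])$term_id)
  N <- length(universe)
  n <- length(gene_set)
  rows <- lapply(names(terms), function(t) {
    K <- length(terms[[t]])
    k <- sum(gene_set %in% terms[[t]])
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = t, k = k, n = n, K = K, N = N, p_value = p)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term_id = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p_value = numeric(),
                      adjusted_p = numeric(), significant = logical()))
  }
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$adjusted_p <= sig_threshold
  out <- out[order(out$adjusted_p, out$p_value, out$term_id), ]
  rownames(out) <- NULL
  out
}

#' Write a peak annotation table as TSV
#' @param annotations data.frame from [annotate_peaks()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a two-column term map TSV (term_id, gene_id)
#' @param path file path.
#' @return data.frame with `term_id`, `gene_id`.
#' @export
read_term_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("term_id", "gene_id") %in% names(df)))
  df
}
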