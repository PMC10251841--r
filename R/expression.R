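## TPM normalization, expressed-gene filtering and replicate-correlation QC
## for the RNA-seq side of the workflow.

#' Transcripts per million from raw counts
#'
#' `rate_g = count_g / (length_g / 1000)`, scaled per sample so that each
#' column sums to one million.  An all-zero sample stays all-zero and is
#' flagged via the `"zero_samples"` attribute.
#'
#' @param counts gene x sample matrix of non-negative counts.
#' @param lengths gene lengths in bp, parallel to rows (recycled names
#'   checked when both are named).
#' @return TPM matrix of the same shape.
#' @export
compute_tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (any(lengths <= 0)) stop("gene lengths must be > 0")
  if (any(counts < 0)) stop("counts must be >= 0")
  if (!is.null(rownames(counts)) && !is.null(names(lengths))) {
    lengths <- lengths[rownames(counts)]
    if (any(is.na(lengths))) stop("lengths missing for some genes")
  }
  rate <- counts / (lengths / 1000)
  totals <- colSums(rate)
  zero <- totals == 0
  totals[zero] <- 1
  tpm <- sweep(rate, 2, totals, "/") * 1e6
  if (any(zero)) {
    warning("sample(s) with zero total counts: ",
            paste(colnames(counts)[zero], collapse = ", "))
  }
  attr(tpm, "zero_samples") <- colnames(counts)[zero]
  tpm
}

#' Expressed genes by mean-TPM filter
#'
#' Genes whose mean TPM across samples is strictly greater than
#' `threshold` (default 2).
#'
#' @param tpm TPM matrix from [compute_tpm()].
#' @param threshold expression cutoff (strict; default 2).
#' @return character vector of expressed gene ids (row indices when the
#'   matrix is unnamed).
#' @export
expressed_genes <- function(tpm, threshold = 2) {
  stopifnot(ncol(tpm) >= 1)
  means <- rowMeans(tpm)
  idx <- which(means > threshold)
  if (is.null(rownames(tpm))) idx else rownames(tpm)[idx]
}

#' Pairwise Pearson correlation between replicates
#'
#' Computed on `log2(TPM + 1)` by default (set `log = FALSE` for the raw
#' scale).  Samples with zero variance are flagged and their pairs
#' reported as `NA`.
#'
#' @param tpm TPM matrix (genes x samples), at least 2 samples.
#' @param log use the log2(TPM + 1) scale (default TRUE).
#' @return symmetric correlation matrix with unit diagonal and a
#'   `"flagged_samples"` attribute naming zero-variance samples.
#' @export
replicate_correlation <- function(tpm, log = TRUE) {
  stopifnot(ncol(tpm) >= 2, nrow(tpm) >= 2)
  x <- if (log) log2(tpm + 1) else tpm
  sds <- apply(x, 2, stats::sd)
  flagged <- colnames(x)[sds == 0]
  r <- suppressWarnings(stats::cor(x, method = "pearson"))
  r[sds == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  diag(r) <- 1
  attr(r, "flagged_samples") <- flagged
  r
}
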