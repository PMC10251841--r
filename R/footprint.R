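## PWM scanning and Tn5 footprint analysis: motif occurrences by log-odds
## score, target-vs-background motif enrichment, aggregate cut profiles
## around motif centers, and an active/inactive call from footprint depth
## plus trough shape, cross-checked against RNA-seq expression.

BASES <- c("A", "C", "G", "T")

#' Construct a PWM around a consensus sequence
#'
#' Probability `p` for the consensus base at each position, `(1-p)/3` for
#' the others -- a convenient sharp motif for simulations and tests.
#'
#' @param consensus character scalar over ACGT, length >= 4.
#' @param name motif/TF name.
#' @param p consensus-base probability (default 0.85).
#' @param pseudocount regularizer used in log-odds scoring (default 0.01).
#' @return list of class `pwm`: `name`, `mat` (4 x L, rows A,C,G,T;
#'   columns sum to 1), `pseudocount`.
#' @export
consensus_pwm <- function(consensus, name = consensus, p = 0.85,
                          pseudocount = 0.01) {
  chars <- strsplit(toupper(consensus), "")[[1]]
  stopifnot(length(chars) >= 4, all(chars %in% BASES))
  mat <- matrix((1 - p) / 3, nrow = 4, ncol = length(chars),
                dimnames = list(BASES, NULL))
  mat[cbind(match(chars, BASES), seq_along(chars))] <- p
  new_pwm(name, mat, pseudocount)
}

new_pwm <- function(name, mat, pseudocount = 0.01) {
  stopifnot(nrow(mat) == 4, ncol(mat) >= 4)
  if (any(abs(colSums(mat) - 1) > 1e-6)) {
    stop("PWM columns must each sum to 1 (within 1e-6)")
  }
  rownames(mat) <- BASES
  structure(list(name = name, mat = mat, pseudocount = pseudocount),
            class = "pwm")
}

pwm_width <- function(pwm) ncol(pwm$mat)

#' Consensus string of a PWM (argmax base per position)
#' @param pwm a `pwm`.
#' @return character scalar.
#' @export
pwm_consensus <- function(pwm) {
  paste(BASES[apply(pwm$mat, 2, which.max)], collapse = "")
}

## regularized probabilities and log2-odds against a background model
pwm_logodds <- function(pwm, background = rep(0.25, 4)) {
  pr <- (pwm$mat + pwm$pseudocount) / (1 + 4 * pwm$pseudocount)
  log2(pr / background)
}

#' Maximum attainable log-odds score of a PWM (bits)
#' @param pwm a `pwm`.
#' @param background background base frequencies (default uniform).
#' @return numeric scalar.
#' @export
pwm_max_score <- function(pwm, background = rep(0.25, 4)) {
  sum(apply(pwm_logodds(pwm, background), 2, max))
}

#' Reverse complement of a DNA string
#' @param x character vector over ACGTN.
#' @return character vector.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgtN", "TGCAtgcaN", s), "")[[1]]),
          collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Scan a sequence for PWM matches by log-odds score
#'
#' Scores every window on both strands with `sum(log2(p'/bg))` bits, where
#' `p'` is the pseudocount-regularized PWM probability, and reports windows
#' scoring at least `score_threshold`.  Windows containing `N` are
#' skipped.  Minus-strand hits are positions on the forward sequence whose
#' reverse complement matches.
#'
#' @param sequence character scalar over ACGTN.
#' @param pwm a `pwm`.
#' @param score_threshold minimum score in bits.
#' @param background background base frequencies (default uniform 0.25).
#' @return data.frame with `pos` (1-based window start on the forward
#'   strand), `strand`, `score`; empty when the motif is longer than the
#'   sequence.
#' @export
pwm_scan <- function(sequence, pwm, score_threshold,
                     background = rep(0.25, 4)) {
  seq_chars <- strsplit(toupper(sequence), "")[[1]]
  L <- pwm_width(pwm)
  n <- length(seq_chars)
  empty <- data.frame(pos = integer(), strand = character(),
                      score = numeric())
  if (n < L) return(empty)
  codes <- match(seq_chars, BASES)        # N and friends -> NA
  lo_f <- pwm_logodds(pwm, background)
  lo_r <- lo_f[4:1, L:1]                  # reverse-complement motif
  n_win <- n - L + 1L
  score_windows <- function(lo) {
    s <- numeric(n_win)
    for (j in seq_len(L)) {
      s <- s + lo[cbind(codes[seq_len(n_win) + j - 1L], j)]
    }
    s
  }
  sf <- score_windows(lo_f)
  sr <- score_windows(lo_r)
  hits_f <- which(!is.na(sf) & sf >= score_threshold)
  hits_r <- which(!is.na(sr) & sr >= score_threshold)
  out <- rbind(
    data.frame(pos = hits_f, strand = rep("+", length(hits_f)),
               score = sf[hits_f]),
    data.frame(pos = hits_r, strand = rep("-", length(hits_r)),
               score = sr[hits_r]))
  out <- out[order(out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Target-vs-background motif enrichment
#'
#' For each PWM, counts sequences containing at least one hit at
#' `threshold_frac` of the motif's maximum score, in the target and
#' background sets, and tests enrichment with a one-tailed hypergeometric
#' (Fisher) p-value; BH adjustment across motifs.
#'
#' @param target_seqs,background_seqs character vectors of sequences.
#' @param pwms a `pwm` or list of `pwm`s.
#' @param threshold_frac fraction of the maximum score used as hit
#'   threshold (default 0.8).
#' @return data.frame ranked by p: `motif`, `target_hits`, `n_target`,
#'   `background_hits`, `n_background`, `p_value`, `adjusted_p`.
#' @export
motif_enrichment <- function(target_seqs, background_seqs, pwms,
                             threshold_frac = 0.8) {
  if (!length(background_seqs)) stop("empty background sequence set")
  if (!length(target_seqs)) stop("empty target sequence set")
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  nt <- length(target_seqs); nb <- length(background_seqs)
  rows <- lapply(pwms, function(pwm) {
    thr <- threshold_frac * pwm_max_score(pwm)
    hit <- function(seqs) {
      vapply(seqs, function(s) nrow(pwm_scan(s, pwm, thr)) > 0, TRUE,
             USE.NAMES = FALSE)
    }
    a <- sum(hit(target_seqs))
    b <- sum(hit(background_seqs))
    p <- stats::phyper(a - 1, a + b, nt + nb - a - b, nt, lower.tail = FALSE)
    data.frame(motif = pwm$name, target_hits = a, n_target = nt,
               background_hits = b, n_background = nb, p_value = p)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$motif), ]
  rownames(out) <- NULL
  out
}

#' Aggregate Tn5 cut profile around motif occurrences
#'
#' Sums cut-site counts per base offset in a +/-`window` bp frame around
#' each motif center, after orienting every site by its strand (minus-
#' strand profiles are reversed).  The depth score is the mean count in
#' the outermost `flank` bp on each side divided by the mean count over
#' the motif span (floored at 1 count to avoid division by zero).
#'
#' @param cut_sites width-1 GRanges of corrected cut sites.
#' @param occurrences stranded GRanges of motif spans (equal widths).
#' @param window half-window in bp (default 100).
#' @param flank flank width in bp used by the depth score (default 20).
#' @param tf_name label carried into the profile.
#' @return list of class `footprint_profile`: `tf_name`, `window`,
#'   `counts` (length `2*window+1`, named by offset), `n_sites`,
#'   `motif_width`, `depth_score`.
#' @export
aggregate_footprint <- function(cut_sites, occurrences, window = 100L,
                                flank = 20L, tf_name = "TF") {
  stopifnot(length(occurrences) >= 1)
  w <- unique(BiocGenerics::width(occurrences))
  if (length(w) != 1L) stop("motif occurrences must share one width")
  centers <- BiocGenerics::start(occurrences) + ((w - 1L) %/% 2L)
  frames <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(occurrences),
    IRanges::IRanges(centers - window, centers + window))
  ov <- GenomicRanges::findOverlaps(cut_sites, frames, ignore.strand = TRUE)
  site <- S4Vectors::subjectHits(ov)
  pos <- BiocGenerics::start(cut_sites)[S4Vectors::queryHits(ov)]
  offset <- pos - centers[site]
  minus <- as.character(BiocGenerics::strand(occurrences))[site] == "-"
  offset[minus] <- -offset[minus]
  counts <- table(factor(offset, levels = seq(-window, window)))
  counts <- stats::setNames(as.numeric(counts), seq(-window, window))
  offs <- seq(-window, window)
  motif_offs <- motif_center_offsets(w)
  center_mean <- mean(counts[offs %in% motif_offs])
  flank_mean <- mean(counts[abs(offs) > window - flank])
  structure(list(tf_name = tf_name, window = window, counts = counts,
                 n_sites = length(occurrences), motif_width = w,
                 depth_score = flank_mean / max(center_mean, 1)),
            class = "footprint_profile")
}

#' @export
print.footprint_profile <- function(x, ...) {
  cat(sprintf("footprint profile for %s: %d sites, motif %d bp, depth %.2f\n",
              x$tf_name, x$n_sites, x$motif_width, x$depth_score))
  invisible(x)
}

#' Classify a TF footprint as active, inactive or indeterminate
#'
#' Active when the depth score reaches `min_depth` *and* the trough of the
#' 5-bp-smoothed profile falls within the motif span (a centered dip, not
#' a disordered curve).  Profiles built from fewer than `min_sites` sites
#' are indeterminate.
#'
#' @param profile a `footprint_profile`.
#' @param min_depth minimum flank/center depth score (default 1.5).
#' @param min_sites minimum motif occurrences (default 50).
#' @return one of "active", "inactive", "indeterminate".
#' @export
classify_active <- function(profile, min_depth = 1.5, min_sites = 50L) {
  if (profile$n_sites < min_sites) return("indeterminate")
  counts <- profile$counts
  sm <- as.numeric(stats::filter(counts, rep(1 / 5, 5), sides = 2))
  offs <- seq(-profile$window, profile$window)
  ok <- !is.na(sm)
  motif_offs <- motif_center_offsets(profile$motif_width)
  trough <- offs[ok][which.min(sm[ok])]
  centered <- trough %in% motif_offs
  if (profile$depth_score >= min_depth && centered) "active" else "inactive"
}

#' Cross-check TF footprint calls against RNA-seq expression
#'
#' Joins footprint activity calls with mean TPM of the TF's gene.  A TF is
#' expressed when mean TPM exceeds `threshold`; an active & expressed (or
#' inactive & not-expressed) TF is concordant.  TFs missing from the map
#' are flagged unmapped, not dropped.
#'
#' @param tf_calls data.frame with `tf` and `call`
#'   (active/inactive/indeterminate).
#' @param tpm TPM matrix with gene rownames.
#' @param tf_gene_map data.frame with `tf`, `gene_id`.
#' @param threshold expression cutoff on mean TPM (strict; default 2).
#' @return data.frame: `tf`, `call`, `gene_id`, `mean_tpm`, `expressed`,
#'   `mapped`, `concordant` (NA for unmapped or indeterminate TFs).
#' @export
crosscheck_expression <- function(tf_calls, tpm, tf_gene_map,
                                  threshold = 2) {
  means <- rowMeans(tpm)
  idx <- match(tf_calls$tf, tf_gene_map$tf)
  gene <- tf_gene_map$gene_id[idx]
  mapped <- !is.na(gene) & gene %in% names(means)
  mean_tpm <- ifelse(mapped, means[gene], NA_real_)
  expressed <- ifelse(mapped, mean_tpm > threshold, NA)
  concordant <- ifelse(!mapped | tf_calls$call == "indeterminate", NA,
                       (tf_calls$call == "active") == expressed)
  data.frame(tf = tf_calls$tf, call = tf_calls$call,
             gene_id = ifelse(mapped, gene, NA_character_),
             mean_tpm = mean_tpm, expressed = expressed, mapped = mapped,
             concordant = concordant, stringsAsFactors = FALSE)
}

#' Read/write a PWM as plain text
#'
#' Format: optional `>name` header, then four whitespace-delimited rows of
#' probabilities in A, C, G, T order; each position (column) sums to 1.
#'
#' @param pwm a `pwm`.
#' @param path file path.
#' @return `write_pwm`: `path`, invisibly; `read_pwm`: a `pwm`.
#' @export
write_pwm <- function(pwm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", pwm$name), con)
  for (b in seq_len(4)) {
    writeLines(paste(format(pwm$mat[b, ], digits = 10), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_pwm
#' @param pseudocount regularizer attached on read (default 0.01).
#' @export
read_pwm <- function(path, pseudocount = 0.01) {
  lines <- trimws(readLines(path))
  lines <- lines[lines != ""]
  name <- tools::file_path_sans_ext(basename(path))
  if (startsWith(lines[1], ">")) {
    name <- sub("^>\\s*", "", lines[1])
    lines <- lines[-1]
  }
  if (length(lines) != 4) stop("expected 4 PWM rows (A, C, G, T), got ",
                               length(lines))
  mat <- do.call(rbind, lapply(lines, function(l) {
    as.numeric(strsplit(l, "\\s+")[[1]])
  }))
  new_pwm(name, mat, pseudocount)
}

#' Read sequences from a FASTA file
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write sequences to a FASTA file
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
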