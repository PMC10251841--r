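## Independent brute-force oracles and small random-instance generators.
## These deliberately avoid the package's interval machinery: plain data
## frames, nested loops and per-base bitmaps, so they can disagree with the
## implementation if it is wrong.

suppressPackageStartupMessages({
  library(GenomicRanges)
})

## random internally non-overlapping interval set on one chromosome,
## 0-based half-open columns (chrom, start, end)
random_interval_set <- function(n, chrom = "chr1", genome_len = 50000,
                                min_len = 50, max_len = 500) {
  if (n == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  }
  lens <- sample(min_len:max_len, n, replace = TRUE)
  gaps <- sample(1:200, n, replace = TRUE)
  starts <- cumsum(gaps) + cumsum(c(0, lens[-n]))
  offset <- sample(0:max(0, genome_len - (max(starts + lens))), 1)
  data.frame(chrom = chrom, start = starts + offset,
             end = starts + lens + offset)
}

df_to_gr <- function(df) {
  GRanges(df$chrom, IRanges(df$start + 1L, df$end))
}

## all-pairs brute-force consensus oracle on 0-based half-open tables
oracle_consensus <- function(rep_dfs, min_replicates = 2, threshold = 0.5) {
  peaks <- do.call(rbind, lapply(seq_along(rep_dfs), function(i) {
    df <- rep_dfs[[i]]
    if (!nrow(df)) return(NULL)
    cbind(df, rep = i)
  }))
  if (is.null(peaks) || !nrow(peaks)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), support = integer()))
  }
  n <- nrow(peaks)
  retained <- logical(n)
  for (i in seq_len(n)) {
    partner_reps <- integer(0)
    for (j in seq_len(n)) {
      if (peaks$rep[j] == peaks$rep[i]) next
      if (peaks$chrom[j] != peaks$chrom[i]) next
      ov <- min(peaks$end[i], peaks$end[j]) - max(peaks$start[i], peaks$start[j])
      if (ov <= 0) next
      fi <- ov / (peaks$end[i] - peaks$start[i])
      fj <- ov / (peaks$end[j] - peaks$start[j])
      if (fi > threshold && fj > threshold) {
        partner_reps <- union(partner_reps, peaks$rep[j])
      }
    }
    retained[i] <- length(partner_reps) >= (min_replicates - 1)
  }
  kept <- peaks[retained, , drop = FALSE]
  if (!nrow(kept)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), support = integer()))
  }
  ## transitive union of overlapping (>0 bp) retained peaks
  kept <- kept[order(kept$chrom, kept$start, kept$end), , drop = FALSE]
  comp <- list()
  cur <- kept[1, , drop = FALSE]
  cur_end <- cur$end
  for (i in seq_len(nrow(kept))[-1]) {
    if (kept$chrom[i] == cur$chrom[1] && kept$start[i] < cur_end) {
      cur <- rbind(cur, kept[i, ])
      cur_end <- max(cur_end, kept$end[i])
    } else {
      comp[[length(comp) + 1]] <- cur
      cur <- kept[i, , drop = FALSE]
      cur_end <- cur$end
    }
  }
  comp[[length(comp) + 1]] <- cur
  out <- do.call(rbind, lapply(comp, function(cc) {
    data.frame(chrom = cc$chrom[1], start = min(cc$start),
               end = max(cc$end), support = length(unique(cc$rep)))
  }))
  out[order(out$chrom, out$start), , drop = FALSE]
}

## per-base bitmap genome-coverage oracle (single small genome)
oracle_genome_fraction <- function(df, chrom_lengths) {
  covered <- 0
  for (cn in names(chrom_lengths)) {
    bitmap <- logical(chrom_lengths[[cn]])
    sel <- df$chrom == cn
    for (i in which(sel)) {
      bitmap[(df$start[i] + 1):df$end[i]] <- TRUE
    }
    covered <- covered + sum(bitmap)
  }
  covered / sum(chrom_lengths)
}

## per-base priority-annotation oracle: category of a 0-based half-open peak
## from per-base track membership
oracle_annotate <- function(peak, tracks_df) {
  prio <- c("promoter", "5'UTR", "3'UTR", "exon", "intron", "downstream")
  best <- "distal_intergenic"
  best_rank <- length(prio) + 1
  for (base in (peak$start + 1):peak$end) {      # 1-based bases
    for (r in seq_along(prio)) {
      if (r >= best_rank) break
      tr <- tracks_df[[prio[r]]]
      if (is.null(tr) || !nrow(tr)) next
      hit <- any(tr$chrom == peak$chrom & tr$start1 <= base & tr$end1 >= base)
      if (hit) {
        best <- prio[r]; best_rank <- r
        break
      }
    }
    if (best_rank == 1) break
  }
  best
}

tracks_to_df <- function(tracks) {
  lapply(tracks, function(gr) {
    data.frame(chrom = as.character(seqnames(gr)),
               start1 = start(gr), end1 = end(gr))
  })
}

## hypergeometric upper-tail by explicit pmf summation
oracle_hyper_upper <- function(k, N, K, n) {
  x <- k:min(K, n)
  sum(choose(K, x) * choose(N - K, n - x)) / choose(N, n)
}

## definitional BH: adj_i = min_{j: p_j >= p_i} min(1, N * p_j / rank_j)
oracle_bh <- function(p) {
  N <- length(p)
  o <- order(p)
  r <- seq_len(N)
  stepped <- pmin(1, p[o] * N / r)
  adj_sorted <- rev(cummin(rev(stepped)))
  out <- numeric(N)
  out[o] <- adj_sorted
  out
}
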