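## Brute-force oracles, independent of the implementation paths they
## check. All work on plain data.frames in 0-based half-open file
## coordinates (chrom, start, end) so they share no interval arithmetic
## with the package internals.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

## random interval set in file coordinates
random_intervals0 <- function(n, chroms = c("chrA", "chrB"), L = 10000,
                              max_w = 500) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- floor(runif(n, 0, L - max_w))
  width <- floor(runif(n, 1, max_w))
  data.frame(chrom = chrom, start = start, end = start + width)
}

df_to_gr <- function(df) {
  GRanges(df$chrom, IRanges(df$start + 1, df$end))
}

## O(n*m) overlap scan under half-open arithmetic
bf_overlap_pairs <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] == b$chrom[j] &&
        max(a$start[i], b$start[j]) < min(a$end[i], b$end[j]))
      out[[length(out) + 1]] <- c(i, j)
  }
  if (!length(out)) return(data.frame(query = integer(0), subject = integer(0)))
  m <- do.call(rbind, out)
  data.frame(query = m[, 1], subject = m[, 2])
}

## nearest TSS with the package's documented tie rules, by enumeration
bf_nearest <- function(qchrom, qstart0, qend0, fchrom, tss0, ids) {
  n <- length(qchrom)
  out_id <- character(n); out_d <- numeric(n)
  for (k in seq_len(n)) {
    cand_id <- character(0); cand_d <- numeric(0); cand_side <- numeric(0)
    for (j in seq_along(fchrom)) {
      if (fchrom[j] != qchrom[k]) next
      if (tss0[j] >= qstart0[k] && tss0[j] < qend0[k]) {
        d <- 0; side <- 0
      } else if (tss0[j] < qstart0[k]) {
        d <- qstart0[k] - tss0[j]; side <- -1
      } else {
        d <- tss0[j] - qend0[k]; side <- 1
      }
      cand_id <- c(cand_id, ids[j]); cand_d <- c(cand_d, d)
      cand_side <- c(cand_side, side)
    }
    o <- order(cand_d, cand_side, cand_id)[1]
    out_id[k] <- cand_id[o]
    out_d[k] <- cand_d[o] * ifelse(cand_side[o] < 0, -1, 1)
  }
  data.frame(gene_id = out_id, distance = out_d)
}

## Benjamini-Hochberg step-up by direct definition
bf_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

## upper-tail hypergeometric by explicit summation of choose() terms
bf_hyper_tail <- function(x, K, N, n) {
  ks <- x:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

## median-of-ratios by direct definition
bf_size_factors <- function(counts) {
  geo <- apply(counts, 1, function(r) exp(mean(log(r))))
  keep <- is.finite(geo) & geo > 0
  apply(counts, 2, function(col) median((col / geo)[keep]))
}

## per-bin read-overlap counts by scanning every (read, bin) pair
bf_bin_counts <- function(starts0, ends0, n_bins, binsize) {
  out <- integer(n_bins)
  for (b in seq_len(n_bins)) {
    bs <- (b - 1) * binsize; be <- bs + binsize
    out[b] <- sum(starts0 < be & ends0 > bs)
  }
  out
}

## count reads per region by scanning every pair (same chrom assumed)
bf_region_counts <- function(r_start0, r_end0, q_start0, q_end0) {
  vapply(seq_along(r_start0), function(i)
    sum(q_start0 < r_end0[i] & q_end0 > r_start0[i]), 0L)
}

## consensus majority oracle: single-linkage components via an explicit
## adjacency closure, strict-majority filter
bf_consensus <- function(peak_dfs) {
  n <- length(peak_dfs)
  parts <- Map(function(d, r) if (nrow(d)) cbind(d, rep = r) else NULL,
               peak_dfs, seq_len(n))
  all <- do.call(rbind, parts[!vapply(parts, is.null, NA)])
  if (is.null(all) || !nrow(all))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), support = integer(0)))
  m <- nrow(all)
  adj <- matrix(FALSE, m, m)
  for (i in seq_len(m)) for (j in seq_len(m))
    adj[i, j] <- all$chrom[i] == all$chrom[j] &&
      max(all$start[i], all$start[j]) < min(all$end[i], all$end[j])
  comp <- seq_len(m)
  repeat {
    changed <- FALSE
    for (i in seq_len(m)) for (j in seq_len(m))
      if (adj[i, j] && comp[j] > comp[i]) { comp[j] <- comp[i]; changed <- TRUE }
    if (!changed) break
  }
  out <- list()
  thresh <- n %/% 2 + 1
  for (cc in unique(comp)) {
    idx <- which(comp == cc)
    if (length(unique(all$rep[idx])) >= thresh)
      out[[length(out) + 1]] <- data.frame(
        chrom = all$chrom[idx[1]],
        start = min(all$start[idx]), end = max(all$end[idx]),
        support = length(unique(all$rep[idx])))
  }
  if (!length(out)) return(data.frame(chrom = character(0), start = numeric(0),
                                      end = numeric(0), support = integer(0)))
  d <- do.call(rbind, out)
  d[order(d$chrom, d$start), , drop = FALSE]
}

## brute-force best PWM log-odds score of one sequence over both strands
bf_best_pwm_score <- function(seq, lo) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ch <- strsplit(seq, "")[[1]]
  rc <- rev(unname(comp[ch]))
  L <- ncol(lo)
  best <- -Inf
  for (s in list(ch, rc)) {
    if (length(s) < L) next
    for (i in seq_len(length(s) - L + 1)) {
      sc <- 0
      for (j in seq_len(L)) {
        b <- s[i + j - 1]
        sc <- sc + if (b %in% rownames(lo)) lo[b, j] else -Inf
      }
      best <- max(best, sc)
    }
  }
  best
}

## dinucleotide counts of a sequence
dinuc_counts <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  table(paste0(ch[-length(ch)], ch[-1]))
}

## build a coverage_track directly from per-chromosome count vectors
make_track <- function(values, n_reads, binsize = 100) {
  structure(list(values = values, binsize = binsize, n_reads = n_reads,
                 seqlengths = vapply(values, function(v) length(v) * binsize, 0)),
            class = "coverage_track")
}
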