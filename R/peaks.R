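## Stand-in peak calling, replicate QC, blacklist filtering, and the
## majority-rules consensus / master-set construction.

#' Poisson local-background peak caller
#'
#' A documented stand-in for a full model-based caller, adequate for
#' synthetic and well-behaved data: per window the ChIP count is tested
#' against a Poisson background whose rate is the larger of the
#' genome-wide input rate and a local (default 10-kb) input rate, scaled
#' by the ChIP/input depth ratio. Window p-values are Benjamini-Hochberg
#' adjusted genome-wide, adjacent significant windows are merged, and
#' peaks shorter than `min_width` bp are discarded. The summit is the
#' centre of the window with the highest ChIP count (leftmost on ties).
#' Externally called narrowPeak files can be used instead via
#' [read_regions].
#'
#' @param chip,input `coverage_track`s sharing bins. An all-zero input
#'   falls back to the genome-wide ChIP mean as background rate, with a
#'   warning.
#' @param q_threshold BH-adjusted significance cutoff (default 0.05).
#' @param local_window width in bp of the local background window
#'   (default 10000).
#' @param min_width minimum peak width in bp (default 200).
#' @return `GRanges` of peaks with metadata `score` (max window count),
#'   `summit` (absolute 1-based position), `qvalue` (min window q),
#'   `name`, and narrowPeak-compatible `signalValue`/`pValue`/`qValue`/
#'   `peak` columns.
#' @export
call_peaks_poisson <- function(chip, input, q_threshold = 0.05,
                               local_window = 10000, min_width = 200) {
  if (chip$binsize != input$binsize ||
      !identical(names(chip$values), names(input$values)))
    stopf("call_peaks_poisson: chip and input tracks do not share bins")
  binsize <- chip$binsize
  total_input <- sum(vapply(input$values, sum, 0))
  nbins_total <- sum(lengths(input$values))
  if (total_input == 0) {
    warnf("call_peaks_poisson: all-zero input; using genome-wide chip mean as background")
    base_rate <- sum(vapply(chip$values, sum, 0)) / nbins_total
    ratio <- 1
    use_input <- FALSE
  } else {
    base_rate <- total_input / nbins_total
    ratio <- chip$n_reads / input$n_reads
    use_input <- TRUE
  }
  k <- max(1L, round(local_window / binsize))
  pvals <- lapply(names(chip$values), function(chrom) {
    c_ <- chip$values[[chrom]]
    lambda <- if (use_input) {
      pmax(base_rate, running_mean(input$values[[chrom]], k)) * ratio
    } else rep(base_rate, length(c_))
    stats::ppois(c_ - 1, lambda, lower.tail = FALSE)
  })
  names(pvals) <- names(chip$values)
  q <- stats::p.adjust(unlist(pvals, use.names = FALSE), method = "BH")
  offs <- c(0, cumsum(lengths(pvals)))
  out <- list()
  for (i in seq_along(pvals)) {
    chrom <- names(pvals)[i]
    qc <- q[(offs[i] + 1):offs[i + 1]]
    sig <- which(qc < q_threshold)
    if (!length(sig)) next
    ## merge runs of adjacent significant windows
    brk <- c(0, which(diff(sig) > 1), length(sig))
    c_ <- chip$values[[chrom]]
    L <- chip$seqlengths[[chrom]]
    for (r in seq_len(length(brk) - 1)) {
      bins <- sig[(brk[r] + 1):brk[r + 1]]       # 1-based window indices
      s1 <- (bins[1] - 1) * binsize + 1
      e1 <- min(bins[length(bins)] * binsize, L)
      if (e1 - s1 + 1 < min_width) next
      top <- bins[which.max(c_[bins])]           # leftmost max
      summit <- min((top - 1) * binsize + floor(binsize / 2) + 1, L)
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom, start = s1, end = e1, summit = summit,
        score = max(c_[bins]), qvalue = min(qc[bins]))
    }
  }
  if (!length(out)) {
    gr <- GenomicRanges::GRanges()
    gr$score <- numeric(0); gr$summit <- numeric(0); gr$qvalue <- numeric(0)
    return(gr)
  }
  df <- do.call(rbind, out)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
  gr$name <- paste0("peak_", seq_along(gr))
  gr$score <- df$score
  gr$signalValue <- df$score
  gr$pValue <- -1
  gr$qValue <- -log10(pmax(df$qvalue, 1e-300))
  gr$peak <- df$summit - df$start               # 0-based offset, narrowPeak col 10
  gr$summit <- df$summit
  gr$qvalue <- df$qvalue
  sort(gr)
}

#' Peak-count quality control over technical replicates
#'
#' Technical replicates with fewer than `min_peaks` called peaks are
#' discarded. An error is raised if an entire experimental group
#' (cell_type, condition, mark) loses every technical replicate, naming
#' the group.
#'
#' @param peaksets named list of peak `GRanges`, names = sample ids.
#' @param meta `data.frame` with one row per entry of `peaksets`
#'   (columns `sample_id`, `cell_type`, `condition`, `mark`,
#'   `replicate`); rows are matched to `peaksets` by `sample_id`.
#' @param min_peaks threshold (default 10000, the scale used for a full
#'   human genome; scale it down for small synthetic genomes).
#' @return List with `kept` and `dropped` sample-id vectors and a
#'   `report` data.frame (sample_id, n_peaks, kept).
#' @export
qc_filter <- function(peaksets, meta, min_peaks = 10000) {
  meta <- meta[match(names(peaksets), meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) stopf("qc_filter: meta lacks some sample ids")
  n <- vapply(peaksets, length, 0L)
  keep <- n >= min_peaks
  grp <- paste(meta$cell_type, meta$condition, meta$mark, sep = "/")
  for (g in unique(grp)) {
    if (!any(keep[grp == g]))
      stopf("qc_filter: all technical replicates of group %s dropped (< %d peaks)",
            g, min_peaks)
  }
  list(kept = names(peaksets)[keep],
       dropped = names(peaksets)[!keep],
       report = data.frame(sample_id = names(peaksets), n_peaks = unname(n),
                           kept = unname(keep)))
}

#' Remove peaks overlapping blacklisted regions
#'
#' Any peak overlapping a blacklist region by >= 1 bp is removed whole.
#'
#' @param peaks,blacklist `GRanges`.
#' @return Filtered `GRanges`.
#' @export
remove_blacklist <- function(peaks, blacklist) {
  if (!length(blacklist) || !length(peaks)) return(peaks)
  hits <- GenomicRanges::countOverlaps(peaks, blacklist, minoverlap = 1L,
                                       ignore.strand = TRUE)
  peaks[hits == 0]
}

#' Majority-rules consensus peak set
#'
#' Overlap-connected components (single linkage, >= 1 bp) are formed
#' across the union of all replicates' peaks. A component is valid iff
#' peaks from at least `floor(n/2) + 1` distinct replicates contribute
#' (strict majority; for n = 2 both). The consensus region is the union
#' span of the component; its summit is inherited from the contributing
#' peak with the highest score (first on ties).
#'
#' @param peaksets list of peak `GRanges`, one per biological replicate.
#' @param min_support overrides the strict-majority threshold if given.
#' @return `GRanges` with metadata `support` (distinct replicates),
#'   `summit`, `score`.
#' @export
consensus_majority <- function(peaksets, min_support = NULL) {
  n <- length(peaksets)
  stopifnot(n >= 1)
  if (is.null(min_support)) min_support <- n %/% 2 + 1L
  all_peaks <- suppressWarnings(do.call(c, unname(lapply(peaksets, function(p) {
    GenomicRanges::granges(p)
  }))))
  if (!length(all_peaks)) {
    gr <- GenomicRanges::GRanges()
    gr$support <- integer(0); gr$summit <- numeric(0); gr$score <- numeric(0)
    return(gr)
  }
  rep_idx <- rep(seq_len(n), vapply(peaksets, length, 0L))
  summit <- unlist(lapply(peaksets, function(p)
    if (!is.null(p$summit)) as.numeric(p$summit)
    else start(p) + width(p) %/% 2))
  score <- unlist(lapply(peaksets, function(p)
    if (!is.null(p$score)) as.numeric(p$score) else rep(0, length(p))))
  comp <- merge_intervals(all_peaks)             # single-linkage components
  h <- GenomicRanges::findOverlaps(all_peaks, comp, minoverlap = 1L,
                                   ignore.strand = TRUE)
  ci <- S4Vectors::subjectHits(h)[order(S4Vectors::queryHits(h))]
  support <- vapply(split(rep_idx, ci), function(x) length(unique(x)), 0L)
  keep_comp <- as.integer(names(support))[support >= min_support]
  if (!length(keep_comp)) {
    gr <- GenomicRanges::GRanges()
    gr$support <- integer(0); gr$summit <- numeric(0); gr$score <- numeric(0)
    return(gr)
  }
  best <- vapply(keep_comp, function(k) {
    members <- which(ci == k)
    members[which.max(score[members])]
  }, 0L)
  out <- comp[keep_comp]
  out$support <- unname(support[as.character(keep_comp)])
  out$summit <- summit[best]
  out$score <- score[best]
  sort(out)
}

#' Master peak set across experimental groups
#'
#' Overlap-merge (>= 1 bp single linkage) of all groups' consensus
#' regions; sorted and non-overlapping.
#'
#' @param consensus_sets list of consensus `GRanges`.
#' @return `GRanges` with `n_sources` = number of contributing groups.
#' @export
master_set <- function(consensus_sets) {
  stopifnot(length(consensus_sets) >= 1)
  all_regions <- suppressWarnings(
    do.call(c, unname(lapply(consensus_sets, GenomicRanges::granges))))
  m <- merge_intervals(all_regions)
  src <- rep(seq_along(consensus_sets), vapply(consensus_sets, length, 0L))
  h <- GenomicRanges::findOverlaps(all_regions, m, minoverlap = 1L,
                                   ignore.strand = TRUE)
  ns <- vapply(split(src[S4Vectors::queryHits(h)], S4Vectors::subjectHits(h)),
               function(x) length(unique(x)), 0L)
  m$n_sources <- 0L
  m$n_sources[as.integer(names(ns))] <- unname(ns)
  m$name <- paste0("master_", seq_along(m))
  m
}
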