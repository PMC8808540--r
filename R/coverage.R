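## Binned coverage, the input-subtracted depth-normalized signal, FrIP,
## promoter signal matrices and their Pearson correlation structure.

#' Extend reads symmetrically
#'
#' Each read is widened by `flank` bp on either side (a 50-bp read with the
#' default flank becomes 250 bp), approximating fragment occupancy; the
#' result is clipped to chromosome bounds. Order is preserved.
#'
#' @param reads `GRanges`.
#' @param genome [chip_genome].
#' @param flank bp added on each side (default 100).
#' @return `GRanges`.
#' @export
extend_reads <- function(reads, genome, flank = 100) {
  if (!length(reads)) return(reads)
  check_chroms(as.character(GenomeInfoDb::seqnames(reads)), genome, "read")
  gr <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(reads),
                               IRanges::IRanges(start(reads) - flank,
                                                end(reads) + flank))
  clip_to_genome(gr, genome)
}

#' Binned read coverage over the whole genome
#'
#' The count in each fixed-size window is the number of reads overlapping
#' it by >= 1 bp (reads are expected to be extended already). The track
#' also records the total mapped read count `n_reads`.
#'
#' @param reads `GRanges` of (extended) reads.
#' @param genome [chip_genome].
#' @param binsize window size in bp (default 100).
#' @return A `coverage_track`: list with `values` (per-chromosome integer
#'   vectors of length `ceiling(length / binsize)`), `binsize`,
#'   `n_reads`, `seqlengths`.
#' @export
make_coverage <- function(reads, genome, binsize = 100) {
  chroms <- names(genome$seqlengths)
  nbin <- ceiling(genome$seqlengths / binsize)
  rchrom <- as.character(GenomeInfoDb::seqnames(reads))
  check_chroms(rchrom, genome, "read")
  values <- vector("list", length(chroms))
  names(values) <- chroms
  for (chrom in chroms) {
    idx <- which(rchrom == chrom)
    nb <- nbin[[chrom]]
    if (!length(idx)) {
      values[[chrom]] <- integer(nb)
      next
    }
    ## a read [s,e] (1-based closed) overlaps bins floor((s-1)/B)..floor((e-1)/B)
    b0 <- (start(reads)[idx] - 1L) %/% binsize
    b1 <- (end(reads)[idx] - 1L) %/% binsize
    b1 <- pmin(b1, nb - 1L)
    lens <- b1 - b0 + 1L
    hits <- rep(b0, lens) + sequence(lens) # 1-based bin index
    values[[chrom]] <- tabulate(hits, nbins = nb)
  }
  structure(list(values = values, binsize = binsize,
                 n_reads = length(reads), seqlengths = genome$seqlengths),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> bin %d bp, %d reads, %d chromosome(s)\n",
              x$binsize, x$n_reads, length(x$values)))
  invisible(x)
}

#' Input-subtracted depth-normalized signal
#'
#' Per window: `(chip / n_chip_reads - input / n_input_reads) * 1e6`, i.e.
#' both tracks are scaled to reads-per-million before subtraction. Values
#' may be negative where input exceeds ChIP.
#'
#' @param chip,input `coverage_track`s on the same genome and bin size.
#' @return A `signal_track` (same shape, numeric values).
#' @export
normalized_signal <- function(chip, input) {
  if (chip$binsize != input$binsize)
    stopf("normalized_signal: bin sizes differ (%d vs %d)",
          chip$binsize, input$binsize)
  if (!identical(names(chip$values), names(input$values)))
    stopf("normalized_signal: tracks cover different chromosomes")
  if (chip$n_reads == 0 || input$n_reads == 0)
    stopf("normalized_signal: zero mapped reads in %s track",
          if (chip$n_reads == 0) "chip" else "input")
  values <- mapply(function(c, i) (c / chip$n_reads - i / input$n_reads) * 1e6,
                   chip$values, input$values, SIMPLIFY = FALSE)
  structure(list(values = values, binsize = chip$binsize,
                 seqlengths = chip$seqlengths),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("<signal_track> bin %d bp, %d chromosome(s)\n",
              x$binsize, length(x$values)))
  invisible(x)
}

## mean of several signal tracks (used for per-group tracks)
mean_signal <- function(tracks) {
  stopifnot(length(tracks) >= 1)
  out <- tracks[[1]]
  for (chrom in names(out$values)) {
    m <- rowMeans(do.call(cbind, lapply(tracks, function(t) t$values[[chrom]])))
    out$values[[chrom]] <- m
  }
  out
}

#' Fraction of reads in peaks (FrIP)
#'
#' @param reads `GRanges` of mapped reads.
#' @param peaks `GRanges` of called peaks; a read is in peaks if it
#'   overlaps any peak by >= 1 bp.
#' @return Fraction in \[0, 1\].
#' @export
frip <- function(reads, peaks) {
  if (!length(reads)) stopf("frip: zero reads")
  if (!length(peaks)) return(0)
  mean(GenomicRanges::countOverlaps(reads, peaks, minoverlap = 1L,
                                    ignore.strand = TRUE) > 0)
}

#' Signal summed over promoter windows, per sample
#'
#' Entry (gene, sample) is the sum of the sample's signal over all bins
#' overlapping the TSS +/- `flank` window (window truncated at chromosome
#' edges).
#'
#' @param signals named list of `signal_track`s (or `coverage_track`s),
#'   one per sample, sharing bin size.
#' @param genes `GRanges` from [read_tss].
#' @param flank half-window in bp (default 2000).
#' @return Numeric matrix, genes x samples.
#' @export
promoter_matrix <- function(signals, genes, flank = 2000) {
  binsize <- unique(vapply(signals, function(s) s$binsize, 0))
  if (length(binsize) != 1) stopf("promoter_matrix: samples differ in bin size")
  tss0 <- genes$tss - 1          # 0-based TSS coordinate
  chrom <- as.character(GenomeInfoDb::seqnames(genes))
  mat <- matrix(0, nrow = length(genes), ncol = length(signals),
                dimnames = list(genes$gene_id, names(signals)))
  ## per sample, cumulative sums per chromosome make window sums O(1)
  for (j in seq_along(signals)) {
    cs <- lapply(signals[[j]]$values, function(v) cumsum(c(0, v)))
    for (chr in unique(chrom)) {
      gi <- which(chrom == chr)
      v <- cs[[chr]]
      if (is.null(v)) stopf("promoter_matrix: track lacks chromosome %s", chr)
      nb <- length(v) - 1
      ## window [tss0 - flank, tss0 + flank) overlaps bins
      ## floor((tss0-flank)/B) .. floor((tss0+flank-1)/B), clipped
      b0 <- pmax((tss0[gi] - flank) %/% binsize, 0)
      b1 <- pmin((tss0[gi] + flank - 1) %/% binsize, nb - 1)
      mat[gi, j] <- v[b1 + 2] - v[b0 + 1]
    }
  }
  mat
}

#' Sample-sample Pearson correlation of a promoter signal matrix
#'
#' @param mat genes x samples matrix from [promoter_matrix].
#' @return Symmetric correlation matrix with unit diagonal and a
#'   `"band"` attribute holding the verbal quality band per pair
#'   (see [correlation_band]).
#' @export
pearson_matrix <- function(mat) {
  if (ncol(mat) < 2) stopf("pearson_matrix: need >= 2 samples")
  v <- apply(mat, 2, stats::var)
  if (any(v == 0))
    stopf("pearson_matrix: zero variance in sample %s",
          colnames(mat)[which(v == 0)[1]])
  r <- stats::cor(mat, method = "pearson")
  attr(r, "band") <- matrix(correlation_band(r), nrow(r),
                            dimnames = dimnames(r))
  r
}

#' Verbal quality band for a correlation coefficient
#'
#' Bands follow common ChIP-seq reporting practice: high (r > 0.95),
#' good (> 0.9), fair (> 0.75), low (<= 0.75), poor (< 0.6).
#'
#' @param r numeric vector of correlations.
#' @return Character vector of band labels.
#' @export
correlation_band <- function(r) {
  ifelse(r > 0.95, "high",
         ifelse(r > 0.9, "good",
                ifelse(r > 0.75, "fair",
                       ifelse(r >= 0.6, "low", "poor"))))
}
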