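## Region x sample counting, size factors, the negative-binomial Wald
## test for differential histone modification, threshold selection, and
## the all-peak signal comparison.

#' Count reads per master region and sample
#'
#' A read counts for a region when it overlaps it by >= 1 bp. Master
#' regions are non-overlapping, so double counting is limited to reads
#' straddling two regions.
#'
#' @param regions `GRanges` of master regions.
#' @param reads_list named list of (extended) read `GRanges`, one per
#'   sample.
#' @return Integer matrix regions x samples.
#' @export
count_reads <- function(regions, reads_list) {
  counts <- vapply(reads_list, function(r)
    GenomicRanges::countOverlaps(regions, r, minoverlap = 1L,
                                 ignore.strand = TRUE),
    integer(length(regions)))
  if (length(regions) == 1) counts <- matrix(counts, nrow = 1,
                                             dimnames = list(NULL, names(reads_list)))
  rownames(counts) <- if (!is.null(regions$name)) regions$name
                      else paste0("region_", seq_along(regions))
  counts
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over all-positive regions of the ratio of
#' its count to the row geometric mean; the conventional normalization
#' for sequencing-depth differences in count matrices. With no
#' all-positive region the total-count ratio is used, with a warning.
#'
#' @param counts regions x samples count matrix.
#' @return Positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    warnf("size_factors: no region with all-positive counts; using total-count ratio")
    tot <- colSums(counts)
    return(tot / exp(mean(log(tot))))
  }
  lg <- log(counts[pos, , drop = FALSE])
  geo <- rowMeans(lg)
  apply(exp(sweep(lg, 1, geo)), 2, stats::median)
}

#' Negative-binomial Wald test for differential modification
#'
#' Re-implements the standard count-based differential contract: counts
#' are depth-normalized by median-of-ratios size factors; per-region
#' dispersion is estimated by method of moments (floored at 1e-8) and
#' shrunk 50/50 toward a log-linear mean-dispersion trend (the trend is
#' fit on moment estimates pooled within mean-quantile bins, which is
#' nearly noise-free); the log2 fold change is computed from group means
#' of normalized counts with a pseudo-count of 0.5; the Wald statistic
#' divides it by a delta-method standard error from the NB variance
#' function mu + alpha mu^2. Two-sided p-values use a Student-t
#' reference with 4 x (n1 + n2 - 2) degrees of freedom: the 50/50 blend
#' quarters the variance of the dispersion estimate entering the SE, so
#' the residual estimation noise is that of a variance with four times
#' the within-group degrees of freedom; this small-sample reference is
#' what keeps the test calibrated at n = 3 per group. P-values are BH
#' adjusted across regions. `condition` must contain exactly the
#' reference and numerator levels (numerator = second level;
#' conventionally MUT vs NC).
#'
#' @param counts regions x samples integer matrix.
#' @param condition factor/character per sample; the fold change is
#'   level 2 vs level 1 of `levels` (default `c("NC", "MUT")`).
#' @param levels length-2 character, reference first.
#' @param sf optional precomputed size factors.
#' @return `data.frame`: `region`, `baseMean`, `log2FC`, `lfcSE`,
#'   `stat`, `pvalue`, `padj`, `direction` (`up_in_<numerator>` /
#'   `down_in_<numerator>`).
#' @export
nb_wald_test <- function(counts, condition, levels = c("NC", "MUT"), sf = NULL) {
  condition <- as.character(condition)
  if (!all(condition %in% levels))
    stopf("nb_wald_test: condition labels outside %s", paste(levels, collapse = "/"))
  g1 <- which(condition == levels[1])
  g2 <- which(condition == levels[2])
  if (length(g1) < 2 || length(g2) < 2)
    stopf("nb_wald_test: need >= 2 samples per condition (got %d vs %d)",
          length(g1), length(g2))
  if (is.null(sf)) sf <- size_factors(counts)
  q <- sweep(counts, 2, sf, "/")
  m1 <- rowMeans(q[, g1, drop = FALSE])
  m2 <- rowMeans(q[, g2, drop = FALSE])
  baseMean <- rowMeans(q)
  v1 <- apply(q[, g1, drop = FALSE], 1, stats::var)
  v2 <- apply(q[, g2, drop = FALSE], 1, stats::var)
  n1 <- length(g1); n2 <- length(g2)
  vpool <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  ## E[var of q within group] ~= mu * mean(1/s) + alpha * mu^2, with the
  ## group mean as mu; average the two groups' moment equations
  inv1 <- mean(1 / sf[g1]); inv2 <- mean(1 / sf[g2])
  mu_pois <- ((n1 - 1) * m1 * inv1 + (n2 - 1) * m2 * inv2) / (n1 + n2 - 2)
  mu_sq <- ((n1 - 1) * m1^2 + (n2 - 1) * m2^2) / (n1 + n2 - 2)
  alpha_mom <- pmax((vpool - mu_pois) / pmax(mu_sq, 1e-12), 1e-8)
  ## log-linear mean-dispersion trend fit on mean-quantile-binned moment
  ## estimates (binned moments are nearly noise-free), then a 50/50
  ## linear blend per region
  nz <- baseMean > 0
  alpha_fit <- rep(1e-8, length(alpha_mom))
  if (sum(nz) >= 20) {
    br <- unique(stats::quantile(baseMean[nz],
                                 probs = seq(0, 1, length.out = 21)))
    br[1] <- br[1] - 1
    bin <- cut(baseMean[nz], br)
    atr <- tapply(which(nz), bin, function(i)
      max((mean(vpool[i]) - mean(mu_pois[i])) / mean(mu_sq[i]), 1e-8))
    mtr <- tapply(baseMean[nz], bin, mean)
    keep <- !is.na(atr) & !is.na(mtr)
    if (sum(keep) >= 3) {
      fit <- stats::lm(log(atr[keep]) ~ log(mtr[keep]))
      pred <- cbind(1, log(pmax(baseMean, 1e-8))) %*% stats::coef(fit)
      alpha_fit <- pmin(pmax(exp(as.numeric(pred)), 1e-8), 100)
    } else {
      alpha_fit <- rep(max(mean(atr[keep]), 1e-8), length(alpha_mom))
    }
  }
  alpha <- 0.5 * alpha_mom + 0.5 * alpha_fit
  log2fc <- log2((m2 + 0.5) / (m1 + 0.5))
  ## delta-method variance of log2 of a group mean of normalized counts
  var_qbar <- function(m, idx) {
    sapply(seq_along(m), function(i)
      sum(m[i] / sf[idx] + alpha[i] * m[i]^2) / length(idx)^2)
  }
  vlog <- function(m, vq) vq / ((m + 0.5)^2 * log(2)^2)
  se <- sqrt(vlog(m1, var_qbar(m1, g1)) + vlog(m2, var_qbar(m2, g2)))
  df <- 4 * (n1 + n2 - 2)
  stat <- ifelse(se > 0, log2fc / se, 0)
  pvalue <- ifelse(se > 0, 2 * stats::pt(-abs(stat), df), 1)
  pvalue[m1 == 0 & m2 == 0] <- 1
  padj <- stats::p.adjust(pvalue, method = "BH")
  data.frame(region = rownames(counts) %||% paste0("region_", seq_len(nrow(counts))),
             baseMean = baseMean, log2FC = log2fc, lfcSE = se, stat = stat,
             pvalue = pvalue, padj = padj,
             direction = ifelse(log2fc >= 0, paste0("up_in_", levels[2]),
                                paste0("down_in_", levels[2])),
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select significant differential regions
#'
#' A region is selected iff |log2FC| >= log2(fc) and FDR < fdr;
#' partitioned by sign of the fold change.
#'
#' @param result `data.frame` from [nb_wald_test].
#' @param fc fold-change threshold on the linear scale (default 2).
#' @param fdr BH FDR threshold (default 0.05).
#' @return List with `up` and `down` subsets of `result` and the
#'   combined `selected` subset.
#' @export
select_significant <- function(result, fc = 2, fdr = 0.05) {
  ## fdr >= 1 disables the FDR filter (padj is capped at exactly 1)
  sel <- !is.na(result$padj) & (fdr >= 1 | result$padj < fdr) &
    abs(result$log2FC) >= log2(fc)
  list(up = result[sel & result$log2FC > 0, , drop = FALSE],
       down = result[sel & result$log2FC < 0, , drop = FALSE],
       selected = result[sel, , drop = FALSE])
}

#' Compare normalized signal at all peak regions between two groups
#'
#' Per group the mean normalized signal per region (across that group's
#' samples) is computed; reported are the two medians, the percent change
#' of the numerator group's median relative to the reference, and a
#' two-sided paired t-test across regions. Identical groups (zero paired
#' differences) are reported with p = 1.
#'
#' @param signal_mat regions x samples matrix of per-region normalized
#'   signal (e.g. from [region_signal]).
#' @param condition per-sample labels.
#' @param levels length-2 character, reference first.
#' @return List: `median_ref`, `median_num`, `percent_change`,
#'   `p_value`, `n_regions`.
#' @export
allpeak_signal_comparison <- function(signal_mat, condition,
                                      levels = c("NC", "MUT")) {
  if (nrow(signal_mat) < 2) stopf("allpeak_signal_comparison: need >= 2 regions")
  condition <- as.character(condition)
  x1 <- rowMeans(signal_mat[, condition == levels[1], drop = FALSE])
  x2 <- rowMeans(signal_mat[, condition == levels[2], drop = FALSE])
  med1 <- stats::median(x1); med2 <- stats::median(x2)
  d <- x2 - x1
  ## constant paired differences make the t undefined; report 1
  p <- if (stats::sd(d) <= 1e-12 * max(abs(d), 1)) 1
       else stats::t.test(x2, x1, paired = TRUE)$p.value
  list(median_ref = med1, median_num = med2,
       percent_change = if (med1 != 0) (med2 - med1) / med1 * 100 else NA_real_,
       p_value = p, n_regions = nrow(signal_mat))
}

#' Mean signal per region and sample
#'
#' Entry (region, sample) is the mean of the sample's signal over the
#' bins overlapping the region.
#'
#' @param signals named list of `signal_track`s.
#' @param regions `GRanges`.
#' @return Numeric matrix regions x samples.
#' @export
region_signal <- function(signals, regions) {
  binsize <- unique(vapply(signals, function(s) s$binsize, 0))
  stopifnot(length(binsize) == 1)
  chrom <- as.character(GenomeInfoDb::seqnames(regions))
  mat <- matrix(0, nrow = length(regions), ncol = length(signals),
                dimnames = list(regions$name, names(signals)))
  for (j in seq_along(signals)) {
    cs <- lapply(signals[[j]]$values, function(v) cumsum(c(0, v)))
    for (chr in unique(chrom)) {
      gi <- which(chrom == chr)
      v <- cs[[chr]]
      nb <- length(v) - 1
      b0 <- pmax((start(regions)[gi] - 1) %/% binsize, 0)
      b1 <- pmin((end(regions)[gi] - 1) %/% binsize, nb - 1)
      mat[gi, j] <- (v[b1 + 2] - v[b0 + 1]) / (b1 - b0 + 1)
    }
  }
  mat
}
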