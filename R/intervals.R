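## Interval engine: overlap pairing and nearest-feature annotation.
## Overlap semantics are >= 1 bp everywhere (half-open abutment does not
## count); GenomicRanges' closed-interval findOverlaps with minoverlap = 1
## implements exactly that once file coordinates have been converted.

#' Report all overlapping pairs between two interval sets
#'
#' A pair is reported iff the two intervals share at least 1 bp. Strand is
#' ignored (histone marks are unstranded).
#'
#' @param a,b `GRanges`.
#' @return A `data.frame` with indices `query` (into `a`) and
#'   `subject` (into `b`).
#' @export
interval_overlap <- function(a, b) {
  h <- GenomicRanges::findOverlaps(a, b, minoverlap = 1L, ignore.strand = TRUE)
  data.frame(query = S4Vectors::queryHits(h), subject = S4Vectors::subjectHits(h))
}

#' Nearest TSS for each query region
#'
#' Distance is 0 when a TSS lies within the query; otherwise the distance
#' from the nearest query edge to the TSS, signed negative when the TSS is
#' upstream (left) of the region. Ties are broken by smaller |distance|,
#' then upstream side, then lexicographically smaller gene id.
#'
#' @param query `GRanges` of regions.
#' @param genes `GRanges` from [read_tss] (metadata `gene_id`, `tss`), or
#'   any `GRanges` with those columns.
#' @return `data.frame` with `gene_id` and signed `distance` per query.
#' @export
nearest_feature <- function(query, genes) {
  if (!length(genes)) stopf("nearest_feature: empty feature list")
  qchrom <- as.character(GenomeInfoDb::seqnames(query))
  fchrom <- as.character(GenomeInfoDb::seqnames(genes))
  gene_id <- as.character(genes$gene_id)
  tss <- as.numeric(genes$tss)
  out_id <- character(length(query))
  out_d <- numeric(length(query))
  for (chrom in unique(qchrom)) {
    qi <- which(qchrom == chrom)
    fi <- which(fchrom == chrom)
    if (!length(fi)) {
      ## fall back to all features on other chromosomes being "infinitely"
      ## far would leave NA; the pipeline never queries a chromosome with
      ## no annotated gene, so treat it as an error
      stopf("nearest_feature: no features on chromosome %s", chrom)
    }
    pos <- tss[fi]
    ids <- gene_id[fi]
    o <- order(pos, ids)
    pos <- pos[o]; ids <- ids[o]
    ## at duplicated positions keep the lexicographically smallest id
    ## (order above puts it first)
    keep <- !duplicated(pos)
    upos <- pos[keep]; uids <- ids[keep]
    qs <- start(query)[qi]; qe <- end(query)[qi]
    for (k in seq_along(qi)) {
      s <- qs[k]; e <- qe[k]
      ## contained TSS -> distance 0; lexicographic tie-break among them
      lo <- findInterval(s - 1, upos) + 1L
      hi <- findInterval(e, upos)
      if (lo <= hi) {
        out_id[qi[k]] <- min(uids[lo:hi])
        out_d[qi[k]] <- 0
        next
      }
      ## gaps in file (0-based half-open) coordinates: upstream gap is
      ## start0 - tss0 = s - upos; downstream gap is tss0 - end0 =
      ## upos - e - 1 (both region edges are the coordinates start0/end0)
      dl <- if (lo > 1) s - upos[lo - 1] else Inf
      dr <- if (hi < length(upos)) upos[hi + 1] - e - 1 else Inf
      if (dl < dr || (dl == dr && is.finite(dl))) {    # tie -> upstream
        out_id[qi[k]] <- uids[lo - 1]
        out_d[qi[k]] <- -dl
      } else {
        out_id[qi[k]] <- uids[hi + 1]
        out_d[qi[k]] <- dr
      }
    }
  }
  data.frame(gene_id = out_id, distance = out_d)
}

#' Merge overlapping intervals
#'
#' Single-linkage union of intervals sharing >= 1 bp; abutting intervals
#' stay separate (half-open semantics).
#'
#' @param gr `GRanges`.
#' @return Sorted non-overlapping `GRanges`.
#' @export
merge_intervals <- function(gr) {
  GenomicRanges::reduce(gr, min.gapwidth = 0L, ignore.strand = TRUE)
}
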