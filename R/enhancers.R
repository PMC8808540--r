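## Enhancer calling (summit-anchored 1-kb regions with promoter
## exclusion) and the enhancer-level analyses: condition Venn/coverage,
## genomic-location annotation, SNP proximity, and cell-type-specific
## gene change fractions.

## promoter windows TSS +/- flank, i.e. 0-based [tss0-flank, tss0+flank)
promoter_windows <- function(genes, flank = 500) {
  t1 <- genes$tss                      # 1-based TSS
  GenomicRanges::GRanges(GenomeInfoDb::seqnames(genes),
                         IRanges::IRanges(t1 - flank, t1 + flank - 1),
                         gene_id = genes$gene_id)
}

## summit +/- half_width, 0-based [summit0-hw, summit0+hw)
summit_windows <- function(peaks, genome, half_width = 500) {
  summit <- peaks$summit
  if (is.null(summit)) {
    warnf("summit_windows: missing summits; using interval midpoints")
    ## same midpoint convention as the narrowPeak -1 summit:
    ## summit0 = start0 + floor(width/2)
    summit <- start(peaks) + width(peaks) %/% 2
  }
  gr <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(peaks),
                               IRanges::IRanges(summit - half_width,
                                                summit + half_width - 1))
  S4Vectors::mcols(gr) <- S4Vectors::mcols(peaks)
  gr$summit <- summit
  clip_to_genome(gr, genome)
}

#' Call enhancers from per-condition consensus peaks
#'
#' Each consensus peak becomes a 1-kb region anchored at its summit
#' (summit +/- `half_width`); regions overlapping any promoter window
#' (TSS +/- `promoter_flank`) by >= 1 bp are removed. Cross-condition
#' identity uses >= 1 bp overlap of the 1-kb regions: the two condition
#' sets are merged into overlap-connected union components, each labelled
#' with the conditions it is present in.
#'
#' @param consensus named list of H3K27ac consensus `GRanges` (with
#'   `summit`), one per condition, e.g. `list(NC = ..., MUT = ...)`.
#' @param genes `GRanges` from [read_tss].
#' @param genome [chip_genome].
#' @param cell_type label stored on the output.
#' @param half_width enhancer half-width in bp (default 500).
#' @param promoter_flank promoter half-width in bp (default 500).
#' @return An `enhancer_set`: list with `cell_type`, `by_condition`
#'   (list of `GRanges`), `union` (`GRanges` with `present_in` as a
#'   comma-collapsed label), and `venn` (named counts: `<cond1>_only`,
#'   `shared`, `<cond2>_only`, using union components).
#' @export
call_enhancers <- function(consensus, genes, genome, cell_type = NA_character_,
                           half_width = 500, promoter_flank = 500) {
  stopifnot(length(consensus) >= 1, !is.null(names(consensus)))
  prom <- promoter_windows(genes, promoter_flank)
  by_condition <- lapply(consensus, function(peaks) {
    enh <- summit_windows(peaks, genome, half_width)
    drop <- GenomicRanges::countOverlaps(enh, prom, minoverlap = 1L,
                                         ignore.strand = TRUE) > 0
    enh <- enh[!drop]
    ## hard postcondition: no emitted enhancer touches a promoter window
    stopifnot(!any(GenomicRanges::countOverlaps(enh, prom, minoverlap = 1L,
                                                ignore.strand = TRUE) > 0))
    enh
  })
  conds <- names(consensus)
  all_enh <- suppressWarnings(
    do.call(c, unname(lapply(by_condition, GenomicRanges::granges))))
  src <- rep(conds, vapply(by_condition, length, 0L))
  comp <- merge_intervals(all_enh)
  h <- GenomicRanges::findOverlaps(all_enh, comp, minoverlap = 1L,
                                   ignore.strand = TRUE)
  lab <- vapply(split(src[S4Vectors::queryHits(h)], S4Vectors::subjectHits(h)),
                function(x) paste(sort(unique(x)), collapse = ","), "")
  comp$present_in <- ""
  comp$present_in[as.integer(names(lab))] <- unname(lab)
  venn <- c(sum(comp$present_in == conds[1]),
            sum(grepl(",", comp$present_in)),
            if (length(conds) > 1) sum(comp$present_in == conds[2]) else 0L)
  names(venn) <- c(paste0(conds[1], "_only"), "shared",
                   paste0(if (length(conds) > 1) conds[2] else "none", "_only"))
  structure(list(cell_type = cell_type, by_condition = by_condition,
                 union = comp, venn = venn),
            class = "enhancer_set")
}

#' @export
print.enhancer_set <- function(x, ...) {
  cat(sprintf("<enhancer_set> %s: %s\n", x$cell_type,
              paste(sprintf("%s=%d", names(x$venn), x$venn), collapse = ", ")))
  invisible(x)
}

#' Fraction of reference enhancers covered by the other condition
#'
#' Identity is >= 1 bp overlap. Also reports the fraction of the other
#' condition's enhancers that are unique (not overlapping any reference
#' enhancer).
#'
#' @param ref,other enhancer `GRanges` (e.g. the NC and MUT components of
#'   an [call_enhancers] result).
#' @return List: `covered_fraction` (|ref overlapped| / |ref|),
#'   `other_unique_fraction`.
#' @export
coverage_fraction <- function(ref, other) {
  if (!length(ref)) stopf("coverage_fraction: empty reference enhancer set")
  cov <- mean(GenomicRanges::countOverlaps(ref, other, minoverlap = 1L,
                                           ignore.strand = TRUE) > 0)
  uniq <- if (length(other))
    mean(GenomicRanges::countOverlaps(other, ref, minoverlap = 1L,
                                      ignore.strand = TRUE) == 0) else NA_real_
  list(covered_fraction = cov, other_unique_fraction = uniq)
}

#' Genomic-location annotation of enhancers
#'
#' Priority classification: `promoter_vicinity` (< `vicinity` bp from the
#' nearest promoter-window edge, measured between the facing edges in
#' file coordinates) > `genic` (overlaps a gene span) >
#' `distal_intergenic`.
#'
#' @param enhancers `GRanges`.
#' @param genes `GRanges` from [read_tss] (gene spans + `tss`).
#' @param promoter_flank promoter half-width (default 500).
#' @param vicinity distance threshold in bp (default 2000).
#' @return List: `category` (character per enhancer), `distribution`
#'   (named fractions summing to 1).
#' @export
annotate_locations <- function(enhancers, genes, promoter_flank = 500,
                               vicinity = 2000) {
  cats <- c("promoter_vicinity", "genic", "distal_intergenic")
  if (!length(enhancers))
    return(list(category = character(0),
                distribution = setNames(rep(NA_real_, 3), cats)))
  prom <- promoter_windows(genes, promoter_flank)
  ## edge distance in file (0-based half-open) coordinates equals the
  ## closed-range gap GenomicRanges::distance() reports: for enhancer end0
  ## = e and promoter start0 = p the gap is p - e bases
  d <- GenomicRanges::distanceToNearest(enhancers, prom, ignore.strand = TRUE)
  edge_dist <- rep(Inf, length(enhancers))
  edge_dist[S4Vectors::queryHits(d)] <- S4Vectors::mcols(d)$distance
  genic <- GenomicRanges::countOverlaps(enhancers, genes, minoverlap = 1L,
                                        ignore.strand = TRUE) > 0
  category <- ifelse(edge_dist < vicinity, "promoter_vicinity",
                     ifelse(genic, "genic", "distal_intergenic"))
  tab <- table(factor(category, levels = cats))
  list(category = category,
       distribution = setNames(as.numeric(tab) / length(enhancers), cats))
}

#' Fraction of enhancers proximal to GWAS SNPs
#'
#' An enhancer is flagged when some SNP lies within `window` bp of its
#' edges (inclusive left, exclusive right in file coordinates, i.e. the
#' flanked interval `[start - window, end + window)`).
#'
#' @param enhancers `GRanges`.
#' @param snps width-1 `GRanges` from [read_snps].
#' @param window proximity window in bp (default 150000, the scale used
#'   with a full human genome; scale it down for small synthetic
#'   genomes).
#' @return List: `flags` (logical per enhancer), `fraction`.
#' @export
snp_fraction <- function(enhancers, snps, window = 150000) {
  if (!length(snps)) stopf("snp_fraction: empty SNP list")
  if (!length(enhancers)) return(list(flags = logical(0), fraction = NA_real_))
  widened <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(enhancers),
    IRanges::IRanges(pmax(start(enhancers) - window, 1), end(enhancers) + window))
  flags <- GenomicRanges::countOverlaps(widened, snps, minoverlap = 1L,
                                        ignore.strand = TRUE) > 0
  list(flags = flags, fraction = mean(flags))
}

#' Fraction of a cell-type gene list with changed H3K27ac state
#'
#' A gene is "changed" iff it is the nearest gene of at least one
#' significant differential region. `fraction_down` is the share of
#' changed genes whose associated regions are majority `down` (ties
#' count as down).
#'
#' @param diff_regions `GRanges` of significant differential regions
#'   with a `direction` metadata column (values containing `"down"` are
#'   treated as down).
#' @param gene_list character vector of cell-type-specific gene ids.
#' @param genes `GRanges` from [read_tss].
#' @return List: `n_changed`, `n_total`, `fraction`, `fraction_down`,
#'   `changed_genes`.
#' @export
gene_change_fraction <- function(diff_regions, gene_list, genes) {
  if (!length(gene_list)) stopf("gene_change_fraction: empty gene list")
  if (!length(diff_regions))
    return(list(n_changed = 0L, n_total = length(gene_list), fraction = 0,
                fraction_down = NA_real_, changed_genes = character(0)))
  nf <- nearest_feature(diff_regions, genes)
  is_down <- grepl("down", as.character(diff_regions$direction))
  hit <- nf$gene_id %in% gene_list
  changed <- unique(nf$gene_id[hit])
  down_gene <- vapply(changed, function(g) {
    dd <- is_down[nf$gene_id == g]
    mean(dd) >= 0.5                     # majority rule, ties -> down
  }, NA)
  list(n_changed = length(changed), n_total = length(gene_list),
       fraction = length(changed) / length(gene_list),
       fraction_down = if (length(changed)) mean(down_gene) else NA_real_,
       changed_genes = changed)
}

#' Overlap-based Jaccard index between two region sets
#'
#' The two sets are merged into overlap-connected components (>= 1 bp,
#' single linkage); the index is the number of components containing
#' members of both sets divided by the total number of components.
#'
#' @param a,b `GRanges`.
#' @return Numeric in \[0, 1\].
#' @export
region_jaccard <- function(a, b) {
  if (!length(a) && !length(b)) return(NA_real_)
  all_r <- suppressWarnings(c(GenomicRanges::granges(a), GenomicRanges::granges(b)))
  src <- rep(c("a", "b"), c(length(a), length(b)))
  comp <- merge_intervals(all_r)
  h <- GenomicRanges::findOverlaps(all_r, comp, minoverlap = 1L,
                                   ignore.strand = TRUE)
  lab <- split(src[S4Vectors::queryHits(h)], S4Vectors::subjectHits(h))
  both <- vapply(lab, function(x) all(c("a", "b") %in% x), NA)
  sum(both) / length(comp)
}
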