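## Enhancer calling with promoter exclusion, and the enhancer-level
## analyses.

mk_genes <- function(tss0, ids = sprintf("g%02d", seq_along(tss0)),
                     span = 5000, chrom = "chr1") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(tss0 + 1, tss0 + span),
                         strand = "+", gene_id = ids, tss = tss0 + 1)
}

mk_peaks <- function(summits0, chrom = "chr1") {
  g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(summits0 - 300 + 1,
                                                      summits0 + 300))
  g$summit <- summits0 + 1
  g$score <- seq_along(g)
  g
}

test_that("call_enhancers builds 1-kb summit windows and excludes promoters", {
  genome <- chip_genome(c(chr1 = 1e6))
  genes <- mk_genes(c(50000, 200000))
  ## summits: 2 kb from a TSS (kept), exactly 1 kb (abuts the promoter,
  ## kept), 800 bp (overlaps, dropped), far away (kept)
  cons <- list(NC = mk_peaks(c(52000, 51000, 200800, 500000)),
               MUT = mk_peaks(c(500100, 800000)))
  es <- call_enhancers(cons, genes, genome)
  expect_equal(length(es$by_condition$NC), 3)
  expect_equal(length(es$by_condition$MUT), 2)
  expect_true(all(width(es$by_condition$NC) == 1000))
  ## the summit-at-1-kb enhancer ends where the promoter begins
  e2 <- es$by_condition$NC[start(es$by_condition$NC) == 51000 - 500 + 1]
  expect_equal(end(e2), 51500 - 1 + 1)
  ## venn classes partition the union set
  expect_equal(unname(es$venn["NC_only"] + es$venn["shared"]), 3)
  expect_equal(unname(es$venn["MUT_only"] + es$venn["shared"]), 2)
  expect_equal(unname(es$venn["shared"]), 1)   # the two 500-kb summits overlap
})

test_that("missing summits fall back to midpoints with a warning", {
  genome <- chip_genome(c(chr1 = 1e6))
  genes <- mk_genes(900000)
  pk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(99001, 101000))
  expect_warning(es <- call_enhancers(list(NC = pk), genes, genome),
                 "missing summits")
  expect_equal(start(es$by_condition$NC), 100000 - 500 + 1)
})

test_that("coverage_fraction matches a brute-force pairwise check", {
  withr::local_seed(12)
  idsame <- df_to_gr(random_intervals0(50))
  expect_equal(coverage_fraction(idsame, idsame)$covered_fraction, 1)
  far <- GenomicRanges::shift(idsame, 100000)
  expect_equal(coverage_fraction(idsame, far)$covered_fraction, 0)
  expect_equal(coverage_fraction(idsame, far)$other_unique_fraction, 1)
  expect_error(coverage_fraction(GenomicRanges::GRanges(), idsame), "empty")

  for (rep in 1:10) {
    a <- random_intervals0(40); b <- random_intervals0(40)
    pairs <- bf_overlap_pairs(a, b)
    expect_equal(coverage_fraction(df_to_gr(a), df_to_gr(b))$covered_fraction,
                 length(unique(pairs$query)) / nrow(a))
  }
})

test_that("annotate_locations classifies by promoter vicinity > genic > distal", {
  genome <- chip_genome(c(chr1 = 1e7))
  genes <- mk_genes(100000, span = 80000)
  ## promoter window is [99500,100500); enhancer 1999 bp left of it
  near <- GenomicRanges::GRanges("chr1", IRanges::IRanges(99500 - 2000 - 1000 + 1 + 1,
                                                          99500 - 1999))
  genic <- GenomicRanges::GRanges("chr1", IRanges::IRanges(150001, 151000))
  distal <- GenomicRanges::GRanges("chr1", IRanges::IRanges(600001, 601000))
  ann <- annotate_locations(c(near, genic, distal), genes)
  expect_equal(ann$category,
               c("promoter_vicinity", "genic", "distal_intergenic"))
  expect_equal(sum(ann$distribution), 1)
  ## 2000 bp away is no longer "vicinity"
  at2000 <- GenomicRanges::shift(near, -1)
  expect_equal(annotate_locations(at2000, genes)$category, "distal_intergenic")
  ## stable under input order
  ann2 <- annotate_locations(c(distal, near, genic), genes)
  expect_equal(sort(ann2$category), sort(ann$category))
  expect_equal(ann2$distribution, ann$distribution)
})

test_that("snp_fraction applies the half-open +/- window exactly", {
  enh <- df_to_gr(data.frame(chrom = "chr1", start = 500000, end = 501000))
  snp_at <- function(pos0) GenomicRanges::GRanges("chr1",
                                                  IRanges::IRanges(pos0 + 1, width = 1),
                                                  snp_id = "s")
  W <- 150000
  ## inside
  expect_true(snp_fraction(enh, snp_at(500500), W)$flags)
  ## exactly 150 kb from the left edge: still associated
  expect_true(snp_fraction(enh, snp_at(500000 - W), W)$flags)
  ## 150,001 bp away: not associated
  expect_false(snp_fraction(enh, snp_at(500000 - W - 1), W)$flags)
  ## right side is exclusive: end + W - 1 is the last associated base
  expect_true(snp_fraction(enh, snp_at(501000 + W - 1), W)$flags)
  expect_false(snp_fraction(enh, snp_at(501000 + W), W)$flags)

  ## monotone non-decreasing in window size
  withr::local_seed(18)
  enhs <- df_to_gr(random_intervals0(100, "chr1", 1e6, 1000))
  snps <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(sort(sample.int(1e6, 30)), width = 1))
  fr <- vapply(c(0, 100, 1000, 10000, 1e5),
               function(w) snp_fraction(enhs, snps, w)$fraction, 0)
  expect_true(all(diff(fr) >= 0))
})

test_that("gene_change_fraction counts nearest-gene hits with majority-down logic", {
  genes <- mk_genes(seq(0, 712 - 1) * 10000 + 5000,
                    ids = sprintf("gene%03d", 1:712))
  glist <- genes$gene_id
  none <- gene_change_fraction(GenomicRanges::GRanges(), glist, genes)
  expect_equal(none$fraction, 0)

  ## construct regions whose nearest genes are exactly genes 1..41
  hits0 <- (seq_len(41) - 1) * 10000 + 5000
  regions <- GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(hits0 + 1 - 200, hits0 + 200))
  regions$direction <- rep(c("down_in_MUT", "up_in_MUT"),
                           c(39, 2))
  gc <- gene_change_fraction(regions, glist, genes)
  expect_equal(gc$n_changed, 41)
  expect_equal(gc$n_total, 712)
  expect_equal(gc$fraction, 41 / 712)
  expect_equal(round(100 * gc$fraction), 6)
  expect_equal(gc$fraction_down, 39 / 41)

  ## ties (1 up + 1 down on the same gene) count as down
  g2 <- mk_genes(5000, ids = "solo")
  r2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(4801, 5201), width = 100))
  r2$direction <- c("up_in_MUT", "down_in_MUT")
  expect_equal(gene_change_fraction(r2, "solo", g2)$fraction_down, 1)
  expect_error(gene_change_fraction(r2, character(0), g2), "empty gene list")
})

test_that("gene_change_fraction agrees with brute-force nearest-gene mapping", {
  withr::local_seed(33)
  for (rep in 1:5) {
    tss0 <- sort(sample.int(9e5, 60))
    genes <- mk_genes(tss0, ids = sprintf("g%03d", sample(60)))
    d <- random_intervals0(30, "chr1", 9e5, 2000)
    regions <- df_to_gr(d)
    regions$direction <- sample(c("up_in_MUT", "down_in_MUT"), 30, TRUE)
    glist <- sample(genes$gene_id, 25)
    got <- gene_change_fraction(regions, glist, genes)
    nf <- bf_nearest(d$chrom, d$start, d$end, rep("chr1", 60), tss0,
                     genes$gene_id)
    changed <- unique(nf$gene_id[nf$gene_id %in% glist])
    expect_equal(got$n_changed, length(changed))
    expect_setequal(got$changed_genes, changed)
  }
})

test_that("region_jaccard is the fraction of union components with both sets", {
  a <- df_to_gr(data.frame(chrom = "chr1", start = c(0, 1000), end = c(500, 1500)))
  expect_equal(region_jaccard(a, a), 1)
  b <- GenomicRanges::shift(a, 10000)
  expect_equal(region_jaccard(a, b), 0)
  expect_equal(region_jaccard(a, a[1]), 0.5)
})
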