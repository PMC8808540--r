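## Domain types, interval engine, and on-disk format round-trips.

test_that("BED reader keeps 0-based half-open coordinates and validates input", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t0\t50", "chr2\t999\t1000"), f)
  gr <- read_regions(f, "bed")
  expect_equal(start(gr), c(101, 1, 1000))
  expect_equal(end(gr), c(200, 50, 1000))
  expect_equal(width(gr), c(100, 50, 1))

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t300"), bad)
  expect_error(read_regions(bad, "bed"), "line 2")
  writeLines(c("chr1\t200\t100"), bad)
  expect_error(read_regions(bad, "bed"), "line 1")

  g <- chip_genome(c(chr1 = 1000))
  f2 <- withr::local_tempfile(fileext = ".bed")
  writeLines("chrX\t10\t20", f2)
  expect_error(read_regions(f2, "bed", genome = g), "chrX")
})

test_that("narrowPeak summits follow the dialect conventions", {
  f <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines(c("chr1\t100\t200\tp1\t10\t.\t5.5\t3.2\t2.0\t50",
               "chr1\t100\t200\tp2\t10\t.\t5.5\t3.2\t2.0\t-1"), f)
  gr <- read_regions(f, "narrowPeak")
  ## summit offset 50 on [100,200) -> absolute 150 (0-based) = 151 1-based
  expect_equal(gr$summit[1], 151)
  ## -1 -> midpoint 150
  expect_equal(gr$summit[2], 151)
  expect_equal(gr$qvalue, rep(10^-2, 2))

  bad <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines("chr1\t100\t200\tp\t1\t.\t1\t1\t1\t100", bad)
  expect_error(read_regions(bad, "narrowPeak"), "summit offset")
})

test_that("region writers round-trip BED and narrowPeak bit-exactly", {
  withr::local_seed(11)
  df <- random_intervals0(80)
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(paste(df$chrom, df$start, df$end, sep = "\t"), f)
  f2 <- withr::local_tempfile(fileext = ".bed")
  write_regions(read_regions(f, "bed"), f2, "bed")
  expect_identical(readLines(f2), readLines(f))

  np <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines(sprintf("%s\t%d\t%d\tpk%d\t%d\t.\t%g\t%g\t%g\t%d",
                     df$chrom, df$start, df$end, seq_len(nrow(df)),
                     seq_len(nrow(df)), 1.25, 3.5, 2,
                     pmin(5L, df$end - df$start - 1L)), np)
  np2 <- withr::local_tempfile(fileext = ".narrowPeak")
  write_regions(read_regions(np, "narrowPeak"), np2, "narrowPeak")
  expect_identical(readLines(np2), readLines(np))
})

test_that("interval_overlap uses >= 1 bp half-open semantics", {
  a <- df_to_gr(data.frame(chrom = "chr1", start = 100, end = 200))
  b <- df_to_gr(data.frame(chrom = "chr1", start = c(200, 199), end = c(300, 300)))
  ov <- interval_overlap(a, b)
  expect_equal(nrow(ov), 1)      # abutment does not overlap, 1 bp does
  expect_equal(ov$subject, 2)
})

test_that("interval_overlap matches the brute-force scan on random sets", {
  withr::local_seed(42)
  for (rep in 1:25) {
    a <- random_intervals0(40)
    b <- random_intervals0(40)
    got <- interval_overlap(df_to_gr(a), df_to_gr(b))
    want <- bf_overlap_pairs(a, b)
    expect_identical(got[order(got$query, got$subject), ],
                     want[order(want$query, want$subject), ],
                     ignore_attr = TRUE)
  }
})

test_that("nearest_feature honours containment, distance and tie rules", {
  g <- chip_genome(c(chr1 = 1e6))
  mk_genes <- function(tss0, ids) {
    GenomicRanges::GRanges("chr1", IRanges::IRanges(tss0 + 1, tss0 + 100),
                           gene_id = ids, tss = tss0 + 1)
  }
  q <- df_to_gr(data.frame(chrom = "chr1", start = 1000, end = 2000))
  ## TSS inside the region -> 0
  expect_equal(nearest_feature(q, mk_genes(1500, "gA")),
               data.frame(gene_id = "gA", distance = 0))
  ## 500 upstream beats 600 downstream
  nf <- nearest_feature(q, mk_genes(c(500, 2600), c("g1", "g2")))
  expect_equal(nf$gene_id, "g1")
  expect_equal(nf$distance, -500)
  ## |100| tie -> upstream wins
  nf <- nearest_feature(q, mk_genes(c(900, 2100), c("gB", "gA")))
  expect_equal(nf$gene_id, "gB")
  expect_equal(nf$distance, -100)
  ## same-position tie -> lexicographically smaller id
  nf <- nearest_feature(q, mk_genes(c(500, 500), c("gZ", "gC")))
  expect_equal(nf$gene_id, "gC")
  expect_error(nearest_feature(q, GenomicRanges::GRanges()), "empty")
})

test_that("nearest_feature matches brute force and is translation invariant", {
  withr::local_seed(7)
  for (rep in 1:10) {
    nq <- 30; nf_ <- 15
    qs <- floor(runif(nq, 0, 9e5)); qe <- qs + floor(runif(nq, 1, 3000))
    ts <- floor(runif(nf_, 0, 9e5))
    ids <- sprintf("g%02d", sample(nf_))
    q <- GenomicRanges::GRanges("chr1", IRanges::IRanges(qs + 1, qe))
    genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(ts + 1, ts + 10),
                                    gene_id = ids, tss = ts + 1)
    got <- nearest_feature(q, genes)
    want <- bf_nearest(rep("chr1", nq), qs, qe, rep("chr1", nf_), ts, ids)
    expect_equal(got, want)
    ## translate everything by a constant
    off <- 12345
    q2 <- GenomicRanges::shift(q, off)
    genes2 <- GenomicRanges::shift(genes, off)
    genes2$tss <- genes$tss + off
    expect_equal(nearest_feature(q2, genes2)$distance, got$distance)
  }
})

test_that("TSS, SNP and sample-sheet readers validate their invariants", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t5000\tgeneA\t0\t+", "chr1\t8000\t9000\tgeneA\t0\t-"), f)
  expect_error(read_tss(f), "duplicate gene_id")
  writeLines(c("chr1\t100\t5000\tgeneA\t0\t+", "chr1\t8000\t9000\tgeneB\t0\t-"), f)
  genes <- read_tss(f)
  expect_equal(genes$tss, c(101, 9000))   # 5' end per strand

  s <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,cell_type,condition,mark,replicate,tech_rep,role",
               "a,BC,NC,H3K27ac,1,1,chip",
               "b,BC,NC,H3K27ac,1,1,chip"), s)
  expect_error(read_sample_sheet(s), "duplicate sample key")
})

test_that("JASPAR-style PWM files round-trip", {
  m <- matrix(c(10, 0, 0, 0,  0, 10, 0, 0,  2, 2, 4, 2,  0, 0, 0, 10), nrow = 4)
  p <- pwm(m, id = "M1", name = "testTF")
  f <- withr::local_tempfile(fileext = ".txt")
  write_pwms(list(M1 = p), f)
  back <- read_pwms(f)
  expect_equal(names(back), "M1")
  expect_equal(back$M1$prob, p$prob, tolerance = 1e-6)
  expect_equal(pwm_consensus(back$M1), pwm_consensus(p))
})
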