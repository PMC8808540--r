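## The seeded study generator: determinism, composition, planted
## structure, and the sampling model.

test_that("genome generation is deterministic and respects its spacing rules", {
  p <- small_sim_params()
  g1 <- generate_genome_and_annotation(p)
  g2 <- generate_genome_and_annotation(p)
  expect_identical(as.character(g1$genome$sequences),
                   as.character(g2$genome$sequences))
  expect_identical(g1$genes, g2$genes)

  expect_equal(length(g1$genes), p$n_genes)
  expect_equal(anyDuplicated(g1$genes$gene_id), 0)
  tss_sorted <- sort(g1$genes$tss)
  expect_true(all(diff(tss_sorted) >= p$gene_min_space))

  ## infeasible spacing errors out
  expect_error(generate_genome_and_annotation(
    sim_params(n_chroms = 1, chrom_length = 2e5, n_genes = 100)),
    "infeasible")
})

test_that("base composition matches the GC parameter", {
  g <- generate_genome_and_annotation(
    sim_params(n_chroms = 1, chrom_length = 1e6, gc = 0.5, n_genes = 20))
  counts <- Biostrings::alphabetFrequency(g$genome$sequences[[1]])
  gc_obs <- counts[["C"]] + counts[["G"]]
  ## binomial(1e6, 0.5): observed GC within 3 sd of expectation
  expect_lt(abs(gc_obs - 5e5), 3 * sqrt(1e6 * 0.25))
})

test_that("the planted landscape honours its structural invariants", {
  st <- get_small_study()
  truth <- st$truth
  p <- truth$params
  expect_equal(length(truth$snps), p$n_snps)
  expect_equal(sim_params()$n_snps, 123)     # reference catalogue size

  prom <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(truth$genes),
    IRanges::IRanges(truth$genes$tss - 500, truth$genes$tss + 499))
  for (grp in names(truth$enhancer_truth))
    expect_equal(sum(GenomicRanges::countOverlaps(
      truth$enhancer_truth[[grp]], prom)), 0)

  ## planted peaks are pairwise disjoint and in bounds
  pk <- truth$peaks
  expect_equal(sum(GenomicRanges::countOverlaps(pk, pk) != 1), 0)
  expect_true(all(start(pk) >= 1 &
                    end(pk) <= truth$genome$seqlengths[
                      as.character(GenomeInfoDb::seqnames(pk))]))

  ## every motif-carrying region contains its consensus on some strand
  carry <- which(!is.na(pk$motif))
  for (i in carry[seq(1, length(carry), length.out = 25)]) {
    ids <- strsplit(pk$motif[i], ",")[[1]]
    seq <- region_sequences(truth$genome,
                            GenomicRanges::GRanges(
                              GenomeInfoDb::seqnames(pk)[i],
                              IRanges::IRanges(pk$center[i] - 500,
                                               pk$center[i] + 499)))
    for (id in ids) {
      cons <- pwm_consensus(truth$pwms[[id]])
      rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons)))
      expect_true(grepl(cons, seq, fixed = TRUE) ||
                    grepl(rc, seq, fixed = TRUE))
    }
  }
})

test_that("read simulation is deterministic per sample and depth-scalable", {
  st <- get_small_study()
  truth <- st$truth
  meta <- list(sample_id = "BC_NC_rep1", cell_type = "BC", condition = "NC",
               role = "chip", replicate = 1)
  r1 <- simulate_sample(truth, meta)
  r2 <- simulate_sample(truth, meta)
  expect_identical(r1, r2)
  expect_equal(length(r1), truth$params$n_reads_chip)

  meta2 <- meta; meta2$sample_id <- "BC_NC_rep1_t2"
  expect_false(identical(simulate_sample(truth, meta2), r1))

  meta3 <- meta; meta3$depth_factor <- 0.05
  expect_equal(length(simulate_sample(truth, meta3)),
               round(truth$params$n_reads_chip / 20))
})

test_that("input reads are uniform across the genome", {
  st <- get_small_study()
  truth <- st$truth
  meta <- list(sample_id = "BC_NC_input", cell_type = "BC", condition = "NC",
               role = "input", replicate = 1)
  reads <- simulate_sample(truth, meta)
  L <- truth$genome$seqlengths[[1]]
  win <- GenomicRanges::GRanges(names(truth$genome$seqlengths)[1],
                                IRanges::IRanges(L / 2, width = L / 100))
  n_in <- sum(GenomicRanges::countOverlaps(reads, win) > 0)
  expect_lt(abs(n_in - 0.01 * length(reads)),
            3 * sqrt(length(reads) * 0.01 * 0.99) + 2)
})

test_that("condition-differential regions carry the planted fold ratio", {
  st <- get_small_study()
  truth <- st$truth
  nc <- chipscape:::active_regions(truth, "BC", "NC")
  mut <- chipscape:::active_regions(truth, "BC", "MUT")
  pk <- truth$peaks
  diff_bc <- pk[pk$class == "differential" & pk$cell_type == "BC"]
  for (i in seq_along(diff_bc)) {
    w_nc <- nc$weight[nc$center == diff_bc$center[i]]
    w_mut <- mut$weight[mut$center == diff_bc$center[i]]
    want <- if (diff_bc$direction[i] == "down_in_MUT") 1 / diff_bc$fold[i]
            else diff_bc$fold[i]
    expect_equal(w_mut / w_nc, want, tolerance = 1e-12)
  }
  ## condition-exclusive regions are absent from the other condition
  excl_nc <- pk[pk$class == "exclusive" & pk$cell_type == "BC" &
                  pk$condition == "NC"]
  expect_true(all(excl_nc$center %in% nc$center))
  expect_false(any(excl_nc$center %in% mut$center))
})

test_that("simulated ChIP samples land near the target FrIP", {
  st <- get_small_study()
  truth <- st$truth
  act <- chipscape:::active_regions(truth, "LP", "NC")
  regions <- GenomicRanges::GRanges(act$chrom,
                                    IRanges::IRanges(act$center - act$width %/% 2,
                                                     act$center + act$width %/% 2))
  meta <- list(sample_id = "LP_NC_rep1", cell_type = "LP", condition = "NC",
               role = "chip", replicate = 1)
  reads <- simulate_sample(truth, meta)
  expect_lt(abs(frip(reads, regions) - truth$params$target_frip), 0.05)
})

test_that("full regeneration under a fixed seed is byte-identical", {
  p <- small_sim_params(n_reads_chip = 1e4, n_reads_input = 1e4)
  d1 <- file.path(tempdir(), "regen1")
  d2 <- file.path(tempdir(), "regen2")
  simulate_study(p, d1)
  simulate_study(p, d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  unlink(c(d1, d2), recursive = TRUE)
})
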