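## PWM scanning, shuffled backgrounds, hypergeometric enrichment, and
## the TF specificity/preservation logic.

sharp_pwm <- function(cons, id = "M") {
  m <- matrix(0.1 / 3, 4, nchar(cons), dimnames = list(c("A", "C", "G", "T"), NULL))
  idx <- match(strsplit(cons, "")[[1]], c("A", "C", "G", "T"))
  for (j in seq_along(idx)) m[idx[j], j] <- 0.9
  pwm(m, id = id)
}

test_that("pwm validates and normalizes its matrix", {
  expect_error(pwm(matrix(1, 3, 6)), "4 rows")
  expect_error(pwm(matrix(1, 4, 3)), "length 3")
  p <- pwm(matrix(c(8, 0, 0, 0), 4, 8))      # counts get normalized
  expect_equal(colSums(p$prob), rep(1, 8))
  expect_equal(pwm_consensus(p), "AAAAAAAA")
})

test_that("scan_sequences finds planted consensus sites and rejects N runs", {
  p <- sharp_pwm("ACGTACGTAC")
  seq1 <- paste0(strrep("T", 40), "ACGTACGTAC", strrep("G", 30))
  res <- scan_sequences(c(seq1, strrep("N", 80)), p, positions = TRUE)
  expect_equal(res$hit, c(TRUE, FALSE))
  expect_equal(res$positions[[1]]$pos, 41)
  expect_equal(res$positions[[1]]$strand, "+")
  ## reverse-complement planting is found on the minus strand
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString("ACGTACGTAC")))
  seq2 <- paste0(strrep("T", 20), rc, strrep("C", 30))
  res2 <- scan_sequences(seq2, p, positions = TRUE)
  expect_true(res2$hit)
  expect_true("-" %in% res2$positions[[1]]$strand)
  expect_warning(scan_sequences("ACGT", p), "shorter than motif")
})

test_that("scanning is strand-symmetric under reverse complementation", {
  withr::local_seed(27)
  seqs <- vapply(1:30, function(i)
    paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = ""), "")
  seqs[1:5] <- paste0(seqs[1:5], "ACGTACGTAC")
  p <- sharp_pwm("ACGTACGTAC")
  fwd <- scan_sequences(seqs, p)$hit
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
  expect_equal(scan_sequences(rc, p)$hit, fwd)
})

test_that("hexamer hit sets equal exhaustive brute-force score enumeration", {
  p <- sharp_pwm("TGACGC")
  hex <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), 6),
                                     stringsAsFactors = FALSE))
  expect_length(hex, 4096)
  got <- scan_sequences(hex, p, threshold = 0.8)$hit
  want <- vapply(hex, function(s)
    bf_best_pwm_score(s, p$log_odds) >= 0.8 * p$max_score, NA,
    USE.NAMES = FALSE)
  expect_equal(got, want)
  ## and the best scores agree numerically on a sample
  idx <- seq(1, 4096, by = 37)
  expect_equal(scan_sequences(hex[idx], p)$best_score,
               vapply(hex[idx], bf_best_pwm_score, 0, lo = p$log_odds,
                      USE.NAMES = FALSE))
})

test_that("dinuc_shuffle preserves dinucleotide composition", {
  withr::local_seed(44)
  for (rep in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 500, TRUE,
                      prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
    sh <- dinuc_shuffle(s)
    expect_equal(nchar(sh), nchar(s))
    expect_equal(dinuc_counts(sh), dinuc_counts(s))
    expect_false(sh == s)   # 500 bp: astronomically unlikely to be unmoved
  }
  bg <- make_background(c("ACGTACGTAA", "GGGTTTAACC"), n_copies = 2, seed = 1)
  expect_length(bg, 4)
  ## seeded: regeneration is identical
  expect_identical(bg, make_background(c("ACGTACGTAA", "GGGTTTAACC"), 2, seed = 1))
})

test_that("enrichment_test equals the explicit hypergeometric tail", {
  p <- sharp_pwm("TGACGCAA")
  mk <- function(n_hit, n_tot) c(replicate(n_hit, paste0(strrep("T", 20), "TGACGCAA", strrep("A", 20))),
                                 replicate(n_tot - n_hit, strrep("C", 48)))
  res <- enrichment_test(mk(40, 50), mk(8, 100), p)
  expect_equal(res$fg_hits, 40)
  expect_equal(res$bg_hits, 8)
  expect_equal(res$p_value, bf_hyper_tail(40, 48, 150, 50))

  ## equal hit rates are not significant
  eq <- enrichment_test(mk(10, 50), mk(20, 100), p)
  expect_gte(eq$p_value, 0.4)
  expect_error(enrichment_test(character(0), mk(1, 10), p), "empty foreground")

  ## monotone decreasing in foreground hits at fixed totals
  ps <- vapply(c(10, 20, 30, 40), function(k)
    enrichment_test(mk(k, 50), mk(8, 100), p)$p_value, 0)
  expect_true(all(diff(ps) < 0))
})

test_that("random p-value tables drive the selection logic as enumerated", {
  withr::local_seed(51)
  motifs <- sprintf("M%02d", 1:25)
  groups <- expand.grid(cell_type = c("BC", "LP", "ML"),
                        condition = c("NC", "MUT"), stringsAsFactors = FALSE)
  tab <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i)
    data.frame(motif = motifs, cell_type = groups$cell_type[i],
               condition = groups$condition[i],
               p_value = 10^-runif(25, 0, 8))))
  alpha <- 1e-4
  ## condition-differential rules
  cd <- condition_differential_motifs(tab, "BC", alpha)
  pn <- tab$p_value[tab$cell_type == "BC" & tab$condition == "NC"]
  pm <- tab$p_value[tab$cell_type == "BC" & tab$condition == "MUT"]
  expect_setequal(cd$NC_only, motifs[pn < alpha & pm >= alpha])
  expect_setequal(cd$MUT_only, motifs[pn >= alpha & pm < alpha])
  expect_setequal(cd$shared, motifs[pn < alpha & pm < alpha])
  ## alpha = 1 makes everything shared
  cd1 <- condition_differential_motifs(tab, "BC", alpha = 1.0000001)
  expect_setequal(cd1$shared, motifs)

  ## cell-type-specific sets equal the brute-force triple-condition scan
  sp <- celltype_specific_tfs(tab, alpha = alpha)
  pmat <- sapply(c("BC", "LP", "ML"), function(ct)
    tab$p_value[tab$cell_type == ct & tab$condition == "NC"])
  rownames(pmat) <- motifs
  for (ct in c("BC", "LP", "ML")) {
    want <- motifs[pmat[, ct] < alpha &
                     rowSums(pmat[, setdiff(colnames(pmat), ct)] < alpha) == 0]
    expect_setequal(sp[[ct]], want)
  }
  ## pairwise disjoint by construction
  expect_equal(anyDuplicated(unlist(sp)), 0)

  ## preservation: MUT tables identical to NC -> diagonal = set sizes
  tab_same <- tab
  tab_same$p_value[tab_same$condition == "MUT"] <-
    tab_same$p_value[tab_same$condition == "NC"]
  M <- mut_preservation(sp, tab_same, alpha = alpha)
  expect_equal(unname(diag(M)), unname(lengths(sp)))
  expect_true(all(M[upper.tri(M)] == 0) && all(M[lower.tri(M)] == 0))

  ## empty specific sets give zeros
  M0 <- mut_preservation(list(BC = character(0), LP = character(0),
                              ML = character(0)), tab, alpha = alpha)
  expect_true(all(M0 == 0))
})
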