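## Seeded miniature four-cell-type x two-condition ChIP-seq study with
## known ground truth. The generator emulates post-alignment inputs:
## per-sample ChIP and input read BEDs with peak-enriched coverage,
## genome FASTA, TSS/gene table, SNP catalogue, blacklist decoys, a
## synthetic PWM panel, and a truth/ directory sufficient to score every
## downstream recovery analysis.

#' Simulation parameters
#'
#' Defaults define the package's reference desk-scale study: a 2 x 5 Mb
#' genome, 300 genes, 400 shared peaks, 120 cell-type-specific, 60
#' condition-differential (fold 4) and 60 condition-exclusive peaks per
#' class, 2e5 reads per sample at a target FrIP of 0.3, three biological
#' replicates per condition, and 123 GWAS-style SNPs of which a fraction
#' is planted near MUT-BC-exclusive enhancers.
#'
#' @param ... overrides for any default listed above (see the function
#'   body for the full set).
#' @return Named list of parameters (class `sim_params`).
#' @export
sim_params <- function(...) {
  p <- list(
    seed = 17,
    n_chroms = 2, chrom_length = 5e6, gc = 0.41,
    n_genes = 300, gene_min_space = 10000, gene_length = c(5000, 30000),
    n_shared = 400, n_celltype = 120, n_differential = 60, n_exclusive = 60,
    diff_fold = 4, peak_width = c(600, 2000),
    n_reads_chip = 2e5, n_reads_input = 2e5, target_frip = 0.3,
    read_length = 50, fragment_length = 250, summit_sd = 75,
    n_replicates = 3, rep_sigma = 0.15, weight_shape = 4,
    n_snps = 123, snp_frac_proximal = 0.4, snp_flank = 2000,
    n_blacklist = 5, blacklist_width = 2000, blacklist_weight = 8,
    n_housekeeping = 100, n_ct_genes = 30, promoter_halfwidth = 400,
    motif_length = 12, n_decoy_motifs = 8,
    cell_types = c("BC", "LP", "ML", "SC"),
    conditions = c("NC", "MUT"), mark = "H3K27ac",
    scenario = "bc_lp_shift")
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stopf("sim_params: unknown parameter(s): %s",
                         paste(bad, collapse = ", "))
  p[names(over)] <- over
  stopifnot(p$target_frip > 0, p$target_frip < 1, p$n_genes > 0,
            p$n_reads_chip > 0, p$n_reads_input > 0)
  structure(p, class = "sim_params")
}

#' Generate the synthetic genome and gene annotation
#'
#' I.i.d. bases at the stated GC content; genes placed uniformly per
#' chromosome with a minimum TSS spacing, random strand and length, TSS
#' at the 5' end of the span. Deterministic given the seed.
#'
#' @param params [sim_params].
#' @return List: `genome` ([chip_genome] with sequence), `genes`
#'   (`GRanges` as from [read_tss]).
#' @export
generate_genome_and_annotation <- function(params = sim_params()) {
  with_seed(derive_seed(params$seed, "genome"), {
    chroms <- paste0("chr", seq_len(params$n_chroms))
    L <- rep(params$chrom_length, params$n_chroms)
    names(L) <- chroms
    base_prob <- c(A = (1 - params$gc) / 2, C = params$gc / 2,
                   G = params$gc / 2, T = (1 - params$gc) / 2)
    seqs <- Biostrings::DNAStringSet(vapply(chroms, function(ch)
      paste(sample(names(base_prob), params$chrom_length, replace = TRUE,
                   prob = base_prob), collapse = ""), ""))
    names(seqs) <- chroms
    genome <- chip_genome(L, seqs)
    ## distribute genes across chromosomes proportional to length
    n_per <- floor(params$n_genes * L / sum(L))
    rem <- params$n_genes - sum(n_per)
    if (rem > 0) n_per[seq_len(rem)] <- n_per[seq_len(rem)] + 1
    margin <- 50000
    sp <- params$gene_min_space
    recs <- list()
    gid <- 0
    for (ch in chroms) {
      k <- n_per[[ch]]
      if (!k) next
      avail <- L[[ch]] - 2 * margin - (k - 1) * sp
      if (avail <= 0)
        stopf("generate_genome_and_annotation: TSS spacing %d bp infeasible for %d genes on %s",
              sp, k, ch)
      u <- sort(runif(k, 0, avail))
      tss <- round(margin + u + (seq_len(k) - 1) * sp)
      strand <- sample(c("+", "-"), k, replace = TRUE)
      len <- round(runif(k, params$gene_length[1], params$gene_length[2]))
      s1 <- ifelse(strand == "+", tss, pmax(tss - len + 1, 1))
      e1 <- ifelse(strand == "+", pmin(tss + len - 1, L[[ch]]), tss)
      recs[[ch]] <- data.frame(chrom = ch, start = s1, end = e1,
                               strand = strand, tss = tss,
                               gene_id = sprintf("G%04d", gid + seq_len(k)))
      gid <- gid + k
    }
    df <- do.call(rbind, recs)
    genes <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                                    strand = df$strand,
                                    gene_id = df$gene_id, tss = df$tss)
    list(genome = genome, genes = genes)
  })
}

## synthetic consensus-dominated PWM panel; ids SYNTF01.. ; 0.9 on the
## consensus base so a single mismatch falls below the 0.8 score cutoff
make_pwm_panel <- function(n, motif_length, seed) {
  with_seed(seed, {
    panel <- list()
    seen <- character(0)
    while (length(panel) < n) {
      cons <- paste(sample(c("A", "C", "G", "T"), motif_length, replace = TRUE),
                    collapse = "")
      rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons)))
      if (cons %in% seen || rc %in% seen) next
      seen <- c(seen, cons)
      id <- sprintf("SYNTF%02d", length(panel) + 1)
      m <- matrix(0.1 / 3, 4, motif_length,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
      idx <- match(strsplit(cons, "")[[1]], c("A", "C", "G", "T"))
      for (j in seq_len(motif_length)) m[idx[j], j] <- 0.9
      panel[[id]] <- pwm(m, id = id, name = paste0("synthetic_", id))
    }
    panel
  })
}

## place regions of given widths into the free space of the genome
## (outside TSS +/- tss_clear and chromosome edges), with a minimum gap;
## deterministic stick-breaking walk, randomized order and gaps
place_regions <- function(genome, genes, widths, seed,
                          tss_clear = 3000, edge = 1000, min_gap = 200) {
  chroms <- names(genome$seqlengths)
  whole <- GenomicRanges::GRanges(chroms,
                                  IRanges::IRanges(edge + 1, genome$seqlengths - edge))
  tssw <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(genes),
                                 IRanges::IRanges(genes$tss - tss_clear,
                                                  genes$tss + tss_clear))
  free <- GenomicRanges::setdiff(whole, GenomicRanges::reduce(tssw),
                                 ignore.strand = TRUE)
  total_free <- sum(width(free))
  n <- length(widths)
  slack <- total_free - sum(widths) - n * min_gap
  if (slack <= 0)
    stopf("place_regions: %d regions (%.3g bp) do not fit into %.3g bp of free space",
          n, sum(widths), total_free)
  with_seed(seed, {
    ord <- sample.int(n)
    for (attempt in 1:6) {
      frac <- 0.8 / 2^(attempt - 1)
      extra <- stats::runif(n)
      extra <- extra / sum(extra) * slack * frac
      out_chrom <- character(n); out_start <- numeric(n)
      seg <- 1
      pos <- start(free)[1]
      ok <- TRUE
      for (i in seq_len(n)) {
        w <- widths[ord[i]]
        g <- min_gap + extra[i]
        placed <- FALSE
        while (seg <= length(free)) {
          cand <- pos + g
          if (cand + w - 1 <= end(free)[seg]) {
            out_chrom[ord[i]] <- as.character(GenomeInfoDb::seqnames(free))[seg]
            out_start[ord[i]] <- round(cand)
            pos <- cand + w
            placed <- TRUE
            break
          }
          seg <- seg + 1
          if (seg <= length(free)) pos <- start(free)[seg]
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok)
        return(GenomicRanges::GRanges(out_chrom,
                                      IRanges::IRanges(out_start,
                                                       out_start + widths - 1)))
      seg <- 1; pos <- start(free)[1]
    }
    stopf("place_regions: overlap-free placement failed after bounded retries")
  })
}

#' Plant the ground-truth landscape
#'
#' Places all peak classes (shared, cell-type-specific,
#' condition-differential with fold, condition-exclusive), promoter
#' activity programs, blacklist decoys, the synthetic PWM panel with
#' consensus strings written into the genome sequence at enhancer-class
#' region centres (random strand), and the SNP catalogue with a planted
#' excess near MUT-BC-exclusive enhancers. In the `bc_lp_shift`
#' scenario the LP cell-type motif is additionally planted into
#' MUT-BC-exclusive regions.
#'
#' @param genome [chip_genome] with sequence (will be modified to carry
#'   the planted motifs).
#' @param genes `GRanges` from [generate_genome_and_annotation].
#' @param params [sim_params].
#' @return A `landscape_truth` list; `$genome` carries the motif-planted
#'   sequence.
#' @export
plant_landscape <- function(genome, genes, params = sim_params()) {
  cts <- params$cell_types
  conds <- params$conditions
  ## class table
  cls <- list(data.frame(class = "shared", cell_type = NA, condition = NA,
                         direction = NA, n = params$n_shared))
  for (ct in cts)
    cls[[length(cls) + 1]] <- data.frame(class = "ct_specific", cell_type = ct,
                                         condition = NA, direction = NA,
                                         n = params$n_celltype)
  for (ct in cts)
    cls[[length(cls) + 1]] <- data.frame(class = "differential", cell_type = ct,
                                         condition = NA, direction = NA,
                                         n = params$n_differential)
  for (ct in cts) for (cond in conds)
    cls[[length(cls) + 1]] <- data.frame(class = "exclusive", cell_type = ct,
                                         condition = cond, direction = NA,
                                         n = params$n_exclusive)
  cls <- do.call(rbind, cls)
  tab <- cls[rep(seq_len(nrow(cls)), cls$n), c("class", "cell_type", "condition")]
  rownames(tab) <- NULL
  n_peaks <- nrow(tab)
  with_seed(derive_seed(params$seed, "landscape"), {
    widths <- round(runif(n_peaks + params$n_blacklist,
                          params$peak_width[1], params$peak_width[2]))
    widths[n_peaks + seq_len(params$n_blacklist)] <- params$blacklist_width
    placed <- place_regions(genome, genes, widths,
                            seed = derive_seed(params$seed, "placement"))
    peaks <- placed[seq_len(n_peaks)]
    blacklist <- placed[n_peaks + seq_len(params$n_blacklist)]
    S4Vectors::mcols(peaks) <- S4Vectors::DataFrame(tab)
    peaks$direction <- NA_character_
    di <- which(peaks$class == "differential")
    peaks$direction[di] <- rep_len(c("up_in_MUT", "down_in_MUT"), length(di))
    peaks$fold <- ifelse(peaks$class == "differential", params$diff_fold, 1)
    peaks$weight <- rgamma(n_peaks, shape = params$weight_shape, scale = 1)
    peaks$center <- floor((start(peaks) + end(peaks)) / 2)
    peaks$name <- sprintf("truth_%04d", seq_len(n_peaks))
    ## promoter activity programs
    gene_ids <- genes$gene_id
    hk <- sample(gene_ids, params$n_housekeeping)
    rest <- setdiff(gene_ids, hk)
    ct_genes <- list()
    for (ct in cts) {
      ct_genes[[ct]] <- sample(rest, params$n_ct_genes)
      rest <- setdiff(rest, ct_genes[[ct]])
    }
    pa <- matrix(0, length(gene_ids), length(cts),
                 dimnames = list(gene_ids, cts))
    for (ct in cts) {
      act <- c(hk, ct_genes[[ct]])
      pa[act, ct] <- rgamma(length(act), shape = params$weight_shape, scale = 1)
    }
    ## motif panel and assignment
    n_motifs <- length(cts) + length(cts) * length(conds) + params$n_decoy_motifs
    panel <- make_pwm_panel(n_motifs, params$motif_length,
                            derive_seed(params$seed, "pwms"))
    ids <- names(panel)
    assign <- data.frame(motif = ids, role = "decoy",
                         cell_type = NA_character_, condition = NA_character_)
    k <- 1
    for (ct in cts) {
      assign$role[k] <- "ct_specific"; assign$cell_type[k] <- ct; k <- k + 1
    }
    for (ct in cts) for (cond in conds) {
      assign$role[k] <- "exclusive"; assign$cell_type[k] <- ct
      assign$condition[k] <- cond; k <- k + 1
    }
    ## write consensus strings into the genome at region centres
    motif_of <- function(role, ct, cond = NA) {
      i <- which(assign$role == role &
                   (is.na(ct) | assign$cell_type %in% ct) &
                   (is.na(cond) | assign$condition %in% cond))
      assign$motif[i[1]]
    }
    plant <- list()  # per chrom: at-ranges + replacement strings
    add_plant <- function(chrom, at_start, motif_id) {
      cons <- pwm_consensus(panel[[motif_id]])
      if (runif(1) < 0.5)
        cons <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons)))
      plant[[length(plant) + 1]] <<- data.frame(
        chrom = chrom, start = at_start, value = cons)
    }
    peaks$motif <- NA_character_
    Lm <- params$motif_length
    for (i in seq_len(n_peaks)) {
      cl <- peaks$class[i]
      if (cl == "shared" || cl == "differential") next
      mid <- if (cl == "ct_specific") motif_of("ct_specific", peaks$cell_type[i])
             else motif_of("exclusive", peaks$cell_type[i], peaks$condition[i])
      chrom <- as.character(GenomeInfoDb::seqnames(peaks))[i]
      add_plant(chrom, peaks$center[i] - 15, mid)
      peaks$motif[i] <- mid
      if (params$scenario == "bc_lp_shift" && cl == "exclusive" &&
          peaks$cell_type[i] == "BC" && peaks$condition[i] == "MUT") {
        extra <- motif_of("ct_specific", "LP")
        add_plant(chrom, peaks$center[i] + 15, extra)
        peaks$motif[i] <- paste(mid, extra, sep = ",")
      }
    }
    plant <- if (length(plant)) do.call(rbind, plant) else
      data.frame(chrom = character(0), start = numeric(0), value = character(0))
    seqs <- genome$sequences
    for (ch in unique(plant$chrom)) {
      sub <- plant[plant$chrom == ch, ]
      at <- IRanges::IRanges(sub$start, width = Lm)
      seqs[[ch]] <- Biostrings::replaceAt(seqs[[ch]], at, as.character(sub$value))
    }
    genome <- chip_genome(genome$seqlengths, seqs)
    ## SNP catalogue: a fraction planted near MUT-BC-exclusive enhancers
    n_prox <- round(params$n_snps * params$snp_frac_proximal)
    bc_excl <- which(peaks$class == "exclusive" & peaks$cell_type == "BC" &
                       peaks$condition == "MUT")
    take <- sample(bc_excl, n_prox, replace = n_prox > length(bc_excl))
    prox_pos <- peaks$center[take] +
      round(runif(n_prox, -params$snp_flank, params$snp_flank))
    prox_chrom <- as.character(GenomeInfoDb::seqnames(peaks))[take]
    n_unif <- params$n_snps - n_prox
    uchrom <- sample(names(genome$seqlengths), n_unif, replace = TRUE,
                     prob = genome$seqlengths)
    upos <- round(runif(n_unif, 1, genome$seqlengths[uchrom]))
    snps <- GenomicRanges::GRanges(
      c(prox_chrom, uchrom),
      IRanges::IRanges(pmin(pmax(c(prox_pos, upos), 1),
                            genome$seqlengths[c(prox_chrom, uchrom)]), width = 1),
      snp_id = sprintf("SYNSNP%03d", seq_len(params$n_snps)),
      planted = rep(c(TRUE, FALSE), c(n_prox, n_unif)))
    ## per-(cell type, condition) enhancer truth: centre +/- 500 of the
    ## active enhancer-class regions
    enhancer_truth <- list()
    for (ct in cts) for (cond in conds) {
      act <- peaks$class == "shared" |
        (peaks$class == "ct_specific" & peaks$cell_type == ct) |
        (peaks$class == "differential" & peaks$cell_type == ct) |
        (peaks$class == "exclusive" & peaks$cell_type == ct &
           peaks$condition == cond)
      sub <- peaks[act]
      enhancer_truth[[paste(ct, cond, sep = ".")]] <-
        GenomicRanges::GRanges(GenomeInfoDb::seqnames(sub),
                               IRanges::IRanges(sub$center - 500,
                                                sub$center + 499),
                               name = sub$name, class = sub$class)
    }
    structure(list(params = params, genome = genome, genes = genes,
                   peaks = peaks, blacklist = blacklist,
                   promoter_activity = pa, housekeeping = hk,
                   celltype_genes = ct_genes, pwms = panel,
                   motif_assignment = assign, snps = snps,
                   enhancer_truth = enhancer_truth),
              class = "landscape_truth")
  })
}

## active region table for one (cell type, condition) chip sample:
## planted peaks + promoter-activity regions + blacklist decoys
active_regions <- function(truth, cell_type, condition) {
  p <- truth$params
  pk <- truth$peaks
  act <- pk$class == "shared" |
    (pk$class == "ct_specific" & pk$cell_type == cell_type) |
    (pk$class == "differential" & pk$cell_type == cell_type) |
    (pk$class == "exclusive" & pk$cell_type == cell_type &
       pk$condition == condition)
  pk <- pk[act]
  w <- pk$weight
  ## differential fold applied symmetrically: the favoured condition gets
  ## sqrt(fold), the other 1/sqrt(fold), so the expected ratio is `fold`
  di <- pk$class == "differential"
  up_mut <- di & pk$direction == "up_in_MUT"
  dn_mut <- di & pk$direction == "down_in_MUT"
  f <- sqrt(pk$fold)
  if (condition == "MUT") {
    w[up_mut] <- w[up_mut] * f[up_mut]
    w[dn_mut] <- w[dn_mut] / f[dn_mut]
  } else {
    w[up_mut] <- w[up_mut] / f[up_mut]
    w[dn_mut] <- w[dn_mut] * f[dn_mut]
  }
  g <- truth$genes
  pa <- truth$promoter_activity[, cell_type]
  gi <- which(pa > 0)
  prom <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(g)[gi],
    IRanges::IRanges(pmax(g$tss[gi] - p$promoter_halfwidth, 1),
                     g$tss[gi] + p$promoter_halfwidth - 1))
  bl <- truth$blacklist
  data.frame(
    chrom = c(as.character(GenomeInfoDb::seqnames(pk)),
              as.character(GenomeInfoDb::seqnames(prom)),
              as.character(GenomeInfoDb::seqnames(bl))),
    center = c(pk$center,
               floor((start(prom) + end(prom)) / 2),
               floor((start(bl) + end(bl)) / 2)),
    width = c(width(pk), width(prom), width(bl)),
    weight = c(w, pa[gi], rep(p$blacklist_weight, length(bl))),
    class = c(pk$class, rep("promoter", length(prom)),
              rep("blacklist", length(bl))))
}

#' Simulate one sample's reads
#'
#' ChIP samples draw a FrIP-calibrated fraction of reads from the active
#' regions of their (cell type, condition), with per-region weights =
#' planted Gamma weight x condition fold multiplier x a per-biological-
#' replicate lognormal jitter (shared by technical replicates); read
#' positions are Normal(region centre, `summit_sd`). All remaining ChIP
#' reads, and all input reads, are uniform. Deterministic given
#' (seed, sample id).
#'
#' @param truth `landscape_truth`.
#' @param meta list/row with `sample_id`, `cell_type`, `condition`,
#'   `role`, `replicate`, and optionally `depth_factor` (scales the read
#'   count, default 1).
#' @param params [sim_params] (defaults to the truth's).
#' @return `GRanges` of reads (width `read_length`).
#' @export
simulate_sample <- function(truth, meta, params = truth$params) {
  L <- truth$genome$seqlengths
  depth <- if (!is.null(meta$depth_factor)) meta$depth_factor else 1
  rl <- params$read_length
  uniform_reads <- function(n) {
    chrom <- sample(names(L), n, replace = TRUE, prob = L)
    pos <- floor(runif(n, 1, L[chrom] - rl + 1))
    GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = rl))
  }
  if (meta$role == "input") {
    n <- round(params$n_reads_input * depth)
    return(with_seed(derive_seed(params$seed, "sample", meta$sample_id),
                     sort(uniform_reads(n))))
  }
  n <- round(params$n_reads_chip * depth)
  reg <- active_regions(truth, meta$cell_type, meta$condition)
  jitter <- with_seed(
    derive_seed(params$seed, "bio", meta$cell_type, meta$condition,
                meta$replicate),
    rlnorm(nrow(reg), 0, params$rep_sigma))
  w <- reg$weight * jitter
  ## calibrate the enriched fraction so downstream FrIP matches the
  ## target: uniform reads landing inside active regions also count
  f_bg <- sum(reg$width) / sum(L)
  p_enr <- min(max((params$target_frip - f_bg) / (1 - f_bg), 0), 1)
  with_seed(derive_seed(params$seed, "sample", meta$sample_id), {
    n_peak <- rbinom(1, n, p_enr)
    idx <- sample.int(nrow(reg), n_peak, replace = TRUE, prob = w)
    pos <- round(rnorm(n_peak, reg$center[idx], params$summit_sd)) -
      floor(rl / 2)
    pos <- pmin(pmax(pos, 1), L[reg$chrom[idx]] - rl + 1)
    peak_reads <- GenomicRanges::GRanges(reg$chrom[idx],
                                         IRanges::IRanges(pos, width = rl))
    sort(c(peak_reads, uniform_reads(n - n_peak)))
  })
}

#' Simulate a negative-binomial count matrix for test calibration
#'
#' Region means are log-normal, dispersions follow a 1/mu trend, and
#' sample depths vary; an optional fraction of regions carries a planted
#' symmetric fold change (numerator group x sqrt(fold), reference group
#' / sqrt(fold), alternating direction). Used to measure type-I error,
#' FDR and power of [nb_wald_test] at known truth.
#'
#' @param n_regions number of regions (default 2000).
#' @param n_per_group samples per condition (default 3).
#' @param frac_differential fraction of regions with a planted effect
#'   (default 0).
#' @param fold planted fold change (default 4).
#' @param seed RNG seed (default 17).
#' @param mean_log,sd_log log-normal parameters of region means.
#' @return List: `counts`, `condition` (`NC`/`MUT`), `truth`
#'   (data.frame with `differential` flag and `direction`).
#' @export
simulate_nb_counts <- function(n_regions = 2000, n_per_group = 3,
                               frac_differential = 0, fold = 4, seed = 17,
                               mean_log = log(100), sd_log = 0.7) {
  with_seed(seed, {
    mu <- rlnorm(n_regions, mean_log, sd_log)
    alpha <- 0.01 + 2 / mu
    sf <- runif(2 * n_per_group, 0.7, 1.4)
    condition <- rep(c("NC", "MUT"), each = n_per_group)
    n_diff <- round(n_regions * frac_differential)
    diff_idx <- if (n_diff) sample.int(n_regions, n_diff) else integer(0)
    direction <- rep(NA_character_, n_regions)
    direction[diff_idx] <- rep_len(c("up_in_MUT", "down_in_MUT"), n_diff)
    f <- sqrt(fold)
    mu_mat <- matrix(mu, n_regions, 2 * n_per_group)
    up <- which(direction == "up_in_MUT")
    dn <- which(direction == "down_in_MUT")
    mut_cols <- which(condition == "MUT")
    nc_cols <- which(condition == "NC")
    mu_mat[up, mut_cols] <- mu_mat[up, mut_cols] * f
    mu_mat[up, nc_cols] <- mu_mat[up, nc_cols] / f
    mu_mat[dn, mut_cols] <- mu_mat[dn, mut_cols] / f
    mu_mat[dn, nc_cols] <- mu_mat[dn, nc_cols] * f
    counts <- matrix(0L, n_regions, 2 * n_per_group)
    for (j in seq_len(2 * n_per_group))
      counts[, j] <- rnbinom(n_regions, mu = mu_mat[, j] * sf[j],
                             size = 1 / alpha)
    rownames(counts) <- paste0("region_", seq_len(n_regions))
    colnames(counts) <- paste0(condition, "_", rep(seq_len(n_per_group), 2))
    list(counts = counts, condition = condition,
         truth = data.frame(region = rownames(counts),
                            differential = !is.na(direction),
                            direction = direction))
  })
}

## fast 3-column BED writer/reader for read files (internal; these files
## are the package's own output format)
write_reads_bed <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(as.character(GenomeInfoDb::seqnames(reads)),
                   format(start(reads) - 1, scientific = FALSE, trim = TRUE),
                   format(end(reads), scientific = FALSE, trim = TRUE),
                   sep = "\t"), con)
  invisible(path)
}

read_reads_bed <- function(path, genome = NULL) {
  v <- scan(path, what = list(chrom = "", start = 0, end = 0),
            sep = "\t", quiet = TRUE)
  if (!is.null(genome)) check_chroms(v$chrom, genome, sprintf("file %s", path))
  GenomicRanges::GRanges(v$chrom, IRanges::IRanges(v$start + 1, v$end))
}

#' Simulate and write a complete study
#'
#' Generates the genome, plants the landscape, simulates every sample of
#' the design (per cell type and condition: `n_replicates` ChIP
#' biological replicates and one input), and writes all pipeline inputs
#' plus a `truth/` directory to `dir`.
#'
#' @param params [sim_params].
#' @param dir output directory (created).
#' @param extra_samples optional `data.frame` of additional samples with
#'   columns `sample_id`, `cell_type`, `condition`, `mark`, `replicate`,
#'   `tech_rep`, `role`, `depth_factor` (e.g. extra technical replicates
#'   or deliberately shallow ones).
#' @return Invisibly, a list with `dir`, `truth`, and the sample
#'   `sheet`.
#' @export
simulate_study <- function(params = sim_params(), dir, extra_samples = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "reads"), showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  ga <- generate_genome_and_annotation(params)
  truth <- plant_landscape(ga$genome, ga$genes, params)
  ## design
  sheet <- list()
  for (ct in params$cell_types) for (cond in params$conditions) {
    for (r in seq_len(params$n_replicates))
      sheet[[length(sheet) + 1]] <- data.frame(
        sample_id = sprintf("%s_%s_rep%d", ct, cond, r),
        cell_type = ct, condition = cond, mark = params$mark,
        replicate = r, tech_rep = 1, role = "chip", depth_factor = 1)
    sheet[[length(sheet) + 1]] <- data.frame(
      sample_id = sprintf("%s_%s_input", ct, cond),
      cell_type = ct, condition = cond, mark = params$mark,
      replicate = 1, tech_rep = 1, role = "input", depth_factor = 1)
  }
  sheet <- do.call(rbind, sheet)
  if (!is.null(extra_samples)) {
    if (is.null(extra_samples$depth_factor)) extra_samples$depth_factor <- 1
    sheet <- rbind(sheet, extra_samples[names(sheet)])
  }
  sheet$reads_path <- file.path("reads", paste0(sheet$sample_id, ".bed"))
  for (i in seq_len(nrow(sheet))) {
    reads <- simulate_sample(truth, as.list(sheet[i, ]), params)
    write_reads_bed(reads, file.path(dir, sheet$reads_path[i]))
  }
  ## pipeline inputs
  Biostrings::writeXStringSet(truth$genome$sequences, file.path(dir, "genome.fa"))
  write_chrom_sizes(truth$genome, file.path(dir, "chrom.sizes"))
  write_tss(truth$genes, file.path(dir, "tss.bed"))
  write_snps(truth$snps, file.path(dir, "snps.bed"))
  write_regions(truth$blacklist, file.path(dir, "blacklist.bed"), "bed")
  write_pwms(truth$pwms, file.path(dir, "pwms.txt"))
  utils::write.table(sheet, file.path(dir, "sample_sheet.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass(params), file.path(dir, "params.yaml"))
  ## truth exports: enough to score every recovery test from disk
  pk <- truth$peaks
  pk_out <- pk
  pk_out$name <- paste(pk$name, pk$class,
                       ifelse(is.na(pk$cell_type), ".", pk$cell_type),
                       ifelse(is.na(pk$condition), ".", pk$condition),
                       sep = "|")
  pk_out$score <- 0
  write_regions(pk_out, file.path(dir, "truth", "peaks.bed"), "bed")
  for (grp in names(truth$enhancer_truth)) {
    e <- truth$enhancer_truth[[grp]]
    e$score <- 0
    write_regions(e, file.path(dir, "truth", paste0("enhancers_", grp, ".bed")),
                  "bed")
  }
  di <- pk[pk$class == "differential"]
  di$name <- paste(di$name, di$cell_type, di$direction, di$fold, sep = "|")
  di$score <- 0
  write_regions(di, file.path(dir, "truth", "differential.bed"), "bed")
  jsonlite::write_json(
    list(celltype_genes = truth$celltype_genes,
         housekeeping = truth$housekeeping,
         motif_assignment = truth$motif_assignment,
         planted_snps = truth$snps$snp_id[truth$snps$planted],
         scenario = params$scenario),
    file.path(dir, "truth", "truth.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(list(dir = dir, truth = truth, sheet = sheet))
}
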