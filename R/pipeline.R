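## Orchestration: simulate -> signal -> peaks -> differential ->
## enhancers -> motifs, with one config, a manifest of artifacts and a
## summary report. Stages are deterministic given the config seed; a
## completed run is resumed (no-op) unless `force = TRUE`.

#' Pipeline configuration
#'
#' Paths and thresholds for [run_pipeline]. Defaults are the full-genome
#' scale values (min_peaks = 10000 called peaks per technical replicate,
#' 150-kb SNP window); [synthetic_config] rescales the two genome-scale
#' thresholds for the desk-sized synthetic genome.
#'
#' @param data_dir directory containing `chrom.sizes`, `tss.bed`,
#'   `sample_sheet.csv`, `reads/`, and optionally `genome.fa`,
#'   `blacklist.bed`, `snps.bed`, `pwms.txt`, `truth/`.
#' @param out_dir output directory.
#' @param ... overrides for any threshold (see function body).
#' @return Named list (class `pipeline_config`).
#' @export
pipeline_config <- function(data_dir, out_dir, ...) {
  cfg <- list(
    data_dir = data_dir, out_dir = out_dir,
    mark = "H3K27ac",
    binsize = 100, read_flank = 100,
    q_peak = 0.05, local_window = 10000, peak_min_width = 200,
    min_peaks = 10000,
    fc = 2, fdr = 0.05,
    motif_alpha = 1e-4, motif_threshold = 0.8, motif_bg_copies = 2,
    snp_window = 150000,
    promoter_flank = 500, enhancer_half_width = 500,
    correlation_flank = 2000,
    celltype_genes = NULL,       # named list of gene-id vectors, or JSON path
    seed = 1, force = FALSE)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stopf("pipeline_config: unknown option(s): %s",
                         paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  if (any(unlist(cfg[c("binsize", "q_peak", "fc", "fdr", "motif_alpha",
                       "snp_window", "promoter_flank", "enhancer_half_width",
                       "correlation_flank")]) <= 0))
    stopf("pipeline_config: thresholds must be positive")
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @export
synthetic_config <- function(data_dir, out_dir, ...) {
  defaults <- list(min_peaks = 300, snp_window = 5000)
  over <- list(...)
  defaults[names(over)] <- over
  ## point gene-change scoring at the generator's truth lists when present
  tj <- file.path(data_dir, "truth", "truth.json")
  if (is.null(defaults$celltype_genes) && file.exists(tj))
    defaults$celltype_genes <- tj
  do.call(pipeline_config, c(list(data_dir = data_dir, out_dir = out_dir),
                             defaults))
}

## sum coverage tracks (pooling technical replicates)
pool_coverage <- function(tracks) {
  out <- tracks[[1]]
  if (length(tracks) > 1) {
    for (t in tracks[-1]) {
      for (ch in names(out$values))
        out$values[[ch]] <- out$values[[ch]] + t$values[[ch]]
      out$n_reads <- out$n_reads + t$n_reads
    }
  }
  out
}

#' Extract region sequences from a genome
#'
#' @param genome [chip_genome] with sequence.
#' @param gr `GRanges`.
#' @return Character vector of sequences, one per range.
#' @export
region_sequences <- function(genome, gr) {
  if (is.null(genome$sequences))
    stopf("region_sequences: genome carries no sequence")
  out <- character(length(gr))
  chrom <- as.character(GenomeInfoDb::seqnames(gr))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    at <- IRanges::IRanges(start(gr)[i], end(gr)[i])
    out[i] <- as.character(Biostrings::extractAt(genome$sequences[[ch]], at))
  }
  out
}

#' Run the full comparative pipeline
#'
#' Stages: load inputs; binned coverage and normalized signal per sample;
#' peak calling per technical replicate with peak-count QC; pooling of
#' retained technical replicates per biological replicate; blacklist
#' filtering; majority-rules consensus per (cell type, condition) and the
#' master set; per-cell-type NB Wald differential test and selection;
#' promoter-matrix correlation; enhancer calling with all enhancer-level
#' analyses; motif enrichment with condition-differential,
#' cell-type-specific and preservation logic (when a genome FASTA and a
#' PWM panel are available). Artifacts are written under
#' `config$out_dir` with a `manifest.json`; a finished run is returned
#' from disk unless `config$force`.
#'
#' @param config [pipeline_config] or [synthetic_config].
#' @return A `pipeline_report` list.
#' @export
run_pipeline <- function(config) {
  dd <- config$data_dir
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  rds <- file.path(out, "report.rds")
  if (file.exists(rds) && !isTRUE(config$force)) {
    rep <- readRDS(rds)
    rep$resumed <- TRUE
    return(rep)
  }
  manifest <- character(0)
  emit <- function(path) { manifest <<- c(manifest, path); path }

  ## ---- load ----
  genome <- read_chrom_sizes(file.path(dd, "chrom.sizes"))
  fa <- file.path(dd, "genome.fa")
  if (file.exists(fa)) genome <- load_genome_fasta(fa, genome)
  genes <- read_tss(file.path(dd, "tss.bed"), genome)
  bl_path <- file.path(dd, "blacklist.bed")
  blacklist <- if (file.exists(bl_path)) read_regions(bl_path, "bed", genome)
               else GenomicRanges::GRanges()
  snp_path <- file.path(dd, "snps.bed")
  snps <- if (file.exists(snp_path)) read_snps(snp_path, genome) else NULL
  pwm_path <- file.path(dd, "pwms.txt")
  pwms <- if (file.exists(pwm_path)) read_pwms(pwm_path) else NULL
  sheet <- read_sample_sheet(file.path(dd, "sample_sheet.csv"))
  sheet <- sheet[sheet$mark == config$mark, , drop = FALSE]
  if (!nrow(sheet)) stopf("run_pipeline: no samples with mark %s", config$mark)
  if (is.null(sheet$reads_path))
    sheet$reads_path <- file.path("reads", paste0(sheet$sample_id, ".bed"))

  ## ---- coverage per sample ----
  cov <- list()
  for (i in seq_len(nrow(sheet))) {
    reads <- read_reads_bed(file.path(dd, sheet$reads_path[i]), genome)
    reads <- extend_reads(reads, genome, config$read_flank)
    cov[[sheet$sample_id[i]]] <- make_coverage(reads, genome, config$binsize)
  }
  chips <- sheet[sheet$role == "chip", , drop = FALSE]
  inputs <- sheet[sheet$role == "input", , drop = FALSE]
  input_of <- function(ct, cond) {
    i <- which(inputs$cell_type == ct & inputs$condition == cond)
    if (!length(i)) stopf("run_pipeline: no input sample for %s/%s", ct, cond)
    inputs$sample_id[i[1]]
  }

  ## ---- peaks: per technical replicate, QC, pooling, consensus ----
  tech_peaks <- list()
  for (i in seq_len(nrow(chips))) {
    sid <- chips$sample_id[i]
    tech_peaks[[sid]] <- call_peaks_poisson(
      cov[[sid]], cov[[input_of(chips$cell_type[i], chips$condition[i])]],
      q_threshold = config$q_peak, local_window = config$local_window,
      min_width = config$peak_min_width)
  }
  qc <- qc_filter(tech_peaks, chips, min_peaks = config$min_peaks)
  utils::write.table(qc$report, emit(file.path(out, "qc_report.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  kept <- chips[chips$sample_id %in% qc$kept, , drop = FALSE]
  ## pool retained technical replicates of one cell sample
  kept$bio_id <- sprintf("%s_%s_rep%s", kept$cell_type, kept$condition,
                         kept$replicate)
  bio <- unique(kept[c("bio_id", "cell_type", "condition", "replicate")])
  bio_cov <- list(); bio_paths <- list()
  for (i in seq_len(nrow(bio))) {
    members <- kept$sample_id[kept$bio_id == bio$bio_id[i]]
    bio_cov[[bio$bio_id[i]]] <- pool_coverage(cov[members])
    bio_paths[[bio$bio_id[i]]] <-
      file.path(dd, kept$reads_path[match(members, kept$sample_id)])
  }
  bio_signal <- list(); bio_peaks <- list()
  for (i in seq_len(nrow(bio))) {
    bid <- bio$bio_id[i]
    icov <- cov[[input_of(bio$cell_type[i], bio$condition[i])]]
    bio_signal[[bid]] <- normalized_signal(bio_cov[[bid]], icov)
    pk <- call_peaks_poisson(bio_cov[[bid]], icov,
                             q_threshold = config$q_peak,
                             local_window = config$local_window,
                             min_width = config$peak_min_width)
    bio_peaks[[bid]] <- remove_blacklist(pk, blacklist)
  }
  bio$group <- paste(bio$cell_type, bio$condition, sep = ".")
  consensus <- list()
  for (g in unique(bio$group)) {
    consensus[[g]] <- consensus_majority(bio_peaks[bio$bio_id[bio$group == g]])
    cons_out <- consensus[[g]]
    cons_out$name <- paste0(g, "_", seq_along(cons_out))
    cons_out$score <- cons_out$support
    write_regions(cons_out,
                  emit(file.path(out, paste0("consensus_", g, ".bed"))), "bed")
  }
  master <- master_set(consensus)
  master_out <- master
  master_out$score <- master_out$n_sources
  write_regions(master_out, emit(file.path(out, "master.bed")), "bed")

  ## ---- counting pass: reads per bio replicate on the master set ----
  counts <- matrix(0L, length(master), nrow(bio),
                   dimnames = list(master$name, bio$bio_id))
  frip_tab <- data.frame(bio_id = bio$bio_id, frip = NA_real_)
  for (i in seq_len(nrow(bio))) {
    reads <- do.call(c, unname(lapply(bio_paths[[bio$bio_id[i]]],
                                      read_reads_bed, genome = genome)))
    reads <- extend_reads(reads, genome, config$read_flank)
    counts[, i] <- GenomicRanges::countOverlaps(master, reads,
                                                minoverlap = 1L,
                                                ignore.strand = TRUE)
    frip_tab$frip[i] <- frip(reads, bio_peaks[[bio$bio_id[i]]])
  }
  utils::write.table(frip_tab, emit(file.path(out, "frip.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(region = rownames(counts), counts,
                                check.names = FALSE),
                     emit(file.path(out, "counts.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## ---- differential per cell type ----
  cell_types <- unique(bio$cell_type)
  sig_mat <- region_signal(bio_signal, master)
  differential <- list(); signal_comparison <- list()
  for (ct in cell_types) {
    idx <- which(bio$cell_type == ct)
    if (length(unique(bio$condition[idx])) < 2) next
    res <- nb_wald_test(counts[, idx, drop = FALSE], bio$condition[idx])
    sel <- select_significant(res, fc = config$fc, fdr = config$fdr)
    differential[[ct]] <- list(result = res, selected = sel)
    utils::write.table(res, emit(file.path(out, paste0("differential_", ct, ".tsv"))),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sig_gr <- master[match(sel$selected$region, master$name)]
    sig_gr$direction <- sel$selected$direction
    sig_gr$name <- paste(sel$selected$region, sel$selected$direction, sep = "|")
    sig_gr$score <- 0
    write_regions(sig_gr, emit(file.path(out, paste0("significant_", ct, ".bed"))),
                  "bed")
    signal_comparison[[ct]] <- allpeak_signal_comparison(
      sig_mat[, idx, drop = FALSE], bio$condition[idx])
    ## heatmap input: per-row-scaled normalized counts of the selected
    ## regions (z-score across this cell type's samples)
    if (nrow(sel$selected)) {
      q <- sweep(counts[sel$selected$region, idx, drop = FALSE], 2,
                 size_factors(counts[, idx, drop = FALSE]), "/")
      z <- t(scale(t(q)))
      utils::write.table(data.frame(region = rownames(z), round(z, 4),
                                    check.names = FALSE),
                         emit(file.path(out, paste0("heatmap_", ct, ".tsv"))),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  ## ---- promoter-matrix correlation ----
  pmat <- promoter_matrix(bio_signal, genes, flank = config$correlation_flank)
  correlation <- pearson_matrix(pmat)
  utils::write.table(round(correlation, 6),
                     emit(file.path(out, "correlation.tsv")),
                     sep = "\t", quote = FALSE)

  ## ---- enhancers per cell type ----
  ct_genes <- config$celltype_genes
  if (is.character(ct_genes) && length(ct_genes) == 1 && file.exists(ct_genes)) {
    tj <- jsonlite::read_json(ct_genes, simplifyVector = TRUE)
    ct_genes <- if (!is.null(tj$celltype_genes)) tj$celltype_genes else tj
  }
  enhancers <- list(); snp_fractions <- list(); locations <- list()
  gene_changes <- list()
  for (ct in cell_types) {
    grp <- paste(ct, c("NC", "MUT"), sep = ".")
    have <- grp[grp %in% names(consensus)]
    if (!length(have)) next
    sets <- consensus[have]
    names(sets) <- sub("^.*\\.", "", have)
    es <- call_enhancers(sets, genes, genome, cell_type = ct,
                         half_width = config$enhancer_half_width,
                         promoter_flank = config$promoter_flank)
    enhancers[[ct]] <- es
    for (cond in names(es$by_condition)) {
      e <- es$by_condition[[cond]]
      e$name <- paste(ct, cond, seq_along(e), sep = "|")
      e$score <- if (!is.null(e$support)) e$support else 0
      write_regions(e, emit(file.path(out, sprintf("enhancers_%s_%s.bed", ct, cond))),
                    "bed")
      if (!is.null(snps))
        snp_fractions[[paste(ct, cond, sep = ".")]] <-
          snp_fraction(e, snps, window = config$snp_window)$fraction
    }
    locations[[ct]] <- annotate_locations(es$union, genes,
                                          promoter_flank = config$promoter_flank)$distribution
    if (!is.null(ct_genes) && !is.null(ct_genes[[ct]]) &&
        !is.null(differential[[ct]])) {
      sel <- differential[[ct]]$selected$selected
      sig_gr <- master[match(sel$region, master$name)]
      sig_gr$direction <- sel$direction
      gene_changes[[ct]] <- gene_change_fraction(sig_gr, ct_genes[[ct]], genes)
    }
  }
  venn <- do.call(rbind, lapply(enhancers, function(e) e$venn))
  if (!is.null(venn)) {
    utils::write.table(data.frame(cell_type = rownames(venn), venn),
                       emit(file.path(out, "enhancer_venn.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (length(locations)) {
    loc <- do.call(rbind, locations)
    utils::write.table(data.frame(cell_type = names(locations),
                                  round(loc, 4)),
                       emit(file.path(out, "enhancer_locations.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (length(snp_fractions))
    utils::write.table(
      data.frame(group = names(snp_fractions),
                 fraction = unlist(snp_fractions)),
      emit(file.path(out, "snp_fractions.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)

  ## ---- motifs ----
  motifs <- NULL
  if (!is.null(pwms) && !is.null(genome$sequences) && length(enhancers)) {
    seq_sets <- list()
    for (ct in names(enhancers))
      for (cond in names(enhancers[[ct]]$by_condition)) {
        e <- enhancers[[ct]]$by_condition[[cond]]
        if (length(e))
          seq_sets[[paste(ct, cond, sep = ".")]] <- region_sequences(genome, e)
      }
    table <- motif_enrichment_table(seq_sets, pwms,
                                    threshold = config$motif_threshold,
                                    bg_copies = config$motif_bg_copies,
                                    seed = config$seed)
    utils::write.table(table, emit(file.path(out, "motif_enrichment.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ## heatmap-style matrix: -log10 p per motif x group, non-significant
    ## entries masked
    neg <- -log10(pmax(table$p_value, 1e-300))
    neg[table$p_value >= config$motif_alpha] <- NA
    hm <- matrix(NA_real_, length(unique(table$motif)),
                 length(unique(table$group)),
                 dimnames = list(unique(table$motif), unique(table$group)))
    hm[cbind(table$motif, table$group)] <- neg
    utils::write.table(data.frame(motif = rownames(hm), round(hm, 3),
                                  check.names = FALSE),
                       emit(file.path(out, "motif_heatmap.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cond_diff <- lapply(setNames(nm = names(enhancers)), function(ct)
      condition_differential_motifs(table, ct, alpha = config$motif_alpha))
    epithelial <- intersect(c("BC", "LP", "ML"), names(enhancers))
    specific <- preservation <- NULL
    if (length(epithelial) >= 2) {
      specific <- celltype_specific_tfs(table, cell_types = epithelial,
                                        condition = "NC",
                                        alpha = config$motif_alpha)
      preservation <- mut_preservation(specific, table, condition = "MUT",
                                       alpha = config$motif_alpha)
      utils::write.table(preservation, emit(file.path(out, "tf_preservation.tsv")),
                         sep = "\t", quote = FALSE)
    }
    motifs <- list(table = table, condition_differential = cond_diff,
                   specific = specific, preservation = preservation)
  }

  ## ---- report ----
  report <- structure(list(
    config = config, sheet = sheet, qc = qc, bio = bio,
    consensus = consensus, master = master, counts = counts,
    frip = frip_tab, differential = differential,
    signal_comparison = signal_comparison,
    correlation = correlation, promoter_matrix = pmat,
    enhancers = enhancers, locations = locations,
    snp_fractions = snp_fractions, gene_changes = gene_changes,
    motifs = motifs, resumed = FALSE), class = "pipeline_report")
  summary <- pipeline_summary(report)
  jsonlite::write_json(summary, emit(file.path(out, "summary.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  saveRDS(report, emit(rds))
  jsonlite::write_json(list(out_dir = out, files = basename(manifest)),
                       file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  report
}

#' Condensed numeric summary of a pipeline report
#'
#' @param report `pipeline_report` from [run_pipeline].
#' @return Nested list of the headline numbers (differential counts per
#'   cell type, enhancer Venn classes, SNP-proximal fractions, TF
#'   preservation matrix, QC decisions).
#' @export
pipeline_summary <- function(report) {
  list(
    n_samples = nrow(report$sheet),
    qc_dropped = report$qc$dropped,
    n_master = length(report$master),
    differential = lapply(report$differential, function(d)
      list(up = nrow(d$selected$up), down = nrow(d$selected$down))),
    signal_comparison = report$signal_comparison,
    enhancer_venn = lapply(report$enhancers, function(e) as.list(e$venn)),
    snp_fractions = report$snp_fractions,
    gene_changes = lapply(report$gene_changes, function(g)
      g[c("n_changed", "n_total", "fraction", "fraction_down")]),
    tf_preservation = if (!is.null(report$motifs$preservation))
      as.data.frame(report$motifs$preservation) else NULL)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d samples, %d master regions%s\n",
              nrow(x$sheet), length(x$master),
              if (isTRUE(x$resumed)) " (resumed)" else ""))
  for (ct in names(x$differential))
    cat(sprintf("  %s: %d up / %d down differential regions\n", ct,
                nrow(x$differential[[ct]]$selected$up),
                nrow(x$differential[[ct]]$selected$down)))
  invisible(x)
}

#' Score pipeline recovery against planted truth
#'
#' Compares a pipeline report against the `landscape_truth` it was
#' simulated from: peak recall/precision, enhancer Jaccard and promoter
#' violations, differential recall and sign accuracy, SNP-fraction
#' contrast, and planted-motif recovery.
#'
#' @param report `pipeline_report`.
#' @param truth `landscape_truth`.
#' @return Named list of scores.
#' @export
score_recovery <- function(report, truth) {
  params <- truth$params
  ## peak recall/precision per biological replicate vs the active truth
  recalls <- precisions <- numeric(0)
  for (g in names(report$consensus)) {
    parts <- strsplit(g, ".", fixed = TRUE)[[1]]
    act <- active_regions(truth, parts[1], parts[2])
    act <- act[act$class != "blacklist", ]
    tgr <- GenomicRanges::GRanges(act$chrom,
                                  IRanges::IRanges(act$center - act$width %/% 2,
                                                   act$center + act$width %/% 2))
    called <- report$consensus[[g]]
    recalls <- c(recalls,
                 mean(GenomicRanges::countOverlaps(tgr, called,
                                                   ignore.strand = TRUE) > 0))
    precisions <- c(precisions,
                    mean(GenomicRanges::countOverlaps(called, tgr,
                                                      ignore.strand = TRUE) > 0))
  }
  ## enhancer recovery
  jac <- numeric(0)
  prom_viol <- 0
  prom <- promoter_windows(truth$genes, 500)
  for (ct in names(report$enhancers))
    for (cond in names(report$enhancers[[ct]]$by_condition)) {
      e <- report$enhancers[[ct]]$by_condition[[cond]]
      key <- paste(ct, cond, sep = ".")
      if (!is.null(truth$enhancer_truth[[key]]))
        jac <- c(jac, region_jaccard(e, truth$enhancer_truth[[key]]))
      prom_viol <- prom_viol +
        sum(GenomicRanges::countOverlaps(e, prom, ignore.strand = TRUE) > 0)
    }
  ## differential recovery (planted fold regions, per cell type)
  diff_recall <- sign_ok <- numeric(0)
  for (ct in names(report$differential)) {
    tr <- truth$peaks[truth$peaks$class == "differential" &
                        truth$peaks$cell_type == ct]
    if (!length(tr)) next
    sel <- report$differential[[ct]]$selected$selected
    if (!nrow(sel)) { diff_recall <- c(diff_recall, 0); next }
    sel_gr <- report$master[match(sel$region, report$master$name)]
    h <- GenomicRanges::findOverlaps(tr, sel_gr, ignore.strand = TRUE)
    diff_recall <- c(diff_recall,
                     length(unique(S4Vectors::queryHits(h))) / length(tr))
    agree <- tr$direction[S4Vectors::queryHits(h)] ==
      sel$direction[S4Vectors::subjectHits(h)]
    sign_ok <- c(sign_ok, mean(agree))
  }
  out <- list(
    peak_recall = mean(recalls), peak_precision = mean(precisions),
    enhancer_jaccard_mean = mean(jac), enhancer_jaccard_min = min(jac),
    promoter_violations = prom_viol,
    differential_recall = mean(diff_recall),
    differential_sign_accuracy = mean(sign_ok),
    snp_fraction_nc_bc = report$snp_fractions[["BC.NC"]],
    snp_fraction_mut_bc = report$snp_fractions[["BC.MUT"]])
  ## planted-motif recovery
  if (!is.null(report$motifs)) {
    tab <- report$motifs$table
    asg <- truth$motif_assignment
    top_rank <- p_target <- numeric(0)
    for (ct in intersect(unique(asg$cell_type[asg$role == "ct_specific"]),
                         unique(tab$cell_type))) {
      m <- asg$motif[asg$role == "ct_specific" & asg$cell_type == ct]
      sub <- tab[tab$cell_type == ct & tab$condition == "NC", ]
      top_rank <- c(top_rank, rank(sub$p_value, ties.method = "min")[sub$motif == m])
      p_target <- c(p_target, sub$p_value[sub$motif == m])
    }
    out$motif_top_rank_max <- max(top_rank)
    out$motif_target_p_max <- max(p_target)
    if (!is.null(report$motifs$preservation)) {
      P <- report$motifs$preservation
      if (all(c("BC", "LP") %in% rownames(P))) {
        out$gained_bc_from_lp <- P["BC", "LP"]
        out$gained_lp_from_bc <- P["LP", "BC"]
      }
    }
  }
  out
}
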