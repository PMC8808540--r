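## Readers and writers for every on-disk format the pipeline touches.
## File coordinates are 0-based half-open (BED native); internally
## everything is a GRanges (1-based closed). The conversion happens here
## and only here.

.np_cols <- c("chrom", "start", "end", "name", "score", "strand",
              "signalValue", "pValue", "qValue", "peak")

#' Read regions from BED or ENCODE narrowPeak
#'
#' BED gives plain intervals; narrowPeak additionally carries a caller
#' score, signal, -log10 p/q and a summit offset (column 10). A summit
#' offset of -1 (the dialect's missing-summit marker) maps to the interval
#' midpoint. Malformed lines raise an error naming the line number;
#' chromosomes absent from `genome` raise an error naming the chromosome.
#'
#' @param path input file.
#' @param dialect `"bed"` (3-6 columns) or `"narrowPeak"` (10 columns).
#' @param genome optional [chip_genome] used to validate chromosome names.
#' @return A `GRanges`. For narrowPeak, metadata columns `name`, `score`,
#'   `signalValue`, `pValue`, `qValue` (the raw -log10 value), `peak`
#'   (raw column 10), `summit` (absolute 1-based summit position) and
#'   `qvalue` (linear-scale q in \[0,1\]).
#' @export
read_regions <- function(path, dialect = c("bed", "narrowPeak"), genome = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("file does not exist: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(GenomicRanges::GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  need <- if (dialect == "bed") 3L else 10L
  bad <- which(nf < need)
  if (length(bad))
    stopf("malformed %s line %d in %s: expected >= %d fields, got %d",
          dialect, bad[1], path, need, nf[bad[1]])
  chrom <- vapply(fields, `[[`, "", 1L)
  s0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  e0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(s0) | is.na(e0) | s0 < 0 | s0 >= e0)
  if (length(bad))
    stopf("malformed %s line %d in %s: invalid coordinates", dialect, bad[1], path)
  if (!is.null(genome)) check_chroms(chrom, genome, sprintf("file %s", path))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s0 + 1, e0))
  if (dialect == "bed") {
    if (all(nf >= 4L)) gr$name <- vapply(fields, `[[`, "", 4L)
    if (all(nf >= 5L))
      gr$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
    if (all(nf >= 6L)) {
      st <- vapply(fields, `[[`, "", 6L)
      strand(gr) <- ifelse(st %in% c("+", "-"), st, "*")
    }
    return(gr)
  }
  gr$name <- vapply(fields, `[[`, "", 4L)
  gr$score <- as.numeric(vapply(fields, `[[`, "", 5L))
  st <- vapply(fields, `[[`, "", 6L)
  strand(gr) <- ifelse(st %in% c("+", "-"), st, "*")
  gr$signalValue <- as.numeric(vapply(fields, `[[`, "", 7L))
  gr$pValue <- as.numeric(vapply(fields, `[[`, "", 8L))
  gr$qValue <- as.numeric(vapply(fields, `[[`, "", 9L))
  peak <- as.numeric(vapply(fields, `[[`, "", 10L))
  bad <- which(peak != -1 & (peak < 0 | peak >= e0 - s0))
  if (length(bad))
    stopf("malformed narrowPeak line %d in %s: summit offset outside interval",
          bad[1], path)
  gr$peak <- peak
  ## absolute 1-based summit; -1 -> midpoint
  off0 <- ifelse(peak == -1, floor((e0 - s0) / 2), peak)
  gr$summit <- s0 + off0 + 1
  gr$qvalue <- ifelse(gr$qValue < 0, 1, 10^(-gr$qValue))
  gr
}

#' Write regions to BED or narrowPeak
#'
#' Inverse of [read_regions]; coordinates round-trip bit-exactly.
#'
#' @param gr a `GRanges` (for narrowPeak with the metadata columns
#'   produced by [read_regions] or [call_peaks_poisson]).
#' @inheritParams read_regions
#' @export
write_regions <- function(gr, path, dialect = c("bed", "narrowPeak")) {
  dialect <- match.arg(dialect)
  chrom <- as.character(GenomeInfoDb::seqnames(gr))
  s0 <- format(start(gr) - 1, scientific = FALSE, trim = TRUE)
  e0 <- format(end(gr), scientific = FALSE, trim = TRUE)
  mc <- S4Vectors::mcols(gr)
  if (dialect == "bed") {
    df <- data.frame(chrom, s0, e0)
    if (!is.null(mc$name)) {
      df$name <- mc$name
      df$score <- if (is.null(mc$score)) 0 else mc$score
      df$strand <- as.character(strand(gr))
      df$strand[df$strand == "*"] <- "."
    }
  } else {
    fmt <- function(x) ifelse(x == round(x),
                              format(x, scientific = FALSE, trim = TRUE),
                              format(x, trim = TRUE))
    st <- as.character(strand(gr)); st[st == "*"] <- "."
    peak <- if (!is.null(mc$peak)) mc$peak else mc$summit - start(gr)
    df <- data.frame(chrom, s0, e0,
                     name = if (is.null(mc$name)) "." else mc$name,
                     score = if (is.null(mc$score)) 0 else mc$score,
                     strand = st,
                     signalValue = fmt(if (is.null(mc$signalValue)) 0 else mc$signalValue),
                     pValue = fmt(if (is.null(mc$pValue)) -1 else mc$pValue),
                     qValue = fmt(if (is.null(mc$qValue)) -1 else mc$qValue),
                     peak = format(peak, scientific = FALSE, trim = TRUE))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a TSS/gene table
#'
#' Expects a BED6-like table of gene spans: chrom, start, end, gene_id,
#' score, strand (0-based half-open). The TSS is the 5' end of the span
#' per strand. Gene ids must be unique.
#'
#' @param path input file.
#' @param genome optional [chip_genome] for bounds validation.
#' @return A `GRanges` of gene spans with metadata `gene_id` and `tss`
#'   (absolute 1-based TSS position).
#' @export
read_tss <- function(path, genome = NULL) {
  gr <- read_regions(path, "bed", genome)
  if (is.null(gr$name)) stopf("TSS table %s lacks gene ids (column 4)", path)
  if (anyDuplicated(gr$name))
    stopf("duplicate gene_id in %s: %s", path,
          gr$name[anyDuplicated(gr$name)][1])
  if (any(!as.character(strand(gr)) %in% c("+", "-")))
    stopf("TSS table %s needs explicit +/- strands", path)
  gr$gene_id <- gr$name
  gr$tss <- ifelse(as.character(strand(gr)) == "+", start(gr), end(gr))
  if (!is.null(genome)) {
    sl <- genome$seqlengths[as.character(GenomeInfoDb::seqnames(gr))]
    if (any(gr$tss < 1 | gr$tss > sl)) stopf("TSS outside chromosome bounds in %s", path)
  }
  gr
}

#' @rdname read_tss
#' @param genes `GRanges` as returned by [read_tss].
#' @export
write_tss <- function(genes, path) {
  g <- genes
  g$name <- g$gene_id
  g$score <- 0
  write_regions(g, path, "bed")
}

#' Read a SNP list (BED3 + name)
#'
#' @inheritParams read_tss
#' @return A width-1 `GRanges` with metadata `snp_id`.
#' @export
read_snps <- function(path, genome = NULL) {
  gr <- read_regions(path, "bed", genome)
  gr$snp_id <- if (is.null(gr$name)) paste0("snp", seq_along(gr)) else gr$name
  GenomicRanges::GRanges(GenomeInfoDb::seqnames(gr),
                         IRanges::IRanges(start(gr), width = 1),
                         snp_id = gr$snp_id)
}

#' @rdname read_snps
#' @param snps width-1 `GRanges` with `snp_id`.
#' @export
write_snps <- function(snps, path) {
  s <- snps
  s$name <- s$snp_id
  s$score <- 0
  write_regions(s, path, "bed")
}

#' Read a sample sheet
#'
#' CSV with columns `sample_id`, `cell_type`, `condition`, `mark`,
#' `replicate`, `tech_rep`, `role` and optionally `reads_path`. The key
#' (cell_type, condition, mark, replicate, tech_rep, role) must be unique.
#'
#' @param path CSV file.
#' @return A `data.frame`.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = ",",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "cell_type", "condition", "mark",
            "replicate", "tech_rep", "role")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("sample sheet %s lacks columns: %s",
                          path, paste(miss, collapse = ", "))
  if (!all(df$role %in% c("chip", "input")))
    stopf("sample sheet role must be chip or input")
  key <- do.call(paste, df[c("cell_type", "condition", "mark",
                             "replicate", "tech_rep", "role")])
  if (anyDuplicated(key))
    stopf("duplicate sample key in %s: %s", path, key[anyDuplicated(key)][1])
  if (anyDuplicated(df$sample_id))
    stopf("duplicate sample_id in %s", path)
  df
}

#' Export a signal track as bedGraph
#'
#' Four columns, fixed `bin`-sized steps, 0-based half-open, last bin
#' clipped at the chromosome end.
#'
#' @param track a `signal_track` or `coverage_track`.
#' @param path output file.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(track$values)) {
    v <- track$values[[chrom]]
    n <- length(v)
    s0 <- (seq_len(n) - 1) * track$binsize
    e0 <- pmin(s0 + track$binsize, track$seqlengths[[chrom]])
    writeLines(sprintf("%s\t%s\t%s\t%s", chrom,
                       format(s0, scientific = FALSE, trim = TRUE),
                       format(e0, scientific = FALSE, trim = TRUE),
                       format(v, trim = TRUE)), con)
  }
  invisible(path)
}

#' Read a JASPAR-style PWM file
#'
#' Plain-text motifs: a `>ID NAME` header followed by four rows
#' `A [ 12 3 ... ]` (counts or probabilities) in A, C, G, T order.
#'
#' @param path motif file.
#' @return A named list of `pwm` objects (see [pwm]).
#' @export
read_pwms <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads)) stopf("no motifs found in %s", path)
  out <- list()
  for (i in seq_along(heads)) {
    from <- heads[i]
    to <- if (i < length(heads)) heads[i + 1] - 1 else length(lines)
    block <- lines[from:to]
    hdr <- strsplit(sub("^>", "", block[1]), "\\s+")[[1]]
    if (length(block) < 5) stopf("motif %s in %s lacks 4 matrix rows", hdr[1], path)
    rows <- lapply(block[2:5], function(l) {
      l <- gsub("[][]", " ", l)
      v <- strsplit(trimws(l), "\\s+")[[1]]
      as.numeric(v[-1])
    })
    m <- do.call(rbind, rows)
    rownames(m) <- c("A", "C", "G", "T")
    out[[hdr[1]]] <- pwm(m, id = hdr[1],
                         name = if (length(hdr) > 1) hdr[2] else hdr[1])
  }
  out
}

#' @rdname read_pwms
#' @param pwms named list of `pwm` objects.
#' @export
write_pwms <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(sprintf(">%s %s", p$id, p$name), con)
    for (b in c("A", "C", "G", "T"))
      writeLines(sprintf("%s [ %s ]", b,
                         paste(format(p$prob[b, ], digits = 6), collapse = " ")), con)
  }
  invisible(path)
}
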