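#' Genome container: chromosome sizes plus an optional sequence source
#'
#' A lightweight stand-in for a reference genome: named chromosome lengths
#' and, optionally, the sequences themselves as a
#' [Biostrings::DNAStringSet]. All interval operations clip to
#' `[0, length)` in file coordinates.
#'
#' @param seqlengths named numeric vector of chromosome lengths in bp.
#' @param sequences optional `DNAStringSet` whose names and widths match
#'   `seqlengths`.
#' @return An object of class `chip_genome`.
#' @export
chip_genome <- function(seqlengths, sequences = NULL) {
  if (is.null(names(seqlengths)) || any(!nzchar(names(seqlengths))))
    stopf("chromosome sizes must be a named vector")
  if (any(seqlengths <= 0)) stopf("chromosome lengths must be positive")
  if (!is.null(sequences)) {
    if (!all(names(seqlengths) %in% names(sequences)))
      stopf("sequence source is missing chromosomes: %s",
            paste(setdiff(names(seqlengths), names(sequences)), collapse = ", "))
    w <- Biostrings::width(sequences)[match(names(seqlengths), names(sequences))]
    if (!all(w == unname(seqlengths)))
      stopf("sequence widths disagree with chromosome sizes")
  }
  structure(list(seqlengths = setNames(as.numeric(seqlengths), names(seqlengths)),
                 sequences = sequences),
            class = "chip_genome")
}

#' @export
print.chip_genome <- function(x, ...) {
  cat(sprintf("<chip_genome> %d chromosome(s), %.3g bp total%s\n",
              length(x$seqlengths), sum(x$seqlengths),
              if (is.null(x$sequences)) "" else ", with sequence"))
  invisible(x)
}

#' Read a two-column chrom.sizes file
#'
#' @param path file with `chrom<TAB>length` lines.
#' @return A [chip_genome] without sequence.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  chip_genome(setNames(df$length, df$chrom))
}

#' @rdname read_chrom_sizes
#' @param genome a [chip_genome].
#' @export
write_chrom_sizes <- function(genome, path) {
  utils::write.table(
    data.frame(names(genome$seqlengths), format(genome$seqlengths, scientific = FALSE, trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Attach FASTA sequence to a genome
#'
#' @param genome a [chip_genome] (or `NULL` to infer sizes from the FASTA).
#' @param fasta_path path to an uncompressed FASTA file.
#' @return A [chip_genome] carrying sequence.
#' @export
load_genome_fasta <- function(fasta_path, genome = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (is.null(genome))
    genome <- chip_genome(setNames(Biostrings::width(seqs), names(seqs)))
  chip_genome(genome$seqlengths, seqs)
}

## clip a GRanges to genome bounds; drops ranges that fall entirely outside
clip_to_genome <- function(gr, genome) {
  sl <- genome$seqlengths[as.character(GenomeInfoDb::seqnames(gr))]
  if (anyNA(sl))
    stopf("unknown chromosome: %s",
          paste(unique(as.character(GenomeInfoDb::seqnames(gr))[is.na(sl)]), collapse = ", "))
  s <- pmax(start(gr), 1L)
  e <- pmin(end(gr), sl)
  keep <- s <= e
  gr <- gr[keep]
  ranges(gr) <- IRanges::IRanges(s[keep], e[keep])
  gr
}

check_chroms <- function(chroms, genome, context = "region") {
  bad <- setdiff(unique(chroms), names(genome$seqlengths))
  if (length(bad))
    stopf("%s refers to unknown chromosome: %s", context, paste(bad, collapse = ", "))
  invisible(TRUE)
}
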