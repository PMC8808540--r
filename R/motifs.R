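## PWM scanning, dinucleotide-shuffled backgrounds, hypergeometric
## foreground/background enrichment, condition-differential motifs, and
## cell-type-specific TF extraction with cross-condition preservation.

#' Position weight matrix
#'
#' @param prob 4 x L matrix of base probabilities, rows A, C, G, T;
#'   columns must sum to 1 within 1e-6 and L must be >= 4.
#' @param id,name motif identifier and display name.
#' @param background length-4 base frequencies (default uniform).
#' @return A `pwm` object carrying the probability matrix, the floored
#'   log2-odds matrix (`floor` 1e-3) and its maximum achievable score.
#' @export
pwm <- function(prob, id = "motif", name = id,
                background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  prob <- as.matrix(prob)
  if (nrow(prob) != 4) stopf("pwm %s: need 4 rows (A,C,G,T)", id)
  rownames(prob) <- c("A", "C", "G", "T")
  if (ncol(prob) < 4) stopf("pwm %s: length %d < 4", id, ncol(prob))
  cs <- colSums(prob)
  if (any(cs <= 0)) stopf("pwm %s: non-positive column", id)
  prob <- sweep(prob, 2, cs, "/")          # accept counts or probabilities
  lo <- log2(pmax(prob, 1e-3) / background)
  structure(list(id = id, name = name, prob = prob, background = background,
                 log_odds = lo, max_score = sum(apply(lo, 2, max)),
                 length = ncol(prob)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s (%s), length %d, consensus %s\n", x$id, x$name,
              x$length, pwm_consensus(x)))
  invisible(x)
}

#' Consensus string of a PWM
#' @param x a `pwm`.
#' @return Character scalar.
#' @export
pwm_consensus <- function(x) {
  paste(c("A", "C", "G", "T")[apply(x$prob, 2, which.max)], collapse = "")
}

## sequences -> concatenated integer codes A=1 C=2 G=3 T=4, other=5,
## with spacers of 5s between sequences so every motif (length <= spacer)
## can be scored in one vectorized pass over the concatenation. Compiling
## once and scanning many motifs against it is what makes panel scans
## affordable in pure R.

#' Compile sequences for repeated PWM scanning
#'
#' @param seqs character vector or `DNAStringSet`.
#' @param spacer inter-sequence gap (must be >= the longest motif
#'   scanned, default 30).
#' @return A `compiled_seqs` object; accepted by [scan_sequences] in
#'   place of raw sequences.
#' @export
compile_seqs <- function(seqs, spacer = 30L) {
  if (inherits(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  codes <- lapply(strsplit(toupper(seqs), ""), function(ch) {
    x <- match(ch, c("A", "C", "G", "T"))
    x[is.na(x)] <- 5L
    x
  })
  lens <- lengths(codes)
  gap <- rep(5L, spacer)
  cat_codes <- unlist(lapply(codes, function(x) c(x, gap)), use.names = FALSE)
  structure(list(codes = cat_codes, lens = lens,
                 starts = cumsum(c(1L, lens + spacer))[seq_along(lens)],
                 spacer = spacer, n = length(lens)),
            class = "compiled_seqs")
}

## per-window scores on one strand; M is the 4 x L log-odds matrix;
## windows touching a non-ACGT position score -Inf
window_scores <- function(codes, M) {
  n <- length(codes)
  L <- ncol(M)
  if (n < L) return(numeric(0))
  nw <- n - L + 1L
  sc <- numeric(nw)
  for (j in seq_len(L)) {
    Mj <- c(M[, j], -Inf)
    sc <- sc + Mj[codes[j:(j + nw - 1L)]]
  }
  sc
}

#' Scan sequences with a PWM
#'
#' A sequence is a hit iff its best log2-odds window score, over both
#' strands, reaches `threshold` times the maximum achievable score.
#' Positions containing N (or any non-ACGT letter) score -Inf. Sequences
#' shorter than the motif cannot hit (warned once per call).
#'
#' @param seqs character vector, `DNAStringSet`, or a [compile_seqs]
#'   result (compile once when scanning a whole panel).
#' @param pwm a [pwm].
#' @param threshold fraction of the maximum achievable score in (0, 1\]
#'   (default 0.8).
#' @param positions if `TRUE`, also return per-sequence hit positions
#'   (1-based start within the sequence) and strands.
#' @return List: `hit` (logical per sequence), `best_score`, and when
#'   requested `positions` (list of data.frames with `pos`, `strand`).
#' @export
scan_sequences <- function(seqs, pwm, threshold = 0.8, positions = FALSE) {
  cs <- if (inherits(seqs, "compiled_seqs")) seqs else compile_seqs(seqs)
  L <- pwm$length
  if (L > cs$spacer)
    stopf("scan_sequences: motif %s longer than the compiled spacer (%d)",
          pwm$id, cs$spacer)
  if (any(cs$lens < L))
    warnf("scan_sequences: %d sequence(s) shorter than motif %s",
          sum(cs$lens < L), pwm$id)
  cutoff <- threshold * pwm$max_score
  M_fwd <- pwm$log_odds
  M_rev <- M_fwd[4:1, ncol(M_fwd):1, drop = FALSE]  # reverse complement
  sc_f <- window_scores(cs$codes, M_fwd)
  sc_r <- window_scores(cs$codes, M_rev)
  sc <- pmax(sc_f, sc_r)
  hit <- logical(cs$n)
  best <- rep(-Inf, cs$n)
  pos_out <- if (positions) vector("list", cs$n) else NULL
  for (i in seq_len(cs$n)) {
    n_i <- cs$lens[i]
    if (n_i < L) {
      if (positions) pos_out[[i]] <- data.frame(pos = integer(0),
                                                strand = character(0))
      next
    }
    idx <- cs$starts[i]:(cs$starts[i] + n_i - L)
    best[i] <- max(sc[idx])
    hit[i] <- best[i] >= cutoff
    if (positions) {
      pf <- which(sc_f[idx] >= cutoff); pr <- which(sc_r[idx] >= cutoff)
      pos_out[[i]] <- data.frame(
        pos = c(pf, pr),
        strand = rep(c("+", "-"), c(length(pf), length(pr))))
    }
  }
  out <- list(hit = hit, best_score = best)
  if (positions) out$positions <- pos_out
  out
}

#' Dinucleotide-preserving shuffle of a sequence
#'
#' Altschul-Erickson shuffle: the sequence is rewritten as an Eulerian
#' walk on the dinucleotide graph, so every dinucleotide count is
#' preserved exactly. Non-ACGT letters are left untouched in place.
#'
#' @param seq character scalar.
#' @return Shuffled character scalar.
#' @export
dinuc_shuffle <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  ok <- ch %in% c("A", "C", "G", "T")
  x <- ch[ok]
  n <- length(x)
  if (n < 3) return(seq)
  ## successor lists
  succ <- split(x[-1], factor(x[-n], levels = c("A", "C", "G", "T")))
  last <- x[n]
  verts <- names(succ)[lengths(succ) > 0]
  for (attempt in 1:200) {
    ## pick a candidate "last edge" per vertex (except the final vertex)
    pick <- lapply(succ, function(s) if (length(s)) s[sample.int(length(s), 1)] else NULL)
    ## check the picked edges form a tree converging on `last`
    ok_tree <- TRUE
    for (v in setdiff(verts, last)) {
      cur <- v
      for (step in 1:8) {
        nxt <- pick[[cur]]
        if (is.null(nxt)) { ok_tree <- FALSE; break }
        cur <- nxt
        if (cur == last) break
      }
      if (cur != last) ok_tree <- FALSE
      if (!ok_tree) break
    }
    if (!ok_tree) next
    ## shuffle the remaining edges, append the picked edge last
    edges <- lapply(names(succ), function(v) {
      s <- succ[[v]]
      if (!length(s)) return(s)
      if (v %in% setdiff(verts, last)) {
        p <- pick[[v]]
        i <- match(p, s)
        rest <- s[-i]
        c(if (length(rest)) rest[sample.int(length(rest))] else character(0), p)
      } else s[sample.int(length(s))]
    })
    names(edges) <- names(succ)
    ## walk
    out <- character(n)
    out[1] <- x[1]
    ptr <- setNames(rep(1L, 4), c("A", "C", "G", "T"))
    cur <- x[1]
    ok_walk <- TRUE
    for (i in 2:n) {
      e <- edges[[cur]]
      if (ptr[[cur]] > length(e)) { ok_walk <- FALSE; break }
      nxt <- e[ptr[[cur]]]
      ptr[[cur]] <- ptr[[cur]] + 1L
      out[i] <- nxt
      cur <- nxt
    }
    if (ok_walk && all(ptr[verts] == lengths(succ)[verts] + 1L)) {
      ch[ok] <- out
      return(paste(ch, collapse = ""))
    }
  }
  stopf("dinuc_shuffle: failed to find an Eulerian shuffle")
}

#' Dinucleotide-shuffled background set
#'
#' @param seqs character vector or `DNAStringSet` of foreground
#'   sequences.
#' @param n_copies shuffled copies per foreground sequence (default 2).
#' @param seed RNG seed for the shuffle.
#' @return Character vector of `n_copies * length(seqs)` sequences.
#' @export
make_background <- function(seqs, n_copies = 2, seed = 1) {
  if (inherits(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  with_seed(seed, {
    unlist(lapply(seq_len(n_copies), function(k)
      vapply(seqs, dinuc_shuffle, "", USE.NAMES = FALSE)))
  })
}

#' Hypergeometric motif enrichment of foreground vs background
#'
#' One-sided hypergeometric p-value on sequences-with->=1-hit, urn =
#' foreground plus background.
#'
#' @param fg_seqs,bg_seqs sequence sets (character or `DNAStringSet`).
#' @param pwm a [pwm].
#' @param threshold scan threshold (see [scan_sequences]).
#' @return List: `fg_hits`, `fg_total`, `bg_hits`, `bg_total`,
#'   `p_value`.
#' @export
enrichment_test <- function(fg_seqs, bg_seqs, pwm, threshold = 0.8) {
  n_fg <- length(fg_seqs)
  if (!n_fg) stopf("enrichment_test: empty foreground")
  fg_hits <- sum(scan_sequences(fg_seqs, pwm, threshold)$hit)
  bg_hits <- sum(scan_sequences(bg_seqs, pwm, threshold)$hit)
  n_bg <- length(bg_seqs)
  K <- fg_hits + bg_hits
  p <- stats::phyper(fg_hits - 1, K, n_fg + n_bg - K, n_fg, lower.tail = FALSE)
  list(fg_hits = fg_hits, fg_total = n_fg, bg_hits = bg_hits,
       bg_total = n_bg, p_value = p)
}

#' Motif enrichment table across groups
#'
#' Runs [enrichment_test] for every motif in every (cell type,
#' condition) enhancer sequence set, with a dinucleotide-shuffled
#' background per set. BH-adjusted q-values are reported alongside the
#' raw p-values (selection logic uses raw p, mirroring common practice
#' with fixed alpha cutoffs).
#'
#' @param seq_sets named list of sequence sets; names like
#'   `"BC.NC"` (`<cell_type>.<condition>`).
#' @param pwms named list of [pwm]s.
#' @param threshold scan threshold.
#' @param bg_copies shuffled background copies per foreground sequence.
#' @param seed seed for background generation.
#' @return Long `data.frame`: `motif`, `group`, `cell_type`,
#'   `condition`, `fg_hits`, `fg_total`, `bg_hits`, `bg_total`,
#'   `p_value`, `q_value`.
#' @export
motif_enrichment_table <- function(seq_sets, pwms, threshold = 0.8,
                                   bg_copies = 2, seed = 1) {
  rows <- list()
  for (grp in names(seq_sets)) {
    fg <- seq_sets[[grp]]
    bg <- make_background(fg, bg_copies, seed = derive_seed(seed, grp))
    parts <- strsplit(grp, ".", fixed = TRUE)[[1]]
    res <- lapply(pwms, function(p) enrichment_test(fg, bg, p, threshold))
    df <- data.frame(
      motif = vapply(pwms, function(p) p$id, ""),
      group = grp,
      cell_type = parts[1],
      condition = if (length(parts) > 1) parts[2] else NA_character_,
      fg_hits = vapply(res, function(r) r$fg_hits, 0),
      fg_total = vapply(res, function(r) r$fg_total, 0),
      bg_hits = vapply(res, function(r) r$bg_hits, 0),
      bg_total = vapply(res, function(r) r$bg_total, 0),
      p_value = vapply(res, function(r) r$p_value, 0),
      row.names = NULL)
    df$q_value <- stats::p.adjust(df$p_value, method = "BH")
    rows[[grp]] <- df
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

## p-value lookup helper
.table_p <- function(table, cell_type, condition) {
  sub <- table[table$cell_type == cell_type & table$condition == condition, ]
  setNames(sub$p_value, sub$motif)
}

#' Condition-differential motifs per cell type
#'
#' A motif is NC-only iff significant (raw p < alpha) in NC but not MUT;
#' symmetric for MUT-only; shared iff significant in both.
#'
#' @param table `data.frame` from [motif_enrichment_table].
#' @param cell_type cell type to evaluate.
#' @param alpha significance cutoff (default 1e-4).
#' @param conditions length-2 character (default `c("NC", "MUT")`).
#' @return List of motif-id vectors: `<cond1>_only`, `shared`,
#'   `<cond2>_only`.
#' @export
condition_differential_motifs <- function(table, cell_type, alpha = 1e-4,
                                          conditions = c("NC", "MUT")) {
  p1 <- .table_p(table, cell_type, conditions[1])
  p2 <- .table_p(table, cell_type, conditions[2])
  motifs <- union(names(p1), names(p2))
  p1 <- p1[motifs]; p2 <- p2[motifs]
  p1[is.na(p1)] <- 1; p2[is.na(p2)] <- 1
  out <- list(motifs[p1 < alpha & p2 >= alpha],
              motifs[p1 < alpha & p2 < alpha],
              motifs[p1 >= alpha & p2 < alpha])
  names(out) <- c(paste0(conditions[1], "_only"), "shared",
                  paste0(conditions[2], "_only"))
  out
}

#' Cell-type-specific TF motifs from reference-condition tables
#'
#' A motif is specific to cell type X iff p < alpha in X and p >= alpha
#' in every other listed cell type (all within `condition`).
#'
#' @param table `data.frame` from [motif_enrichment_table].
#' @param cell_types cell types to compare (default the three epithelial
#'   populations `c("BC", "LP", "ML")`).
#' @param condition condition whose tables define specificity (default
#'   `"NC"`).
#' @param alpha cutoff (default 1e-4).
#' @return Named list of motif-id vectors, one per cell type; pairwise
#'   disjoint by construction.
#' @export
celltype_specific_tfs <- function(table, cell_types = c("BC", "LP", "ML"),
                                  condition = "NC", alpha = 1e-4) {
  ps <- lapply(cell_types, function(ct) .table_p(table, ct, condition))
  names(ps) <- cell_types
  motifs <- Reduce(union, lapply(ps, names))
  if (!length(motifs))
    return(setNames(rep(list(character(0)), length(cell_types)), cell_types))
  pm <- matrix(1, length(motifs), length(cell_types),
               dimnames = list(motifs, cell_types))
  for (ct in cell_types) {
    p <- ps[[ct]]
    common <- intersect(names(p), motifs)
    pm[common, ct] <- p[common]
  }
  sig <- pm < alpha
  out <- lapply(cell_types, function(ct)
    motifs[sig[, ct] & rowSums(sig) == 1])
  names(out) <- cell_types
  out
}

#' Preservation and cross-gain of cell-type-specific TFs in the other
#' condition
#'
#' Entry (X, Y) counts the motifs specific to cell type Y (in the
#' reference condition) that are significantly enriched in cell type X
#' in `condition`. The diagonal is the preserved count.
#'
#' @param specific named list from [celltype_specific_tfs].
#' @param table `data.frame` from [motif_enrichment_table].
#' @param condition condition to evaluate enrichment in (default
#'   `"MUT"`).
#' @param alpha cutoff (default 1e-4).
#' @return Integer matrix (rows = enriched-in cell type X, cols =
#'   specific-to cell type Y), with a `preserved` attribute (the
#'   diagonal, named).
#' @export
mut_preservation <- function(specific, table, condition = "MUT", alpha = 1e-4) {
  cts <- names(specific)
  M <- matrix(0L, length(cts), length(cts), dimnames = list(cts, cts))
  for (x in cts) {
    px <- .table_p(table, x, condition)
    for (y in cts) {
      motifs <- specific[[y]]
      p <- px[motifs]
      p[is.na(p)] <- 1
      M[x, y] <- sum(p < alpha)
    }
  }
  attr(M, "preserved") <- diag(M)
  M
}
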