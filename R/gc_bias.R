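# GC frame-plot bias training and the preliminary coding score.
#
# In GC-skewed genomes, coding sequence concentrates G+C in a preferred codon
# position (usually the third). The bias is learned by letting every ORF vote
# for the codon position with the highest G+C content, and a gene's
# preliminary score is its length weighted by how much of it sits in windows
# whose locally dominant position matches each codon position.

# cumulative G+C indicator split by global residue class (index mod 3), one
# cumsum per class; `enc` is the encoded strand reading
class_gc_cumsums <- function(enc) {
  gc <- as.integer(!is.na(enc) & (enc == 1L | enc == 2L))
  idx <- (seq_along(enc) - 1L) %% 3L
  lapply(0:2, function(c) cumsum(ifelse(idx == c, gc, 0L)))
}

#' Per-base winning codon-position profile
#'
#' For each base of a strand reading, determines which of the three residue
#' classes (base index mod 3) has the highest G+C content in the window
#' centered on that base; the window is truncated at the sequence edges. Ties
#' are resolved toward the lowest class.
#'
#' @param bases DNA string (one strand, read 5' to 3').
#' @param window window width in bp (default 120; the window at base j covers
#'   indices j-60 through j+59, 0-based).
#' @return Integer vector of length `nchar(bases)` with values 1..3 labelling
#'   the winning residue class (1 = indices congruent to 0 mod 3).
#' @export
max_frame_profile <- function(bases, window = gt_params()$gc_window) {
  enc <- if (is.character(bases)) encode_bases(bases) else bases
  L <- length(enc)
  if (L == 0L) return(integer(0))
  cs <- class_gc_cumsums(enc)
  half <- window %/% 2L
  j <- seq_len(L)                      # 1-based
  hi <- pmin(L, j + half - 1L)         # inclusive, covers j-1+half bases ahead
  lo <- pmax(1L, j - half)             # inclusive
  w <- vapply(cs, function(s) { p <- c(0L, s); p[hi + 1L] - p[lo] }, numeric(L))
  if (L == 1L) w <- matrix(w, nrow = 1L)
  max.col(w, ties.method = "first")
}

#' GC frame bias from all ORFs of the input
#'
#' Every open reading frame at least `min_gene_len` bp long (a stop-to-stop
#' stretch in one frame on either strand, stop codon excluded) votes for the
#' codon position with the highest total G+C content over the ORF, weighted
#' by the ORF's codon count (so the sums measure the fraction of codons in
#' ORFs preferring G/C at each position); the winner fractions f(i) are
#' normalized around 1 and divided by 1/3, i.e. B(i) = 3 f(i), so the three
#' bias scores sum to 3.
#'
#' @param records tibble from [read_genome_fasta()].
#' @param min_gene_len minimum ORF length in bp.
#' @return An object of class `gt_gc_bias`: list with `b` (numeric bias scores
#'   B(1..3)), `window`, and `n_orfs`.
#' @export
compute_gc_bias <- function(records, min_gene_len = gt_params()$min_gene_len) {
  wins <- c(0, 0, 0)
  n <- 0
  n_orfs <- 0L
  for (k in seq_len(nrow(records))) {
    for (strand in c(1L, -1L)) {
      seq_k <- if (strand == 1L) records$bases[[k]] else reverse_complement(records$bases[[k]])
      enc <- encode_bases(seq_k)
      tid <- if (!is.null(records$table_id)) records$table_id[[k]] else 11L
      orfs <- orf_regions(enc, tid, min_gene_len)
      if (!length(orfs)) next
      cs <- class_gc_cumsums(enc)
      from <- vapply(orfs, `[`, integer(1), 1L)
      to <- vapply(orfs, `[`, integer(1), 2L)
      cnt <- matrix(0, nrow = length(orfs), ncol = 3L)  # by gene position
      for (c in 0:2) {
        p <- c(0L, cs[[c + 1L]])
        tot_c <- p[to + 2L] - p[from + 1L]
        pos_c <- ((c - from) %% 3L) + 1L
        cnt[cbind(seq_along(from), pos_c)] <- tot_c
      }
      w <- max.col(cnt, ties.method = "first")
      codons <- (to - from + 1L) %/% 3L
      for (p in 1:3) wins[p] <- wins[p] + sum(codons[w == p])
      n <- n + sum(codons)
      n_orfs <- n_orfs + length(w)
    }
  }
  if (n == 0) {
    stop("no open reading frames of at least ", min_gene_len,
         " bp found; supply more (or less fragmented) sequence to train on")
  }
  structure(list(b = gc_bias_from_tally(wins), window = gt_params()$gc_window,
                 n_orfs = n_orfs),
            class = "gt_gc_bias")
}

#' @export
print.gt_gc_bias <- function(x, ...) {
  cat("GC frame bias from", x$n_orfs, "ORFs: B =",
      paste(sprintf("%.3f", x$b), collapse = ", "), "\n")
  invisible(x)
}

# stop-to-stop ORF regions [from, to] (0-based, stop codon excluded) of one
# encoded strand reading, all three frames, length >= min_len
orf_regions <- function(enc, table_id, min_len) {
  L <- length(enc)
  cod <- codon_codes(enc)
  stop_codes <- vapply(stop_codons(table_id), codon_index, integer(1))
  q_stop <- which(cod %in% stop_codes) - 1L
  out <- list()
  for (f in 0:2) {
    sp <- q_stop[q_stop %% 3L == f]
    edge_right <- if (L >= f + 3L) f + 3L * ((L - f) %/% 3L) - 1L else NA_integer_
    if (is.na(edge_right)) next
    froms <- c(f, sp + 3L)
    tos <- c(sp - 1L, edge_right)
    keep <- (tos - froms + 1L) >= min_len
    for (i in which(keep)) out[[length(out) + 1L]] <- c(froms[i], tos[i])
  }
  out
}

#' Bias scores from a winner tally
#'
#' Normalizes a tally of codon-position wins around 1 and divides by 1/3:
#' with winner fractions f(i), B(i) = 3 f(i), so a position preferred by 2/3
#' of the codons scores 2.
#'
#' @param wins numeric tally of wins per codon position (length 3).
#' @return Numeric vector of three bias scores summing to 3.
#' @export
gc_bias_from_tally <- function(wins) {
  stopifnot(length(wins) == 3, sum(wins) > 0)
  3 * wins / sum(wins)
}

#' Preliminary coding score of a gene from the GC frame profile
#'
#' S = sum over codon positions i of B(i) * l(i), where l(i) is the number of
#' bases of the gene whose windowed maximal-GC class corresponds to codon
#' position i of the gene's own frame.
#'
#' @param labels integer profile from [max_frame_profile()] for the gene's
#'   strand reading.
#' @param from,to 0-based gene extent on that strand reading (start codon
#'   first base through stop codon last base).
#' @param bias a `gt_gc_bias` object (or numeric vector of three bias scores).
#' @return The preliminary coding score (numeric scalar).
#' @export
preliminary_coding_score <- function(labels, from, to, bias) {
  b <- if (inherits(bias, "gt_gc_bias")) bias$b else bias
  cls <- labels[(from:to) + 1L] - 1L            # global class 0..2
  gene_pos <- ((cls - from) %% 3L) + 1L         # codon position within gene
  sum(b[gene_pos])
}

# vectorized preliminary scores for many genes on one strand reading:
# `lab_cum` = list of 3 cumsums of (labels == class c), genes given by
# 0-based from/to vectors
prelim_scores_batch <- function(lab_cum, from, to, b) {
  s <- numeric(length(from))
  for (c in 0:2) {
    p <- c(0L, lab_cum[[c + 1L]])
    cnt <- p[to + 2L] - p[from + 1L]
    i <- ((c - from) %% 3L) + 1L
    s <- s + b[i] * cnt
  }
  s
}
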