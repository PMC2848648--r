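# Hexamer (5th-order Markov) coding statistics and per-gene coding scores.
#
# A gene's coding score is the sum over its in-frame hexamers (dicodons,
# windows of 6 starting at each codon boundary) of log(G/B), where G is the
# word's frequency among training-gene hexamers and B its frequency over the
# entire input, both strands, irrespective of frame. Scores are clamped to a
# floor and ceiling where data are insufficient.

ALL_HEXAMERS <- local({
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b6 = b, b5 = b, b4 = b, b3 = b, b2 = b, b1 = b,
                   stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3, g$b4, g$b5, g$b6)  # index = code + 1
})

# hexamer codes 0..4095 at every position of an encoded reading (length L-5);
# NA where any base is not A/C/G/T
hexamer_codes <- function(enc) {
  L <- length(enc)
  if (L < 6L) return(integer(0))
  n <- L - 5L
  1024L * enc[1:n] + 256L * enc[2:(n + 1L)] + 64L * enc[3:(n + 2L)] +
    16L * enc[4:(n + 3L)] + 4L * enc[5:(n + 4L)] + enc[6:(n + 5L)]
}

#' Train the hexamer coding model
#'
#' Tabulates in-frame hexamer frequencies over a set of training genes against
#' the background frequency of each word over the whole input (both strands,
#' frame-free) and scores each of the 4096 words as log(G/B), natural log,
#' clamped to `hex_floor`/`hex_ceiling`. The stop codon is excluded from the
#' in-frame tally.
#'
#' @param genes tibble of training genes with columns `contig`, `strand`,
#'   `left`, `right` (0-based forward-coordinate gene extents).
#' @param records tibble from [read_genome_fasta()].
#' @param params parameter list from [gt_params()].
#' @return Object of class `gt_hexamers`: named numeric vector of 4096 scores
#'   with attributes `floor` and `ceiling`.
#' @export
train_hexamers <- function(genes, records, params = gt_params()) {
  if (is.null(genes) || nrow(genes) == 0L) stop("empty training gene set")
  bg <- integer(4096)
  fg <- integer(4096)
  for (k in seq_len(nrow(records))) {
    enc_f <- encode_bases(records$bases[[k]])
    enc_r <- rev(3L - enc_f)
    hf <- hexamer_codes(enc_f)
    hr <- hexamer_codes(enc_r)
    bg <- bg + tabulate(c(hf, hr) + 1L, 4096L)
    gk <- genes[genes$contig == records$id[[k]], , drop = FALSE]
    if (nrow(gk) == 0L) next
    L <- length(enc_f)
    for (i in seq_len(nrow(gk))) {
      idx <- gene_hexamer_positions(gk$strand[i], gk$left[i], gk$right[i], L)
      if (length(idx)) {
        h <- if (gk$strand[i] == 1L) hf[idx + 1L] else hr[idx + 1L]
        fg <- fg + tabulate(h + 1L, 4096L)
      }
    }
  }
  hexamer_scores(fg, bg, params)
}

# 0-based own-strand positions of the in-frame hexamers of a gene (stop codon
# excluded): q, q+3, ..., q_end - 8
gene_hexamer_positions <- function(strand, left, right, L) {
  if (strand == 1L) { q1 <- left; q2 <- right } else { q1 <- L - 1L - right; q2 <- L - 1L - left }
  if (q2 - q1 + 1L < 9L) return(integer(0))
  seq.int(q1, q2 - 8L, by = 3L)
}

# log-ratio scores from foreground/background counts
hexamer_scores <- function(fg, bg, params = gt_params()) {
  gfreq <- fg / max(1L, sum(fg))
  bfreq <- bg / max(1L, sum(bg))
  s <- numeric(4096)
  pos <- gfreq > 0 & bfreq > 0
  s[pos] <- log(gfreq[pos] / bfreq[pos])
  s[gfreq == 0 & bfreq > 0] <- params$hex_floor
  s[gfreq > 0 & bfreq == 0] <- params$hex_ceiling
  s <- pmin(pmax(s, params$hex_floor), params$hex_ceiling)
  names(s) <- ALL_HEXAMERS
  structure(s, class = "gt_hexamers",
            floor = params$hex_floor, ceiling = params$hex_ceiling)
}

#' Coding score of a gene sequence
#'
#' Sums the hexamer scores over the in-frame hexamers of a gene given 5' to 3'
#' on its own strand (including the stop codon, which is excluded from the
#' windows). Hexamers containing N contribute 0.
#'
#' @param bases gene nucleotide sequence (multiple of 3, with stop codon).
#' @param table a `gt_hexamers` object.
#' @return Numeric coding score.
#' @export
gene_coding_score <- function(bases, table) {
  enc <- encode_bases(bases)
  n <- length(enc)
  if (n < 9L) return(0)
  h <- hexamer_codes(enc)
  idx <- seq.int(1L, n - 8L, by = 3L)
  v <- unclass(table)[h[idx] + 1L]
  sum(v, na.rm = TRUE)
}

#' Penalty for truncated alternatives of the same gene
#'
#' Given the coding scores of all starts sharing one stop, ordered from the
#' outermost (longest gene) inward, a start whose best longer alternative
#' scores higher is penalized by the difference: adjusted = own - (best_longer
#' - own). The comparator is the running maximum of adjusted scores scanning
#' outermost to innermost.
#'
#' @param scores numeric vector of coding scores, outermost start first.
#' @return Numeric vector of adjusted scores in the same order.
#' @export
truncation_penalty <- function(scores) {
  if (!length(scores)) return(scores)
  adj <- scores
  best <- -Inf
  for (k in seq_along(scores)) {
    if (best > scores[k]) adj[k] <- scores[k] - (best - scores[k])
    best <- max(best, adj[k])
  }
  adj
}

#' Minimal positive score for very long genes
#'
#' Long genes with a negative coding score are lifted to a small positive
#' value, on the grounds that such long ORFs are rarely spurious. The length
#' threshold rises linearly with genome GC content from `boost_len_low` bp at
#' GC `boost_gc_low` to `boost_len_high` bp at GC `boost_gc_high` (clamped
#' outside), since high-GC genomes contain longer spurious ORFs.
#'
#' @param score coding score (scalar or vector).
#' @param gene_len gene length in bp.
#' @param gc genome GC content as a fraction.
#' @param params parameter list from [gt_params()].
#' @return Adjusted score(s).
#' @export
long_gene_boost <- function(score, gene_len, gc, params = gt_params()) {
  thr <- boost_threshold(gc, params)
  ifelse(gene_len >= thr & score < 0, params$boost_eps, score)
}

boost_threshold <- function(gc, params = gt_params()) {
  f <- (gc - params$boost_gc_low) / (params$boost_gc_high - params$boost_gc_low)
  f <- min(1, max(0, f))
  params$boost_len_low + f * (params$boost_len_high - params$boost_len_low)
}
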