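# Final per-start score: combine the coding score with the start-signal
# components (RBS motif R, start type T, upstream U), scaled by the start
# weight constant, with a length penalty below the 250 bp equilibrium point
# and a flat penalty for genes with negative coding scores.

#' Length-scaled start-weight penalty
#'
#' Genes shorter than the equilibrium length (250 bp) have their start weight
#' scaled: a positive weight s becomes (l/250) * s, a negative weight becomes
#' (250/l) * s, so short genes need proportionally stronger start evidence.
#' Additionally, any gene with a negative coding score has its start weight
#' reduced by a flat amount regardless of length.
#'
#' @param start_w combined start weight (scalar or vector).
#' @param gene_len gene length in bp (> 0).
#' @param C coding score of the gene.
#' @param params parameter list from [gt_params()].
#' @return Adjusted start weight.
#' @export
length_penalty <- function(start_w, gene_len, C, params = gt_params()) {
  if (any(gene_len <= 0)) stop("gene length must be positive")
  n <- max(length(start_w), length(gene_len), length(C))
  s <- rep_len(start_w, n)
  l <- rep_len(gene_len, n)
  Cv <- rep_len(C, n)
  eq <- params$len_pen_equilibrium
  out <- ifelse(l < eq,
                ifelse(s > 0, s * l / eq,
                       ifelse(s < 0, s * eq / l, s)),
                s)
  out - ifelse(Cv < 0, params$neg_coding_start_penalty, 0)
}

#' Final score of a candidate start
#'
#' total = C + start_weight * (R + T + upstream_factor * U), with the
#' start-signal term passed through [length_penalty()] first.
#'
#' @param C coding score.
#' @param R RBS motif score.
#' @param T_ start-type score.
#' @param U upstream PWM score.
#' @param gene_len gene length in bp.
#' @param params parameter list.
#' @return List with `start_w` (penalized start weight) and `total`.
#' @export
combine_start_score <- function(C, R, T_, U, gene_len, params = gt_params()) {
  sw <- params$start_weight * (R + T_ + params$upstream_factor * U)
  sw <- length_penalty(sw, gene_len, C, params)
  list(start_w = sw, total = C + sw)
}
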