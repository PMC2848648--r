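#' Tunable parameters of the gene model
#'
#' Returns the full list of named constants used by training and prediction.
#' Every threshold in the algorithm is exposed here so that sensitivity
#' analyses can vary one constant at a time; the defaults are the values the
#' model was designed around and are not meant to be tuned per genome.
#'
#' @param ... named overrides for individual constants.
#'
#' @return A named list of parameters:
#' \describe{
#'   \item{min_gene_len}{minimum gene length in bp, first base of the start
#'     codon through last base of the stop codon, inclusive (default 90).}
#'   \item{gc_window}{window width in bp for the GC frame profile (120).}
#'   \item{hex_floor, hex_ceiling}{clamp for hexamer log-ratio scores, natural
#'     log units (-4, +4).}
#'   \item{start_weight}{multiplier applied to the combined start-signal score
#'     before adding it to the coding score (4.25).}
#'   \item{upstream_factor}{relative weight of the upstream PWM score inside
#'     the start-signal combination (0.4).}
#'   \item{len_pen_equilibrium}{gene length in bp below which the start weight
#'     is scaled by length (250).}
#'   \item{neg_coding_start_penalty}{amount subtracted from the start weight
#'     of any gene whose coding score is negative (0.5).}
#'   \item{boost_eps}{small positive coding score given to very long genes
#'     with negative coding score (0.1).}
#'   \item{boost_len_low, boost_len_high, boost_gc_low, boost_gc_high}{anchors
#'     of the long-gene boost length threshold: 700 bp at GC 0.35 rising
#'     linearly to 1200 bp at GC 0.70, clamped outside.}
#'   \item{peak_threshold}{minimum coding score for an ORF's peak to enter
#'     start training (35.0).}
#'   \item{min_peaks}{fewer training peaks than this triggers a warning (10).}
#'   \item{max_start_iter, start_move_tol}{start-training loop stops after 20
#'     iterations or when under 1\% of peaks move.}
#'   \item{sec_seed_frac}{fraction of peaks a 3-mer must occur in to seed the
#'     secondary motif search (0.20).}
#'   \item{sec_word_min_frac}{fraction of peaks a candidate word must occur in
#'     to keep its own bin; rarer words fall into the no-motif bin (0.20, the
#'     same frequency bar as the seeds).}
#'   \item{sec_clearcut_weight}{minimum top secondary-word weight for the
#'     secondary system to be used on its own (1.0).}
#'   \item{weight_clamp}{clamp for all start-signal log-ratio weights (4.0).}
#'   \item{same_strand_max_overlap}{maximum overlap between same-strand genes
#'     (60 bp).}
#'   \item{opp_strand_max_overlap}{maximum overlap between converging
#'     opposite-strand 3' ends (200 bp).}
#'   \item{max_connection_gap}{maximum span of an intergenic connection in the
#'     dynamic programming (5000 bp).}
#'   \item{operon_bonus_dist, operon_penalty_dist}{intergenic distances below/
#'     above which the distance modifier is a bonus/penalty (60, 180 bp).}
#'   \item{train_dist_mod}{magnitude of the distance modifier in the training
#'     pass (0.2).}
#'   \item{final_operon_bonus, final_operon_penalty}{distance modifier
#'     magnitudes in the final pass (0.5 each).}
#'   \item{tiebreak_dist}{starts closer than this share their coding score and
#'     compete on start signal alone (15 bp).}
#'   \item{upstream_window}{bp searched upstream of a start for RBS motifs
#'     (21 = longest motif 6 + longest spacer 15).}
#'   \item{pwm_offsets}{upstream offsets covered by the generic upstream PWM
#'     (1-2 and 15-45 bp before the start codon).}
#'   \item{min_train_bp, warn_train_bp}{training input shorter than
#'     min_train_bp is an error; shorter than warn_train_bp a warning.}
#' }
#' @export
#' @examples
#' p <- gt_params()
#' p$min_gene_len
#' gt_params(hex_floor = -3)$hex_floor
gt_params <- function(...) {
  p <- list(
    min_gene_len = 90L,
    gc_window = 120L,
    hex_floor = -4.0,
    hex_ceiling = 4.0,
    start_weight = 4.25,
    upstream_factor = 0.4,
    len_pen_equilibrium = 250,
    neg_coding_start_penalty = 0.5,
    boost_eps = 0.1,
    boost_len_low = 700,
    boost_len_high = 1200,
    boost_gc_low = 0.35,
    boost_gc_high = 0.70,
    peak_threshold = 35.0,
    min_peaks = 10L,
    max_start_iter = 20L,
    start_move_tol = 0.01,
    sec_seed_frac = 0.20,
    sec_word_min_frac = 0.20,
    sec_clearcut_weight = 1.0,
    sec_max_iter = 10L,
    weight_clamp = 4.0,
    same_strand_max_overlap = 60L,
    opp_strand_max_overlap = 200L,
    max_connection_gap = 5000L,
    operon_bonus_dist = 60L,
    operon_penalty_dist = 180L,
    train_dist_mod = 0.2,
    final_operon_bonus = 0.5,
    final_operon_penalty = 0.5,
    tiebreak_dist = 15L,
    upstream_window = 21L,
    pwm_offsets = c(1L, 2L, 15:45),
    min_train_bp = 20000,
    warn_train_bp = 1e5
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  p
}
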