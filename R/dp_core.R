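# R surface of the dynamic-programming engine: gene/connection assembly,
# the overlap index, per-connection scoring, and the optimal tiling path.

# DP node types used by the engine
DP_SF <- 0L  # forward start (5'F)
DP_EF <- 1L  # forward stop  (3'F)
DP_ER <- 2L  # reverse stop  (3'R)
DP_SR <- 3L  # reverse start (5'R)

# build the gene table (one row per start node) and the DP node table from an
# enumerate_nodes() tibble; gene rows carry the index of their start node row
dp_assemble <- function(nodes) {
  is_start <- nodes$kind == "start"
  genes <- nodes[is_start, , drop = FALSE]
  genes$node_row <- which(is_start)
  genes$len <- genes$right - genes$left + 1L
  # stop identity: the gene's 3'-end coordinate on its strand
  genes$stop_key <- ifelse(genes$strand == 1L,
                           paste0("+", genes$right), paste0("-", genes$left))
  stops <- nodes[!is_start, , drop = FALSE]
  dp_nodes <- tibble::tibble(
    coord = ifelse(stops$strand == 1L, stops$right, stops$left),
    type = ifelse(stops$strand == 1L, DP_EF, DP_ER),
    key = ifelse(stops$strand == 1L, paste0("+", stops$right), paste0("-", stops$left))
  )
  dp_nodes <- dp_nodes[!duplicated(dp_nodes$key), , drop = FALSE]
  start_nodes <- tibble::tibble(
    coord = ifelse(genes$strand == 1L, genes$left, genes$right),
    type = ifelse(genes$strand == 1L, DP_SF, DP_SR),
    key = paste0("s", genes$node_row)
  )
  all_nodes <- dplyr::bind_rows(dp_nodes, start_nodes)
  ord <- order(all_nodes$coord, all_nodes$type)
  all_nodes <- all_nodes[ord, , drop = FALSE]
  all_nodes$idx0 <- seq_len(nrow(all_nodes)) - 1L
  node_of_key <- stats::setNames(all_nodes$idx0, all_nodes$key)
  genes$lnode <- ifelse(genes$strand == 1L,
                        node_of_key[paste0("s", genes$node_row)],
                        node_of_key[genes$stop_key])
  genes$rnode <- ifelse(genes$strand == 1L,
                        node_of_key[genes$stop_key],
                        node_of_key[paste0("s", genes$node_row)])
  if (anyNA(genes$lnode) || anyNA(genes$rnode)) {
    stop("internal error: gene with unmatched stop node")
  }
  list(genes = genes, dp_nodes = all_nodes)
}

#' Optimal gene tiling by dynamic programming
#'
#' Finds the maximal-score tiling path over candidate genes, honoring the
#' nine legal connection types: gene, intergenic (with distance modifiers),
#' same-strand overlaps up to 60 bp, and opposite-strand 3' overlaps up to
#' 200 bp with no 5'-end overlap. Intergenic connections are limited to
#' `max_connection_gap`; only a gene's own start-stop connection may span
#' further.
#'
#' @param nodes tibble from [enumerate_nodes()] for one contig.
#' @param scores numeric vector with one score per start node (rows of
#'   `nodes` with kind "start", in order): the full gene score.
#' @param scores_waived optional alternative scores with the RBS component
#'   zeroed, used when a 1 or 4 bp same-strand overlap waives the RBS
#'   requirement (defaults to `scores`).
#' @param waiver_ok logical per start: gene lacks an RBS and has a negative
#'   RBS score (defaults to all FALSE).
#' @param pass "final" (operon-distance modifiers, waiver active) or
#'   "training" (small distance modifiers, no waiver).
#' @param params parameter list from [gt_params()].
#' @return Tibble of the selected genes (columns of `nodes` plus `waived`),
#'   in path order, with attribute `total` (the path score).
#' @export
dp_optimal_path <- function(nodes, scores, scores_waived = NULL,
                            waiver_ok = NULL, pass = c("final", "training"),
                            params = gt_params()) {
  pass <- match.arg(pass)
  asm <- dp_assemble(nodes)
  genes <- asm$genes
  if (nrow(genes) == 0L) {
    out <- genes[integer(0), , drop = FALSE]
    attr(out, "total") <- 0
    return(out)
  }
  if (length(scores) != nrow(genes)) stop("need one score per start node")
  if (is.null(scores_waived)) scores_waived <- scores
  if (is.null(waiver_ok)) waiver_ok <- rep(FALSE, nrow(genes))
  final <- pass == "final"
  res <- dp_engine_cpp(
    asm$dp_nodes$coord, asm$dp_nodes$type,
    as.integer(genes$lnode), as.integer(genes$rnode),
    as.integer(genes$left), as.integer(genes$right),
    genes$strand == 1L,
    as.numeric(scores), as.numeric(scores_waived), waiver_ok,
    final,
    as.integer(params$max_connection_gap),
    as.integer(params$operon_bonus_dist),
    as.integer(params$operon_penalty_dist),
    if (final) params$final_operon_bonus else params$train_dist_mod,
    if (final) params$final_operon_penalty else params$train_dist_mod,
    as.integer(params$same_strand_max_overlap),
    as.integer(params$opp_strand_max_overlap)
  )
  out <- genes[res$genes, , drop = FALSE]
  out$waived <- res$waived
  out$score <- ifelse(out$waived, scores_waived[res$genes], scores[res$genes])
  attr(out, "total") <- res$total
  out
}

#' Best overlapping follower gene for each 3' end
#'
#' For every stop node, finds in each frame the highest-scoring same-strand
#' gene whose 5' end lies within the same-strand overlap window (overlap of
#' 1 to 60 bp with that 3' end) and whose 3' end lies beyond it.
#'
#' @param nodes tibble from [enumerate_nodes()] for one contig.
#' @param scores one score per start node.
#' @param params parameter list.
#' @return Tibble: `stop_key`, `strand`, `frame` (follower gene frame),
#'   `start_row` (row of the follower's start node in `nodes`), `score`,
#'   `overlap`.
#' @export
build_overlap_index <- function(nodes, scores, params = gt_params()) {
  asm <- dp_assemble(nodes)
  genes <- asm$genes
  genes$score <- scores
  stops <- nodes[nodes$kind == "stop", , drop = FALSE]
  maxov <- params$same_strand_max_overlap
  out <- list()
  for (i in seq_len(nrow(stops))) {
    strand <- stops$strand[i]
    end3 <- if (strand == 1L) stops$right[i] else stops$left[i]
    key <- paste0(if (strand == 1L) "+" else "-", end3)
    if (strand == 1L) {
      cand <- genes[genes$strand == 1L & genes$left >= end3 - maxov + 1L &
                      genes$left <= end3 & genes$right > end3, , drop = FALSE]
      ovl <- end3 - cand$left + 1L
    } else {
      cand <- genes[genes$strand == -1L & genes$right <= end3 + maxov - 1L &
                      genes$right >= end3 & genes$left < end3, , drop = FALSE]
      ovl <- cand$right - end3 + 1L
    }
    if (nrow(cand) == 0L) next
    cand$overlap <- ovl
    best <- cand |>
      dplyr::mutate(.row = seq_len(nrow(cand))) |>
      dplyr::group_by(.data$frame) |>
      dplyr::slice_max(.data$score, n = 1L, with_ties = FALSE) |>
      dplyr::ungroup()
    out[[length(out) + 1L]] <- tibble::tibble(
      stop_key = key, strand = strand, frame = best$frame,
      start_row = best$node_row, score = best$score, overlap = best$overlap
    )
  }
  if (!length(out)) {
    return(tibble::tibble(stop_key = character(0), strand = integer(0),
                          frame = integer(0), start_row = integer(0),
                          score = numeric(0), overlap = integer(0)))
  }
  dplyr::bind_rows(out)
}

#' Score of a single dynamic-programming connection
#'
#' Scores one connection by its type: a gene connection scores the gene
#' itself; an intergenic connection scores the distance modifier for the gap
#' between the two genes; an overlap connection scores the implied second
#' gene (overlapping genes carry no distance modifier).
#'
#' @param kind one of "gene", "intergenic", "same_strand_overlap",
#'   "opposite_strand_overlap".
#' @param gene_score score of the gene carried by the connection (ignored for
#'   intergenic connections).
#' @param gap signed gap in bp between the two gene extents (negative for
#'   overlaps: gap = -overlap).
#' @param pass "final" or "training".
#' @param params parameter list.
#' @return Numeric connection score.
#' @export
connection_score <- function(kind = c("gene", "intergenic",
                                      "same_strand_overlap",
                                      "opposite_strand_overlap"),
                             gene_score = 0, gap = NA_integer_,
                             pass = c("final", "training"),
                             params = gt_params()) {
  kind <- match.arg(kind)
  pass <- match.arg(pass)
  if (kind == "gene") return(gene_score)
  bonus <- if (pass == "final") params$final_operon_bonus else params$train_dist_mod
  penalty <- if (pass == "final") params$final_operon_penalty else params$train_dist_mod
  if (is.na(gap)) stop("intergenic and overlap connections need a gap")
  if (kind == "same_strand_overlap" && -gap > params$same_strand_max_overlap) {
    stop("same-strand overlap exceeds ", params$same_strand_max_overlap, " bp")
  }
  if (kind == "opposite_strand_overlap" && -gap > params$opp_strand_max_overlap) {
    stop("opposite-strand overlap exceeds ", params$opp_strand_max_overlap, " bp")
  }
  if (kind != "intergenic") return(gene_score)
  if (gap < params$operon_bonus_dist) bonus
  else if (gap > params$operon_penalty_dist) -penalty
  else 0
}
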