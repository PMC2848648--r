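# Independent oracle for the dynamic-programming engine: exhaustively
# enumerates gene sequences (tilings) under the pairwise connection rules and
# returns the maximal total score. Kept deliberately separate from the DP
# implementation: recursion over coordinate-sorted candidate genes with
# closed-form leading/trailing hop terms.
#
# Channel bookkeeping: a reverse gene reached through an opposite-strand
# overlap connection stands at its 5' node, so it cannot subsequently open a
# reverse-reverse overlap connection (which leaves from its 3' node before
# the gene connection). The path may also end on a dangling reverse-reverse
# overlap connection, which re-scores nothing but collects the short-gap
# bonus.

oracle_best_tiling <- function(nodes, scores, scores_waived = NULL,
                               waiver_ok = NULL, pass = "final",
                               params = gt_params()) {
  asm <- genetiler:::dp_assemble(nodes)
  g <- asm$genes
  ng <- nrow(g)
  if (is.null(scores_waived)) scores_waived <- scores
  if (is.null(waiver_ok)) waiver_ok <- rep(FALSE, ng)
  final <- pass == "final"
  bonus <- if (final) params$final_operon_bonus else params$train_dist_mod
  pen <- if (final) params$final_operon_penalty else params$train_dist_mod
  dmod <- function(gap) {
    ifelse(gap < params$operon_bonus_dist, bonus,
           ifelse(gap > params$operon_penalty_dist, -pen, 0))
  }
  waive_ok_at <- function(j, ovl) final && waiver_ok[j] && ovl %in% c(1L, 4L)
  dpn <- asm$dp_nodes
  exit_like <- dpn$coord[dpn$type %in% c(1L, 3L)]   # 3'F and 5'R
  entry_like <- dpn$coord[dpn$type %in% c(0L, 2L)]  # 5'F and 3'R
  ef_coords <- dpn$coord[dpn$type == 1L]
  er_coords <- dpn$coord[dpn$type == 2L]

  # best path-ending value after gene i (entered via channel `via_opp`)
  trail <- function(i, via_opp) {
    coord <- g$right[i]
    w <- entry_like[entry_like > coord &
                      entry_like - coord - 1L <= params$max_connection_gap]
    best <- if (length(w)) max(0, dmod(w - coord - 1L)) else 0
    if (g$strand[i] == -1L && !via_opp) {
      # dangling reverse-reverse overlap connection: no distance modifier, so
      # it only ever pays through the waiver delta on gene i
      eb <- er_coords[er_coords > g$left[i] &
                        er_coords >= g$right[i] - params$same_strand_max_overlap + 1L &
                        er_coords <= g$right[i] & er_coords != g$left[i]]
      for (cb in eb) {
        ovl <- g$right[i] - cb + 1L
        delta <- if (waive_ok_at(i, ovl)) scores_waived[i] - scores[i] else 0
        best <- max(best, delta)
      }
    }
    best
  }

  # entry options for gene j as first gene: value includes the gene's score;
  # returns c(normal_channel, opp_channel) with -Inf for unavailable
  lead_value <- function(j) {
    entry <- g$left[j]
    u <- exit_like[exit_like < entry &
                     entry - exit_like - 1L <= params$max_connection_gap]
    normal <- (if (length(u)) max(0, dmod(entry - u - 1L)) else 0) + scores[j]
    opp <- -Inf
    if (g$strand[j] == 1L) {
      uu <- ef_coords[ef_coords >= g$left[j] &
                        ef_coords <= min(g$left[j] + params$same_strand_max_overlap - 1L,
                                         g$right[j] - 1L)]
      for (cu in uu) {
        ovl <- cu - g$left[j] + 1L
        sc <- if (waive_ok_at(j, ovl)) scores_waived[j] else scores[j]
        normal <- max(normal, sc)
      }
    } else {
      uu <- ef_coords[ef_coords >= g$left[j] &
                        ef_coords <= min(g$left[j] + params$opp_strand_max_overlap - 1L,
                                         g$right[j] - 1L)]
      if (length(uu)) opp <- scores[j]
    }
    c(normal, opp)
  }

  # delta for appending gene j after gene i, or NULL if illegal; returns
  # list(value, via_opp for j)
  pair_value <- function(i, j, i_via_opp) {
    if (g$left[j] <= g$left[i] || g$right[j] <= g$right[i]) return(NULL)
    gap <- g$left[j] - g$right[i] - 1L
    if (gap >= 0L) {
      if (gap > params$max_connection_gap) return(NULL)
      return(list(value = scores[j] + dmod(gap), via_opp = FALSE))
    }
    ovl <- -gap
    si <- g$strand[i]; sj <- g$strand[j]
    if (si == 1L && sj == 1L) {
      if (ovl > params$same_strand_max_overlap) return(NULL)
      sc <- if (waive_ok_at(j, ovl)) scores_waived[j] else scores[j]
      return(list(value = sc, via_opp = FALSE))
    }
    if (si == -1L && sj == -1L) {
      if (ovl > params$same_strand_max_overlap || i_via_opp) return(NULL)
      # the connection leaves from gene i's 3' node and carries gene i; the
      # waiver therefore applies to gene i (the downstream minus-strand gene)
      delta <- if (waive_ok_at(i, ovl)) scores_waived[i] - scores[i] else 0
      return(list(value = scores[j] + delta, via_opp = FALSE))
    }
    if (si == 1L && sj == -1L) {
      if (ovl > params$opp_strand_max_overlap) return(NULL)
      return(list(value = scores[j], via_opp = TRUE))
    }
    NULL  # diverging 5' ends may not overlap
  }

  ord <- order(g$left, g$right)
  best_total <- 0
  # empty path may still harvest a single bonus hop
  for (cu in exit_like) {
    w <- entry_like[entry_like > cu &
                      entry_like - cu - 1L <= params$max_connection_gap]
    if (length(w)) best_total <- max(best_total, dmod(w - cu - 1L))
  }
  recurse <- function(i, via_opp, cum) {
    best_total <<- max(best_total, cum + trail(i, via_opp))
    for (j in ord) {
      if (g$left[j] <= g$left[i]) next
      pv <- pair_value(i, j, via_opp)
      if (!is.null(pv)) recurse(j, pv$via_opp, cum + pv$value)
    }
  }
  for (j in ord) {
    lv <- lead_value(j)
    if (is.finite(lv[1])) recurse(j, FALSE, lv[1])
    if (is.finite(lv[2])) recurse(j, TRUE, lv[2])
  }
  best_total
}

# random DNA of length n
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
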