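# Orchestration: train a profile on the input, score every candidate start,
# call genes with the final dynamic-programming pass, and write outputs.

# per-position hexamer score array for one encoded strand reading (0 where the
# word is incomplete or contains N)
hex_score_array <- function(enc, table) {
  h <- hexamer_codes(enc)
  v <- unclass(table)[h + 1L]
  v[is.na(v)] <- 0
  v
}

# step-3 cumulative sums of a per-position array, one per residue class
step3_cums <- function(hs) {
  n <- length(hs)
  lapply(0:2, function(f) {
    if (n <= f) return(0)
    c(0, cumsum(hs[seq.int(f + 1L, n, by = 3L)]))
  })
}

# sum of in-frame hexamer scores for genes [q1, q2] (0-based, own strand,
# stop codon excluded from windows)
coding_from_cums <- function(cums, q1, q2) {
  f <- q1 %% 3L
  k1 <- q1 %/% 3L
  k2 <- (q2 - 8L - f) %/% 3L
  out <- numeric(length(q1))
  for (ff in 0:2) {
    i <- which(f == ff)
    if (!length(i)) next
    cf <- cums[[ff + 1L]]
    ok <- i[k2[i] >= k1[i] & (k2[i] + 2L) <= length(cf)]
    out[ok] <- cf[k2[ok] + 2L] - cf[k1[ok] + 1L]
  }
  out
}

# workspace for one contig: nodes, assembled genes, raw coding scores and
# upstream sequence windows
contig_workspace <- function(rec, params, hex_table = NULL) {
  nodes <- enumerate_nodes(rec, params$min_gene_len)
  asm <- dp_assemble(nodes)
  genes <- asm$genes
  bases <- rec$bases[[1]]
  L <- nchar(bases)
  rc <- reverse_complement(bases)
  ws <- list(id = rec$id[[1]], L = L, bases = bases, rc = rc,
             nodes = nodes, genes = genes)
  if (!is.null(hex_table) && nrow(genes)) {
    cums_f <- step3_cums(hex_score_array(encode_bases(bases), hex_table))
    cums_r <- step3_cums(hex_score_array(encode_bases(rc), hex_table))
    q1 <- ifelse(genes$strand == 1L, genes$left, L - 1L - genes$right)
    q2 <- ifelse(genes$strand == 1L, genes$right, L - 1L - genes$left)
    C <- numeric(nrow(genes))
    fwd <- genes$strand == 1L
    C[fwd] <- coding_from_cums(cums_f, q1[fwd], q2[fwd])
    C[!fwd] <- coding_from_cums(cums_r, q1[!fwd], q2[!fwd])
    ws$C_raw <- C
  }
  ws
}

# upstream windows (width bp, 5'->3', ending just before the start codon)
upstream_strings <- function(ws, genes, width) {
  fwd <- genes$strand == 1L
  out <- character(nrow(genes))
  l <- genes$left[fwd]
  out[fwd] <- substring(ws$bases, pmax(1L, l - width + 1L), l)
  q <- ws$L - 1L - genes$right[!fwd]
  out[!fwd] <- substring(ws$rc, pmax(1L, q - width + 1L), q)
  out
}

# truncation penalty + long-gene boost applied per ORF (stop group)
adjust_coding <- function(genes, C, gc, params) {
  ord <- order(genes$orf, -genes$len, genes$left)
  adj <- C
  grp <- split(ord, genes$orf[ord])
  for (g in grp) adj[g] <- truncation_penalty(C[g])
  long_gene_boost(adj, genes$len, gc, params)
}

# overall GC fraction and symmetrized base frequencies of the input
input_composition <- function(records) {
  counts <- c(A = 0, C = 0, G = 0, T = 0)
  total <- 0
  for (b in records$bases) {
    enc <- encode_bases(b)
    tb <- tabulate(enc + 1L, 4L)
    counts <- counts + tb
    total <- total + sum(tb)
  }
  fr <- counts / max(1, total)
  sym <- (fr + fr[c("T", "G", "C", "A")]) / 2
  names(sym) <- BASES
  list(gc = unname(fr["C"] + fr["G"]), base_freq = sym)
}

#' Train an organism-specific gene model
#'
#' Learns everything needed to call genes from nothing but the input
#' sequence: the GC frame-plot bias, a preliminary training tiling by
#' dynamic programming over preliminary scores, the hexamer coding model,
#' start-codon and RBS bin weights via iterative peak refinement (with a
#' secondary motif search when the organism does not use the Shine-Dalgarno
#' motif), and the generic upstream PWM.
#'
#' @param records tibble from [read_genome_fasta()] (or compatible).
#' @param params parameter list from [gt_params()].
#' @param quiet suppress progress messages.
#' @return An object of class `gt_profile`.
#' @export
gt_train <- function(records, params = gt_params(), quiet = TRUE) {
  stopifnot(nrow(records) >= 1L)
  total_bp <- sum(nchar(records$bases))
  if (total_bp < params$min_train_bp) {
    stop("training input is only ", total_bp, " bp; at least ",
         params$min_train_bp, " bp are required to learn a usable model")
  }
  if (total_bp < params$warn_train_bp) {
    warning("training input is under ", format(params$warn_train_bp, scientific = FALSE),
            " bp; the model may be unreliable")
  }
  say <- function(...) if (!quiet) message(...)
  comp <- input_composition(records)
  say("computing GC frame bias")
  bias <- compute_gc_bias(records, params$min_gene_len)

  say("building training tiling")
  ws_list <- lapply(seq_len(nrow(records)), function(k) {
    contig_workspace(records[k, , drop = FALSE], params)
  })
  tiling <- list()
  for (ws in ws_list) {
    if (!nrow(ws$genes)) next
    lab_f <- max_frame_profile(ws$bases, params$gc_window)
    lab_r <- max_frame_profile(ws$rc, params$gc_window)
    cum_f <- lapply(1:3, function(c) cumsum(lab_f == c))
    cum_r <- lapply(1:3, function(c) cumsum(lab_r == c))
    g <- ws$genes
    q1 <- ifelse(g$strand == 1L, g$left, ws$L - 1L - g$right)
    q2 <- ifelse(g$strand == 1L, g$right, ws$L - 1L - g$left)
    S <- numeric(nrow(g))
    fwd <- g$strand == 1L
    S[fwd] <- prelim_scores_batch(cum_f, q1[fwd], q2[fwd], bias$b)
    S[!fwd] <- prelim_scores_batch(cum_r, q1[!fwd], q2[!fwd], bias$b)
    sel <- dp_optimal_path(ws$nodes, S, pass = "training", params = params)
    if (nrow(sel)) {
      tiling[[length(tiling) + 1L]] <- tibble::tibble(
        contig = ws$id, strand = sel$strand, left = sel$left, right = sel$right)
    }
  }
  tiling <- if (length(tiling)) dplyr::bind_rows(tiling) else
    tibble::tibble(contig = character(0), strand = integer(0),
                   left = integer(0), right = integer(0))
  say("training hexamer model on ", nrow(tiling), " genes")
  hex <- train_hexamers(tiling, records, params)

  say("scoring candidate starts")
  starts <- list()
  for (k in seq_along(ws_list)) {
    ws <- contig_workspace(records[k, , drop = FALSE], params, hex)
    ws_list[[k]] <- ws
    g <- ws$genes
    if (!nrow(g)) next
    starts[[length(starts) + 1L]] <- tibble::tibble(
      contig = ws$id, strand = g$strand, left = g$left, right = g$right,
      len = g$len, codon = g$codon, edge = g$edge,
      orf_key = paste0(ws$id, g$stop_key), C = ws$C_raw,
      up21 = upstream_strings(ws, g, params$upstream_window),
      up45 = upstream_strings(ws, g, 45L)
    )
  }
  starts <- dplyr::bind_rows(starts)
  sne <- starts[!starts$edge & !is.na(starts$codon), , drop = FALSE]
  if (nrow(sne) == 0L) stop("no candidate starts found; cannot train a start model")
  sne$orf <- match(sne$orf_key, unique(sne$orf_key))
  sne <- sne[order(sne$orf, -sne$len, sne$left), , drop = FALSE]

  say("iterative start training")
  chm <- upstream_char_matrix(sne$up21, params$upstream_window)
  adm <- sd_admissibility(chm)
  peaks0 <- initial_peaks(sne, params)
  sd_fit <- iterate_start_training(sne, adm, peaks0, params)
  uses_sd <- detect_sd_usage(sd_fit$rbs_w)
  sec <- NULL
  type_w <- sd_fit$type_w
  final_peaks <- sd_fit$peaks
  if (!uses_sd) {
    say("no strong Shine-Dalgarno signal; running the secondary motif finder")
    sec <- find_secondary_motif(sne, chm, sd_fit$peaks, params)
    if (length(sec$words)) {
      type_w <- sec$type_w
      final_peaks <- sec$peaks
    }
  }
  rbs_mode <- if (uses_sd) "SD"
    else if (!is.null(sec) && length(sec$words) &&
             sec$top_weight >= params$sec_clearcut_weight && sec$none_w < 0) "SECONDARY"
    else "MAX"
  pwm <- train_upstream_pwm(sne$up45[final_peaks], comp$base_freq, params)

  structure(list(
    version = 1L,
    table_id = if (!is.null(records$table_id)) records$table_id[[1]] else 11L,
    gc = comp$gc,
    base_freq = comp$base_freq,
    gc_bias = bias$b,
    n_bias_orfs = bias$n_orfs,
    hexamer = hex,
    type_w = type_w,
    rbs_w = sd_fit$rbs_w,
    uses_sd = uses_sd,
    rbs_mode = rbs_mode,
    sec_words = if (!is.null(sec)) sec$words else character(0),
    sec_weights = if (!is.null(sec)) sec$weights else matrix(0, 0, 4),
    sec_none_w = if (!is.null(sec)) sec$none_w else 0,
    pwm = pwm,
    params = params,
    training = list(
      n_train_genes = nrow(tiling),
      n_peaks = length(final_peaks),
      sd_moved = sd_fit$moved,
      sd_iterations = sd_fit$iterations,
      sec_moved = if (!is.null(sec)) sec$moved else integer(0)
    )
  ), class = "gt_profile")
}

# per-start signal components (R, T, U) plus RBS bookkeeping for one contig
start_components <- function(ws, profile, params) {
  g <- ws$genes
  n <- nrow(g)
  R <- T_ <- U <- numeric(n)
  has_rbs <- rep(FALSE, n)
  sd_bin <- rep(NA_integer_, n)
  sec_word <- rep(NA_character_, n)
  sec_class <- rep(NA_integer_, n)
  scoreable <- !g$edge & !is.na(g$codon)
  if (any(scoreable)) {
    gi <- which(scoreable)
    up21 <- upstream_strings(ws, g[gi, , drop = FALSE], params$upstream_window)
    up45 <- upstream_strings(ws, g[gi, , drop = FALSE], 45L)
    chm <- upstream_char_matrix(up21, params$upstream_window)
    adm <- sd_admissibility(chm)
    bins <- choose_bins(adm, profile$rbs_w)
    R_sd <- profile$rbs_w[bins + 1L]
    R_sec <- rep(profile$sec_none_w, length(gi))
    bins_sec <- rep(0L, length(gi))
    if (length(profile$sec_words)) {
      nw <- length(profile$sec_words)
      adm2 <- matrix(FALSE, length(gi), 1L + 4L * nw)
      adm2[, 1L] <- TRUE
      for (i in seq_len(nw)) {
        adm2[, 1L + (i - 1L) * 4L + 1:4] <- word_admissibility(chm, profile$sec_words[i])
      }
      wflat <- c(profile$sec_none_w, as.vector(t(profile$sec_weights)))
      bins_sec <- choose_bins(adm2, wflat)
      R_sec <- wflat[bins_sec + 1L]
    }
    Ri <- switch(profile$rbs_mode,
                 SD = R_sd,
                 SECONDARY = R_sec,
                 MAX = pmax(R_sd, R_sec))
    R[gi] <- Ri
    T_[gi] <- profile$type_w[g$codon[gi]]
    U[gi] <- upstream_pwm_score(up45, profile$pwm, params)
    sd_bin[gi] <- bins
    use_sec <- profile$rbs_mode == "SECONDARY" |
      (profile$rbs_mode == "MAX" & R_sec > R_sd)
    has_rbs[gi] <- ifelse(use_sec, bins_sec > 0L, bins > 0L)
    if (length(profile$sec_words)) {
      w_idx <- (bins_sec - 1L) %/% 4L + 1L
      c_idx <- (bins_sec - 1L) %% 4L + 1L
      sec_word[gi] <- ifelse(use_sec & bins_sec > 0L, profile$sec_words[w_idx], NA)
      sec_class[gi] <- ifelse(use_sec & bins_sec > 0L, c_idx, NA)
    }
  }
  list(R = R, T = T_, U = U, has_rbs = has_rbs, sd_bin = sd_bin,
       sec_word = sec_word, sec_class = sec_class)
}

# is gene B (right) legal immediately after gene A (left)?
pair_legal <- function(a_left, a_right, a_strand, b_left, b_right, b_strand,
                       params = gt_params()) {
  if (b_left <= a_left || b_right <= a_right) return(FALSE)
  gap <- b_left - a_right - 1L
  if (gap >= 0L) return(TRUE)
  ovl <- -gap
  if (a_strand == b_strand) return(ovl <= params$same_strand_max_overlap)
  if (a_strand == 1L && b_strand == -1L) return(ovl <= params$opp_strand_max_overlap)
  FALSE  # diverging 5' ends may not overlap
}

#' Predict genes with a trained profile
#'
#' Scores every candidate start (coding score with truncation penalty and
#' long-gene boost, RBS/type/upstream signals with the length-scaled start
#' weight), runs the final dynamic-programming pass with operon-distance
#' modifiers and the 1/4 bp overlap RBS waiver, removes genes with
#' non-positive scores, and applies the close-start tie-break.
#'
#' @param records tibble from [read_genome_fasta()].
#' @param profile a `gt_profile` from [gt_train()].
#' @param diagnostics if TRUE, attach a tibble of every scored candidate
#'   start as attribute "starts".
#' @return A tibble of gene predictions (class `gt_genes`), one row per gene,
#'   sorted by contig and begin coordinate, with 1-based inclusive `begin`/
#'   `end`, strand, partial flags, start codon, RBS assignment, and component
#'   scores.
#' @export
gt_predict <- function(records, profile, diagnostics = FALSE) {
  stopifnot(inherits(profile, "gt_profile"))
  params <- profile$params
  out <- list()
  diag <- list()
  for (k in seq_len(nrow(records))) {
    ws <- contig_workspace(records[k, , drop = FALSE], params, profile$hexamer)
    g <- ws$genes
    if (!nrow(g)) next
    g$orf <- match(g$stop_key, unique(g$stop_key))
    C_adj <- adjust_coding(g, ws$C_raw, profile$gc, params)
    cmp <- start_components(ws, profile, params)
    cs <- combine_start_score(C_adj, cmp$R, cmp$T, cmp$U, g$len, params)
    cs_w <- combine_start_score(C_adj, 0, cmp$T, cmp$U, g$len, params)
    waiver_ok <- !cmp$has_rbs & cmp$R < 0
    sel <- dp_optimal_path(ws$nodes, cs$total, cs_w$total, waiver_ok,
                           pass = "final", params = params)
    if (diagnostics) {
      diag[[length(diag) + 1L]] <- tibble::tibble(
        contig = ws$id, begin = g$left + 1L, end = g$right + 1L,
        strand = ifelse(g$strand == 1L, "+", "-"),
        start_codon = g$codon, edge = g$edge, length = g$len,
        C = C_adj, R = cmp$R, T = cmp$T, U = cmp$U,
        start_w = cs$start_w, total = cs$total, sd_bin = cmp$sd_bin
      )
    }
    if (!nrow(sel)) next
    sel_rows <- match(sel$node_row, g$node_row)
    # close-start tie-break: within 15 bp of the chosen start, coding is
    # considered equal and the start weight alone decides
    sel_rows <- tiebreak_starts(g, sel_rows, cs$start_w, params)
    sel <- g[sel_rows, , drop = FALSE]
    waived <- dp_waived_flags(g, sel_rows, sel, ws, cs, cs_w, waiver_ok, params)
    total <- ifelse(waived, cs_w$total[sel_rows], cs$total[sel_rows])
    keep <- total > 0
    sel <- sel[keep, , drop = FALSE]
    sel_rows <- sel_rows[keep]
    waived <- waived[keep]
    total <- total[keep]
    if (!nrow(sel)) next
    out[[length(out) + 1L]] <- tibble::tibble(
      contig = ws$id,
      begin = sel$left + 1L,
      end = sel$right + 1L,
      strand = ifelse(sel$strand == 1L, "+", "-"),
      partial_left = sel$partial_left,
      partial_right = sel$partial_right,
      start_codon = sel$codon,
      length = sel$len,
      score_coding = C_adj[sel_rows],
      score_rbs = ifelse(waived, 0, cmp$R[sel_rows]),
      score_type = cmp$T[sel_rows],
      score_upstream = cmp$U[sel_rows],
      score_start = ifelse(waived, cs_w$start_w[sel_rows], cs$start_w[sel_rows]),
      score_total = total,
      rbs_waived = waived,
      sd_bin = cmp$sd_bin[sel_rows],
      sec_word = cmp$sec_word[sel_rows],
      sec_class = cmp$sec_class[sel_rows]
    )
  }
  preds <- if (length(out)) dplyr::bind_rows(out) else empty_predictions()
  preds <- dplyr::arrange(preds, match(.data$contig, records$id), .data$begin, .data$end)
  preds <- annotate_rbs_details(preds, records, profile)
  preds$gene_id <- paste0(preds$contig, "_",
                          stats::ave(seq_len(nrow(preds)), preds$contig, FUN = seq_along))
  class(preds) <- c("gt_genes", class(preds))
  if (diagnostics) attr(preds, "starts") <- dplyr::bind_rows(diag)
  preds
}

empty_predictions <- function() {
  tibble::tibble(contig = character(0), begin = integer(0), end = integer(0),
                 strand = character(0), partial_left = logical(0),
                 partial_right = logical(0), start_codon = character(0),
                 length = integer(0), score_coding = numeric(0),
                 score_rbs = numeric(0), score_type = numeric(0),
                 score_upstream = numeric(0), score_start = numeric(0),
                 score_total = numeric(0), rbs_waived = logical(0),
                 sd_bin = integer(0), sec_word = character(0),
                 sec_class = integer(0))
}

# re-derive which selected genes had the RBS waiver applied (1 or 4 bp
# same-strand overlap with the previous selected gene)
dp_waived_flags <- function(g, sel_rows, sel, ws, cs, cs_w, waiver_ok, params) {
  n <- length(sel_rows)
  waived <- rep(FALSE, n)
  if (n < 2L) return(waived)
  ord <- order(sel$left)
  for (k in 2:n) {
    i <- ord[k]; p <- ord[k - 1L]
    if (sel$strand[i] != sel$strand[p]) next
    ovl <- sel$right[p] - sel$left[i] + 1L
    if (ovl %in% c(1L, 4L) && waiver_ok[sel_rows[i]]) waived[i] <- TRUE
  }
  waived
}

# choose the best start within tiebreak_dist of the chosen one by start
# weight alone, keeping neighbor-pair legality
tiebreak_starts <- function(g, sel_rows, start_w, params) {
  if (length(sel_rows) < 1L) return(sel_rows)
  sel <- g[sel_rows, , drop = FALSE]
  ord <- order(sel$left)
  for (k in seq_along(ord)) {
    i <- ord[k]
    row <- sel_rows[i]
    five <- if (g$strand[row] == 1L) g$left[row] else g$right[row]
    cand <- which(g$orf == g$orf[row] & !g$edge &
                    abs(ifelse(g$strand == 1L, g$left, g$right) - five) <
                      params$tiebreak_dist)
    if (length(cand) <= 1L) next
    # neighbor legality
    ok <- vapply(cand, function(r) {
      if (k > 1L) {
        p <- sel_rows[ord[k - 1L]]
        if (!pair_legal(g$left[p], g$right[p], g$strand[p],
                        g$left[r], g$right[r], g$strand[r], params)) return(FALSE)
      }
      if (k < length(ord)) {
        nx <- sel_rows[ord[k + 1L]]
        if (!pair_legal(g$left[r], g$right[r], g$strand[r],
                        g$left[nx], g$right[nx], g$strand[nx], params)) return(FALSE)
      }
      TRUE
    }, logical(1))
    cand <- cand[ok]
    if (!length(cand)) next
    best <- cand[order(-start_w[cand], -g$len[cand])][1L]
    sel_rows[i] <- best
  }
  sel_rows
}

# add human-readable RBS motif/spacer columns for emitted genes
annotate_rbs_details <- function(preds, records, profile) {
  preds$rbs_motif <- rep("None", nrow(preds))
  preds$rbs_spacer <- rep(NA_integer_, nrow(preds))
  if (!nrow(preds)) return(preds)
  params <- profile$params
  for (i in seq_len(nrow(preds))) {
    if (isTRUE(preds$partial_left[i] & preds$strand[i] == "+") ||
        isTRUE(preds$partial_right[i] & preds$strand[i] == "-")) next
    rec <- records[records$id == preds$contig[i], , drop = FALSE]
    bases <- rec$bases[[1]]
    L <- nchar(bases)
    if (preds$strand[i] == "+") {
      l <- preds$begin[i] - 1L
      up <- substr(bases, max(1L, l - params$upstream_window + 1L), l)
    } else {
      q <- L - preds$end[i]   # 1-based rc end of the upstream window
      rc <- reverse_complement(bases)
      up <- substr(rc, max(1L, q - params$upstream_window + 1L), q)
    }
    if (!is.na(preds$sec_word[i])) {
      preds$rbs_motif[i] <- preds$sec_word[i]
      rng <- SEC_SPACER_CLASSES[[preds$sec_class[i]]]
      chm <- upstream_char_matrix(up, params$upstream_window)
      for (d in rng[1]:rng[2]) {
        if (match_at_spacer(chm, preds$sec_word[i], d)) { preds$rbs_spacer[i] <- d; break }
      }
    } else if (!is.na(preds$sd_bin[i]) && preds$sd_bin[i] > 0L && !preds$rbs_waived[i]) {
      det <- assign_sd_bin(up, profile$rbs_w)
      preds$rbs_motif[i] <- det$motif[1]
      preds$rbs_spacer[i] <- det$spacer[1]
    }
  }
  preds
}

#' Train and predict in one step
#'
#' @param records tibble from [read_genome_fasta()].
#' @param params parameter list.
#' @param quiet suppress progress messages.
#' @param diagnostics attach per-start diagnostics to the result.
#' @return A list with `profile` (gt_profile) and `genes` (gt_genes tibble).
#' @export
gt_run <- function(records, params = gt_params(), quiet = TRUE,
                   diagnostics = FALSE) {
  profile <- gt_train(records, params, quiet = quiet)
  genes <- gt_predict(records, profile, diagnostics = diagnostics)
  list(profile = profile, genes = genes)
}
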