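# Translation initiation site model: start-codon type weights, binned
# Shine-Dalgarno RBS motif weights, an exhaustive secondary motif finder for
# organisms that do not use SD, and a generic upstream position-weight matrix.
#
# All weight families are log-ratios log(R/B) of observed frequency in the
# current training peaks (R) over background frequency across all start nodes
# (B), with zero counts replaced by a single pseudo-occurrence, clamped to
# +/- weight_clamp.

#' The Shine-Dalgarno RBS bin table
#'
#' The 28 bins pairing motif sets with admissible spacer ranges, ordered by
#' default priority from lowest (0, no motif) to highest (27, AGGAGG at
#' 5-10 bp). `x` in a motif matches any single base. The spacer is the number
#' of bases between the motif's 3' end and the first base of the start codon.
#'
#' @return Tibble with columns `bin`, `motif`, `smin`, `smax` (one row per
#'   motif in a bin; bin 0 has motif "None").
#' @export
sd_bin_table <- function() {
  spec <- list(
    list(0L, "None", NA, NA),
    list(1L, c("GGA", "GAG", "AGG"), 3L, 4L),
    list(2L, c("GGA", "GAG", "AGG", "AGxAG", "GGxGG"), 13L, 15L),
    list(3L, c("AGGA", "GGAG", "GAGG", "AGxAGG", "AGGxGG"), 13L, 15L),
    list(4L, "AGxAG", 11L, 12L),
    list(5L, "AGxAG", 3L, 4L),
    list(6L, c("GGA", "GAG", "AGG"), 11L, 12L),
    list(7L, "GGxGG", 11L, 12L),
    list(8L, "GGxGG", 3L, 4L),
    list(9L, "AGxAG", 5L, 10L),
    list(10L, c("AGGAG", "GGAGG", "AGGAGG"), 13L, 15L),
    list(11L, c("AGGA", "GGAG", "GAGG"), 3L, 4L),
    list(12L, c("AGGA", "GGAG", "GAGG"), 11L, 12L),
    list(13L, c("GGA", "GAG", "AGG"), 5L, 10L),
    list(14L, "GGxGG", 5L, 10L),
    list(15L, "AGGA", 5L, 10L),
    list(16L, c("GGAG", "GAGG"), 5L, 10L),
    list(17L, c("AGxAGG", "AGGxGG"), 11L, 12L),
    list(18L, c("AGxAGG", "AGGxGG"), 3L, 4L),
    list(19L, c("AGxAGG", "AGGxGG"), 5L, 10L),
    list(20L, c("AGGAG", "GGAGG"), 11L, 12L),
    list(21L, "AGGAG", 3L, 4L),
    list(22L, "AGGAG", 5L, 10L),
    list(23L, "GGAGG", 3L, 4L),
    list(24L, "GGAGG", 5L, 10L),
    list(25L, "AGGAGG", 11L, 12L),
    list(26L, "AGGAGG", 3L, 4L),
    list(27L, "AGGAGG", 5L, 10L)
  )
  dplyr::bind_rows(lapply(spec, function(r) {
    tibble::tibble(bin = r[[1]], motif = r[[2]], smin = r[[3]], smax = r[[4]])
  }))
}

# upstream strings -> character matrix with `width` columns, right-aligned
# (last column = base immediately before the start codon); short strings are
# left-padded with '-'
upstream_char_matrix <- function(upstreams, width) {
  n <- length(upstreams)
  pad <- strrep("-", pmax(0L, width - nchar(upstreams)))
  u <- paste0(pad, substr(upstreams, pmax(1L, nchar(upstreams) - width + 1L),
                          nchar(upstreams)))
  matrix(unlist(strsplit(u, "", fixed = TRUE), use.names = FALSE),
         nrow = n, byrow = TRUE)
}

# does `pattern` (character scalar, 'x' wildcard) match at spacer d for each
# row of the upstream char matrix?
match_at_spacer <- function(chmat, pattern, d) {
  m <- nchar(pattern)
  width <- ncol(chmat)
  o <- width - d - m + 1L
  if (o < 1L) return(rep(FALSE, nrow(chmat)))
  pc <- strsplit(pattern, "", fixed = TRUE)[[1]]
  ok <- rep(TRUE, nrow(chmat))
  for (k in seq_len(m)) {
    if (pc[k] != "x") ok <- ok & (chmat[, o + k - 1L] == pc[k])
  }
  ok
}

# n x 28 admissibility matrix: is any motif of bin b present at an admissible
# spacer? column b+1 corresponds to bin b; bin 0 is always admissible
sd_admissibility <- function(chmat) {
  tab <- sd_bin_table()
  n <- nrow(chmat)
  adm <- matrix(FALSE, n, 28L)
  adm[, 1L] <- TRUE
  for (i in seq_len(nrow(tab))) {
    if (tab$bin[i] == 0L) next
    for (d in tab$smin[i]:tab$smax[i]) {
      hit <- match_at_spacer(chmat, tab$motif[i], d)
      adm[hit, tab$bin[i] + 1L] <- TRUE
    }
  }
  adm
}

# pick one bin per row: the admissible bin maximizing `weights` (ties toward
# the higher-numbered bin); passing weights 0:27 gives the initial
# highest-bin-wins priority rule
choose_bins <- function(adm, weights) {
  n <- nrow(adm)
  w <- matrix(rep(weights, each = n), n, length(weights))
  w <- w + matrix(rep(seq_along(weights) * 1e-9, each = n), n, length(weights))
  w[!adm] <- -Inf
  max.col(w, ties.method = "first") - 1L
}

#' Assign the best Shine-Dalgarno bin to upstream sequence
#'
#' Searches the window upstream of a start codon for the best-scoring RBS bin
#' of [sd_bin_table()]. With `weights = NULL` the initial priority rule is
#' used (the highest-numbered matching bin wins); otherwise the admissible
#' bin with the highest weight wins.
#'
#' @param upstream character vector of upstream sequences, each read 5' to 3'
#'   and ending at the base immediately before the start codon.
#' @param weights optional numeric vector of 28 bin weights.
#' @return Tibble with one row per input: `bin`, `motif` (matched upstream
#'   text, "None" for bin 0), `spacer` (NA for bin 0).
#' @export
assign_sd_bin <- function(upstream, weights = NULL) {
  width <- gt_params()$upstream_window
  chmat <- upstream_char_matrix(upstream, width)
  adm <- sd_admissibility(chmat)
  bins <- choose_bins(adm, if (is.null(weights)) as.numeric(0:27) else weights)
  tab <- sd_bin_table()
  motif <- rep("None", length(upstream))
  spacer <- rep(NA_integer_, length(upstream))
  for (i in which(bins > 0L)) {
    rows <- tab[tab$bin == bins[i], , drop = FALSE]
    rows <- rows[order(-nchar(rows$motif)), , drop = FALSE]
    found <- FALSE
    for (r in seq_len(nrow(rows))) {
      for (d in rows$smin[r]:rows$smax[r]) {
        if (match_at_spacer(chmat[i, , drop = FALSE], rows$motif[r], d)) {
          o <- width - d - nchar(rows$motif[r]) + 1L
          motif[i] <- paste(chmat[i, o:(o + nchar(rows$motif[r]) - 1L)], collapse = "")
          spacer[i] <- d
          found <- TRUE
          break
        }
      }
      if (found) break
    }
  }
  tibble::tibble(bin = bins, motif = motif, spacer = spacer)
}

# frequency vector with zero counts replaced by one pseudo-occurrence
freq_with_pseudo <- function(counts) {
  counts[counts == 0] <- 1
  counts / sum(counts)
}

clamp_weights <- function(w, params) {
  pmin(pmax(w, -params$weight_clamp), params$weight_clamp)
}

#' Select initial training starts from coding peaks
#'
#' The coding peak of an ORF is its highest-scoring start-stop pair; peaks
#' with a coding score of at least `peak_threshold` seed the start training.
#'
#' @param starts tibble of candidate starts with columns `orf` (stop-group
#'   id), `C` (coding score), ordered outermost start first within each ORF.
#' @param params parameter list from [gt_params()].
#' @return Integer vector of row indices into `starts`, one per selected ORF.
#' @export
initial_peaks <- function(starts, params = gt_params()) {
  ord <- order(starts$orf, -starts$C, seq_len(nrow(starts)))
  first <- ord[!duplicated(starts$orf[ord])]
  peaks <- first[starts$C[first] >= params$peak_threshold]
  if (length(peaks) < params$min_peaks) {
    warning("only ", length(peaks), " coding peaks reached the training ",
            "threshold; start training may be unreliable")
  }
  sort(peaks)
}

# one tabulation of type and bin weights from a peak set; both sides of the
# ratio use the same fixed priority assignment `bins` — an assignment that
# moves with the weights makes correlated bins saturate the clamp and cycle,
# while the symmetric rule yields honest enrichment ratios. The learned
# weights drive only the peak re-picking and the final start scoring.
tabulate_weights <- function(starts, peaks, bins, nbins, params) {
  type_levels <- START_CODONS
  type_all <- factor(starts$codon, levels = type_levels)
  tb <- freq_with_pseudo(table(type_all))
  tp <- freq_with_pseudo(table(type_all[peaks]))
  type_w <- clamp_weights(log(as.numeric(tp) / as.numeric(tb)), params)
  names(type_w) <- type_levels
  bb <- freq_with_pseudo(tabulate(bins + 1L, nbins))
  bp <- freq_with_pseudo(tabulate(bins[peaks] + 1L, nbins))
  rbs_w <- clamp_weights(log(bp / bb), params)
  list(type_w = type_w, rbs_w = rbs_w)
}

#' Iterative start training
#'
#' Alternates between (1) tabulating start-codon type and RBS-bin
#' log-likelihood weights from the current peaks against the background of
#' all start nodes and (2) re-picking each ORF's peak to maximize
#' coding + start_weight * (type + RBS), until fewer than `start_move_tol`
#' of the peaks move or `max_start_iter` iterations are reached. In the first
#' iteration the RBS bin is assigned by the highest-bin-wins priority rule;
#' afterwards by the current weights.
#'
#' @param starts tibble of candidate starts (`orf`, `codon`, `C`), ordered
#'   outermost-first within ORFs; edge starts must be excluded.
#' @param adm logical admissibility matrix from the SD bin search
#'   (n starts x 28).
#' @param peaks initial peak row indices from [initial_peaks()].
#' @param params parameter list.
#' @return List with `type_w` (named 3-vector), `rbs_w` (28 weights for bins
#'   0..27), `bins_all` (final bin assignment of every start), `peaks` (final
#'   peak rows), `moved` (peaks moved per iteration), `iterations`.
#' @export
iterate_start_training <- function(starts, adm, peaks, params = gt_params()) {
  nbins <- ncol(adm)
  moved_hist <- integer(0)
  rbs_w <- NULL
  orf_of_peaks <- starts$orf[peaks]
  cand <- which(starts$orf %in% orf_of_peaks)
  bins_bg <- choose_bins(adm, as.numeric(seq_len(nbins) - 1L))
  for (it in seq_len(params$max_start_iter)) {
    w <- tabulate_weights(starts, peaks, bins_bg, nbins, params)
    rbs_w <- w$rbs_w
    type_w <- w$type_w
    bins_new <- choose_bins(adm, rbs_w)
    obj <- starts$C[cand] + params$start_weight *
      (type_w[starts$codon[cand]] + rbs_w[bins_new[cand] + 1L])
    ord <- order(starts$orf[cand], -obj, cand)
    newpeaks <- sort(cand[ord][!duplicated(starts$orf[cand][ord])])
    moved <- sum(!(newpeaks %in% peaks))
    moved_hist <- c(moved_hist, moved)
    peaks <- newpeaks
    if (moved < params$start_move_tol * length(peaks)) break
  }
  # final weights from the settled peak set
  w <- tabulate_weights(starts, peaks, bins_bg, nbins, params)
  list(type_w = w$type_w, rbs_w = w$rbs_w,
       bins_all = choose_bins(adm, w$rbs_w),
       peaks = peaks, moved = moved_hist, iterations = length(moved_hist))
}

#' Does the organism use the Shine-Dalgarno motif?
#'
#' The organism is judged not to use SD strongly when the no-motif bin weight
#' is positive, or when it is above -0.5 while none of the 4-base motif bins
#' (3, 11, 12) reaches 1.0.
#'
#' @param rbs_w numeric vector of 28 SD bin weights (bin 0 first).
#' @return TRUE if the organism uses the SD motif.
#' @export
detect_sd_usage <- function(rbs_w) {
  w0 <- rbs_w[1L]
  four <- max(rbs_w[c(3L, 11L, 12L) + 1L])
  !(w0 > 0 || (w0 > -0.5 && four < 1.0))
}

SEC_SPACER_CLASSES <- list(c(3L, 4L), c(5L, 10L), c(11L, 12L), c(13L, 15L))

# all exact words of length 3-6 containing `seed` as a substring
expand_seed_words <- function(seed) {
  out <- character(0)
  for (len in 3:6) {
    extra <- len - nchar(seed)
    if (extra < 0L) next
    for (off in 0:extra) {
      n_left <- off
      n_right <- extra - off
      flanks <- expand.grid(rep(list(BASES), n_left + n_right),
                            stringsAsFactors = FALSE)
      if (nrow(flanks) == 0L) flanks <- data.frame(row.names = 1L)
      for (r in seq_len(max(1L, nrow(flanks)))) {
        fl <- if (n_left + n_right > 0L) unlist(flanks[r, ], use.names = FALSE) else character(0)
        left <- if (n_left > 0L) paste(fl[seq_len(n_left)], collapse = "") else ""
        right <- if (n_right > 0L) paste(fl[seq_len(n_right) + n_left], collapse = "") else ""
        out <- c(out, paste0(left, seed, right))
      }
    }
  }
  unique(out)
}

# admissibility of word w (columns = spacer class) for every row of chmat
word_admissibility <- function(chmat, word) {
  n <- nrow(chmat)
  adm <- matrix(FALSE, n, length(SEC_SPACER_CLASSES))
  for (k in seq_along(SEC_SPACER_CLASSES)) {
    rng <- SEC_SPACER_CLASSES[[k]]
    for (d in rng[1]:rng[2]) {
      adm[match_at_spacer(chmat, word, d), k] <- TRUE
    }
  }
  adm
}

#' Exhaustive secondary (non-SD) motif search
#'
#' For organisms that do not use the Shine-Dalgarno motif: finds all 3-mers
#' present upstream (spacer 3-15 bp) of at least `sec_seed_frac` of the
#' training peaks, expands them to every 3-6 bp word containing a seed,
#' drops words present in fewer than `sec_word_min_frac` of the peaks into
#' the no-motif bin, and runs the same iterative log(R/B) training over
#' word-by-spacer-class bins (spacer classes 3-4, 5-10, 11-12, 13-15 bp).
#'
#' @param starts,peaks,params as in [iterate_start_training()].
#' @param chmat upstream character matrix for all starts (21 columns).
#' @return List with `words` (kept words; may be empty), `weights` (matrix
#'   words x 4 spacer classes), `none_w`, `type_w`, `bins_all` (final flat
#'   bin index per start, 0 = no motif), `peaks`, `moved`, `top_weight`.
#' @export
find_secondary_motif <- function(starts, chmat, peaks, params = gt_params()) {
  n <- nrow(chmat)
  pk <- chmat[peaks, , drop = FALSE]
  npk <- nrow(pk)
  width <- ncol(chmat)
  # 3-mers present at any spacer 3..15 in each peak's upstream window
  found <- vector("list", npk)
  for (d in 3:15) {
    o <- width - d - 2L
    if (o < 1L) next
    w3 <- paste0(pk[, o], pk[, o + 1L], pk[, o + 2L])
    for (i in seq_len(npk)) found[[i]] <- c(found[[i]], w3[i])
  }
  occ <- table(unlist(lapply(found, unique)))
  occ <- occ[!grepl("[^ACGT]", names(occ))]
  seeds <- names(occ)[occ >= params$sec_seed_frac * npk]
  degenerate <- list(words = character(0),
                     weights = matrix(0, 0, length(SEC_SPACER_CLASSES)),
                     none_w = 0, type_w = NULL, bins_all = rep(0L, n),
                     peaks = peaks, moved = integer(0), top_weight = -Inf)
  if (!length(seeds)) return(degenerate)
  words <- sort(unique(unlist(lapply(seeds, expand_seed_words))))
  # keep words frequent enough among the peaks (any admissible spacer)
  keep <- vapply(words, function(w) {
    hit <- rep(FALSE, npk)
    for (d in 3:15) hit <- hit | match_at_spacer(pk, w, d)
    sum(hit) >= params$sec_word_min_frac * npk
  }, logical(1))
  words <- words[keep]
  if (!length(words)) return(degenerate)
  # flat bins: 0 = none, then (word i, class k) -> (i-1)*4 + k
  adm <- matrix(FALSE, n, 1L + 4L * length(words))
  adm[, 1L] <- TRUE
  for (i in seq_along(words)) {
    wa <- word_admissibility(chmat, words[i])
    adm[, 1L + (i - 1L) * 4L + 1:4] <- wa
  }
  nbins <- ncol(adm)
  prio <- c(0, rep(nchar(words), each = 4L))  # longest word wins initially
  rbs_w <- NULL
  moved_hist <- integer(0)
  orf_of_peaks <- starts$orf[peaks]
  cand <- which(starts$orf %in% orf_of_peaks)
  bins_bg <- choose_bins(adm, prio)
  for (it in seq_len(params$sec_max_iter)) {
    w <- tabulate_weights(starts, peaks, bins_bg, nbins, params)
    rbs_w <- w$rbs_w
    type_w <- w$type_w
    bins_new <- choose_bins(adm, rbs_w)
    obj <- starts$C[cand] + params$start_weight *
      (type_w[starts$codon[cand]] + rbs_w[bins_new[cand] + 1L])
    ord <- order(starts$orf[cand], -obj, cand)
    newpeaks <- sort(cand[ord][!duplicated(starts$orf[cand][ord])])
    moved <- sum(!(newpeaks %in% peaks))
    moved_hist <- c(moved_hist, moved)
    peaks <- newpeaks
    if (moved < params$start_move_tol * length(peaks)) break
  }
  w <- tabulate_weights(starts, peaks, bins_bg, nbins, params)
  bins_all <- choose_bins(adm, w$rbs_w)
  wmat <- matrix(w$rbs_w[-1L], nrow = length(words), ncol = 4L, byrow = TRUE,
                 dimnames = list(words, c("3-4", "5-10", "11-12", "13-15")))
  list(words = words, weights = wmat, none_w = w$rbs_w[1L], type_w = w$type_w,
       bins_all = bins_all, peaks = peaks, moved = moved_hist,
       top_weight = if (length(wmat)) max(wmat) else -Inf)
}

#' Train the generic upstream position-weight matrix
#'
#' Builds per-position base weights log(observed/background) over the
#' upstream offsets not covered by the RBS scorer (1-2 bp and 15-45 bp before
#' the start codon), from the final training peaks only.
#'
#' @param up45 character vector: 45 bp upstream of each final peak (5' to 3',
#'   ending immediately before the start codon; may be shorter near contig
#'   edges).
#' @param bg_base named numeric background frequency of A/C/G/T.
#' @param params parameter list.
#' @return Numeric matrix 4 x length(pwm_offsets), rownames A/C/G/T,
#'   colnames the upstream offsets.
#' @export
train_upstream_pwm <- function(up45, bg_base, params = gt_params()) {
  offs <- params$pwm_offsets
  chmat <- upstream_char_matrix(up45, 45L)
  pwm <- matrix(0, 4L, length(offs), dimnames = list(BASES, as.character(offs)))
  for (j in seq_along(offs)) {
    col <- chmat[, 45L - offs[j] + 1L]
    counts <- vapply(BASES, function(b) sum(col == b), numeric(1))
    fr <- freq_with_pseudo(counts)
    pwm[, j] <- clamp_weights(log(fr / bg_base[BASES]), params)
  }
  pwm
}

# sum of PWM weights for each start given its 45 bp upstream string
upstream_pwm_score <- function(up45, pwm, params = gt_params()) {
  offs <- params$pwm_offsets
  chmat <- upstream_char_matrix(up45, 45L)
  u <- numeric(length(up45))
  for (j in seq_along(offs)) {
    col <- chmat[, 45L - offs[j] + 1L]
    idx <- match(col, BASES)
    v <- unname(pwm[idx, j])
    v[is.na(v)] <- 0
    u <- u + v
  }
  u
}
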