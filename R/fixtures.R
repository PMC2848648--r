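# Deterministic synthetic genomes with planted genes, and the evaluation
# metrics used to benchmark predictions against the planted truth.
#
# The generator emulates the statistical structure the algorithm trains on:
# codon usage with a controllable third-position GC bias (coding emission is
# an order-5 Markov chain that factorizes over codons of a GC-parameterized
# codon-usage profile), chosen start-codon usage, RBS regimes (Shine-Dalgarno
# motifs at chosen spacers, a secondary motif, or AT-rich upstream regions),
# operon-like intergenic gaps, and same-strand 1/4 bp and convergent
# overlaps. Planted genes never contain an in-frame stop.

#' Specification of a synthetic genome
#'
#' @param length genome length in bp.
#' @param gc target GC fraction (realized within about 0.02).
#' @param density target coding fraction of the genome.
#' @param bias3 third-position GC bias strength: GC3 is `gc + bias3`
#'   (clamped), so coding sequence prefers G/C in the third codon position.
#' @param start_usage named probabilities for ATG/GTG/TTG planted starts.
#' @param rbs_regime "sd" (AGGAGG at spacer 5-10), "secondary" (GGTG at
#'   spacer 3-10 with AT-rich upstream background), or "none" (AT-rich
#'   upstream regions only).
#' @param motif_prob probability that a planted gene receives the regime's
#'   motif upstream (where geometry allows).
#' @param operon_frac fraction of junctions drawn from the short operon-gap
#'   distribution (3-25 bp).
#' @param overlap_rate probability of injecting a 1 or 4 bp same-strand
#'   overlap (or a 4 bp convergent overlap at strand switches) at a junction.
#' @param strand_switch probability the next gene changes strand.
#' @param mean_gene_len,min_gene_len,max_gene_len gene length distribution
#'   (gamma, rounded to codons).
#' @param margin gene-free bp at each contig end.
#' @param contig_id contig name.
#' @param table_id NCBI translation table for the planted genes.
#' @param seed RNG seed; generation is a pure function of the spec.
#' @return An object of class `gt_genome_spec`.
#' @export
genome_spec <- function(length = 1e5, gc = 0.5, density = 0.8, bias3 = 0.25,
                        start_usage = c(ATG = 0.75, GTG = 0.15, TTG = 0.10),
                        rbs_regime = c("sd", "secondary", "none"),
                        motif_prob = 0.9, operon_frac = 0.6,
                        overlap_rate = 0.1, strand_switch = 0.3,
                        mean_gene_len = 900, min_gene_len = 150,
                        max_gene_len = 4500, margin = 200,
                        contig_id = "fixture", table_id = 11L, seed = 1L) {
  rbs_regime <- match.arg(rbs_regime)
  stopifnot(length >= 1000, gc > 0.2, gc < 0.8, density > 0.05,
            min_gene_len >= 90, mean_gene_len >= min_gene_len,
            abs(sum(start_usage) - 1) < 1e-6)
  if (density > 0.97) stop("infeasible spec: gene density above 0.97")
  mean_gap <- mean_gene_len * (1 / density - 1)
  long_gap_mean <- (mean_gap - operon_frac * 14) / (1 - operon_frac) - 40
  if (long_gap_mean < 2) stop("infeasible spec: density too high for the gap model")
  structure(list(length = as.integer(length), gc = gc, density = density,
                 bias3 = bias3, start_usage = start_usage,
                 rbs_regime = rbs_regime, motif_prob = motif_prob,
                 operon_frac = operon_frac, overlap_rate = overlap_rate,
                 strand_switch = strand_switch,
                 mean_gene_len = mean_gene_len, min_gene_len = min_gene_len,
                 max_gene_len = max_gene_len, margin = as.integer(margin),
                 contig_id = contig_id, table_id = as.integer(table_id),
                 seed = as.integer(seed), long_gap_mean = long_gap_mean),
            class = "gt_genome_spec")
}

# codon-usage profile: probability of each codon 0..63 (stops zero) as the
# product of per-position base distributions; third position carries the GC
# bias
codon_usage_profile <- function(gc, bias3) {
  blend <- function(p) {
    w <- gc / 0.5
    q <- p * c(1, w, w, 1)
    q / sum(q)
  }
  p1 <- blend(c(A = 0.26, C = 0.20, G = 0.33, T = 0.21))
  p2 <- blend(c(A = 0.30, C = 0.22, G = 0.17, T = 0.31))
  gc3 <- min(0.95, max(0.05, gc + bias3))
  p3 <- c(A = (1 - gc3) / 2, C = gc3 / 2, G = gc3 / 2, T = (1 - gc3) / 2)
  probs <- numeric(64)  # code = 16 b1 + 4 b2 + b3
  for (b1 in 0:3) for (b2 in 0:3) for (b3 in 0:3) {
    probs[16 * b1 + 4 * b2 + b3 + 1] <- p1[b1 + 1] * p2[b2 + 1] * p3[b3 + 1]
  }
  probs[c(48, 50, 56) + 1] <- 0  # TAA, TAG, TGA
  list(probs = probs / sum(probs),
       gc_coding = (sum(p1[2:3]) + sum(p2[2:3]) + gc3) / 3)
}

CODON_B1 <- (0:63) %/% 16L
CODON_B2 <- ((0:63) %/% 4L) %% 4L
CODON_B3 <- (0:63) %% 4L

#' Generate a synthetic genome with planted genes
#'
#' @param spec a `gt_genome_spec` from [genome_spec()].
#' @return List with `records` (tibble compatible with
#'   [read_genome_fasta()]) and `truth` (BED-like tibble of planted genes:
#'   `contig`, `begin`, `end` 1-based inclusive, `strand`, `start_codon`,
#'   `gene_id`).
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "gt_genome_spec"))
  withr::with_seed(spec$seed, generate_genome_impl(spec))
}

generate_genome_impl <- function(spec) {
  L <- spec$length
  cu <- codon_usage_profile(spec$gc, spec$bias3)

  # ---- layout ----------------------------------------------------------
  genes <- list()
  prev_right <- spec$margin - 1L
  prev_strand <- 0L
  repeat {
    len <- 3L * as.integer(round(stats::rgamma(1, shape = 2,
                                               scale = spec$mean_gene_len / 2) / 3))
    len <- as.integer(min(max(len, spec$min_gene_len), spec$max_gene_len))
    len <- len - len %% 3L
    strand <- if (prev_strand == 0L) sample(c(1L, -1L), 1L)
              else if (stats::runif(1) < spec$strand_switch) -prev_strand
              else prev_strand
    ovl <- "none"
    if (prev_strand != 0L) {
      u <- stats::runif(1)
      if (prev_strand == 1L && strand == 1L && u < spec$overlap_rate) {
        ovl <- sample(c("ovl1", "ovl4"), 1L)
        gap <- if (ovl == "ovl1") -1L else -4L
      } else if (prev_strand == 1L && strand == -1L && u < spec$overlap_rate) {
        ovl <- "conv4"
        gap <- -4L
      } else if (stats::runif(1) < spec$operon_frac) {
        gap <- sample(3:25, 1L)
      } else {
        gap <- 40L + stats::rgeom(1, 1 / spec$long_gap_mean)
      }
      if (prev_strand == -1L && strand == 1L) gap <- max(gap, 60L)  # diverging 5' ends
    } else gap <- 0L
    gap <- as.integer(gap)
    left <- prev_right + gap + 1L
    right <- left + len - 1L
    if (right > L - spec$margin) break
    genes[[length(genes) + 1L]] <- list(left = left, right = right,
                                        strand = strand, ovl = ovl)
    prev_right <- right
    prev_strand <- strand
  }
  ng <- length(genes)
  if (ng == 0L) stop("spec produced no genes; increase length")

  # ---- choose start/stop codons honoring junction constraints ----------
  start_codes <- c(ATG = 14L, GTG = 46L, TTG = 62L)
  stop_codes <- c(TAA = 48L, TGA = 56L, TAG = 50L)
  starts <- sample(names(spec$start_usage), ng, replace = TRUE,
                   prob = spec$start_usage)
  stops <- sample(names(stop_codes), ng, replace = TRUE,
                  prob = c(0.6, 0.25, 0.15))
  force_sense_end <- rep(NA_character_, ng)    # last base of last sense codon
  force_sense_start <- rep(NA_character_, ng)  # first base of first sense codon
  for (i in seq_len(ng)) {
    if (genes[[i]]$ovl == "ovl1") {
      # shared base: stop of i-1 ends with first base of start of i
      starts[i] <- sample(c("ATG", "GTG"), 1L,
                          prob = spec$start_usage[c("ATG", "GTG")])
      stops[i - 1L] <- if (starts[i] == "ATG") sample(c("TAA", "TGA"), 1L) else "TAG"
    } else if (genes[[i]]$ovl == "ovl4") {
      # ATGA: start ATG inside stop TGA, preceded by A; the base after the
      # shared stop is the next gene's first sense base and must stay A
      starts[i] <- "ATG"
      stops[i - 1L] <- "TGA"
      force_sense_end[i - 1L] <- "A"
      force_sense_start[i] <- "A"
    } else if (genes[[i]]$ovl == "conv4") {
      # TTAA: forward TAA stop overlapping reverse TAA stop; the reverse
      # gene's last sense codon must end T (read) so the shared A survives
      stops[i - 1L] <- "TAA"
      stops[i] <- "TAA"
      force_sense_end[i - 1L] <- "T"
      force_sense_end[i] <- "T"
    }
  }

  # ---- background ------------------------------------------------------
  coding_bp <- sum(vapply(genes, function(g) g$right - g$left + 1L, integer(1)))
  gi <- (spec$gc * L - cu$gc_coding * coding_bp) / max(1L, L - coding_bp)
  gi <- min(0.95, max(0.05, gi))
  bgp <- c((1 - gi) / 2, gi / 2, gi / 2, (1 - gi) / 2)
  seqv <- sample.int(4L, L, replace = TRUE, prob = bgp)  # 1..4 = A C G T
  protected <- logical(L)
  in_gene <- logical(L)

  # ---- write genes -----------------------------------------------------
  base_int <- function(ch) match(ch, BASES)
  for (i in seq_len(ng)) {
    g <- genes[[i]]
    len <- g$right - g$left + 1L
    n_sense <- len %/% 3L - 2L
    cod <- sample.int(64L, n_sense, replace = TRUE, prob = cu$probs) - 1L
    if (!is.na(force_sense_end[i]) && n_sense > 0L) {
      want <- CODON_B3 == (base_int(force_sense_end[i]) - 1L)
      p <- cu$probs * want
      cod[n_sense] <- sample.int(64L, 1L, prob = p / sum(p)) - 1L
    }
    if (!is.na(force_sense_start[i]) && n_sense > 0L) {
      want <- CODON_B1 == (base_int(force_sense_start[i]) - 1L)
      p <- cu$probs * want
      cod[1L] <- sample.int(64L, 1L, prob = p / sum(p)) - 1L
    }
    all_cod <- c(start_codes[starts[i]], cod, stop_codes[stops[i]])
    b <- as.integer(rbind(CODON_B1[all_cod + 1L],
                          CODON_B2[all_cod + 1L],
                          CODON_B3[all_cod + 1L])) + 1L
    if (g$strand == -1L) b <- rev(5L - b)
    seqv[g$left:g$right + 1L] <- b
    in_gene[g$left:g$right + 1L] <- TRUE
    # protect start and stop codons (forward coordinates)
    if (g$strand == 1L) {
      protected[g$left:(g$left + 2L) + 1L] <- TRUE
      protected[(g$right - 2L):g$right + 1L] <- TRUE
    } else {
      protected[(g$right - 2L):g$right + 1L] <- TRUE
      protected[g$left:(g$left + 2L) + 1L] <- TRUE
    }
  }

  # ---- AT-rich upstream regions (non-SD regimes): strong for the
  # cyanobacteria-like regime, moderate for the archaeon-like one (where the
  # planted motif is the dominant signal) ---------------------------------
  if (spec$rbs_regime != "sd") {
    atp <- if (spec$rbs_regime == "none") c(0.40, 0.10, 0.10, 0.40)
           else c(0.325, 0.175, 0.175, 0.325)
    for (i in seq_len(ng)) {
      g <- genes[[i]]
      reg <- if (g$strand == 1L) (g$left - 45L):(g$left - 1L)
             else (g$right + 1L):(g$right + 45L)
      reg <- reg[reg >= 0L & reg < L]
      reg <- reg[!in_gene[reg + 1L] & !protected[reg + 1L]]
      if (length(reg)) {
        seqv[reg + 1L] <- sample.int(4L, length(reg), replace = TRUE, prob = atp)
      }
    }
  }

  # ---- plant RBS motifs ------------------------------------------------
  motif_used <- rep(FALSE, ng)
  if (spec$rbs_regime != "none") {
    motif <- if (spec$rbs_regime == "sd") "AGGAGG" else "GGTG"
    spacers <- if (spec$rbs_regime == "sd") 5:10 else 3:10
    mi <- base_int(strsplit(motif, "")[[1]])
    m <- length(mi)
    for (i in seq_len(ng)) {
      if (stats::runif(1) >= spec$motif_prob) next
      g <- genes[[i]]
      for (d in sample(spacers)) {
        if (g$strand == 1L) {
          reg <- (g$left - d - m):(g$left - d - 1L)
          vals <- mi
        } else {
          reg <- (g$right + d + 1L):(g$right + d + m)
          vals <- rev(5L - mi)
        }
        if (reg[1] < 0L || reg[length(reg)] >= L) next
        if (any(protected[reg + 1L])) next
        seqv[reg + 1L] <- vals
        protected[reg + 1L] <- TRUE
        motif_used[i] <- TRUE
        break
      }
    }
  }

  # ---- repair in-frame interior stops introduced by overwrites ---------
  stop_set <- c(48L, 50L, 56L)
  for (i in seq_len(ng)) {
    g <- genes[[i]]
    b <- seqv[g$left:g$right + 1L]
    if (g$strand == -1L) b <- rev(5L - b)
    n_cod <- length(b) %/% 3L
    cod <- 16L * (b[seq(1L, by = 3L, length.out = n_cod)] - 1L) +
           4L * (b[seq(2L, by = 3L, length.out = n_cod)] - 1L) +
           (b[seq(3L, by = 3L, length.out = n_cod)] - 1L)
    bad <- which(cod %in% stop_set)
    bad <- bad[bad > 1L & bad < n_cod]
    for (j in bad) {
      # mutate the first unprotected base of the codon to C (as read), which
      # turns any stop codon into a sense codon
      for (k in 0:2) {
        off <- (j - 1L) * 3L + k    # 0-based offset of the base in the gene
        pos <- if (g$strand == 1L) g$left + off else g$right - off
        if (!protected[pos + 1L]) {
          seqv[pos + 1L] <- if (g$strand == 1L) 2L else 3L  # C on its own strand
          break
        }
      }
    }
  }

  bases <- intToUtf8(c(65L, 67L, 71L, 84L)[seqv])
  records <- tibble::tibble(id = spec$contig_id, bases = bases,
                            table_id = spec$table_id)
  truth <- tibble::tibble(
    contig = spec$contig_id,
    begin = vapply(genes, function(g) g$left + 1L, integer(1)),
    end = vapply(genes, function(g) g$right + 1L, integer(1)),
    strand = vapply(genes, function(g) if (g$strand == 1L) "+" else "-", character(1)),
    start_codon = starts,
    motif_planted = motif_used,
    gene_id = paste0(spec$contig_id, "_t", seq_len(ng))
  )
  list(records = records, truth = truth)
}

#' Evaluate predictions against a planted truth table
#'
#' A prediction is 3'-correct when it reproduces an annotated gene's stop
#' (same contig, strand, and 3'-end coordinate), and exact when both the
#' translation initiation site and the stop match.
#'
#' @param preds `gt_genes` tibble (or any tibble with `contig`, `begin`,
#'   `end`, `strand`).
#' @param truth truth tibble from [generate_genome()].
#' @return One-row tibble: `n_truth`, `n_pred`, `sens_3p` (fraction of truth
#'   genes whose 3' end is found), `exact` (fraction matched exactly),
#'   `ratio` (predicted over annotated gene count).
#' @export
evaluate_predictions <- function(preds, truth) {
  if (!any(truth$contig %in% preds$contig) && nrow(preds) > 0L) {
    stop("prediction and truth tables share no contig identifiers")
  }
  key3 <- function(d) {
    paste(d$contig, d$strand, ifelse(d$strand == "+", d$end, d$begin))
  }
  keyx <- function(d) paste(d$contig, d$strand, d$begin, d$end)
  tibble::tibble(
    n_truth = nrow(truth),
    n_pred = nrow(preds),
    sens_3p = mean(key3(truth) %in% key3(preds)),
    exact = mean(keyx(truth) %in% keyx(preds)),
    ratio = nrow(preds) / max(1L, nrow(truth))
  )
}
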