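# Sequence input, genetic codes, and candidate start/stop node enumeration.
#
# Internal coordinates are 0-based throughout; a node's `pos` is the index of
# the first base of its codon *as read on its own strand*, expressed in
# forward-sequence coordinates (so for a minus-strand codon `pos` is the
# rightmost base of the codon in the forward view). All user-facing output is
# converted to 1-based inclusive coordinates.

BASES <- c("A", "C", "G", "T")
START_CODONS <- c("ATG", "GTG", "TTG")

#' Read a nucleotide FASTA file
#'
#' Reads one or more contigs, uppercases the sequence, and normalizes U to T.
#' Characters outside A/C/G/T/N are retained but never form a valid start or
#' stop codon.
#'
#' @param path path to a FASTA file.
#' @param table_id NCBI translation table identifier (default 11, bacterial).
#' @return A tibble with one row per contig: `id` (first whitespace-separated
#'   token of the header), `bases`, and `table_id`.
#' @export
read_genome_fasta <- function(path, table_id = 11L) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("not a readable FASTA file: ", path))
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyNA(ids) || any(!nzchar(ids))) stop("malformed FASTA header in ", path)
  bases <- toupper(as.character(set))
  bases <- gsub("U", "T", bases, fixed = TRUE)
  for (i in seq_along(bases)) {
    n_ok <- sum(charToRaw(bases[i]) %in% charToRaw("ACGTN"))
    if (nchar(bases[i]) == 0L || n_ok < 0.9 * nchar(bases[i])) {
      stop("record '", ids[i], "' does not look like nucleotide sequence")
    }
  }
  tibble::tibble(id = unname(ids), bases = unname(bases),
                 table_id = as.integer(table_id))
}

#' Reverse complement of a DNA string
#'
#' Standard complement with N mapped to N; an involution on its domain.
#'
#' @param bases a DNA character string.
#' @return The reverse complement string.
#' @export
reverse_complement <- function(bases) {
  if (length(bases) != 1L) return(vapply(bases, reverse_complement, character(1), USE.NAMES = FALSE))
  if (nchar(bases) == 0L) return("")
  x <- chartr("ACGTN", "TGCAN", bases)
  paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")
}

# genetic code as named character vector codon -> amino acid ('*' for stop)
gt_genetic_code <- function(table_id = 11L) {
  Biostrings::getGeneticCode(as.character(table_id))
}

stop_codons <- function(table_id = 11L) {
  gc <- gt_genetic_code(table_id)
  names(gc)[gc == "*"]
}

#' Translate a gene sequence to protein
#'
#' @param bases nucleotide sequence of the gene, 5' to 3' on its own strand,
#'   including the stop codon for complete genes; length must be a multiple
#'   of 3.
#' @param table_id NCBI translation table (default 11).
#' @param partial_left if TRUE the gene is truncated at its 5' end and the
#'   first codon is not treated as an initiator.
#' @return Amino-acid string; the terminal stop is not emitted; codons
#'   containing N translate to `X`; an initiator ATG/GTG/TTG is rendered M.
#' @export
translate_gene <- function(bases, table_id = 11L, partial_left = FALSE) {
  n <- nchar(bases)
  if (n == 0L) stop("cannot translate a zero-length sequence")
  n <- n - n %% 3L
  codons <- substring(bases, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
  code <- gt_genetic_code(table_id)
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  if (!partial_left && codons[1] %in% START_CODONS) aa[1] <- "M"
  if (length(aa) > 1L || aa[length(aa)] == "*") {
    if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
  }
  paste(aa, collapse = "")
}

# encode bases as integers 0..3 (A C G T), NA otherwise
encode_bases <- function(bases) {
  v <- utf8ToInt(bases)
  out <- rep(NA_integer_, length(v))
  out[v == 65L] <- 0L  # A
  out[v == 67L] <- 1L  # C
  out[v == 71L] <- 2L  # G
  out[v == 84L] <- 3L  # T
  out
}

codon_index <- function(codon) {
  b <- encode_bases(codon)
  16L * b[1] + 4L * b[2] + b[3]
}

# per-position codon codes (NA where any base is non-ACGT); length L-2
codon_codes <- function(enc) {
  L <- length(enc)
  if (L < 3L) return(integer(0))
  16L * enc[1:(L - 2L)] + 4L * enc[2:(L - 1L)] + enc[3:L]
}

# Enumerate starts/stops on one strand reading `enc` (already oriented 5'->3').
# Returns list of data frames in own-strand 0-based coordinates.
scan_strand <- function(enc, table_id, min_gene_len) {
  L <- length(enc)
  start_codes <- vapply(START_CODONS, codon_index, integer(1))
  stop_codes <- vapply(stop_codons(table_id), codon_index, integer(1))
  cod <- codon_codes(enc)
  q_start <- which(cod %in% start_codes) - 1L
  q_stop <- which(cod %in% stop_codes) - 1L
  starts <- list(); stops <- list()
  for (f in 0:2) {
    sp <- q_stop[q_stop %% 3L == f]
    # right-boundary edge stop: last base of the last complete codon in frame f
    edge_right <- if (L >= f + 3L) f + 3L * ((L - f) %/% 3L) - 1L else NA_integer_
    st <- q_start[q_start %% 3L == f]
    # candidate starts: edge start at q = f plus all real starts
    st_all <- if (L >= f + 3L) c(f, st) else integer(0)
    st_edge <- if (L >= f + 3L) c(TRUE, rep(FALSE, length(st))) else logical(0)
    if (length(st_all)) {
      i <- findInterval(st_all, sp) + 1L
      pair_stop <- ifelse(i <= length(sp), sp[i], NA_integer_)
      gene_right <- ifelse(is.na(pair_stop), edge_right, pair_stop + 2L)
      stop_is_edge <- is.na(pair_stop)
      len <- gene_right - st_all + 1L
      keep <- !is.na(gene_right) & len >= min_gene_len
      # drop duplicate edge start when a real start also sits at q = f
      if (length(st_all) > 1L && st_edge[1] && any(st_all[-1] == st_all[1])) keep[1] <- FALSE
      starts[[f + 1L]] <- data.frame(
        q = st_all[keep], frame = rep(f, sum(keep)), edge = st_edge[keep],
        q_stop = pair_stop[keep], gene_right_q = gene_right[keep],
        stop_is_edge = stop_is_edge[keep]
      )
    } else {
      starts[[f + 1L]] <- data.frame(q = integer(0), frame = integer(0),
                                     edge = logical(0), q_stop = integer(0),
                                     gene_right_q = integer(0), stop_is_edge = logical(0))
    }
    need_edge_stop <- !is.na(edge_right) &&
      (length(starts[[f + 1L]]$q) == 0L || any(starts[[f + 1L]]$stop_is_edge))
    sp_all <- c(sp, if (!is.na(edge_right)) edge_right - 2L else integer(0))
    stops[[f + 1L]] <- data.frame(
      q = sp_all,
      frame = rep(f, length(sp_all)),
      edge = c(rep(FALSE, length(sp)), if (!is.na(edge_right)) TRUE else logical(0))
    )
  }
  list(starts = do.call(rbind, starts), stops = do.call(rbind, stops))
}

#' Enumerate candidate start and stop nodes for one contig
#'
#' Finds every ATG/GTG/TTG start codon and every stop codon (per the
#' translation table) on both strands in all frames, pairs each start with its
#' downstream in-frame stop, and adds synthetic edge nodes in each frame at
#' both contig boundaries so genes may run off the ends of draft contigs.
#' Start nodes whose gene (start through stop, inclusive) would be shorter
#' than `min_gene_len` are excluded. Codons containing N are never valid
#' starts or stops.
#'
#' @param record one row of the tibble returned by [read_genome_fasta()] (or a
#'   list with `id`, `bases`, `table_id`).
#' @param min_gene_len minimum gene length in bp (default 90).
#' @return A tibble of nodes: `contig`, `kind` ("start"/"stop"), `strand`
#'   (+1/-1), `pos` (0-based first base of the codon as read on its own
#'   strand, in forward coordinates), `frame`, `codon` (NA for edge nodes),
#'   `edge`, `stop_pos` (paired stop for starts), `left`/`right` (gene extent
#'   in forward coordinates for starts), `partial_left`/`partial_right`.
#' @export
enumerate_nodes <- function(record, min_gene_len = gt_params()$min_gene_len) {
  bases <- record$bases[[1]]
  table_id <- if (!is.null(record$table_id)) record$table_id[[1]] else 11L
  contig <- record$id[[1]]
  L <- nchar(bases)
  enc_f <- encode_bases(bases)
  enc_r <- rev(3L - enc_f)  # complement of A<->T, C<->G preserves NA
  fwd <- scan_strand(enc_f, table_id, min_gene_len)
  rev_ <- scan_strand(enc_r, table_id, min_gene_len)

  codon_at <- function(enc, q) {
    ok <- !is.na(q) & q >= 0L & q + 2L < length(enc)
    out <- rep(NA_character_, length(q))
    if (any(ok)) {
      idx <- 16L * enc[q[ok] + 1L] + 4L * enc[q[ok] + 2L] + enc[q[ok] + 3L]
      all_cod <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
      # index layout: 16*b1 + 4*b2 + b3 -> build lookup in that order
      lut <- character(64)
      for (b1 in 0:3) for (b2 in 0:3) for (b3 in 0:3) {
        lut[16 * b1 + 4 * b2 + b3 + 1] <- paste0(BASES[b1 + 1], BASES[b2 + 1], BASES[b3 + 1])
      }
      out[ok] <- ifelse(is.na(idx), NA_character_, lut[idx + 1L])
    }
    out
  }

  mk <- function(sc, sgn, enc) {
    st <- sc$starts; sp <- sc$stops
    map <- function(q) if (sgn == 1L) q else L - 1L - q
    start_tbl <- tibble::tibble(
      contig = contig, kind = "start", strand = sgn,
      pos = map(st$q), frame = st$frame,
      codon = { cd <- codon_at(enc, st$q); cd[st$edge] <- NA_character_; cd },
      edge = st$edge,
      stop_pos = map(st$q_stop),
      left = if (sgn == 1L) st$q else L - 1L - st$gene_right_q,
      right = if (sgn == 1L) st$gene_right_q else L - 1L - st$q,
      partial_left = if (sgn == 1L) st$edge else st$stop_is_edge,
      partial_right = if (sgn == 1L) st$stop_is_edge else st$edge
    )
    stop_tbl <- tibble::tibble(
      contig = contig, kind = "stop", strand = sgn,
      pos = map(sp$q), frame = sp$frame,
      codon = { cd <- codon_at(enc, sp$q); cd[sp$edge] <- NA_character_; cd },
      edge = sp$edge,
      stop_pos = NA_integer_,
      left = if (sgn == 1L) sp$q else L - 1L - (sp$q + 2L),
      right = if (sgn == 1L) sp$q + 2L else L - 1L - sp$q,
      partial_left = FALSE, partial_right = FALSE
    )
    dplyr::bind_rows(start_tbl, stop_tbl)
  }
  nodes <- dplyr::bind_rows(mk(fwd, 1L, enc_f), mk(rev_, -1L, enc_r))
  nodes$stop_pos[nodes$kind == "stop"] <- NA_integer_
  dplyr::arrange(nodes, .data$left, .data$kind, .data$strand)
}
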