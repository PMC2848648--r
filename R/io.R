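# Output writers (GFF3, protein FASTA, per-start diagnostics) and the
# versioned JSON training-profile file used by the two-step mode.

#' Write gene predictions as GFF3
#'
#' One CDS feature per gene with the score column carrying the total score
#' (2 decimals) and attributes for the partial flags, start codon, RBS motif
#' and spacer, and the component scores.
#'
#' @param preds `gt_genes` tibble from [gt_predict()].
#' @param path output file path.
#' @param records optional records tibble; if given, sequence-region pragmas
#'   are written.
#' @return Invisibly, `path`.
#' @export
write_gff <- function(preds, path, records = NULL) {
  if (inherits(path, "connection")) {
    con <- path
  } else {
    con <- file(path, open = "wt")
    on.exit(close(con))
  }
  writeLines("##gff-version 3", con)
  if (!is.null(records)) {
    for (k in seq_len(nrow(records))) {
      writeLines(sprintf("##sequence-region %s 1 %d", records$id[[k]],
                         nchar(records$bases[[k]])), con)
    }
  }
  if (nrow(preds)) {
    attrs <- sprintf(
      "ID=%s;partial=%d%d;start_type=%s;rbs_motif=%s;rbs_spacer=%s;cscore=%.2f;rscore=%.2f;tscore=%.2f;uscore=%.2f;sscore=%.2f",
      preds$gene_id,
      as.integer(preds$partial_left), as.integer(preds$partial_right),
      ifelse(is.na(preds$start_codon), "Edge", preds$start_codon),
      preds$rbs_motif,
      ifelse(is.na(preds$rbs_spacer), "None", paste0(preds$rbs_spacer, "bp")),
      preds$score_coding, preds$score_rbs, preds$score_type,
      preds$score_upstream, preds$score_start)
    lines <- sprintf("%s\tgenetiler\tCDS\t%d\t%d\t%.2f\t%s\t0\t%s",
                     preds$contig, preds$begin, preds$end, preds$score_total,
                     preds$strand, attrs)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a genetiler GFF3 file back into a tibble
#'
#' Parses the coordinate fields of a GFF3 written by [write_gff()].
#'
#' @param path GFF3 file path.
#' @return Tibble with `contig`, `begin`, `end`, `strand`, `score_total`,
#'   `gene_id`.
#' @export
read_gff <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#")]
  if (!length(ln)) {
    return(tibble::tibble(contig = character(0), begin = integer(0),
                          end = integer(0), strand = character(0),
                          score_total = numeric(0), gene_id = character(0)))
  }
  f <- strsplit(ln, "\t", fixed = TRUE)
  tibble::tibble(
    contig = vapply(f, `[`, character(1), 1L),
    begin = as.integer(vapply(f, `[`, character(1), 4L)),
    end = as.integer(vapply(f, `[`, character(1), 5L)),
    strand = vapply(f, `[`, character(1), 7L),
    score_total = as.numeric(vapply(f, `[`, character(1), 6L)),
    gene_id = sub(";.*$", "", sub("^ID=", "", vapply(f, `[`, character(1), 9L)))
  )
}

#' Write protein translations as FASTA
#'
#' Headers follow `>geneid # begin # end # strand`.
#'
#' @param preds `gt_genes` tibble.
#' @param records records tibble the predictions came from.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_proteins <- function(preds, records, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  tid <- if (!is.null(records$table_id)) records$table_id[[1]] else 11L
  for (i in seq_len(nrow(preds))) {
    rec <- records[records$id == preds$contig[i], , drop = FALSE]
    dna <- substr(rec$bases[[1]], preds$begin[i], preds$end[i])
    if (preds$strand[i] == "-") dna <- reverse_complement(dna)
    partial5 <- if (preds$strand[i] == "+") preds$partial_left[i] else preds$partial_right[i]
    aa <- translate_gene(dna, tid, partial_left = partial5)
    writeLines(sprintf(">%s # %d # %d # %d", preds$gene_id[i], preds$begin[i],
                       preds$end[i], if (preds$strand[i] == "+") 1L else -1L), con)
    writeLines(substring(aa, seq(1L, nchar(aa), 60L),
                         pmin(nchar(aa), seq(60L, nchar(aa) + 59L, 60L))), con)
  }
  invisible(path)
}

#' Write the per-start diagnostics table
#'
#' Tab-separated table of every scored candidate start with its component
#' scores, as attached by `gt_predict(..., diagnostics = TRUE)`.
#'
#' @param starts tibble from `attr(preds, "starts")`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_starts <- function(starts, path) {
  utils::write.table(starts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Save a training profile to a JSON file
#'
#' The profile is written as a versioned JSON document at full numeric
#' precision, so a reloaded profile reproduces predictions exactly.
#'
#' @param profile a `gt_profile`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_profile <- function(profile, path) {
  p <- unclass(profile)
  p$hexamer <- unname(unclass(p$hexamer))
  p$pwm <- list(dimnames = dimnames(profile$pwm),
                values = as.vector(profile$pwm))
  p$sec_weights <- list(words = rownames(profile$sec_weights),
                        values = as.vector(profile$sec_weights))
  p$type_w <- as.list(profile$type_w)
  p$base_freq <- as.list(profile$base_freq)
  json <- jsonlite::toJSON(p, auto_unbox = TRUE, digits = I(17), pretty = TRUE,
                           null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Load a training profile from a JSON file
#'
#' @param path path written by [write_profile()].
#' @return A `gt_profile`.
#' @export
read_profile <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(p$version) || p$version != 1L) {
    stop("unrecognized training-profile version in ", path)
  }
  hex <- as.numeric(p$hexamer)
  names(hex) <- ALL_HEXAMERS
  params <- gt_params()
  stored <- p$params
  for (nm in names(params)) {
    if (!is.null(stored[[nm]])) {
      params[[nm]] <- if (is.integer(params[[nm]])) as.integer(stored[[nm]])
                      else stored[[nm]]
    }
  }
  pwm <- matrix(as.numeric(p$pwm$values), nrow = 4L)
  dimnames(pwm) <- p$pwm$dimnames
  nw <- length(p$sec_weights$words)
  sec_weights <- matrix(as.numeric(p$sec_weights$values), nrow = nw, ncol = 4L,
                        dimnames = if (nw) list(p$sec_weights$words,
                                                c("3-4", "5-10", "11-12", "13-15")))
  structure(list(
    version = 1L,
    table_id = as.integer(p$table_id),
    gc = p$gc,
    base_freq = unlist(p$base_freq)[BASES],
    gc_bias = as.numeric(p$gc_bias),
    n_bias_orfs = p$n_bias_orfs,
    hexamer = structure(hex, class = "gt_hexamers",
                        floor = params$hex_floor, ceiling = params$hex_ceiling),
    type_w = unlist(p$type_w)[START_CODONS],
    rbs_w = as.numeric(p$rbs_w),
    uses_sd = isTRUE(p$uses_sd),
    rbs_mode = p$rbs_mode,
    sec_words = as.character(p$sec_words %||% character(0)),
    sec_weights = sec_weights,
    sec_none_w = as.numeric(p$sec_none_w %||% 0),
    pwm = pwm,
    params = params,
    training = p$training
  ), class = "gt_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
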