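# Printing, broom-style tidiers, and plotting for fitted profiles and
# prediction tables.

#' @export
print.gt_profile <- function(x, ...) {
  cat("<gt_profile> self-trained gene model\n")
  cat(sprintf("  GC content: %.1f%%; translation table %d\n", 100 * x$gc, x$table_id))
  cat(sprintf("  GC frame bias B(1..3): %s\n",
              paste(sprintf("%.2f", x$gc_bias), collapse = " ")))
  cat(sprintf("  start types (log-likelihood): ATG %.2f, GTG %.2f, TTG %.2f\n",
              x$type_w["ATG"], x$type_w["GTG"], x$type_w["TTG"]))
  cat(sprintf("  Shine-Dalgarno: %s (RBS mode %s)\n",
              if (x$uses_sd) "used" else "not used", x$rbs_mode))
  if (length(x$sec_words)) {
    top <- which(x$sec_weights == max(x$sec_weights), arr.ind = TRUE)[1, ]
    cat(sprintf("  secondary motif: %s (weight %.2f)\n",
                rownames(x$sec_weights)[top[1]], max(x$sec_weights)))
  }
  cat(sprintf("  trained on %d tiling genes, %d start peaks\n",
              x$training$n_train_genes, x$training$n_peaks))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trained profile into a weight table
#'
#' @param x a `gt_profile`.
#' @param ... unused.
#' @return Tibble with `family` ("start_type", "sd_bin", "secondary",
#'   "gc_bias"), `term`, and `estimate`.
#' @export
tidy.gt_profile <- function(x, ...) {
  out <- list(
    tibble::tibble(family = "gc_bias", term = paste0("B", 1:3),
                   estimate = x$gc_bias),
    tibble::tibble(family = "start_type", term = names(x$type_w),
                   estimate = unname(x$type_w)),
    tibble::tibble(family = "sd_bin", term = paste0("bin", 0:27),
                   estimate = x$rbs_w)
  )
  if (length(x$sec_words)) {
    out[[length(out) + 1L]] <- tibble::tibble(
      family = "secondary",
      term = paste0(rep(rownames(x$sec_weights), times = 4L), "/",
                    rep(colnames(x$sec_weights), each = nrow(x$sec_weights))),
      estimate = as.vector(x$sec_weights))
  }
  dplyr::bind_rows(out)
}

#' One-row summary of a trained profile
#'
#' @param x a `gt_profile`.
#' @param ... unused.
#' @return One-row tibble: GC content, SD usage, RBS mode, training sizes,
#'   iteration count.
#' @export
glance.gt_profile <- function(x, ...) {
  tibble::tibble(
    gc = x$gc,
    uses_sd = x$uses_sd,
    rbs_mode = x$rbs_mode,
    n_train_genes = x$training$n_train_genes,
    n_peaks = x$training$n_peaks,
    sd_iterations = x$training$sd_iterations
  )
}

#' Genome map of gene predictions
#'
#' Draws each predicted gene as an arrow segment on its strand, colored by
#' total score, faceted by contig.
#'
#' @param object a `gt_genes` tibble from [gt_predict()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.gt_genes <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$y <- ifelse(d$strand == "+", 1, -1)
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$begin, xend = .data$end, y = .data$y,
                   yend = .data$y, color = .data$score_total),
      linewidth = 3, lineend = "butt") +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, linewidth = 0.3) +
    ggplot2::scale_y_continuous(breaks = c(-1, 1), labels = c("-", "+"),
                                limits = c(-2, 2), name = "strand") +
    ggplot2::facet_wrap(~contig, ncol = 1) +
    ggplot2::labs(x = "position (bp)", color = "total score") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Distribution of per-gene score components
#'
#' @param preds a `gt_genes` tibble.
#' @return A ggplot object showing coding and start-signal score
#'   distributions of the emitted genes.
#' @export
plot_score_components <- function(preds) {
  d <- tibble::as_tibble(preds) |>
    dplyr::select(dplyr::all_of(c("score_coding", "score_rbs", "score_type",
                                  "score_upstream", "score_start"))) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "component",
                        values_to = "score")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::facet_wrap(~component, scales = "free") +
    ggplot2::theme_minimal()
}
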