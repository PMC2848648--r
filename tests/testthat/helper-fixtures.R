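# Shared fixtures, cached across test files so expensive genomes and
# training runs are computed once per session.

gt_cache <- new.env(parent = emptyenv())

cache_get <- function(key, build) {
  if (is.null(gt_cache[[key]])) gt_cache[[key]] <- build()
  gt_cache[[key]]
}

# 20 stress genomes (100 kb, high density, injected overlaps) with full runs
stress_suite <- function(n = 20L) {
  cache_get(paste0("stress", n), function() {
    lapply(seq_len(n), function(sd) {
      spec <- genome_spec(length = 1e5, density = 0.9, overlap_rate = 0.25,
                          seed = sd)
      gen <- generate_genome(spec)
      run <- gt_run(gen$records)
      list(truth = gen$truth, profile = run$profile, preds = run$genes)
    })
  })
}

# 500 kb typical-regime (GC 0.5, Shine-Dalgarno starts) fixture + full run
sd500 <- function() {
  cache_get("sd500", function() {
    spec <- genome_spec(length = 5e5, seed = 11)
    gen <- generate_genome(spec)
    run <- gt_run(gen$records)
    list(gen = gen, profile = run$profile, preds = run$genes)
  })
}

# 500 kb archaeon-like fixture (planted GGTG, no SD), training only
sec500 <- function() {
  cache_get("sec500", function() {
    spec <- genome_spec(length = 5e5, rbs_regime = "secondary", seed = 21)
    gen <- generate_genome(spec)
    list(gen = gen, profile = gt_train(gen$records))
  })
}

# 500 kb cyanobacteria-like fixture (AT-rich upstream, no motif)
none500 <- function() {
  cache_get("none500", function() {
    spec <- genome_spec(length = 5e5, rbs_regime = "none", seed = 21)
    gen <- generate_genome(spec)
    list(gen = gen, profile = gt_train(gen$records))
  })
}

# small genome + trained profile for cheap unit tests
small_run <- function() {
  cache_get("small60", function() {
    spec <- genome_spec(length = 6e4, seed = 5)
    gen <- generate_genome(spec)
    run <- suppressWarnings(gt_run(gen$records))
    list(gen = gen, profile = run$profile, preds = run$genes)
  })
}

# pairwise overlap statistics of a prediction table
overlap_stats <- function(p) {
  max_ss <- 0L; max_opp <- 0L; n_opp5 <- 0L
  if (nrow(p) > 1L) {
    ord <- order(p$begin, p$end)
    p <- p[ord, ]
    for (i in 2:nrow(p)) {
      js <- which(p$end[1:(i - 1L)] >= p$begin[i])
      for (j in js) {
        ovl <- min(p$end[i], p$end[j]) - p$begin[i] + 1L
        if (ovl <= 0L) next
        if (p$strand[j] == p$strand[i]) {
          max_ss <- max(max_ss, ovl)
        } else if (p$strand[j] == "+" && p$strand[i] == "-") {
          max_opp <- max(max_opp, ovl)
        } else {
          n_opp5 <- n_opp5 + 1L
        }
      }
    }
  }
  full <- !(p$partial_left | p$partial_right)
  list(max_ss = max_ss, max_opp = max_opp, n_opp5 = n_opp5,
       min_full_len = if (any(full)) min(p$length[full]) else NA_integer_)
}

write_temp_fasta <- function(records, path = tempfile(fileext = ".fna")) {
  con <- file(path, "wt")
  for (k in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[[k]]), con)
    b <- records$bases[[k]]
    writeLines(substring(b, seq(1L, nchar(b), 70L),
                         pmin(nchar(b), seq(70L, nchar(b) + 69L, 70L))), con)
  }
  close(con)
  path
}
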