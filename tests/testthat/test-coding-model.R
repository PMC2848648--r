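test_that("hexamer scores are clamped log frequency ratios over 4096 words", {
  fg <- integer(4096); bg <- integer(4096)
  fg[1] <- 2; bg[1] <- 1   # twice as frequent in genes as in background
  fg[2] <- 2; bg[2] <- 2   # equal frequency
  bg[3] <- 1               # absent from genes -> floor
  tab <- genetiler:::hexamer_scores(fg, bg)
  expect_length(tab, 4096L)
  expect_equal(unname(tab[1]), log(2))
  expect_equal(unname(tab[2]), 0)
  expect_equal(unname(tab[3]), gt_params()$hex_floor)
  expect_true(all(tab >= gt_params()$hex_floor & tab <= gt_params()$hex_ceiling))
})

test_that("trained hexamer frequencies normalize and words are named", {
  run <- small_run()
  tab <- run$profile$hexamer
  expect_length(tab, 4096L)
  expect_setequal(substr(names(tab)[1:4], 1, 5), c("AAAAA"))
  expect_equal(names(tab)[1], "AAAAAA")
  expect_equal(names(tab)[4096], "TTTTTT")
})

test_that("gene coding score sums in-frame hexamers against an oracle", {
  fg <- integer(4096); bg <- rep(1L, 4096)
  fg[seq(1, 4096, 7)] <- 3L
  tab <- genetiler:::hexamer_scores(fg, bg)
  set.seed(5)
  gene <- paste(c("ATG", sample(c("GAA", "CCT", "GGC", "ATC"), 40, TRUE), "TAA"),
                collapse = "")
  # oracle: explicit loop over codon-boundary windows, stop codon excluded
  n <- nchar(gene)
  words <- substring(gene, seq(1, n - 8, 3), seq(6, n - 3, 3))
  want <- sum(unname(tab[words]))
  expect_equal(gene_coding_score(gene, tab), want)
  # every-hexamer-zero gene scores zero
  tab0 <- genetiler:::hexamer_scores(integer(4096), integer(4096))
  expect_equal(gene_coding_score(gene, tab0), 0)
})

test_that("coding score is monotone under swapping in a higher-scoring word", {
  fg <- integer(4096); bg <- rep(1L, 4096)
  fg[genetiler:::codon_index("GAA") * 64 + genetiler:::codon_index("GAA") + 1] <- 50L
  tab <- genetiler:::hexamer_scores(fg, bg)
  low <- paste(c("ATG", rep("CCT", 20), "TAA"), collapse = "")
  high <- paste(c("ATG", rep("GAA", 20), "TAA"), collapse = "")
  expect_gt(gene_coding_score(high, tab), gene_coding_score(low, tab))
})

test_that("truncation penalty follows the worked example and extensions", {
  expect_equal(truncation_penalty(c(500, 400)), c(500, 300))
  expect_equal(truncation_penalty(c(500, 400, 450)), c(500, 300, 400))
  # shorter gene at least as good as all longer ones is unchanged
  expect_equal(truncation_penalty(c(300, 350, 360)), c(300, 350, 360))
  expect_equal(truncation_penalty(numeric(0)), numeric(0))
  expect_equal(truncation_penalty(c(10)), c(10))
})

test_that("long-gene boost lifts only long negative-scoring genes", {
  expect_gt(long_gene_boost(-10, 2000, 0.40), 0)
  expect_equal(long_gene_boost(-10, 300, 0.40), -10)
  expect_equal(long_gene_boost(5, 2000, 0.40), 5)
  # threshold interpolates with GC: a 1000 bp gene is boosted in low GC only
  expect_gt(long_gene_boost(-1, 1000, 0.35), 0)
  expect_equal(long_gene_boost(-1, 1000, 0.70), -1)
  expect_equal(genetiler:::boost_threshold(0.2), 700)
  expect_equal(genetiler:::boost_threshold(0.9), 1200)
})

test_that("trained scores recover enrichment signs on fixture genomes", {
  run <- sd500()
  gen <- run$gen
  tab <- run$profile$hexamer
  # oracle: tally in-frame hexamers over the planted truth genes
  fg <- integer(4096)
  enc_f <- genetiler:::encode_bases(gen$records$bases[[1]])
  enc_r <- rev(3L - enc_f)
  hf <- genetiler:::hexamer_codes(enc_f)
  hr <- genetiler:::hexamer_codes(enc_r)
  L <- length(enc_f)
  for (i in seq_len(nrow(gen$truth))) {
    strand <- if (gen$truth$strand[i] == "+") 1L else -1L
    idx <- genetiler:::gene_hexamer_positions(strand, gen$truth$begin[i] - 1L,
                                              gen$truth$end[i] - 1L, L)
    h <- if (strand == 1L) hf[idx + 1L] else hr[idx + 1L]
    fg <- fg + tabulate(h + 1L, 4096L)
  }
  bg <- tabulate(c(hf, hr) + 1L, 4096L)
  truth_tab <- genetiler:::hexamer_scores(fg, bg)
  frequent <- which(fg >= 50L & unclass(truth_tab) != 0)
  agree <- sign(unclass(tab)[frequent]) == sign(unclass(truth_tab)[frequent])
  expect_gte(mean(agree), 0.95)
})
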