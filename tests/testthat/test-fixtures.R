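test_that("genome generation is a pure function of the spec", {
  spec <- genome_spec(length = 20000, seed = 7)
  g1 <- generate_genome(spec)
  g2 <- generate_genome(spec)
  expect_identical(g1, g2)
  g3 <- generate_genome(genome_spec(length = 20000, seed = 8))
  expect_false(identical(g1$records$bases, g3$records$bases))
})

test_that("requested GC content is realized within two points", {
  for (gc in c(0.4, 0.5, 0.6)) {
    gen <- generate_genome(genome_spec(length = 1e5, gc = gc, seed = 13))
    enc <- genetiler:::encode_bases(gen$records$bases[[1]])
    expect_lt(abs(mean(enc %in% c(1L, 2L)) - gc), 0.02)
  }
})

test_that("planted genes are clean ORFs with the recorded starts", {
  gen <- generate_genome(genome_spec(length = 1e5, density = 0.9,
                                     overlap_rate = 0.25, seed = 4))
  tr <- gen$truth
  b <- gen$records$bases[[1]]
  stops <- c("TAA", "TAG", "TGA")
  for (i in seq_len(nrow(tr))) {
    d <- substr(b, tr$begin[i], tr$end[i])
    if (tr$strand[i] == "-") d <- reverse_complement(d)
    expect_equal(nchar(d) %% 3, 0)
    cods <- substring(d, seq(1, nchar(d) - 2, 3), seq(3, nchar(d), 3))
    expect_equal(cods[1], tr$start_codon[i])
    expect_true(cods[length(cods)] %in% stops)
    expect_equal(sum(cods[-length(cods)] %in% stops), 0L)
  }
  # injected overlaps are present in the layout
  ovl <- tr$begin[-1] - tr$end[-nrow(tr)] - 1L
  expect_true(any(ovl < 0))
  expect_true(all(ovl >= -4L))
})

test_that("the SD regime plants its motif at the recorded rate and spacer", {
  gen <- generate_genome(genome_spec(length = 1e5, seed = 6))
  tr <- gen$truth
  b <- gen$records$bases[[1]]
  rc <- reverse_complement(b)
  L <- nchar(b)
  with_motif <- tr[tr$motif_planted, ]
  expect_gte(nrow(with_motif) / nrow(tr), 0.6)
  hit <- logical(nrow(with_motif))
  for (i in seq_len(nrow(with_motif))) {
    if (with_motif$strand[i] == "+") {
      l <- with_motif$begin[i] - 1L
      up <- substr(b, max(1L, l - 20L), l)
    } else {
      q <- L - with_motif$end[i]
      up <- substr(rc, max(1L, q - 20L), q)
    }
    m <- regexpr("AGGAGG", up, fixed = TRUE)
    if (m > 0) {
      spacer <- nchar(up) - (as.integer(m) + 5L)
      hit[i] <- spacer >= 5L && spacer <= 10L
    }
  }
  expect_gte(mean(hit), 0.95)
})

test_that("evaluation metrics match hand-tallied toys and are order-invariant", {
  truth <- tibble::tibble(contig = "c", begin = c(10L, 200L, 500L, 900L, 1500L),
                          end = c(120L, 400L, 800L, 1200L, 1700L),
                          strand = c("+", "-", "+", "+", "-"))
  ev <- evaluate_predictions(truth, truth)
  expect_equal(ev$sens_3p, 1)
  expect_equal(ev$exact, 1)
  expect_equal(ev$ratio, 1)
  # shift one start: 3' sensitivity keeps, exact drops by 1/5
  p2 <- truth
  p2$begin[3] <- 530L
  ev2 <- evaluate_predictions(p2, truth)
  expect_equal(ev2$sens_3p, 1)
  expect_equal(ev2$exact, 0.8)
  # shift a minus-strand gene's 3' end (its begin): sensitivity drops too
  p3 <- truth
  p3$begin[2] <- 230L
  ev3 <- evaluate_predictions(p3, truth)
  expect_equal(ev3$sens_3p, 0.8)
  # permutation invariance
  ev4 <- evaluate_predictions(p2[sample(5), ], truth)
  expect_equal(ev4, ev2)
  # disjoint contigs error out
  p5 <- truth; p5$contig <- "other"
  expect_error(evaluate_predictions(p5, truth), "contig")
})

test_that("infeasible specs are rejected", {
  expect_error(genome_spec(density = 0.99), "density")
  expect_error(genome_spec(length = 500), "is not TRUE")
})
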