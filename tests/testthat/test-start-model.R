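# brute-force SD bin assigner used as an oracle: enumerate every motif of
# every bin at every admissible spacer
brute_sd_bin <- function(upstream, weights = NULL) {
  tab <- sd_bin_table()
  width <- gt_params()$upstream_window
  pad <- strrep("-", max(0L, width - nchar(upstream)))
  u <- paste0(pad, substr(upstream, max(1L, nchar(upstream) - width + 1L),
                          nchar(upstream)))
  hits <- 0L
  for (r in seq_len(nrow(tab))) {
    if (tab$bin[r] == 0L) next
    m <- nchar(tab$motif[r])
    pc <- strsplit(tab$motif[r], "")[[1]]
    for (d in tab$smin[r]:tab$smax[r]) {
      o <- width - d - m + 1L
      if (o < 1L) next
      txt <- strsplit(substr(u, o, o + m - 1L), "")[[1]]
      if (all(pc == "x" | pc == txt)) hits <- c(hits, tab$bin[r])
    }
  }
  hits <- unique(hits)
  if (is.null(weights)) max(hits) else hits[which.max(weights[hits + 1L] + hits * 1e-9)]
}

test_that("SD bin assignment matches Table-2 worked examples", {
  # AGGAGG at spacer 6
  up <- paste0(strrep("C", 9), "AGGAGG", strrep("C", 6))
  a <- assign_sd_bin(up)
  expect_equal(a$bin, 27L)
  expect_equal(a$motif, "AGGAGG")
  expect_equal(a$spacer, 6L)
  # no motif anywhere
  expect_equal(assign_sd_bin(strrep("C", 21))$bin, 0L)
  # GGAGG and GGA both at spacer 4: priority takes the higher bin (23)
  up2 <- paste0(strrep("C", 12), "GGAGG", "CCCC")
  expect_equal(assign_sd_bin(up2)$bin, 23L)
  # truncated upstream windows still assign (bin 0 allowed)
  expect_equal(assign_sd_bin("AG")$bin, 0L)
})

test_that("SD bin assignment agrees with the brute-force enumerator", {
  set.seed(17)
  n <- 2000
  ups <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), 21, TRUE,
                 prob = c(0.2, 0.2, 0.4, 0.2)), collapse = "")
  }, character(1))
  got <- assign_sd_bin(ups)$bin
  want <- vapply(ups, brute_sd_bin, integer(1), USE.NAMES = FALSE)
  expect_equal(got, want)
  # and under an arbitrary fixed weight vector
  set.seed(18)
  w <- round(runif(28, -2, 2), 3)
  got_w <- assign_sd_bin(ups[1:400], w)$bin
  want_w <- vapply(ups[1:400], brute_sd_bin, integer(1), weights = w,
                   USE.NAMES = FALSE)
  expect_equal(got_w, want_w)
})

test_that("initial peaks take each ORF's best start above the threshold", {
  starts <- tibble::tibble(
    orf = c(1L, 1L, 2L, 3L, 3L),
    C = c(40, 38, 34.9, 80, 90),
    codon = c("ATG", "GTG", "ATG", "ATG", "TTG"),
    len = c(300L, 240L, 120L, 500L, 400L))
  pk <- suppressWarnings(initial_peaks(starts))
  expect_equal(pk, c(1L, 5L))  # 40 beats 38; 34.9 excluded; 90 beats 80
  expect_warning(initial_peaks(starts), "peaks")
})

test_that("type weights are exact log ratios of tabulated frequencies", {
  # all peaks ATG over a uniform background of the three start types
  n <- 300L
  starts <- tibble::tibble(
    orf = rep(1:100, 3),
    C = rep(50, n),
    codon = rep(c("ATG", "GTG", "TTG"), each = 100L),
    len = rep(300L, n))
  peaks <- which(starts$codon == "ATG")
  w <- genetiler:::tabulate_weights(starts, peaks, rep(0L, n), 28L, gt_params())
  # log(1 / (1/3)) = log 3, up to the single pseudo-occurrence per empty type
  expect_equal(unname(w$type_w["ATG"]), log(3), tolerance = 0.02)
  expect_lt(w$type_w["GTG"], -3)  # unobserved types fall to the pseudo-count floor
  expect_lt(w$type_w["TTG"], -3)
})

test_that("start training converges to a fixed point when peaks stop moving", {
  fit <- sd500()$profile$training
  expect_lte(fit$sd_iterations, gt_params()$max_start_iter)
  m <- fit$sd_moved
  expect_lt(m[length(m)], 0.01 * fit$n_peaks + 1)
})

test_that("peak movement is predominantly non-increasing across the suite", {
  suite <- stress_suite()
  steps_total <- 0L; steps_noninc <- 0L
  for (s in suite) {
    m <- s$profile$training$sd_moved
    if (length(m) < 2L) next
    d <- diff(m)
    steps_total <- steps_total + length(d)
    steps_noninc <- steps_noninc + sum(d <= 0)
  }
  expect_gte(steps_noninc / steps_total, 0.9)
})

test_that("the SD usage rule follows the stated decision boundary", {
  w <- rep(-2, 28)
  w[1] <- 0.2
  expect_false(detect_sd_usage(w))             # zero bin positive
  w[1] <- -2; w[12] <- 2.5
  expect_true(detect_sd_usage(w))              # neither clause fires
  w2 <- rep(0.5, 28); w2[1] <- -0.3
  expect_false(detect_sd_usage(w2))            # weak zero bin, weak 4-mers
  w3 <- rep(0.5, 28); w3[1] <- -0.3; w3[4] <- 1.5
  expect_true(detect_sd_usage(w3))             # strong 4-mer bin rescues
})

test_that("SD detection recovers the planted regime at scale", {
  expect_true(sd500()$profile$uses_sd)
  expect_false(sec500()$profile$uses_sd)
  expect_false(none500()$profile$uses_sd)
})

test_that("the secondary finder recovers planted and AT-rich motifs", {
  sec <- sec500()$profile
  expect_true(any(grepl("GGTG", sec$sec_words)))
  fam <- grepl("GGTG", rownames(sec$sec_weights))
  expect_gte(max(sec$sec_weights[fam, ]), max(sec$sec_weights))
  none <- none500()$profile
  mx <- apply(none$sec_weights, 1, max)
  top <- names(sort(mx, decreasing = TRUE))[1]
  expect_true(grepl("^[AT]+$", top))
})

test_that("random upstream regions yield no strong secondary motif", {
  set.seed(31)
  n <- 400L
  starts <- tibble::tibble(
    orf = seq_len(n), C = rep(60, n),
    codon = sample(c("ATG", "GTG", "TTG"), n, TRUE, prob = c(.7, .2, .1)),
    len = rep(600L, n))
  ups <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 21, TRUE), collapse = ""), character(1))
  chm <- genetiler:::upstream_char_matrix(ups, 21L)
  sec <- find_secondary_motif(starts, chm, seq_len(n), gt_params())
  if (length(sec$words)) {
    expect_lt(sec$top_weight, gt_params()$sec_clearcut_weight)
  }
  expect_gt(sec$none_w, -0.5)
})

test_that("the upstream PWM is a per-position log ratio over its offsets", {
  params <- gt_params()
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  # planted: A at offset 20, uniform elsewhere
  set.seed(7)
  ups <- vapply(1:500, function(i) {
    x <- sample(c("A", "C", "G", "T"), 45, TRUE)
    x[45 - 20 + 1] <- "A"
    paste(x, collapse = "")
  }, character(1))
  pwm <- train_upstream_pwm(ups, bg, params)
  expect_equal(dim(pwm), c(4L, length(params$pwm_offsets)))
  expect_equal(unname(pwm["A", "20"]), log(1 / 0.25), tolerance = 0.02)
  off_far <- pwm[, colnames(pwm) != "20"]
  expect_lt(max(abs(off_far)), 0.35)  # roughly zero where nothing is planted
  # scoring sums the matrix over the same offsets
  u <- genetiler:::upstream_pwm_score(ups[1], pwm, params)
  manual <- 0
  ch <- strsplit(ups[1], "")[[1]]
  for (j in seq_along(params$pwm_offsets)) {
    manual <- manual + pwm[ch[45 - params$pwm_offsets[j] + 1], j]
  }
  expect_equal(u, unname(manual))
})
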