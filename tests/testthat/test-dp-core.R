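random_nodes <- function(n, gc = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  b <- paste(sample(c("A", "C", "G", "T"), n, TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
             collapse = "")
  enumerate_nodes(tibble::tibble(id = "t", bases = b, table_id = 11L))
}

test_that("connection scoring follows the Table-1 kinds", {
  expect_equal(connection_score("gene", gene_score = 12.5), 12.5)
  expect_equal(connection_score("intergenic", gap = 30), 0.5)    # operon bonus
  expect_equal(connection_score("intergenic", gap = 200), -0.5)  # long-gap penalty
  expect_equal(connection_score("intergenic", gap = 100), 0)
  expect_equal(connection_score("intergenic", gap = 30, pass = "training"), 0.2)
  expect_equal(connection_score("same_strand_overlap", gene_score = 8, gap = -4),
               8)
  expect_error(connection_score("same_strand_overlap", gene_score = 8, gap = -70),
               "overlap")
  expect_error(connection_score("opposite_strand_overlap", gene_score = 8,
                                gap = -250), "overlap")
})

test_that("the overlap index picks the best follower gene per frame", {
  nodes <- random_nodes(1500, seed = 41)
  ns <- sum(nodes$kind == "start")
  set.seed(42)
  sc <- round(runif(ns, 0, 10), 3)
  idx <- build_overlap_index(nodes, sc)
  # oracle: brute-force search over all start nodes
  genes <- nodes[nodes$kind == "start", ]
  stops <- nodes[nodes$kind == "stop", ]
  for (i in seq_len(nrow(stops))) {
    strand <- stops$strand[i]
    end3 <- if (strand == 1L) stops$right[i] else stops$left[i]
    key <- paste0(if (strand == 1L) "+" else "-", end3)
    if (strand == 1L) {
      cand <- which(genes$strand == 1L & genes$left >= end3 - 59L &
                      genes$left <= end3 & genes$right > end3)
    } else {
      cand <- which(genes$strand == -1L & genes$right <= end3 + 59L &
                      genes$right >= end3 & genes$left < end3)
    }
    rows <- idx[idx$stop_key == key & idx$strand == strand, ]
    if (!length(cand)) {
      expect_equal(nrow(rows), 0L)
    } else {
      for (f in unique(genes$frame[cand])) {
        cf <- cand[genes$frame[cand] == f]
        best <- cf[which.max(sc[cf])]
        expect_equal(rows$score[rows$frame == f], sc[best])
      }
    }
  }
})

test_that("the optimal path equals exhaustive enumeration on random instances", {
  set.seed(55)
  for (k in 1:40) {
    nodes <- random_nodes(sample(200:600, 1), gc = runif(1, 0.3, 0.7))
    ns <- sum(nodes$kind == "start")
    if (ns == 0) next
    sc <- round(runif(ns, -6, 15), 3)
    scw <- sc + round(runif(ns, 0, 3), 3)
    wok <- runif(ns) < 0.4
    pass <- if (k %% 2) "final" else "training"
    dp <- dp_optimal_path(nodes, sc, scw, wok, pass = pass)
    o <- oracle_best_tiling(nodes, sc, scw, wok, pass = pass)
    expect_equal(attr(dp, "total"), o, tolerance = 1e-9)
  }
})

test_that("heavily overlapping alternatives resolve to the higher score", {
  # two long ORFs in different frames over the same locus: the DP must choose
  set.seed(77)
  nodes <- random_nodes(900)
  genes <- nodes[nodes$kind == "start", ]
  ns <- nrow(genes)
  sc <- rep(-5, ns)
  # pick two mutually exclusive genes (overlap beyond the same-strand cap)
  found <- FALSE
  for (i in seq_len(ns)) {
    for (j in seq_len(ns)) {
      if (i == j) next
      ovl <- min(genes$right[i], genes$right[j]) -
        max(genes$left[i], genes$left[j]) + 1L
      if (genes$strand[i] == genes$strand[j] && ovl > 60L &&
          genes$left[j] > genes$left[i] && genes$right[j] > genes$right[i]) {
        sc[i] <- 10; sc[j] <- 7
        sel <- dp_optimal_path(nodes, sc, pass = "final")
        expect_true(genes$left[i] %in% sel$left)
        expect_false(genes$left[j] %in% sel$left &&
                       genes$left[i] %in% sel$left)
        found <- TRUE
      }
      if (found) break
    }
    if (found) break
  }
  expect_true(found)
})

test_that("no emitted pair violates the overlap limits on the stress suite", {
  suite <- stress_suite()
  for (s in suite) {
    st <- overlap_stats(s$preds)
    expect_lte(st$max_ss, 60L)
    expect_lte(st$max_opp, 200L)
    expect_equal(st$n_opp5, 0L)
  }
})

test_that("the DP mirrors under strand reflection with generic scores", {
  # The connection system is mirror-symmetric except for double-overlap
  # chains: a forward gene may overlap neighbours at both ends, while a
  # reverse gene's 5' overlap excludes a simultaneous 3' overlap (its entry
  # node is consumed by the opposite-strand connection). Calls therefore
  # mirror exactly in all but those rare chain configurations.
  set.seed(91)
  n_exact <- 0L
  for (k in 1:20) {
    L <- sample(400:800, 1)
    b <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    n1 <- enumerate_nodes(tibble::tibble(id = "x", bases = b, table_id = 11L))
    n2 <- enumerate_nodes(tibble::tibble(id = "x", bases = reverse_complement(b),
                                         table_id = 11L))
    g1 <- n1[n1$kind == "start", ]
    g2 <- n2[n2$kind == "start", ]
    # assign mirrored scores via the (reflected extent, strand) key
    key1 <- paste(g1$left, g1$right, g1$strand)
    key2 <- paste(L - 1L - g2$right, L - 1L - g2$left, -g2$strand)
    expect_setequal(key1, key2)
    sc1 <- round(runif(nrow(g1), -12, 6), 3)  # sparse positive genes
    sc2 <- sc1[match(key2, key1)]
    s1 <- dp_optimal_path(n1, sc1, pass = "final")
    s2 <- dp_optimal_path(n2, sc2, pass = "final")
    k1 <- paste(s1$left, s1$right, s1$strand)
    k2 <- paste(L - 1L - s2$right, L - 1L - s2$left, -s2$strand)
    jac <- length(intersect(k1, k2)) / max(1L, length(union(k1, k2)))
    expect_gte(jac, 0.4)
    if (setequal(k1, k2)) n_exact <- n_exact + 1L
  }
  expect_gte(n_exact, 17L)
})

test_that("the RBS waiver applies only at 1 or 4 bp same-strand overlaps", {
  # constructed ATGA junction: gene A ends ...GCA TGA; gene B's ATG sits on
  # the A TG of that junction (4 bp overlap), its second codon reuses the
  # stop's final A
  geneA <- paste0("ATG", strrep("GAA", 38), "GCA", "TGA")  # 123 bp
  seqs <- paste0(strrep("C", 30), geneA, "CT", strrep("GCT", 39), "TAA",
                 strrep("C", 30))
  rec <- tibble::tibble(id = "j", bases = seqs, table_id = 11L)
  nodes <- enumerate_nodes(rec)
  genes <- nodes[nodes$kind == "start", ]
  stopA_end <- 30L + nchar(geneA) - 1L
  a_row <- which(genes$left == 30L & genes$strand == 1L)
  b_row <- which(genes$left == stopA_end - 3L & genes$strand == 1L)
  expect_length(a_row, 1L)
  expect_length(b_row, 1L)
  sc <- rep(-100, nrow(genes)); scw <- sc
  sc[a_row] <- 20
  sc[b_row] <- 5; scw[b_row] <- 9   # waived variant is higher
  wok <- rep(FALSE, nrow(genes)); wok[b_row] <- TRUE
  sel <- dp_optimal_path(nodes, sc, scw, wok, pass = "final")
  expect_true(sel$waived[match(genes$left[b_row], sel$left)])
  expect_equal(sel$score[match(genes$left[b_row], sel$left)], 9)
  # without waiver eligibility the raw score is used
  sel2 <- dp_optimal_path(nodes, sc, scw, rep(FALSE, nrow(genes)), pass = "final")
  expect_false(any(sel2$waived))
})
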