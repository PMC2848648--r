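test_that("FASTA reading parses, normalizes, and preserves order", {
  f <- tempfile(fileext = ".fna")
  writeLines(c(">c1 some description", "ATGAAATAA",
               ">c2", "atguuu", "CCC"), f)
  rec <- read_genome_fasta(f)
  expect_equal(rec$id, c("c1", "c2"))
  expect_equal(rec$bases, c("ATGAAATAA", "ATGTTTCCC"))  # uppercased, U -> T
  expect_equal(rec$table_id, c(11L, 11L))

  empty <- tempfile()
  file.create(empty)
  expect_error(read_genome_fasta(empty), "empty|readable")
  bad <- tempfile()
  writeLines(c(">p1", "MKVLLIQWERTYHHH"), bad)
  expect_error(read_genome_fasta(bad), "nucleotide")
})

test_that("reverse complement is a standard involution", {
  expect_equal(reverse_complement("ATGC"), "GCAT")
  expect_equal(reverse_complement(""), "")
  expect_equal(reverse_complement("ANNT"), "ANNT")
  set.seed(1)
  for (i in 1:5) {
    x <- paste(sample(c("A", "C", "G", "T", "N"), 50, TRUE), collapse = "")
    expect_equal(reverse_complement(reverse_complement(x)), x)
  }
})

test_that("translation follows the genetic code with initiator and N rules", {
  expect_equal(translate_gene("ATGAAATAA"), "MK")
  expect_equal(translate_gene("GTGAAATAA"), "MK")   # initiator GTG -> M
  expect_equal(translate_gene("TTGAAATAA"), "MK")
  expect_equal(translate_gene("ATGNNNTAA"), "MX")
  expect_equal(translate_gene("GTGAAATAA", partial_left = TRUE), "VK")
  # table 4 reads TGA as tryptophan
  expect_equal(translate_gene("ATGTGATAA", table_id = 4L), "MW")
  expect_error(translate_gene(""), "zero-length")
})

test_that("node enumeration matches a brute-force codon scan", {
  brute_scan <- function(bases, min_len = 90L) {
    L <- nchar(bases)
    found <- list()
    for (strand in c(1L, -1L)) {
      s <- if (strand == 1L) bases else reverse_complement(bases)
      cods <- substring(s, 1:(L - 2), 3:L)
      for (q in 0:(L - 3)) {
        if (!(cods[q + 1] %in% c("ATG", "GTG", "TTG"))) next
        t <- q + 3L
        while (t <= L - 3 && !(cods[t + 1] %in% c("TAA", "TAG", "TGA"))) t <- t + 3L
        right_q <- if (t <= L - 3) t + 2L else q + 3L * ((L - q) %/% 3L) - 1L
        if (right_q - q + 1L >= min_len) {
          pos <- if (strand == 1L) q else L - 1L - q
          found[[length(found) + 1L]] <- c(pos, strand)
        }
      }
    }
    found
  }
  set.seed(42)
  for (i in 1:6) {
    L <- sample(300:2000, 1)
    bases <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    rec <- tibble::tibble(id = "r", bases = bases, table_id = 11L)
    nodes <- enumerate_nodes(rec)
    got <- nodes[nodes$kind == "start" & !nodes$edge, c("pos", "strand")]
    want <- brute_scan(bases)
    expect_setequal(paste(got$pos, got$strand),
                    vapply(want, function(w) paste(w[1], w[2]), character(1)))
  }
})

test_that("node enumeration is strand-symmetric under reflection", {
  set.seed(9)
  bases <- paste(sample(c("A", "C", "G", "T"), 1200, TRUE), collapse = "")
  L <- nchar(bases)
  n1 <- enumerate_nodes(tibble::tibble(id = "x", bases = bases, table_id = 11L))
  n2 <- enumerate_nodes(tibble::tibble(id = "x", bases = reverse_complement(bases),
                                       table_id = 11L))
  key <- function(n, flip) {
    d <- n[n$kind == "start" & !n$edge, ]
    pos <- if (flip) L - 1L - d$pos else d$pos
    str <- if (flip) -d$strand else d$strand
    paste(pos, str, d$codon)
  }
  expect_setequal(key(n1, FALSE), key(n2, TRUE))
})

test_that("short genes are excluded and edge nodes are present", {
  # one clean 99 bp ORF with no internal start codons
  orf <- paste0("ATG", strrep("GAA", 31), "TAA")
  expect_equal(nchar(orf), 99)
  rec <- tibble::tibble(id = "c", bases = orf, table_id = 11L)
  nodes <- enumerate_nodes(rec)
  real <- nodes[nodes$kind == "start" & !nodes$edge & nodes$strand == 1L, ]
  expect_equal(nrow(real), 1L)
  expect_equal(real$pos, 0L)
  expect_equal(real$stop_pos, 96L)

  tiny <- tibble::tibble(id = "t", bases = "ATGAAATAA", table_id = 11L)
  nt <- enumerate_nodes(tiny)
  expect_equal(sum(nt$kind == "start" & !nt$edge), 0L)  # below 90 bp
  expect_true(any(nt$edge))

  # internal in-frame GTG gives a second start sharing the stop
  orf2 <- paste0("ATG", strrep("GAA", 10), "GTG", strrep("GAA", 29), "TAA")
  n2 <- enumerate_nodes(tibble::tibble(id = "c", bases = orf2, table_id = 11L))
  real2 <- n2[n2$kind == "start" & !n2$edge & n2$strand == 1L, ]
  expect_equal(nrow(real2), 2L)
  expect_equal(length(unique(real2$stop_pos)), 1L)
})

test_that("codons containing N never form starts or stops", {
  seqn <- paste0("ATG", strrep("GAA", 20), "NTG", strrep("GAA", 20), "TAA")
  n <- enumerate_nodes(tibble::tibble(id = "c", bases = seqn, table_id = 11L))
  real <- n[n$kind == "start" & !n$edge & n$strand == 1L, ]
  expect_false(any(is.na(real$codon)))
  expect_true(all(real$codon %in% c("ATG", "GTG", "TTG")))
})
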