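test_that("FASTA records are parsed in order with folded case", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1 description text", "CATG", "ACTG",
               ">s2", "catgactg"), f)
  seqs <- read_fasta(f)
  expect_length(seqs, 2)
  expect_identical(seqs[[1]]$id, "s1")
  expect_identical(as.character(seqs[[1]]), "CATGACTG")
  expect_identical(length(seqs[[1]]), 8L)
  expect_identical(as.character(seqs[[2]]), "CATGACTG")  # case folded
  raw <- read_fasta(f, case_fold = FALSE)
  expect_identical(as.character(raw[[2]]), "catgactg")
})

test_that("empty and malformed FASTA files are rejected with context", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), f)
  expect_error(read_fasta(f), "empty FASTA")
  writeLines(c("CATG", ">s1", "ACGT"), f)
  expect_error(read_fasta(f), "line 1")
  expect_error(read_fasta(file.path(tempdir(), "nope.fa")), "not found")
})

test_that("FASTA output is byte-deterministic and round trips", {
  s <- random_dna(200, seed = 11, id = "chrZ")
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(s, f1)
  write_fasta(random_dna(200, seed = 11, id = "chrZ"), f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_fasta(f1)
  expect_identical(as.character(back[[1]]), as.character(s))
})

test_that("search reports the worked-example matches with every engine", {
  for (eng in c("oracle", "rowparallel", "warpsim")) {
    hits <- asm_search("CATGACTG", "TACTG", k = 2, engine = eng)
    expect_identical(hits$end, c(3L, 6L, 7L), label = eng)
    expect_identical(hits$distance, c(2L, 2L, 1L), label = eng)
  }
  hits4 <- asm_search("CATGACTG", "TACTG", k = 2, engine = "warpsim",
                      warp_width = 4)
  expect_identical(hits4$end, c(3L, 6L, 7L))
  expect_s3_class(attr(hits4, "counters"), "asm_counters")
})

test_that("search edge contracts hold", {
  # the text searched against itself matches its own end exactly
  expect_warning(hits <- asm_search("GATTACA", "GATTACA", k = 0), "n > m > k")
  expect_identical(hits$end, 6L)
  expect_identical(hits$distance, 0L)
  # k >= m matches every position
  expect_warning(all_hits <- asm_search("CATGACTG", "TA", k = 2),
                 "every position")
  expect_identical(all_hits$end, 0:7)
  expect_error(asm_search("CATG", "", 1), "length >= 1")
  expect_error(asm_search("CATG", "A", -1), "non-negative")
  # alphabet-external symbols never match, even themselves
  none <- asm_search("ANA", "N", k = 0)
  expect_identical(nrow(none), 0L)
})

test_that("all engines produce identical reports on random inputs", {
  set.seed(501)
  for (r in 1:20) {
    t <- random_dna(sample(20:300, 1))
    p <- random_dna(sample(2:12, 1))
    k <- sample(0:3, 1)
    ref <- suppressWarnings(asm_search(t, p, k, engine = "oracle"))
    for (eng in list(c("rowparallel", "32"), c("warpsim", "2"),
                     c("warpsim", "8"), c("warpsim", "32"))) {
      alt <- suppressWarnings(
        asm_search(t, p, k, engine = eng[1], warp_width = as.integer(eng[2])))
      expect_identical(alt$end, ref$end)
      expect_identical(alt$distance, ref$distance)
    }
  }
})

test_that("k = 0 reduces to exact substring search", {
  set.seed(502)
  for (r in 1:20) {
    t <- random_dna(sample(30:400, 1))
    p <- random_dna(sample(2:6, 1))
    hits <- suppressWarnings(asm_search(t, p, k = 0))
    expect_identical(hits$end,
                     naive_exact_ends(as.character(t), as.character(p)))
    expect_true(all(hits$distance == 0L))
  }
})

test_that("match reports round trip through TSV and render BED correctly", {
  hits <- asm_search("CATGACTG", "TACTG", k = 2)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_matches(hits, tsv, format = "tsv")
  expect_identical(readLines(tsv),
                   c("record_id\tend\tdistance",
                     "seq\t3\t2", "seq\t6\t2", "seq\t7\t1"))
  back <- read_matches(tsv)
  expect_identical(back$end, hits$end)
  expect_identical(back$distance, hits$distance)
  expect_identical(unique(back$record_id), "seq")

  bed <- withr::local_tempfile(fileext = ".bed")
  write_matches(hits, bed, format = "bed")
  expect_identical(readLines(bed)[3], "seq\t7\t8\ted=1")

  empty <- suppressWarnings(asm_search("CCCCCCCC", "AAAA", k = 0))
  write_matches(empty, tsv, format = "tsv")
  expect_identical(readLines(tsv), "record_id\tend\tdistance")
  expect_error(write_matches(hits, tsv, format = "gff"), "'arg'")
})
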