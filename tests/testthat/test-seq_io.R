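test_that("read_fasta parses records, folds multi-line bodies, errors on bad input", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1", "ACGT"), f)
  expect_equal(read_fasta(f), data.frame(id = "s1", seq = "ACGT"))

  writeLines(c(">s1", "AC", "GT", ">s2", "TT"), f)
  got <- read_fasta(f)
  expect_equal(got$id, c("s1", "s2"))
  expect_equal(got$seq, c("ACGT", "TT"))

  file.create(f2 <- withr::local_tempfile(fileext = ".fa"))
  expect_equal(nrow(read_fasta(f2)), 0L)

  writeLines(c("ACGT", ">s1", "AC"), f)
  expect_error(read_fasta(f))
  expect_error(read_fasta(file.path(tempdir(), "no-such-file.fa")),
               "not found")
})

test_that("read_fasta uppercases soft-masked bases and keeps ambiguity codes", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1", "acgtNryn"), f)
  expect_equal(read_fasta(f)$seq, "ACGTNRYN")
})

test_that("read_fastq parses 4-line records and rejects truncation", {
  f <- withr::local_tempfile(fileext = ".fq")
  writeLines(c("@r1", "ACGT", "+", "IIII"), f)
  expect_equal(read_fastq(f), data.frame(id = "r1", seq = "ACGT"))

  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "TTAA", "+", "IIII"), f)
  got <- read_fastq(f)
  expect_equal(got$id, c("r1", "r2"))
  expect_equal(got$seq, c("ACGT", "TTAA"))

  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2"), f)
  expect_error(read_fastq(f), "malformed FASTQ")
})

test_that("readers preserve record order and content on larger files", {
  withr::local_seed(101)
  n <- 1000L
  seqs <- vapply(sample(20:80, n, replace = TRUE), random_dna, character(1))
  ids <- paste0("r", seq_len(n))
  fa <- withr::local_tempfile(fileext = ".fa")
  # fold some bodies across lines to exercise concatenation
  body <- unlist(lapply(seq_len(n), function(i) {
    s <- seqs[i]
    if (i %% 3 == 0) {
      cut <- nchar(s) %/% 2
      c(paste0(">", ids[i]), substr(s, 1, cut), substr(s, cut + 1, nchar(s)))
    } else {
      c(paste0(">", ids[i]), s)
    }
  }))
  writeLines(body, fa)
  got <- read_fasta(fa)
  expect_equal(got$id, ids)
  expect_equal(got$seq, seqs)

  fq <- withr::local_tempfile(fileext = ".fq")
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+",
                             vapply(nchar(seqs), strrep, character(1),
                                    x = "I"))), fq)
  got <- read_fastq(fq)
  expect_equal(got$id, ids)
  expect_equal(got$seq, seqs)
})

test_that("chunk_records fills greedily by bases without splitting records", {
  recs <- data.frame(id = c("a", "b", "c"),
                     seq = vapply(rep(100, 3), strrep, character(1), x = "A"))
  ch <- chunk_records(recs, 150)
  expect_equal(lengths(lapply(ch, `[[`, "id")), c(2L, 1L))

  expect_length(chunk_records(recs, 1e6), 1L)
  expect_length(chunk_records(recs[0, ], 100), 0L)

  # concatenation of chunks reproduces the input in order
  withr::local_seed(7)
  recs2 <- data.frame(id = paste0("r", 1:50),
                      seq = vapply(sample(10:200, 50, TRUE), random_dna,
                                   character(1)))
  ch2 <- chunk_records(recs2, 300)
  expect_equal(do.call(rbind, c(ch2, list(make.row.names = FALSE))),
               recs2)
  sizes <- vapply(ch2, function(x) sum(nchar(x$seq)), numeric(1))
  # every chunk but the last reached the target, and none would have
  # reached it without its final record
  expect_true(all(head(sizes, -1) >= 300))
  last_rec <- vapply(ch2, function(x) nchar(x$seq[nrow(x)]), numeric(1))
  expect_true(all(sizes - last_rec < 300))
})

test_that("write_counts emits sorted TSV and read_counts round-trips", {
  tab <- new_count_table(c(TTTT = 1, AAAA = 3), k = 4, mode = "forward")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_counts(tab, f)
  expect_equal(readLines(f), c("AAAA\t3", "TTTT\t1"))

  single <- new_count_table(c(ACGT = 2), k = 4, mode = "forward")
  write_counts(single, f)
  expect_equal(readLines(f), "ACGT\t2")

  empty <- new_count_table(stats::setNames(numeric(), character()),
                           k = 4, mode = "forward")
  write_counts(empty, f)
  expect_equal(file.size(f), 0)

  withr::local_seed(11)
  kmers <- unique(random_mmers(500, 8))
  tab2 <- new_count_table(stats::setNames(sample(1:50, length(kmers), TRUE),
                                          kmers), k = 8, mode = "canonical")
  write_counts(tab2, f)
  back <- read_counts(f, k = 8, mode = "canonical")
  expect_equal(back$counts[order(names(back$counts))],
               tab2$counts[order(names(tab2$counts))])
  expect_equal(back$k, tab2$k)
})
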