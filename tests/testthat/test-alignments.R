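test_that("FASTA round-trips preserve ids, order and rows", {
  aln <- seq_alignment(c("tx1", "tx2"), c("ACGTAC", "A-GTNC"))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(aln, path)
  back <- read_fasta(path)
  expect_identical(back$ids, aln$ids)
  expect_identical(back$mat, aln$mat)

  sim <- simulate_codon_alignment(alloteropsis_codon_tree(), 30, seed = 2)
  write_fasta(sim$alignment, path)
  back2 <- read_fasta(path)
  expect_identical(alloscan:::aln_strings(back2),
                   alloscan:::aln_strings(sim$alignment))
})

test_that("load normalizes case and rejects malformed input", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "acgt", ">b", "ttga"), path)
  aln <- read_fasta(path)
  expect_identical(alloscan:::aln_strings(aln), c(a = "ACGT", b = "TTGA"))

  expect_error(seq_alignment(c("a", "b"), c("ACGT", "ACG")), "ragged")
  expect_error(seq_alignment("a", "ACXT"), "illegal")
  expect_error(seq_alignment(c("a", "a"), c("AC", "GT")), "unique")
  expect_error(read_fasta("/nonexistent/file.fa"), "no such file")
})

test_that("codon view enforces frame and internal stop codons", {
  expect_error(as_codon_alignment(seq_alignment("a", "ACGTA")),
               "divisible by 3")
  # TAA internal stop in first codon position
  expect_error(as_codon_alignment(seq_alignment(c("a", "b"),
                                                c("TAAACG", "ACGACG"))),
               "stop codon")
  # gap-containing codon is missing, not a stop
  aln <- as_codon_alignment(seq_alignment(c("a", "b"),
                                          c("T-AACG", "ACGACG")))
  st <- alloscan:::codon_index_matrix(aln)
  expect_true(is.na(st["a", 1]))
  expect_equal(aln$n_codons, 2)
})

test_that("third positions extract columns 2, 5, 8 (0-based)", {
  aln <- seq_alignment("a", "ACGTTGCAT")
  tp <- third_positions(aln)
  expect_identical(alloscan:::aln_strings(tp)[["a"]], "GGT")
  expect_error(third_positions(seq_alignment("a", "ACGT")), "frame")
})

test_that("third positions match the simulator's position-3 truth", {
  sim <- simulate_codon_alignment(tiny_tree3(), 20, seed = 5)
  tp <- alloscan:::aln_strings(third_positions(sim$alignment))
  for (id in sim$alignment$ids) {
    s <- strsplit(alloscan:::aln_strings(sim$alignment)[[id]], "")[[1]]
    expect_identical(tp[[id]], paste(s[seq(3, length(s), 3)],
                                     collapse = ""))
  }
})

test_that("fixed-codon filter keeps between-group, drops within-group variation", {
  #        codon1     codon2     codon3
  # g1: a  AAA        CCC        GGG
  #     b  AAA        CCA        GGG
  # g2: c  TTT        CCC        GGG
  #     d  TTT        CCC        GGC
  aln <- as_codon_alignment(seq_alignment(
    c("a", "b", "c", "d"),
    c("AAACCCGGG", "AAACCAGGG", "TTTCCCGGG", "TTTCCCGGC")))
  out <- fixed_codon_filter(aln, list(g1 = c("a", "b"), g2 = c("c", "d")))
  expect_identical(attr(out, "kept_sites"), 1L)

  expect_error(fixed_codon_filter(aln, list(g1 = c("a", "b"),
                                            g2 = c("zz"))),
               "no tips")

  # oracle scan on a random alignment
  sim <- simulate_codon_alignment(tiny_tree4(), 40, seed = 8)
  groups <- list(g1 = c("A", "B"), g2 = c("C", "D"))
  out2 <- fixed_codon_filter(sim$alignment, groups)
  st <- alloscan:::codon_index_matrix(sim$alignment)
  manual <- which(vapply(seq_len(ncol(st)), function(j) {
    all(vapply(groups, function(g) {
      v <- st[g, j]; v <- v[!is.na(v)]
      length(unique(v)) <= 1
    }, TRUE))
  }, TRUE))
  expect_identical(attr(out2, "kept_sites"), manual)
})
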