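make_refs <- function(seed = 1, len = 600) {
  set.seed(seed)
  list(famA = c(refA1 = paste(sample(c("A", "C", "G", "T"), len,
                                     replace = TRUE), collapse = "")),
       famB = c(refB1 = paste(sample(c("A", "C", "G", "T"), len,
                                     replace = TRUE), collapse = "")))
}

test_that("an exact slice is found with a near-zero e-value", {
  refs <- make_refs()
  contig <- substr(refs$famA[["refA1"]], 101, 400)
  hits <- similarity_search(c(c1 = contig), refs)
  expect_equal(nrow(hits), 1)
  expect_identical(hits$family, "famA")
  expect_equal(hits$end - hits$start, 300)
  expect_lt(hits$evalue, 1e-10)
  expect_identical(hits$strand, "+")
})

test_that("the 50 bp matched-length floor is enforced", {
  refs <- make_refs(seed = 2)
  set.seed(5)
  noise <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                    replace = TRUE), collapse = "")
  c49 <- paste0(noise(60), substr(refs$famA[["refA1"]], 201, 249))
  c50 <- paste0(noise(60), substr(refs$famA[["refA1"]], 201, 250))
  h49 <- similarity_search(c(x = c49), refs["famA"])
  h50 <- similarity_search(c(x = c50), refs["famA"])
  expect_true(nrow(h50) == 1 && h50$end - h50$start >= 50)
  expect_true(nrow(h49) == 0 || h49$end - h49$start < 50)
  if (nrow(h49) == 1) {
    # any sub-threshold match must have been extended past 50 bp by chance
    expect_gte(h49$end - h49$start, 50)
  }
})

test_that("random contigs yield no significant hits", {
  refs <- make_refs(seed = 3)
  set.seed(11)
  n_hit <- 0
  for (i in 1:20) {
    ct <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                collapse = "")
    n_hit <- n_hit + nrow(similarity_search(c(r = ct), refs))
  }
  expect_lte(n_hit, 1)
})

test_that("filters are monotone in e_max and min_match_len", {
  refs <- make_refs(seed = 4)
  set.seed(21)
  contigs <- stats::setNames(lapply(1:6, function(i) {
    s <- sample(c(100, 160, 260), 1)
    substr(refs[[(i %% 2) + 1]][[1]], s, s + sample(60:200, 1))
  }), paste0("c", 1:6))
  contigs <- unlist(contigs)
  n_base <- nrow(similarity_search(contigs, refs))
  expect_lte(nrow(similarity_search(contigs, refs, e_max = 1e-8)), n_base)
  expect_lte(nrow(similarity_search(contigs, refs, min_match_len = 150)),
             n_base)
})

test_that("trimming returns the matched slice, reverse-complemented on minus", {
  refs <- make_refs(seed = 6)
  slice <- substr(refs$famA[["refA1"]], 51, 250)
  # flanks may extend the local alignment by a chance-matching base or
  # two, so assert containment rather than identity
  ct_fwd <- paste0("GGGGG", slice, "AAAAA")
  h <- similarity_search(c(f = ct_fwd), refs["famA"])
  tr_fwd <- trim_to_match(ct_fwd, h[1, ])
  expect_true(grepl(slice, tr_fwd, fixed = TRUE))
  expect_lte(nchar(tr_fwd), nchar(slice) + 5)

  ct_rev <- rev_comp(ct_fwd)
  h2 <- similarity_search(c(r = ct_rev), refs["famA"])
  expect_identical(h2$strand, "-")
  tr_rev <- trim_to_match(ct_rev, h2[1, ])
  expect_true(grepl(slice, tr_rev, fixed = TRUE))
  expect_lte(nchar(tr_rev), nchar(slice) + 5)

  expect_error(trim_to_match("ACGT", data.frame(start = 2, end = 9,
                                                strand = "+")),
               "out of contig bounds")
  full <- similarity_search(c(f = slice), refs["famA"])
  expect_identical(trim_to_match(slice, full[1, ]), slice)
})

test_that("rpm/rpkm arithmetic and conservation hold", {
  pl <- data.frame(contig_id = "c1", lineage = "L1")
  counts <- data.frame(contig_id = "c1", sample_id = "s", reads = 10)
  ab <- quantify(pl, counts, c(c1 = 500), total_reads = c(s = 1e6))
  expect_equal(ab$rpm, 10)
  expect_equal(ab$rpkm, 20)

  pl2 <- data.frame(contig_id = c("c1", "c2"), lineage = c("L", "L"))
  counts2 <- data.frame(contig_id = c("c1", "c2"), sample_id = "s",
                        reads = c(4, 6))
  ab2 <- quantify(pl2, counts2, c(c1 = 300, c2 = 600),
                  total_reads = c(s = 1e6))
  expect_equal(ab2$rpm, 10)  # additivity

  # conservation under random partitions of contigs into lineages
  set.seed(31)
  for (i in 1:20) {
    n <- 12
    ids <- paste0("k", 1:n)
    pl3 <- data.frame(contig_id = ids,
                      lineage = sample(paste0("L", 1:4), n, replace = TRUE))
    counts3 <- data.frame(contig_id = ids, sample_id = "s",
                          reads = rpois(n, 40) + 1)
    ab3 <- quantify(pl3, counts3,
                    stats::setNames(sample(200:900, n), ids))
    expect_equal(sum(ab3$rpm), 1e6, tolerance = 1e-6)
  }

  # counted contig without placement lands in "unassigned"
  ab4 <- quantify(pl, rbind(counts, data.frame(contig_id = "c9",
                                               sample_id = "s",
                                               reads = 5)),
                  c(c1 = 500, c9 = 100))
  expect_true("unassigned" %in% ab4$lineage)
  expect_equal(sum(ab4$rpm), 1e6)
})

test_that("the 1:1 harvest drops duplicated-transcript families", {
  set.seed(41)
  base <- vapply(1:3, function(i)
    paste(sample(c("A", "C", "G", "T"), 700, replace = TRUE),
          collapse = ""), "")
  refs <- list(f1 = c(r1 = base[1]), f2 = c(r2 = base[2]),
               f3 = c(r3 = base[3]))
  mut <- function(s, n) alloscan:::mutate_sequence(s, n)
  tx <- list(
    t1 = c(a1 = mut(substr(base[1], 1, 650), 15),
           a2 = mut(substr(base[2], 1, 640), 15),
           a3 = mut(substr(base[3], 1, 630), 15)),
    t2 = c(b1 = mut(substr(base[1], 21, 680), 15),
           b2 = mut(substr(base[2], 11, 670), 15),
           b3 = mut(substr(base[3], 31, 660), 15),
           b3dup = mut(substr(base[3], 41, 690), 15)),  # duplicate in f3
    t3 = c(c1 = mut(substr(base[1], 5, 660), 15),
           c2 = mut(substr(base[2], 1, 655), 15),
           c3 = mut(substr(base[3], 1, 640), 15)),
    t4 = c(d1 = mut(substr(base[1], 1, 640), 15),
           d2 = mut(substr(base[2], 25, 700), 15),
           d3 = mut(substr(base[3], 12, 652), 15)))
  out <- harvest_orthologs(tx, refs, min_aln_len = 500, min_taxa = 4)
  expect_setequal(names(out), c("f1", "f2"))
  expect_identical(attr(out, "dropped"), "f3")
  expect_setequal(out$f1$ids, c("t1", "t2", "t3", "t4"))

  # a 499 bp alignment is excluded by the length filter
  short_tx <- list(t1 = c(s1 = substr(base[1], 1, 499)))
  out2 <- suppressWarnings(harvest_orthologs(short_tx, refs["f1"],
                                             min_aln_len = 500,
                                             min_taxa = 1))
  expect_length(out2, 0)
})

test_that("placement assigns simulated contigs to their true lineage", {
  ref <- default_reference_package(seed = 8)
  tx <- simulate_transcriptome(ref, pendant = 0.03, seed = 9)
  idx <- seq(1, length(tx$contigs), by = 3)  # subset for speed
  pl <- annotate_contigs(tx$contigs[idx], ref)
  truth <- tx$truth$lineage[match(pl$contig_id, tx$truth$contig_id)]
  expect_gte(mean(pl$lineage == truth), 0.9)
})
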