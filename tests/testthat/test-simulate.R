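test_that("generators are seed-deterministic", {
  tr <- alloteropsis_codon_tree()
  a <- simulate_codon_alignment(tr, 50, seed = 99)
  b <- simulate_codon_alignment(tr, 50, seed = 99)
  expect_identical(a$alignment$mat, b$alignment$mat)
  expect_identical(a$truth, b$truth)

  h1 <- simulate_gene_histories(3, sites = 100, seed = 5)
  h2 <- simulate_gene_histories(3, sites = 100, seed = 5)
  expect_identical(h1$genes[[2]]$alignment$mat, h2$genes[[2]]$alignment$mat)

  ref <- default_reference_package(seed = 2)
  t1 <- simulate_transcriptome(ref, seed = 3)
  t2 <- simulate_transcriptome(ref, seed = 3)
  expect_identical(t1$contigs, t2$contigs)
  expect_identical(t1$counts, t2$counts)
})

test_that("site-class frequencies follow the mixture at large n", {
  tr <- alloscan:::study_tree_14()
  sim <- simulate_codon_alignment(tr, 10000, kappa = 2, p0 = 0.6,
                                  p1 = 0.25, omega0 = 0.2, omega2 = 3,
                                  seed = 13)
  freq <- table(factor(sim$truth$class, levels = 1:4)) / 10000
  cls <- alloscan:::site_classes("BSA1", p0 = 0.6, p1 = 0.25,
                                 omega0 = 0.2, omega2 = 3)
  expect_true(all(abs(as.vector(freq) - cls$prop) < 0.02))
})

test_that("a zero-length tree yields identical sequences", {
  tr <- ape::read.tree(text = "((A:0,B:0):0,C:0);")
  sim <- simulate_codon_alignment(tr, 30, seed = 2)
  s <- alloscan:::aln_strings(sim$alignment)
  expect_identical(unname(s[1]), unname(s[2]))
  expect_identical(unname(s[1]), unname(s[3]))
})

test_that("introgression events rewrite node ages in the gene tree", {
  ev <- data.frame(gene = 2, node = "angusta_semialata_split", age = 2.8)
  sim <- simulate_gene_histories(3, sites = 60, events = ev, seed = 4)
  tt <- sim$truth
  split2 <- tt$true_age[tt$gene == "gene0002" &
                          tt$node == "angusta_semialata_split"]
  expect_equal(split2, 2.8)
  # descendants rescaled proportionally, ordering preserved
  semi2 <- tt$true_age[tt$gene == "gene0002" &
                         tt$node == "crown_semialata"]
  expect_equal(semi2, 4 * 2.8 / 7)
  split1 <- tt$true_age[tt$gene == "gene0001" &
                          tt$node == "angusta_semialata_split"]
  expect_equal(split1, 7)
  # invalid replacement (older than the node) rejected
  bad <- data.frame(gene = 1, node = "crown_semialata", age = 9)
  expect_error(simulate_gene_histories(1, sites = 30, events = bad,
                                       seed = 1), "younger")
})

test_that("substitution counts on a long branch match the model rate", {
  # two-taxon check via a 3-taxon tree with one long branch
  tr <- ape::read.tree(text = "((A:0.0001,B:0.0001):0.0001,C:0.5);")
  m <- gtr_model(alpha = 100)  # nearly homogeneous
  aln <- simulate_nucleotide_alignment(tr, m, 20000, seed = 17)
  s <- alloscan:::aln_strings(aln)
  p_obs <- mean(strsplit(s[["A"]], "")[[1]] != strsplit(s[["C"]], "")[[1]])
  # JC-like expectation at t ~ 0.5: p = 3/4 (1 - exp(-4t/3))
  t <- 0.5002
  p_exp <- 0.75 * (1 - exp(-4 * t / 3))
  se <- sqrt(p_exp * (1 - p_exp) / 20000)
  expect_lt(abs(p_obs - p_exp), 3 * se)
})

test_that("error-free transcriptome contigs are exact source substrings", {
  ref <- default_reference_package(seed = 6)
  tx <- simulate_transcriptome(ref, pendant = 0, error_rate = 0,
                               seed = 7)
  refs <- unlist(lapply(ref, function(f) {
    vapply(alloscan:::aln_strings(f$alignment), gsub,
           pattern = "-", replacement = "", "")
  }))
  hits <- vapply(tx$contigs, function(ct)
    any(vapply(refs, function(r) grepl(ct, r, fixed = TRUE), TRUE)), TRUE)
  expect_true(all(hits))

  # truth rpm recomputed from emitted counts matches the truth file
  rpm <- tapply(tx$counts$reads / (tx$total_reads / 1e6),
                tx$truth$lineage[match(tx$counts$contig_id,
                                       tx$truth$contig_id)], sum)
  m <- match(tx$truth_rpm$lineage, names(rpm))
  expect_equal(as.vector(rpm[m]), tx$truth_rpm$rpm, tolerance = 1e-9)
})
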