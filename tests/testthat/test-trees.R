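test_that("Newick round-trips preserve topology, lengths and labels", {
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1)ab:1,C:2)r;", path)
  tr <- read_newick(path)
  expect_equal(length(tr$tip.label), 3)
  expect_equal(sum(tr$edge[, 1] == length(tr$tip.label) + 1), 2)
  write_newick(tr, path)
  tr2 <- read_newick(path)
  expect_identical(tr2$tip.label, tr$tip.label)
  expect_equal(tr2$edge.length, tr$edge.length, tolerance = 1e-9)
  expect_identical(tr2$node.label, tr$node.label)
})

test_that("negative branch lengths are rejected", {
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:-0.5):1,C:2);", path)
  expect_error(read_newick(path), "negative branch lengths")
})

test_that("foreground flags survive a Newick round trip", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  tr <- label_foreground(tr, scenario_spec("x", list(c("A", "B"))))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, path)
  tr2 <- read_newick(path)
  expect_identical(attr(tr2, "foreground"), attr(tr, "foreground"))
})

test_that("foreground set is stem plus descendants, idempotent", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  sc <- scenario_spec("ab", list(c("A", "B")))
  fl <- label_foreground(tr, sc)
  expect_equal(sum(attr(fl, "foreground")), 3)  # stem + 2 tip branches
  fl2 <- label_foreground(fl, sc)
  expect_identical(attr(fl2, "foreground"), attr(fl, "foreground"))

  # a scenario covering the root clade flags every branch
  all_sc <- scenario_spec("all", list(c("A", "B", "C", "D")))
  expect_true(all(attr(label_foreground(tr, all_sc), "foreground")))

  expect_error(label_foreground(tr, scenario_spec("bad",
                                                  list(c("A", "C")))),
               "not monophyletic")
  expect_error(label_foreground(tr, scenario_spec("bad2",
                                                  list(c("A", "Z")))),
               "absent")
})

test_that("pruning taxa preserves pairwise path lengths among survivors", {
  tr <- alloteropsis_codon_tree()
  sim <- simulate_codon_alignment(tr, 5, seed = 1)
  pruned <- prune_taxa(sim$alignment, tr, c("A_paniculata",
                                            "A_semialata_I2"))
  keep <- pruned$tree$tip.label
  d_before <- ape::cophenetic.phylo(tr)[keep, keep]
  d_after <- ape::cophenetic.phylo(pruned$tree)[keep, keep]
  expect_equal(d_after, d_before, tolerance = 1e-12)
  expect_identical(sort(pruned$alignment$ids), sort(keep))

  ident <- prune_taxa(sim$alignment, tr, character(0))
  expect_identical(ident$tree, tr)
  expect_error(prune_taxa(sim$alignment,
                          ape::read.tree(text = "((A:1,B:1):1,C:1);"),
                          c("A", "B")),
               "fewer than 3")
})
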