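test_that("pruning equals exhaustive enumeration on 3- and 4-taxon data", {
  for (cfg in list(list(tree = tiny_tree3(), n = 6, seed = 11),
                   list(tree = tiny_tree4(), n = 4, seed = 12))) {
    sim <- simulate_codon_alignment(cfg$tree, cfg$n, kappa = 2, p0 = 0.65,
                                    omega0 = 0.25, seed = cfg$seed)
    m <- tiny_codon_model(codon_frequencies(sim$alignment))
    ll <- prune_loglik(sim$alignment, cfg$tree, m)
    bf <- bf_codon_loglik(sim$alignment, cfg$tree, m)
    expect_equal(ll, bf, tolerance = 1e-9)
  }
})

test_that("degenerate inputs give the closed-form likelihood", {
  tr <- ape::read.tree(text = "((A:0,B:0):0,C:0);")
  aln <- as_codon_alignment(seq_alignment(c("A", "B", "C"),
                                          rep("ATG", 3)))
  m <- tiny_codon_model()
  expect_equal(prune_loglik(aln, tr, m), log(m$pi[["ATG"]]))
})

test_that("likelihood is invariant under re-rooting (pulley principle)", {
  tr <- tiny_tree4()
  sim <- simulate_codon_alignment(tr, 8, seed = 4)
  m <- tiny_codon_model(codon_frequencies(sim$alignment))
  ll0 <- prune_loglik(sim$alignment, tr, m)
  # slide the root along its left edge: lengths 0.12/0.08 -> 0.05/0.15
  tr2 <- ape::read.tree(
    text = "((A:0.2,B:0.3):0.05,(C:0.15,D:0.25):0.15);")
  expect_equal(prune_loglik(sim$alignment, tr2, m), ll0,
               tolerance = 1e-9)
})

test_that("missing codons contribute likelihood one at that tip", {
  tr <- tiny_tree3()
  aln <- as_codon_alignment(seq_alignment(c("A", "B", "C"),
                                          c("ATGAAA", "ATGAAG", "NNNAAA")))
  m <- tiny_codon_model()
  ll <- prune_loglik(aln, tr, m)
  bf <- bf_codon_loglik(aln, tr, m)
  expect_equal(ll, bf, tolerance = 1e-9)
  expect_error(
    prune_loglik(aln, ape::read.tree(text = "((A:1,Z:1):1,C:1);"), m),
    "without sequence")
})

test_that("nucleotide GTR+G lnL matches phangorn on shared data", {
  tr <- tiny_tree4()
  m <- gtr_model(rates = c(1, 3, 0.6, 0.9, 2.8, 1),
                 base_freq = c(0.31, 0.24, 0.21, 0.24), alpha = 0.8)
  aln <- simulate_nucleotide_alignment(tr, m, 400, seed = 6)
  ll <- prune_loglik(aln, tr, m)
  dat <- phangorn::phyDat(alloscan:::states_for_tree(
    alloscan:::nuc_states(aln), tr) |>
      apply(c(1, 2), function(i) c("a", "c", "g", "t")[i]),
    type = "DNA")
  fit <- phangorn::pml(tr, dat, bf = m$base_freq,
                       Q = m$rates / m$rates[6], k = 4, shape = m$alpha)
  expect_equal(ll, fit$logLik, tolerance = 1e-4)
})

test_that("GTR+G+I converges to homogeneous GTR as alpha grows", {
  tr <- tiny_tree4()
  base <- gtr_model(rates = c(1, 2, 0.7, 1.1, 2.2, 1),
                    base_freq = c(0.28, 0.22, 0.26, 0.24), alpha = 1)
  aln <- simulate_nucleotide_alignment(tr, base, 300, seed = 9)
  m_hom <- gtr_model(base$rates, base$base_freq, alpha = 1, ncat = 1,
                     p_inv = 0)
  m_lim <- gtr_model(base$rates, base$base_freq, alpha = 500, ncat = 4,
                     p_inv = 0)
  expect_equal(prune_loglik(aln, tr, m_lim),
               prune_loglik(aln, tr, m_hom), tolerance = 1e-4)
})
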