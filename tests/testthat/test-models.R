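test_that("codon rates follow the single-step x kappa x omega rule", {
  pi <- codon_frequencies(equal = TRUE)
  kappa <- 2; omega <- 0.5
  Q <- build_codon_rates(kappa, omega, pi)
  # ATG (Met) -> ATA (Ile): third-position A<->G transition, nonsynonymous
  expect_equal(Q["ATG", "ATA"], pi[["ATA"]] * kappa * omega)
  # GGA -> GGC: transversion, synonymous (both Gly)
  expect_equal(Q["GGA", "GGC"], pi[["GGC"]])
  # two positions differ -> rate 0
  expect_equal(Q["ATG", "TTA"], 0)
  # stop codons are excluded from the state space entirely
  expect_false("TAA" %in% rownames(Q))
  expect_equal(max(abs(rowSums(Q))), 0, tolerance = 1e-12)

  # kappa = omega = 1 with equal frequencies: all single-step rates equal
  Q1 <- build_codon_rates(1, 1, pi)
  off <- Q1[Q1 > 0]
  expect_equal(max(off), min(off))
})

test_that("detailed balance holds for codon and GTR generators", {
  sim <- simulate_codon_alignment(tiny_tree3(), 50, seed = 3)
  pi <- codon_frequencies(sim$alignment)
  Q <- build_codon_rates(2.4, 0.3, pi)
  flux_c <- unname(as.vector(pi) * Q)
  expect_equal(flux_c, t(flux_c), tolerance = 1e-12, ignore_attr = TRUE)
  m <- gtr_model(rates = c(1, 3, 0.5, 0.8, 2.5, 1),
                 base_freq = c(0.3, 0.25, 0.2, 0.25), alpha = 0.7)
  flux <- m$base_freq * m$Q
  expect_equal(flux, t(flux), tolerance = 1e-12)
})

test_that("transition matrices are stochastic for a range of times", {
  pi <- codon_frequencies(equal = TRUE)
  mix <- codon_mixture_scale(site_classes("M1a", 0.6, 0.2), 2, pi)
  eg <- alloscan:::eig_rev(build_codon_rates(2, 0.2, pi) / mix, pi)
  for (t in c(0, 1e-4, 0.05, 0.7, 3, 20)) {
    P <- eg$U %*% (exp(eg$lambda * t) * eg$Uinv)
    expect_equal(rowSums(P), rep(1, 61), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_true(min(P) > -1e-12)
  }
})

test_that("discrete gamma categories average to one and match phangorn", {
  for (a in c(0.3, 1, 4)) {
    r <- discrete_gamma_rates(a, 4)
    expect_equal(mean(r), 1, tolerance = 1e-12)
    expect_true(all(diff(r) > 0))
    expect_equal(r, phangorn::discrete.gamma(a, 4), tolerance = 1e-8)
  }
})

test_that("branch-site class layout reproduces the published structure", {
  m1a <- site_classes("M1a", p0 = 0.7, omega0 = 0.2)
  expect_equal(m1a$prop, c(0.7, 0.3))
  bsa1 <- site_classes("BSA1", p0 = 0.6, p1 = 0.2, omega0 = 0.1,
                       omega2 = 4)
  expect_equal(sum(bsa1$prop), 1)
  # remainder mass split proportionally p0 : p1
  expect_equal(bsa1$prop[3] / bsa1$prop[4], 0.6 / 0.2)
  expect_equal(bsa1$omega_fg[3:4], c(4, 4))
  bsa <- site_classes("BSA", p0 = 0.6, p1 = 0.2, omega0 = 0.1)
  expect_equal(bsa$omega_fg[3:4], c(1, 1))
})
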