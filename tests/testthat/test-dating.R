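test_that("clock configuration validates its invariants", {
  expect_error(clock_config(chain = 1000, burnin = 2000), "burnin")
  expect_error(clock_config(chain = 2000, burnin = 1000, thin = 300))
  cfg <- dating_preset("published")
  expect_equal(cfg$chain, 2e6)
  expect_equal(cfg$burnin, 1e6)
  expect_equal(cfg$thin, 1000)
  expect_equal(cfg$root_age, 31)
  expect_equal(cfg$root_sd, 1e-4)
})

test_that("identical seeds give identical sample streams", {
  sim <- simulate_gene_histories(1, sites = 300, seed = 3)
  g <- sim$genes[[1]]
  cfg <- dating_preset("desk", chain = 4000, burnin = 2000, thin = 10,
                       seed = 42)
  p1 <- suppressWarnings(run_dating(g$alignment, g$tree, cfg,
                                    outgroup = "Sorghum"))
  p2 <- suppressWarnings(run_dating(g$alignment, g$tree, cfg,
                                    outgroup = "Sorghum"))
  expect_identical(p1$samples, p2$samples)
})

test_that("sampled states respect age ordering and the root calibration", {
  sim <- simulate_gene_histories(1, sites = 600, seed = 6)
  g <- sim$genes[[1]]
  cfg <- dating_preset("desk", chain = 20000, burnin = 10000, thin = 20,
                       seed = 8)
  post <- suppressWarnings(run_dating(g$alignment, g$tree, cfg,
                                      outgroup = "Sorghum"))
  s <- post$samples
  tree <- g$tree
  ntip <- length(tree$tip.label)
  for (e in seq_len(nrow(tree$edge))) {
    pa <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    if (ch <= ntip) next
    expect_true(all(s[, paste0("age_", pa)] > s[, paste0("age_", ch)]))
  }
  expect_true(all(s[, paste0("age_", ntip + 1)] > 0))
  # narrow normal calibration pins the root
  root <- s[, paste0("age_", ntip + 1)]
  expect_lt(abs(stats::median(root) - 31), 0.001)
  expect_lt(abs(mean(root) - 31), 0.001)
  expect_lt(stats::sd(root), 1.2e-4 * 1.2)
  expect_gt(stats::sd(root), 0.5e-4)
})

test_that("a non-binary tree is refused and small trees are refused", {
  sim <- simulate_gene_histories(1, sites = 60, seed = 2)
  g <- sim$genes[[1]]
  multi <- ape::read.tree(
    text = "((A_cimicina:11,A_angusta:11,A_semialata_1:11):20,Sorghum:31);")
  expect_error(run_dating(g$alignment, multi, dating_preset("desk")),
               "binary")
})

test_that("age summaries use linear-interpolation quantiles and MRCAs", {
  tree <- panicoid_chronogram()
  ntip <- length(tree$tip.label)
  root_col <- paste0("age_", ntip + 1)
  fake <- fake_age_posterior(
    stats::setNames(list(rep(31, 100), rep(5, 100), 1:100, rep(2, 100)),
                    paste0("age_", (ntip + 1):(ntip + 4))), tree)
  labs <- dating_node_labels()
  recs <- summarize_ages(fake, labs, gene = "g1")
  const <- recs[recs$node == "crown_alloteropsis", ]
  expect_true(all(const[, c("median", "q025", "q975")] == 5))
  split <- recs[recs$node == "angusta_semialata_split", ]
  expect_equal(split$median, 50.5)
  expect_equal(split$q025, 3.475)   # 1 + 0.025 * 99
  expect_equal(split$q975, 97.525)

  # a label with one side unrepresented is skipped
  labs$ghost <- list("Sorghum", "NotInTree")
  expect_message(recs2 <- summarize_ages(fake, labs, gene = "g1"),
                 "skipped")
  expect_false("ghost" %in% recs2$node)
  expect_true(all(recs$q025 <= recs$q25 & recs$q25 <= recs$median &
                    recs$median <= recs$q75 & recs$q75 <= recs$q975))
})

test_that("strict and lognormal clocks agree on clock-like data", {
  sim <- simulate_gene_histories(1, sites = 1000, rate_sd_log = 0,
                                 seed = 12)
  g <- sim$genes[[1]]
  run <- function(clock) {
    cfg <- dating_preset("desk", clock = clock, chain = 30000,
                         burnin = 15000, thin = 30, seed = 5)
    post <- suppressWarnings(run_dating(g$alignment, g$tree, cfg,
                                        outgroup = "Sorghum"))
    summarize_ages(post, dating_node_labels(), gene = "g")
  }
  strict <- run("strict")
  logn <- run("lognormal")
  m <- merge(strict, logn, by = "node")
  # medians agree within Monte-Carlo error on the same data
  expect_true(all(abs(m$median.x - m$median.y) /
                    pmax(m$median.x, 1) < 0.25))
})
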