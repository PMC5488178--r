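rec_df <- function(medians, node = "split") {
  data.frame(gene = paste0("g", seq_along(medians)), node = node,
             median = medians)
}

test_that("distribution summaries use interpolated percentiles", {
  d <- compile_distribution(rec_df(seq(5, 10, length.out = 100)), "split")
  expect_equal(d$interval95, c(5.125, 9.875), tolerance = 1e-9)
  expect_equal(d$peak50, c(5 + 24.75 * 5 / 99, 5 + 74.25 * 5 / 99),
               tolerance = 1e-9)

  d7 <- compile_distribution(rec_df(rep(7, 25)), "split")
  expect_equal(d7$interval95, c(7, 7))
  expect_equal(d7$peak50, c(7, 7))

  expect_error(compile_distribution(rec_df(1:5), "split"), "at least 20")

  # nested-interval invariant on random draws
  set.seed(2)
  for (i in 1:50) {
    d <- compile_distribution(rec_df(rlnorm(40, 2, 0.4)), "split")
    expect_gte(d$peak50[1], d$interval95[1])
    expect_lte(d$peak50[2], d$interval95[2])
  }
})

test_that("outlier flags follow the rank/quantile rule", {
  set.seed(3)
  meds <- sort(rlnorm(200, log(7), 0.2))
  d <- compile_distribution(rec_df(meds), "split")

  # focal equal to the distribution median is not flagged
  r_mid <- flag_outliers(d, data.frame(gene = "f", node = "split",
                                       median = stats::median(meds)))
  expect_false(r_mid$flagged)

  # focal below every member: rank 1, flagged
  r_low <- flag_outliers(d, data.frame(gene = "f", node = "split",
                                       median = min(meds) / 2))
  expect_equal(r_low$rank, 1L)
  expect_true(r_low$flagged)

  # decreasing flag_quantile never enlarges the flagged set
  focal <- data.frame(gene = paste0("f", 1:8), node = "split",
                      median = quantile(meds, seq(0.001, 0.2,
                                                  length.out = 8)))
  f1 <- flag_outliers(d, focal, flag_quantile = 0.05)$flagged
  f2 <- flag_outliers(d, focal, flag_quantile = 0.01)$flagged
  expect_true(all(which(f2) %in% which(f1)))
})

test_that("gene ages are matched to the closest labeled node", {
  mk <- function(node, med, peak) {
    structure(list(node = node, n = 100, interval95 = peak + c(-2, 2),
                   peak50 = peak, median = med, medians = numeric(0)),
              class = "age_distribution")
  }
  sums <- list(mk("split", 7.06, c(5.93, 8.18)),
               mk("crown_semialata", 4.1, c(3.12, 5.07)))
  expect_identical(match_node(2.77, sums), "crown_semialata")
  expect_identical(match_node(7.06, sums), "split")
  # exact tie resolves to the older node
  tie <- list(mk("young", 4, c(3, 5)), mk("old", 8, c(7, 9)))
  expect_identical(match_node(6, tie), "old")
  # zero half-width falls back to absolute distance
  degen <- list(mk("a", 5, c(5, 5)), mk("b", 9, c(9, 9)))
  expect_identical(match_node(5.4, degen), "a")
})
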