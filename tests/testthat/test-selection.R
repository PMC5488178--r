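test_that("AICc and the selection rule behave at the edges", {
  expect_equal(aicc(-100, 4, 300), 200 + 8 + 2 * 4 * 5 / 295)
  expect_error(aicc(-10, 5, 6))

  # null retained when nothing beats it by the threshold
  tab <- data.frame(model = c("M1a", "BSA1"),
                    scenario = c(NA, "one_origin"),
                    aicc = c(1.0, 0.0))
  rep <- select_model(tab)
  expect_false(rep$null_rejected)
  expect_identical(rep$best_model, "M1a")

  # exactly at the threshold the null falls
  tab$aicc <- c(5.22, 0)
  expect_true(select_model(tab)$null_rejected)

  # ties resolve toward fewer parameters
  tab2 <- data.frame(model = c("M1a", "BSA", "BSA1"),
                     scenario = c(NA, "s", "s"),
                     aicc = c(10, 0.001, 0))
  rep2 <- select_model(tab2)
  expect_identical(rep2$best_model, "BSA")

  expect_error(select_model(list()), "no fits")
  expect_error(select_model(data.frame(model = "BSA", scenario = "s",
                                       aicc = 0)),
               "exactly one M1a")
})

test_that("model fits recover simulation truth and respect nesting", {
  tree <- alloscan:::study_tree_14()
  scen <- alloscan:::study_scenarios_14()$cimicina_only
  sim <- simulate_codon_alignment(tree, 2000, kappa = 2, p0 = 0.7,
                                  omega0 = 0.2, seed = 21)
  f0 <- fit_model(sim$alignment, tree, "M1a", n_starts = 1)
  expect_lt(abs(f0$mle$kappa - 2), 0.5)
  expect_lt(abs(f0$mle$p0 - 0.7), 0.1)
  expect_lt(abs(f0$mle$omega0 - 0.2), 0.1)
  f1 <- fit_model(sim$alignment, tree, "BSA", scenario = scen,
                  n_starts = 0, init = f0$mle)
  f2 <- fit_model(sim$alignment, tree, "BSA1", scenario = scen,
                  n_starts = 0, init = f1$mle)
  # nested-model log-likelihood ordering (optimizer noise tolerance)
  expect_gte(f1$lnL, f0$lnL - 1e-3)
  expect_gte(f2$lnL, f1$lnL - 1e-3)
  expect_equal(f0$k, 4); expect_equal(f1$k, 5); expect_equal(f2$k, 6)
  # on null data the alternative collapses: dAICc near 2*dk
  expect_lt(abs((f2$AICc - f0$AICc) - 4), 2.5)
})

test_that("site posteriors normalize and refuse a null best fit", {
  tree <- alloscan:::study_tree_14()
  scen <- alloscan:::study_scenarios_14()$cimicina_only
  tr_fg <- label_foreground(tree, scen)
  sim <- simulate_codon_alignment(tr_fg, 300, kappa = 2, p0 = 0.5,
                                  p1 = 0.2, omega0 = 0.15, omega2 = 6,
                                  seed = 31)
  f0 <- fit_model(sim$alignment, tree, "M1a", n_starts = 1)
  f2 <- fit_model(sim$alignment, tree, "BSA1", scenario = scen,
                  n_starts = 1, init = f0$mle)
  sp <- site_posteriors(f2, sim$alignment, tree, scen)
  expect_equal(nrow(sp), 300)
  expect_true(all(sp$p_selected >= 0 & sp$p_selected <= 1))
  # sites truly in the foreground-selection classes get high posteriors
  sel_sites <- sim$truth$site[sim$truth$class %in% c(3, 4)]
  expect_gt(mean(sp$p_selected[sel_sites]),
            mean(sp$p_selected[-sel_sites]))
  expect_error(site_posteriors(f0, sim$alignment, tree, scen), "BSA1")

  # full per-site class posteriors sum to one
  st <- alloscan:::states_for_tree(
    alloscan:::codon_index_matrix(sim$alignment), tr_fg)
  res <- alloscan:::codon_loglik_engine(
    st, tr_fg, codon_model(f2$mle$kappa, f2$pi,
                           alloscan:::params_to_classes(f2$mle, "BSA1")),
    scale = f2$mle$scale, site_values = TRUE)
  expect_equal(rowSums(res$class_posterior),
               rep(1, nrow(res$class_posterior)), tolerance = 1e-9)
})

test_that("bootstrap robustness is deterministic and bounded", {
  tree <- alloscan:::study_tree_14()
  scen <- alloscan:::study_scenarios_14()$cimicina_only
  tr_fg <- label_foreground(tree, scen)
  sim <- simulate_codon_alignment(tr_fg, 200, kappa = 2, p0 = 0.5,
                                  p1 = 0.2, omega0 = 0.15, omega2 = 8,
                                  seed = 41)
  r1 <- bootstrap_robustness(sim$alignment, tree, list(scen),
                             outgroup = "P_pygmaeum", n_reps = 1,
                             seed = 7)
  expect_true(r1$same_model_fraction %in% c(0, 1))
  r2 <- bootstrap_robustness(sim$alignment, tree, list(scen),
                             outgroup = "P_pygmaeum", n_reps = 1,
                             seed = 7)
  expect_identical(r1$support, r2$support)
})
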