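# High-level experiment drivers shared by the analysis scripts, the test
# suite and the acceptance script.  Each runs one validation study on
# synthetic data (or on the bundled worked-example tables) and returns its
# headline quantities.

#' Replay model selection on the bundled decision tables
#'
#' Feeds each worked-example dAICc table to [select_model()] and compares
#' the outcome with the asterisked best model.
#'
#' @param threshold null-rejection margin (default 5.22).
#' @return data.frame: gene, expected, selected, null_rejected, match.
#' @export
reproduce_worked_examples <- function(threshold = 5.22) {
  wt <- worked_example_tables()
  rows <- lapply(names(wt$rows), function(g) {
    rep <- select_model(wt$rows[[g]], threshold = threshold)
    exp <- wt$expected[[g]]
    expected <- fit_label(exp$model, exp$scenario)
    selected <- fit_label(rep$best_model, rep$best_scenario)
    data.frame(gene = g, expected = expected, selected = selected,
               null_rejected = rep$null_rejected,
               match = expected == selected)
  })
  do.call(rbind, rows)
}

# 14-taxon working tree used by the simulation studies (one C4 semialata
# accession dropped from the 15-taxon preset)
study_tree_14 <- function() {
  ape::drop.tip(alloteropsis_codon_tree(), "A_semialata_C4_6")
}

study_scenarios_14 <- function() {
  sc <- alloteropsis_scenarios()
  fix <- function(s) {
    s$clades <- lapply(s$clades, setdiff, y = "A_semialata_C4_6")
    s
  }
  lapply(sc, fix)
}

#' Type-I error of the null-rejection rule on nearly-neutral data
#'
#' Simulates datasets under the M1a regime (no positive selection) on the
#' 14-taxon working tree, runs the M1a / BSA / BSA1 fits under the
#' single-lineage scenario and counts how often the null is rejected at
#' the dAICc threshold.
#'
#' @param n_sims number of simulated datasets.
#' @param n_codons codon sites per dataset.
#' @param seed base RNG seed (dataset i uses seed + i).
#' @param threshold null-rejection margin.
#' @param kappa,p0,omega0 simulation truth.
#' @return list: rejection_rate, n_sims, per-dataset detail table.
#' @export
typeI_error_experiment <- function(n_sims = 100, n_codons = 300, seed = 1,
                                   threshold = 5.22, kappa = 2, p0 = 0.7,
                                   omega0 = 0.2) {
  tree <- study_tree_14()
  scen <- study_scenarios_14()$cimicina_only
  rejected <- logical(n_sims)
  deltas <- numeric(n_sims)
  for (i in seq_len(n_sims)) {
    sim <- simulate_codon_alignment(tree, n_codons, kappa = kappa, p0 = p0,
                                    omega0 = omega0, seed = seed + i)
    f0 <- fit_model(sim$alignment, tree, "M1a", n_starts = 1)
    f1 <- fit_model(sim$alignment, tree, "BSA", scenario = scen,
                    n_starts = 0, init = f0$mle)
    f2 <- fit_model(sim$alignment, tree, "BSA1", scenario = scen,
                    n_starts = 1, init = f1$mle)
    fits <- list(f0, f1, f2)
    rep <- select_model(fits, threshold = threshold)
    rejected[i] <- rep$null_rejected
    deltas[i] <- rep$table$delta[rep$table$model == "M1a"]
  }
  list(rejection_rate = mean(rejected), n_sims = n_sims,
       detail = data.frame(sim = seq_len(n_sims), rejected = rejected,
                           null_delta = deltas))
}

#' Recovery of the true origin scenario under positive selection
#'
#' Simulates branch-site positive selection (foreground omega2) on one
#' lineage of the 14-taxon working tree, rotating the true lineage across
#' replicates, fits M1a plus BSA1 under each single-lineage candidate
#' scenario, and scores a replicate as correct when the null is rejected
#' and the best scenario matches the simulated one.
#'
#' @param n_sims replicates.
#' @param n_codons codon sites.
#' @param omega2 foreground selection strength.
#' @param p0,p1 class proportions (remainder mass 1 - p0 - p1).
#' @param seed base RNG seed.
#' @param threshold null-rejection margin.
#' @return list: recovery_rate, n_sims, detail table.
#' @export
scenario_recovery_experiment <- function(n_sims = 50, n_codons = 500,
                                         omega2 = 4, p0 = 0.6, p1 = 0.25,
                                         seed = 1, threshold = 5.22) {
  tree <- study_tree_14()
  cand <- study_scenarios_14()[c("cimicina_only", "angusta_only",
                                 "semialata_only")]
  correct <- logical(n_sims)
  picked <- character(n_sims)
  truth <- character(n_sims)
  for (i in seq_len(n_sims)) {
    truth[i] <- names(cand)[((i - 1) %% length(cand)) + 1]
    tr_fg <- label_foreground(tree, cand[[truth[i]]])
    sim <- simulate_codon_alignment(tr_fg, n_codons, kappa = 2, p0 = p0,
                                    p1 = p1, omega0 = 0.2, omega2 = omega2,
                                    seed = seed + i)
    f0 <- fit_model(sim$alignment, tree, "M1a", n_starts = 1)
    fits <- c(list(f0),
              lapply(cand, function(sc)
                fit_model(sim$alignment, tree, "BSA1", scenario = sc,
                          n_starts = 0, init = f0$mle)))
    rep <- select_model(fits, threshold = threshold)
    picked[i] <- if (rep$null_rejected) rep$best_scenario else "none"
    correct[i] <- rep$null_rejected && identical(rep$best_scenario, truth[i])
  }
  list(recovery_rate = mean(correct), n_sims = n_sims,
       detail = data.frame(sim = seq_len(n_sims), truth = truth,
                           picked = picked, correct = correct))
}

#' Calibration and coverage of the dating sampler
#'
#' Simulates genes on the preset chronogram (strict rates up to lognormal
#' gene multipliers), dates each gene, and reports (a) the root-age
#' posterior medians, which the narrow normal(root, 0.0001) calibration
#' must pin to the calibration age, and (b) the fraction of genes whose
#' 95% credible interval covers the true 7 Ma angusta/semialata split.
#'
#' @param n_genes genes to simulate and date.
#' @param sites alignment length per gene.
#' @param rate substitution rate (subs/site/Ma).
#' @param rate_sd_log per-gene rate multiplier SD.
#' @param chain,burnin,thin chain settings for the per-gene runs.
#' @param seed base RNG seed.
#' @return list: root_medians, coverage, min_ess, records.
#' @export
dating_calibration_experiment <- function(n_genes = 20, sites = 1500,
                                          rate = 0.005, rate_sd_log = 0.1,
                                          chain = 48e4, burnin = 16e4,
                                          thin = 160, seed = 1) {
  sim <- simulate_gene_histories(n_genes, rate = rate,
                                 rate_sd_log = rate_sd_log, sites = sites,
                                 seed = seed)
  labels <- dating_node_labels()
  records <- list()
  root_medians <- numeric(n_genes)
  min_ess <- Inf
  for (i in seq_len(n_genes)) {
    g <- sim$genes[[i]]
    cfg <- dating_preset("desk", chain = chain, burnin = burnin,
                         thin = thin, seed = seed + i)
    post <- run_dating(g$alignment, g$tree, cfg, outgroup = "Sorghum")
    root_col <- paste0("age_", length(g$tree$tip.label) + 1L)
    root_medians[i] <- stats::median(post$samples[, root_col])
    min_ess <- min(min_ess, post$ess[grep("^age_", names(post$ess))])
    records[[i]] <- summarize_ages(post, labels, gene = g$id)
  }
  records <- do.call(rbind, records)
  split <- records[records$node == "angusta_semialata_split", ]
  coverage <- mean(split$q025 <= 7 & 7 <= split$q975)
  list(root_medians = root_medians, coverage = coverage,
       min_ess = min_ess, records = records)
}

#' Genome-wide introgression scan on a synthetic gene panel
#'
#' Simulates a panel of genes on the preset chronogram, the first
#' `n_introgressed` of which are designated focal candidates (mirroring
#' the a-priori C4 genes of the study design) and carry a younger
#' angusta/semialata split.  Every gene is dated with a short per-gene
#' chain; the genome-wide distribution is compiled from the background
#' (non-candidate) markers, candidates are flagged against it, and the
#' background genes are scanned against their own distribution to count
#' false flags.
#'
#' @param n_genes panel size (candidates + background markers).
#' @param n_introgressed introgressed candidate genes (ids
#'   1..n_introgressed).
#' @param intro_age replacement age (Ma).
#' @param sites sites per gene.
#' @param rate_sd_log per-gene lognormal rate SD.
#' @param flag_quantile scan threshold.
#' @param chain,burnin,thin per-gene chain settings.
#' @param seed base RNG seed.
#' @return list: recall, n_false, candidate_report, background_report,
#'   distribution, records.
#' @export
introgression_panel_experiment <- function(n_genes = 300,
                                           n_introgressed = 3,
                                           intro_age = 2.8, sites = 600,
                                           rate_sd_log = 0.12,
                                           flag_quantile = 0.005,
                                           chain = 20000, burnin = 10000,
                                           thin = 20, seed = 1) {
  events <- if (n_introgressed > 0)
    data.frame(gene = seq_len(n_introgressed),
               node = "angusta_semialata_split", age = intro_age)
  else NULL
  sim <- simulate_gene_histories(n_genes, rate_sd_log = rate_sd_log,
                                 sites = sites, events = events, seed = seed)
  labels <- dating_node_labels()
  records <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    g <- sim$genes[[i]]
    cfg <- dating_preset("desk", chain = chain, burnin = burnin,
                         thin = thin, seed = seed + i)
    post <- suppressWarnings(run_dating(g$alignment, g$tree, cfg,
                                        outgroup = "Sorghum"))
    records[[i]] <- summarize_ages(post, labels, gene = g$id)
  }
  records <- do.call(rbind, records)
  node <- "angusta_semialata_split"
  candidates <- sprintf("gene%04d", seq_len(n_introgressed))
  bg <- records[records$node == node &
                  !(records$gene %in% candidates), , drop = FALSE]
  dist <- compile_distribution(bg, node)
  cand_report <- if (n_introgressed > 0)
    flag_outliers(dist,
                  records[records$node == node &
                            records$gene %in% candidates, , drop = FALSE],
                  flag_quantile = flag_quantile)
  else NULL
  bg_report <- flag_outliers(dist, bg, flag_quantile = flag_quantile)
  recall <- if (n_introgressed > 0) mean(cand_report$flagged) else NA
  list(recall = recall, n_false = sum(bg_report$flagged),
       candidate_report = cand_report, background_report = bg_report,
       distribution = dist, records = records)
}

#' Replay the two headline outlier decisions on printed facts
#'
#' Rebuilds synthetic stand-in distributions constrained by the printed
#' genome-wide summaries and checks the rank/quantile rule on the two
#' focal genes: the pck split estimate (2.77 Ma, four smaller values among
#' 2,797) and the laterally acquired ppc copy (3.25 Ma, smaller than all).
#'
#' @param flag_quantile scan threshold.
#' @return data.frame: gene, median, rank, quantile, flagged.
#' @export
outlier_worked_examples <- function(flag_quantile = 0.005) {
  f <- worked_example_dating_facts()
  pck_dist <- synthetic_median_distribution(
    f$n_genes, f$split_peak50, f$pck_split_median, f$pck_n_smaller)
  ppc_dist <- synthetic_median_distribution(
    f$n_genes, f$crown_allo_peak50, f$ppc_crown_median, f$ppc_n_smaller)
  rec <- function(node, medians) {
    data.frame(gene = paste0("marker", seq_along(medians)), node = node,
               median = medians)
  }
  pck <- flag_outliers(
    compile_distribution(rec("split", pck_dist), "split"),
    data.frame(gene = "pck-1P1_LGT-C", node = "split",
               median = f$pck_split_median),
    flag_quantile = flag_quantile)
  ppc <- flag_outliers(
    compile_distribution(rec("crown", ppc_dist), "crown"),
    data.frame(gene = "ppc-1P3_LGT-M", node = "crown",
               median = f$ppc_crown_median),
    flag_quantile = flag_quantile)
  out <- rbind(as.data.frame(pck), as.data.frame(ppc))
  out[, c("gene", "median", "rank", "quantile", "flagged")]
}

#' End-to-end annotation recovery on the default synthetic transcriptome
#'
#' Generates the default reference package and `n_samples` independent
#' transcriptome samples from it, annotates every contig by search +
#' placement, and reports assignment accuracy over all contigs and rpm
#' conservation per sample.
#'
#' @param seed RNG seed.
#' @param n_samples pooled transcriptome samples.
#' @return list: accuracy, rpm_total (per-sample mean), rpm_by_sample,
#'   abundance, placements, truth.
#' @export
annotation_recovery_experiment <- function(seed = 1, n_samples = 4) {
  ref <- default_reference_package(seed = seed)
  contigs <- character(0)
  counts <- list(); truth <- list(); totals <- numeric(0)
  for (s in seq_len(n_samples)) {
    sid <- paste0("S", s)
    tx <- simulate_transcriptome(ref, sample_id = sid, seed = seed + s)
    rename <- stats::setNames(paste0(sid, "_", names(tx$contigs)),
                              names(tx$contigs))
    names(tx$contigs) <- rename[names(tx$contigs)]
    tx$counts$contig_id <- rename[tx$counts$contig_id]
    tx$truth$contig_id <- rename[tx$truth$contig_id]
    contigs <- c(contigs, tx$contigs)
    counts[[s]] <- tx$counts
    truth[[s]] <- tx$truth
    totals[sid] <- tx$total_reads
  }
  counts <- do.call(rbind, counts)
  truth <- do.call(rbind, truth)
  pl <- annotate_contigs(contigs, ref)
  truth_lin <- truth$lineage[match(pl$contig_id, truth$contig_id)]
  accuracy <- mean(pl$lineage == truth_lin)
  lens <- stats::setNames(nchar(contigs), names(contigs))
  ab <- quantify(pl, counts, lens, total_reads = totals)
  rpm_by_sample <- tapply(ab$rpm, ab$sample_id, sum)
  list(accuracy = accuracy, rpm_total = mean(rpm_by_sample),
       rpm_by_sample = rpm_by_sample, abundance = ab,
       placements = pl, truth = truth)
}
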