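# Pipeline orchestration: a single configuration object whose "published"
# preset pins every published constant (e-value 0.01, 50 bp match, 500 bp
# harvest, dAICc 5.22, 100 bootstraps, root 31 Ma / SD 0.0001, chain
# 2,000,000 / 1,000,000 / 1,000, site-posterior flags 0.90/0.95, scan
# quantile 0.005), plain-text round-trip via YAML, and stage reports as
# TSV/JSON.

#' Pipeline configuration with published-constant defaults
#'
#' @param preset "published" (the study constants, default) or "desk"
#'   (shortened dating chain for routine use).
#' @param ... named overrides of individual fields (e.g. `threshold`,
#'   `flag_quantile`, `chain`).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(preset = c("published", "desk"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    # annotation
    e_max = 0.01, min_match_len = 50, min_aln_len = 500,
    # selection
    threshold = 5.22, bootstrap = 100, posterior_flags = c(0.90, 0.95),
    # dating
    root_age = 31, root_sd = 0.0001,
    chain = 2e6, burnin = 1e6, thin = 1000, clock = "lognormal",
    # scan
    flag_quantile = 0.005,
    seed = 1)
  if (preset == "desk") {
    cfg$chain <- 2e5; cfg$burnin <- 1e5; cfg$thin <- 100
  }
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0)
    stop("unknown configuration fields: ", paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config preset=", x$preset, ">\n", sep = "")
  for (nm in setdiff(names(x), "preset"))
    cat(sprintf("  %-16s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  invisible(x)
}

#' Write / read a pipeline configuration (YAML round-trip)
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, c(list(preset = cfg$preset),
                             cfg[setdiff(names(cfg), "preset")]))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Run the four-stage pipeline on a set of inputs
#'
#' Stages run in order annotate -> selectscan -> date -> introgression;
#' each is skipped when its inputs are absent from `inputs`.  Stage
#' reports are written under `out_dir` together with a manifest (config,
#' seed, package version) so identical reruns reproduce identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param inputs list with any of: `contigs` + `ref_pkg` + `counts`
#'   (annotation stage; counts needs contig_id/sample_id/reads),
#'   `codon_alignment` + `tree` + `scenarios` (selection stage),
#'   `genes` + `node_labels` + `outgroup` (dating stage: per-gene
#'   list(id, alignment, tree)), `age_records` or the dating output
#'   (introgression stage: `scan_node` names the node to scan).
#' @param out_dir output directory (created).
#' @return list of stage reports (also serialized under `out_dir`).
#' @export
run_pipeline <- function(config, inputs, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  reports <- list()

  manifest <- list(package = "alloscan",
                   version = as.character(utils::packageVersion("alloscan")),
                   config = unclass(config),
                   timestamp = "fixed-for-reproducibility")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  if (!is.null(inputs$contigs)) {
    if (is.null(inputs$ref_pkg)) stop("annotate stage: ref_pkg missing")
    if (is.null(inputs$counts))
      stop("annotate stage: read-count table missing")
    pl <- annotate_contigs(inputs$contigs, inputs$ref_pkg,
                           e_max = config$e_max,
                           min_match_len = config$min_match_len)
    lens <- stats::setNames(nchar(inputs$contigs), names(inputs$contigs))
    ab <- quantify(pl, inputs$counts, lens,
                   total_reads = inputs$total_reads)
    write_tsv(pl, file.path(out_dir, "placements.tsv"))
    write_tsv(ab, file.path(out_dir, "abundance.tsv"))
    reports$annotate <- list(placements = pl, abundance = ab)
  }

  if (!is.null(inputs$codon_alignment)) {
    aln <- inputs$codon_alignment
    tree <- inputs$tree
    fits <- list(fit_model(aln, tree, "M1a"))
    for (sc in inputs$scenarios)
      fits <- c(fits, list(fit_model(aln, tree, "BSA", scenario = sc),
                           fit_model(aln, tree, "BSA1", scenario = sc)))
    sel <- select_model(fits, threshold = config$threshold)
    fit_tab <- do.call(rbind, lapply(fits, function(f)
      data.frame(model = f$model, scenario = f$scenario, lnL = f$lnL,
                 k = f$k, n = f$n, AICc = f$AICc,
                 kappa = f$mle$kappa, p0 = f$mle$p0, p1 = f$mle$p1,
                 omega0 = f$mle$omega0, omega2 = f$mle$omega2)))
    write_tsv(fit_tab, file.path(out_dir, "selection_fits.tsv"))
    jsonlite::write_json(
      list(best_model = sel$best_model, best_scenario = sel$best_scenario,
           null_rejected = sel$null_rejected, threshold = sel$threshold,
           table = sel$table),
      file.path(out_dir, "selection_report.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
    reports$selectscan <- sel
    if (sel$best_model == "BSA1") {
      best_fit <- fits[[which(vapply(fits, function(f)
        f$model == "BSA1" && identical(f$scenario, sel$best_scenario),
        TRUE))[1]]]
      if (!best_fit$collapsed) {
        sc <- inputs$scenarios[[
          which(vapply(inputs$scenarios, function(s)
            s$name == sel$best_scenario, TRUE))[1]]]
        sp <- site_posteriors(best_fit, aln, tree, sc)
        write_tsv(sp, file.path(out_dir, "site_posteriors.tsv"))
        reports$site_posteriors <- sp
      }
    }
  }

  if (!is.null(inputs$genes)) {
    cfg <- clock_config(clock = config$clock, root_age = config$root_age,
                        root_sd = config$root_sd, chain = config$chain,
                        burnin = config$burnin, thin = config$thin,
                        seed = config$seed)
    recs <- list()
    for (g in inputs$genes) {
      gc <- cfg; gc$seed <- gc$seed + length(recs)
      post <- run_dating(g$alignment, g$tree, gc,
                         outgroup = inputs$outgroup)
      recs[[g$id]] <- summarize_ages(post, inputs$node_labels, gene = g$id)
    }
    age_records <- do.call(rbind, recs)
    rownames(age_records) <- NULL
    write_tsv(age_records, file.path(out_dir, "gene_ages.tsv"))
    reports$date <- age_records
    if (is.null(inputs$age_records)) inputs$age_records <- age_records
  }

  if (!is.null(inputs$age_records) && !is.null(inputs$scan_node)) {
    scan <- scan_introgression(inputs$age_records, inputs$scan_node,
                               flag_quantile = config$flag_quantile)
    write_tsv(as.data.frame(scan$report),
              file.path(out_dir, "introgression_scan.tsv"))
    jsonlite::write_json(
      list(node = scan$distribution$node, n = scan$distribution$n,
           interval95 = scan$distribution$interval95,
           peak50 = scan$distribution$peak50),
      file.path(out_dir, "age_distribution.json"),
      auto_unbox = TRUE, digits = NA)
    reports$introgression <- scan
  }

  reports
}
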