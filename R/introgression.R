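# Stage (iv), part 2: genome-wide distribution of per-gene node-age
# medians, its 95% and "peak" (50%) intervals, and young-outlier flagging
# by a rank/quantile rule (the published decisions' descriptive "smaller than all but
# four of the 2,797 estimates" logic made operational).

#' Summarize the genome-wide distribution of age medians for one node
#'
#' @param records data.frame of per-gene age records (see
#'   [summarize_ages()]) with columns `node` and `median`.
#' @param node node label to summarize.
#' @param min_genes minimum number of genes required (default 20).
#' @return object of class `age_distribution`: n, interval95
#'   (2.5-97.5 percentiles), peak50 (25-75 percentiles), median of
#'   medians, and the sorted medians.
#' @export
compile_distribution <- function(records, node, min_genes = 20) {
  med <- records$median[records$node == node]
  if (length(med) < min_genes)
    stop("need at least ", min_genes, " gene records for node '", node,
         "'; got ", length(med))
  q <- stats::quantile(med, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE)
  structure(list(node = node, n = length(med),
                 interval95 = c(q[1], q[5]), peak50 = c(q[2], q[4]),
                 median = q[3], medians = sort(med)),
            class = "age_distribution")
}

#' @export
print.age_distribution <- function(x, ...) {
  cat(sprintf(
    "<age_distribution> %s: n=%d, 95%% of medians in [%.2f, %.2f] Ma, peak [%.2f, %.2f] Ma\n",
    x$node, x$n, x$interval95[1], x$interval95[2], x$peak50[1], x$peak50[2]))
  invisible(x)
}

#' Flag young-age outlier genes against a genome-wide distribution
#'
#' A focal gene's rank is `1 + #{medians smaller than it}` among the
#' distribution's genes; its empirical quantile is `rank / (n + 1)` when it
#' is not itself a member of the distribution (noted in the output), else
#' `rank / n`.  The gene is flagged iff the quantile is at or below
#' `flag_quantile` (one-sided, young).  Rank and quantile are always
#' reported so statements like "smaller than all but four of the 2,797
#' estimates" are recomputable.
#'
#' @param summary an [compile_distribution()] result.
#' @param focal data.frame of focal gene records (gene, node, median).
#' @param flag_quantile flagging threshold (default 0.005).
#' @return object of class `scan_report` (data.frame: gene, node, median,
#'   rank, quantile, flagged, in_distribution).
#' @export
flag_outliers <- function(summary, focal, flag_quantile = 0.005) {
  stopifnot(inherits(summary, "age_distribution"))
  focal <- focal[focal$node == summary$node, , drop = FALSE]
  if (nrow(focal) == 0)
    stop("no focal records for node '", summary$node, "'")
  rows <- lapply(seq_len(nrow(focal)), function(i) {
    m <- focal$median[i]
    in_dist <- any(abs(summary$medians - m) < 1e-12)
    rank <- 1L + sum(summary$medians < m)
    quant <- rank / (summary$n + as.integer(!in_dist))
    data.frame(gene = focal$gene[i], node = summary$node, median = m,
               rank = rank, quantile = quant,
               flagged = quant <= flag_quantile, in_distribution = in_dist)
  })
  out <- do.call(rbind, rows)
  attr(out, "flag_quantile") <- flag_quantile
  class(out) <- c("scan_report", "data.frame")
  out
}

#' Match a gene's age to the labeled node it most resembles
#'
#' Returns the label minimizing the standardized distance between the
#' gene's median and each node's median-of-medians, scaled by that node's
#' 25-75 half-width (absolute distance when the half-width is zero); ties
#' resolve toward the older node.
#'
#' @param focal_median the gene's age median (Ma).
#' @param summaries list of [compile_distribution()] results (>= 2).
#' @return the best-matching node label (character scalar).
#' @export
match_node <- function(focal_median, summaries) {
  stopifnot(length(summaries) >= 2)
  d <- vapply(summaries, function(s) {
    hw <- (s$peak50[2] - s$peak50[1]) / 2
    if (hw <= 0) abs(focal_median - s$median)
    else abs(focal_median - s$median) / hw
  }, 0)
  meds <- vapply(summaries, `[[`, 0, "median")
  labs <- vapply(summaries, `[[`, "", "node")
  cand <- which(d < min(d) + 1e-12)
  labs[cand[order(-meds[cand])][1]]
}

#' Scan per-gene age records for introgression candidates
#'
#' Compiles the distribution for each node label present, flags focal
#' genes (or every gene, leave `focal_genes = NULL`) by the rank/quantile
#' rule, and annotates each flagged gene with its best-matching node.
#'
#' @param records per-gene age records (gene, node, median, ...).
#' @param node node label to scan.
#' @param focal_genes gene ids to test (default: all genes at the node).
#' @param flag_quantile flagging threshold.
#' @param min_genes minimum distribution size.
#' @return list: `distribution`, `report` (with `best_match` column when
#'   two or more node labels are available).
#' @export
scan_introgression <- function(records, node, focal_genes = NULL,
                               flag_quantile = 0.005, min_genes = 20) {
  dist <- compile_distribution(records, node, min_genes = min_genes)
  focal <- records[records$node == node, , drop = FALSE]
  if (!is.null(focal_genes))
    focal <- focal[focal$gene %in% focal_genes, , drop = FALSE]
  report <- flag_outliers(dist, focal, flag_quantile = flag_quantile)
  labs <- unique(records$node)
  if (length(labs) >= 2) {
    sums <- lapply(labs, function(l)
      tryCatch(compile_distribution(records, l, min_genes = min_genes),
               error = function(e) NULL))
    sums <- Filter(Negate(is.null), sums)
    if (length(sums) >= 2)
      report$best_match <- vapply(report$median, match_node,
                                  summaries = sums, "")
  }
  list(distribution = dist, report = report)
}
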