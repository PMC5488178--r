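# Phylogenetic placement of trimmed contigs on a fixed reference topology.
# The query is inserted into the reference alignment frame by pairwise
# alignment against its closest reference row, then attached in turn to the
# midpoint of every branch of the reference tree with an optimized pendant
# length, scored under GTR+G; the maximum-likelihood attachment wins and
# the assigned lineage is the smallest labeled clade containing that edge.

single_tip_tree <- function(label, pendant) {
  structure(list(edge = matrix(c(2L, 1L), 1, 2), tip.label = label,
                 edge.length = pendant, Nnode = 1L), class = "phylo")
}

# lineage label -> edge-index set (stem + descendants), on the family tree
lineage_edge_sets <- function(tree, labels) {
  lin <- unique(unname(labels))
  sets <- lapply(lin, function(l) {
    tips <- names(labels)[labels == l]
    clade_edge_set(tree, tips, check_monophyletic = TRUE)
  })
  stats::setNames(sets, lin)
}

#' Place a trimmed contig on a family reference tree
#'
#' @param query trimmed contig sequence (reference orientation).
#' @param family one family of a reference lineage package:
#'   list(alignment, tree, labels) with `labels` a named vector mapping
#'   reference tips to lineage labels.
#' @param min_match_len refuse queries shorter than this (bp).
#' @param model a [gtr_model()] for scoring; default uses the reference
#'   alignment's empirical base frequencies with alpha = 1.
#' @param min_coverage minimum fraction of the query aligned into the
#'   reference frame; below it the placement is refused ("unassigned").
#' @return list of class `placement`: contig lineage assignment, attachment
#'   edge, placement lnL, pendant length, ambiguity flag, reason.
#' @export
place_contig <- function(query, family, min_match_len = 50, model = NULL,
                         min_coverage = 0.5) {
  stopifnot(nchar(query) >= min_match_len)
  ref_aln <- family$alignment
  tree <- family$tree
  validate_rooted_tree(tree)
  if (is.null(tree$edge.length)) stop("family tree must have branch lengths")

  # choose the closest reference row to anchor the profile insertion
  smat <- sub_matrix()
  refs <- vapply(aln_strings(ref_aln), function(s) gsub("-", "", s), "")
  sc <- vapply(refs, function(r)
    Biostrings::score(Biostrings::pairwiseAlignment(
      query, r, type = "local", substitutionMatrix = smat,
      gapOpening = 4, gapExtension = 1)), 0)
  anchor <- names(refs)[which.max(sc)]

  # project the query into the (ungapped-anchor) coordinate frame, then
  # spread into full alignment columns of the anchor row
  proj <- project_onto_reference(query, refs[[anchor]], smat)
  anchor_row <- ref_aln$mat[anchor, ]
  row <- rep("-", length(anchor_row))
  row[anchor_row != "-"] <- strsplit(proj, "")[[1]]
  coverage <- sum(row %in% NUC) / nchar(query)
  if (coverage < min_coverage) {
    return(structure(list(lineage = "unassigned", edge = NA_integer_,
                          loglik = NA_real_, pendant = NA_real_,
                          ambiguous = FALSE,
                          reason = sprintf("coverage %.2f < %.2f",
                                           coverage, min_coverage)),
                     class = "placement"))
  }

  if (is.null(model)) {
    bf <- table(factor(ref_aln$mat[ref_aln$mat %in% NUC], levels = NUC))
    model <- gtr_model(base_freq = as.vector(bf / sum(bf)), alpha = 1)
  }

  # restrict to columns where the query is informative: other columns
  # contribute identically for every attachment edge
  keep <- which(row %in% NUC)
  qrow <- paste(row[keep], collapse = "")
  sub_aln <- aln_subset(ref_aln, cols = keep)
  aln_q <- seq_alignment(c(sub_aln$ids, "..query.."),
                         c(aln_strings(sub_aln), qrow))

  nedge <- nrow(tree$edge)
  best <- list(edge = NA_integer_, loglik = -Inf, pendant = NA_real_)
  edge_ll <- numeric(nedge)
  for (e in seq_len(nedge)) {
    len <- tree$edge.length[e]
    base <- ape::bind.tree(tree, single_tip_tree("..query..", 0.05),
                           where = tree$edge[e, 2], position = len / 2)
    f <- function(pend) {
      tr <- base
      qe <- which(tr$edge[, 2] == which(tr$tip.label == "..query.."))
      tr$edge.length[qe] <- pend
      -prune_loglik(aln_q, tr, model)
    }
    opt <- stats::optimize(f, c(1e-8, 2), tol = 1e-3)
    edge_ll[e] <- -opt$objective
    if (edge_ll[e] > best$loglik) {
      best <- list(edge = e, loglik = edge_ll[e], pendant = opt$minimum)
    }
  }
  # deterministic tie-break: lowest edge index within 0.01 lnL, flagged
  near <- which(edge_ll > best$loglik - 0.01)
  amb <- length(near) > 1
  best$edge <- min(near)
  best$loglik <- edge_ll[best$edge]

  sets <- lineage_edge_sets(tree, family$labels)
  containing <- names(sets)[vapply(sets, function(s) best$edge %in% s, TRUE)]
  lineage <- if (length(containing) == 0) "unassigned" else {
    sizes <- vapply(sets[containing], length, 0L)
    containing[order(sizes, containing)][1]
  }
  structure(list(lineage = lineage, edge = best$edge,
                 loglik = best$loglik, pendant = best$pendant,
                 ambiguous = amb, reason = NA_character_),
            class = "placement")
}

#' @export
print.placement <- function(x, ...) {
  cat(sprintf("<placement> lineage=%s edge=%s lnL=%.2f%s\n", x$lineage,
              x$edge, if (is.na(x$loglik)) NA else x$loglik,
              if (isTRUE(x$ambiguous)) " (ambiguous)" else ""))
  invisible(x)
}

#' Annotate a contig set against a reference lineage package
#'
#' Runs [similarity_search()], [trim_to_match()] and [place_contig()] per
#' contig and returns the placement table used by [quantify()].
#'
#' @param contigs named character vector.
#' @param ref_pkg list of families (alignment, tree, labels).
#' @param e_max,min_match_len search thresholds.
#' @return data.frame: contig_id, family, lineage, edge, loglik, ambiguous,
#'   matched_len.
#' @export
annotate_contigs <- function(contigs, ref_pkg, e_max = 0.01,
                             min_match_len = 50) {
  references <- lapply(ref_pkg, function(f)
    vapply(aln_strings(f$alignment), function(s) gsub("-", "", s), ""))
  hits <- similarity_search(contigs, references, e_max = e_max,
                            min_match_len = min_match_len)
  rows <- lapply(names(contigs), function(cid) {
    h <- hits[hits$contig_id == cid, , drop = FALSE]
    if (nrow(h) == 0)
      return(data.frame(contig_id = cid, family = NA_character_,
                        lineage = "unassigned", edge = NA_integer_,
                        loglik = NA_real_, ambiguous = FALSE,
                        matched_len = NA_integer_))
    trimmed <- trim_to_match(contigs[[cid]], h[1, ])
    pl <- place_contig(trimmed, ref_pkg[[h$family[1]]],
                       min_match_len = min_match_len)
    data.frame(contig_id = cid, family = h$family[1], lineage = pl$lineage,
               edge = pl$edge, loglik = pl$loglik,
               ambiguous = pl$ambiguous, matched_len = nchar(trimmed))
  })
  do.call(rbind, rows)
}
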