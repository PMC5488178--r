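# Stage (ii): assign transcriptome contigs to labeled gene lineages.
# Similarity search is a seeded local alignment (exact k-mer seeds gating a
# Smith-Waterman extension) with a Karlin-Altschul-style e-value; the
# published thresholds (e <= 0.01, match >= 50 bp) are what is enforced,
# not any specific search engine's statistics.

KA_K <- 0.35  # Karlin-Altschul prefactor, ungapped approximation

ka_lambda <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      # solve sum_ij p_i p_j exp(lambda * s_ij) = 1 for +1/-2 scoring
      f <- function(l) 0.25 * exp(l) + 0.75 * exp(-2 * l) - 1
      cache <<- stats::uniroot(f, c(1e-6, 3))$root
    }
    cache
  }
})

sub_matrix <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                           baseOnly = FALSE)
}

kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, seq_len(n - k + 1), k:n))
}

#' Seeded similarity search of contigs against reference CDS sets
#'
#' Exact k-mer seeds (both strands) gate a gapped local alignment (match
#' +1, mismatch -2, affine gaps); hit significance uses a
#' Karlin-Altschul-style e-value `K m n exp(-lambda S)` with `n` the total
#' reference length of the family.  Hits with e-value above `e_max` or a
#' matched contig interval shorter than `min_match_len` are discarded; the
#' best family per contig is retained (ties broken by score, then family
#' name).
#'
#' @param contigs named character vector of contig sequences (unaligned).
#' @param references list: family id -> named character vector of CDS.
#' @param e_max maximum e-value (default 0.01).
#' @param min_match_len minimum matched length on the contig, bp
#'   (default 50).
#' @param k seed length.
#' @return data.frame of hits: contig_id, family, ref_id, start, end
#'   (0-based half-open on the forward contig), strand, score, evalue.
#' @export
similarity_search <- function(contigs, references, e_max = 0.01,
                              min_match_len = 50, k = 12) {
  if (length(references) == 0) stop("empty reference set")
  stopifnot(length(contigs) > 0, !is.null(names(contigs)))
  lambda <- ka_lambda()
  smat <- sub_matrix()
  fam_kmers <- lapply(references, function(refs)
    unique(unlist(lapply(refs, kmer_set, k = k))))
  fam_len <- vapply(references, function(refs) sum(nchar(refs)), 0)

  out <- list()
  for (ci in seq_along(contigs)) {
    cid <- names(contigs)[ci]
    fwd <- contigs[[ci]]
    rc <- rev_comp(fwd)
    L <- nchar(fwd)
    km_f <- kmer_set(fwd, k); km_r <- kmer_set(rc, k)
    best <- NULL
    for (fam in names(references)) {
      strands <- c(if (any(km_f %in% fam_kmers[[fam]])) "+",
                   if (any(km_r %in% fam_kmers[[fam]])) "-")
      for (strand in strands) {
        qseq <- if (strand == "+") fwd else rc
        for (rid in names(references[[fam]])) {
          al <- Biostrings::pairwiseAlignment(
            qseq, references[[fam]][[rid]], type = "local",
            substitutionMatrix = smat, gapOpening = 4, gapExtension = 1)
          sc <- Biostrings::score(al)
          s0 <- Biostrings::start(Biostrings::pattern(al)) - 1L
          e0 <- Biostrings::end(Biostrings::pattern(al))
          if (strand == "-") { tmp <- s0; s0 <- L - e0; e0 <- L - tmp }
          ev <- KA_K * L * fam_len[[fam]] * exp(-lambda * sc)
          hit <- data.frame(contig_id = cid, family = fam, ref_id = rid,
                            start = s0, end = e0, strand = strand,
                            score = sc, evalue = ev)
          if (is.null(best) || sc > best$score ||
              (sc == best$score && fam < best$family)) best <- hit
        }
      }
    }
    if (!is.null(best) &&
        best$evalue <= e_max &&
        (best$end - best$start) >= min_match_len)
      out[[length(out) + 1]] <- best
  }
  if (length(out) == 0)
    return(data.frame(contig_id = character(0), family = character(0),
                      ref_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      score = numeric(0), evalue = numeric(0)))
  do.call(rbind, out)
}

#' Trim a contig to its matched interval
#'
#' Returns the subsequence of the hit interval (0-based half-open, forward
#' coordinates), reverse-complemented for minus-strand hits so the result
#' is in reference orientation.
#'
#' @param contig contig sequence (character scalar).
#' @param hit one row of a [similarity_search()] result.
#' @export
trim_to_match <- function(contig, hit) {
  L <- nchar(contig)
  if (hit$start < 0 || hit$end > L || hit$start >= hit$end)
    stop("hit interval [", hit$start, ",", hit$end,
         ") out of contig bounds [0,", L, ")")
  s <- substr(contig, hit$start + 1, hit$end)
  if (hit$strand == "-") s <- rev_comp(s) else s
}

#' Aggregate per-contig read counts into lineage rpm/rpkm
#'
#' `rpm = reads / (total_mapped / 1e6)` per contig, summed over the contigs
#' assigned to each lineage; `rpkm = rpm * 1000 / L_eff` with `L_eff` the
#' read-count-weighted mean matched length of the member contigs (recorded
#' for audit).  Counted contigs without a placement accumulate under
#' "unassigned", so per-sample rpm is conserved at 1e6 when the totals
#' equal the per-contig sums.
#'
#' @param placements data.frame with contig_id, lineage.
#' @param counts data.frame with contig_id, sample_id, reads.
#' @param contig_lengths named vector of matched lengths (bp).
#' @param total_reads named per-sample totals of mapped reads (default:
#'   per-sample sum of `counts$reads`).
#' @return data.frame (sample_id, lineage, rpm, rpkm, n_contigs, L_eff)
#'   with per-contig rpm in attribute `contig_rpm`.
#' @export
quantify <- function(placements, counts, contig_lengths,
                     total_reads = NULL) {
  stopifnot(all(c("contig_id", "lineage") %in% names(placements)),
            all(c("contig_id", "sample_id", "reads") %in% names(counts)))
  missing_len <- setdiff(counts$contig_id, names(contig_lengths))
  if (length(missing_len) > 0)
    stop("no length for contigs: ", paste(missing_len, collapse = ", "))
  if (is.null(total_reads)) {
    total_reads <- tapply(counts$reads, counts$sample_id, sum)
  }
  if (any(total_reads <= 0)) stop("total mapped reads must be positive")
  df <- counts
  df$lineage <- placements$lineage[match(df$contig_id, placements$contig_id)]
  df$lineage[is.na(df$lineage)] <- "unassigned"
  df$rpm <- df$reads / (total_reads[df$sample_id] / 1e6)
  df$len <- contig_lengths[df$contig_id]
  agg <- do.call(rbind, lapply(split(df, list(df$sample_id, df$lineage),
                                     drop = TRUE), function(g) {
    L_eff <- if (sum(g$reads) > 0) sum(g$len * g$reads) / sum(g$reads)
             else mean(g$len)
    data.frame(sample_id = g$sample_id[1], lineage = g$lineage[1],
               rpm = sum(g$rpm), rpkm = sum(g$rpm) * 1000 / L_eff,
               n_contigs = nrow(g), L_eff = L_eff)
  }))
  agg <- agg[order(agg$sample_id, agg$lineage), ]
  rownames(agg) <- NULL
  attr(agg, "contig_rpm") <- df[, c("contig_id", "sample_id", "lineage",
                                    "reads", "rpm", "len")]
  agg
}

#' Harvest 1:1 co-ortholog alignments for dating
#'
#' Per gene family, each taxon's contigs are searched against the family
#' CDS set with a long minimum alignment length; a taxon contributes iff
#' exactly one contig survives the filters.  Families in which any taxon
#' has two or more surviving contigs violate 1:1-ness and are dropped
#' (logged); surviving families with at least `min_taxa` represented taxa
#' are emitted as alignments in the coordinate frame of the family's first
#' reference sequence.
#'
#' @param transcriptomes list: taxon id -> named contig vector.
#' @param references list: family id -> named CDS vector.
#' @param min_aln_len minimum alignment length, bp (default 500).
#' @param e_max e-value threshold.
#' @param min_taxa minimum taxa per emitted dataset.
#' @return list of [seq_alignment()] objects (one per surviving family),
#'   with dropped families in attribute `dropped`.
#' @export
harvest_orthologs <- function(transcriptomes, references, min_aln_len = 500,
                              e_max = 0.01, min_taxa = 4) {
  out <- list(); dropped <- character(0)
  smat <- sub_matrix()
  for (fam in names(references)) {
    frame_ref <- references[[fam]][[1]]
    rows <- list()
    ok <- TRUE
    for (taxon in names(transcriptomes)) {
      hits <- similarity_search(transcriptomes[[taxon]],
                                references[fam], e_max = e_max,
                                min_match_len = min_aln_len)
      if (nrow(hits) > 1) { ok <- FALSE; break }
      if (nrow(hits) == 0) next
      trimmed <- trim_to_match(
        transcriptomes[[taxon]][[hits$contig_id[1]]], hits[1, ])
      rows[[taxon]] <- project_onto_reference(trimmed, frame_ref, smat)
    }
    if (!ok) {
      dropped <- c(dropped, fam)
      message("family ", fam, " dropped: taxon with multiple co-orthologs")
      next
    }
    if (length(rows) >= min_taxa)
      out[[fam]] <- seq_alignment(names(rows), unlist(rows))
  }
  if (length(out) == 0) warning("no families survived the 1:1 harvest")
  attr(out, "dropped") <- dropped
  out
}

# align a sequence into the coordinate frame of an ungapped reference
# (query-only insertions are dropped; uncovered reference positions gapped)
project_onto_reference <- function(query, ref, smat = sub_matrix()) {
  al <- Biostrings::pairwiseAlignment(query, ref, type = "global-local",
                                      substitutionMatrix = smat,
                                      gapOpening = 4, gapExtension = 1)
  qa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  L <- nchar(ref)
  row <- rep("-", L)
  spos <- Biostrings::start(Biostrings::subject(al)) - 1L
  for (i in seq_along(sa)) {
    if (sa[i] != "-") {
      spos <- spos + 1L
      if (qa[i] != "-") row[spos] <- qa[i]
    }
  }
  paste(row, collapse = "")
}
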