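# Synthetic-data generators with known truth: codon alignments under
# nearly-neutral and branch-site selection regimes, per-gene nucleotide
# alignments whose node ages follow a species chronogram (with optional
# introgression events), and transcriptome contig sets drawn from labeled
# gene lineages.  All generators are seed-deterministic.

# transition matrices per tree edge for a set of generators; returns
# list over edges of list over kernel ids
edge_pmats <- function(tree, eigs, kernel_for_edge) {
  lapply(seq_len(nrow(tree$edge)), function(e) {
    lapply(kernel_for_edge[[e]], function(k) {
      eg <- eigs[[k]]
      P <- eg$U %*% (exp(eg$lambda * tree$edge.length[e]) * eg$Uinv)
      P[P < 0] <- 0
      P / rowSums(P)
    })
  })
}

# evolve discrete states down a tree: P_edge[[e]] is the transition matrix
# for edge row e of tree$edge; returns ntip x nsites integer matrix
evolve_states <- function(tree, P_edge, root_freq, nsites) {
  ntip <- length(tree$tip.label)
  n_nodes <- ntip + tree$Nnode
  ns <- length(root_freq)
  states <- matrix(NA_integer_, n_nodes, nsites)
  root <- ntip + 1L
  states[root, ] <- sample.int(ns, nsites, replace = TRUE, prob = root_freq)
  po <- ape::reorder.phylo(tree, "postorder")
  perm <- match(paste(po$edge[, 1], po$edge[, 2]),
                paste(tree$edge[, 1], tree$edge[, 2]))
  for (e in rev(seq_len(nrow(po$edge)))) {  # preorder
    pa <- po$edge[e, 1]; ch <- po$edge[e, 2]
    P <- P_edge[[perm[e]]]
    rowcum <- t(apply(P, 1, cumsum))
    u <- stats::runif(nsites)
    # child state = first index whose cumulative probability reaches u
    states[ch, ] <- 1L + as.integer(
      rowSums(rowcum[states[pa, ], , drop = FALSE] < u))
  }
  out <- states[seq_len(ntip), , drop = FALSE]
  rownames(out) <- tree$tip.label
  out
}

#' Simulate a codon alignment under a site/branch-site mixture
#'
#' Per site a class is drawn from the mixture; sequences evolve root-to-tip
#' with the class- and branch-appropriate omega (foreground ratios apply
#' only on branches flagged via [label_foreground()]).  Branch lengths are
#' expected substitutions per codon under the background mixture.
#'
#' @param tree rooted `phylo` with branch lengths, optionally carrying
#'   foreground flags.
#' @param n_codons number of codon sites.
#' @param kappa,p0,p1,omega0,omega2 model parameters; `p1 = NULL` gives the
#'   two-class M1a regime, otherwise the four-class branch-site layout
#'   (with `omega2 = 1` for the BSA relaxation regime).
#' @param pi 61 codon frequencies (default equal).
#' @param seed RNG seed.
#' @return list: `alignment` (a `codon_alignment`) and `truth`
#'   (per-site class assignment, 1-based class index).
#' @export
simulate_codon_alignment <- function(tree, n_codons, kappa = 2, p0 = 0.7,
                                     omega0 = 0.2, p1 = NULL, omega2 = NULL,
                                     pi = NULL, seed = 1) {
  validate_rooted_tree(tree)
  set.seed(seed)
  tab <- codon_tables()
  if (is.null(pi)) pi <- codon_frequencies(equal = TRUE)
  cls <- if (is.null(p1)) site_classes("M1a", p0 = p0, omega0 = omega0)
         else site_classes(if (isTRUE(all.equal(omega2, 1))) "BSA" else "BSA1",
                           p0 = p0, p1 = p1, omega0 = omega0, omega2 = omega2)
  fg <- attr(tree, "foreground")
  if (is.null(fg)) fg <- rep(FALSE, nrow(tree$edge))
  omegas <- sort(unique(c(cls$omega_bg, cls$omega_fg[rep(any(fg), nrow(cls))])))
  if (length(omegas) == 0) omegas <- sort(unique(cls$omega_bg))
  mix_scale <- codon_mixture_scale(cls, kappa, pi)
  eigs <- lapply(omegas, function(w)
    eig_rev(build_codon_rates(kappa, w, pi) / mix_scale, pi))

  site_class <- sample.int(nrow(cls), n_codons, replace = TRUE,
                           prob = cls$prop)
  states <- matrix(NA_integer_, length(tree$tip.label), n_codons)
  for (c in sort(unique(site_class))) {
    idx <- which(site_class == c)
    kernel_for_edge <- lapply(seq_len(nrow(tree$edge)), function(e) {
      w <- if (fg[e]) cls$omega_fg[c] else cls$omega_bg[c]
      match(w, omegas)
    })
    P_edge <- edge_pmats(tree, eigs, kernel_for_edge)
    P_edge <- lapply(P_edge, `[[`, 1)
    states[, idx] <- evolve_states(tree, P_edge, pi, length(idx))
  }
  rownames(states) <- tree$tip.label
  seqs <- apply(states, 1, function(row)
    paste(tab$codons[row], collapse = ""))
  aln <- as_codon_alignment(seq_alignment(tree$tip.label, unname(seqs)))
  list(alignment = aln,
       truth = data.frame(site = seq_len(n_codons), class = site_class))
}

#' Simulate a nucleotide alignment under GTR+G(+I)
#'
#' @param tree rooted `phylo`, branch lengths in substitutions/site.
#' @param model a [gtr_model()].
#' @param nsites alignment columns.
#' @param seed optional seed (NULL leaves the RNG stream untouched).
#' @return A [seq_alignment()].
#' @export
simulate_nucleotide_alignment <- function(tree, model, nsites, seed = NULL) {
  validate_rooted_tree(tree)
  if (!is.null(seed)) set.seed(seed)
  cl <- gtr_classes(model)
  eig <- eig_rev(model$Q, model$base_freq)
  site_class <- sample.int(length(cl$rates), nsites, replace = TRUE,
                           prob = cl$props)
  states <- matrix(NA_integer_, length(tree$tip.label), nsites)
  for (c in sort(unique(site_class))) {
    idx <- which(site_class == c)
    tr_c <- tree
    tr_c$edge.length <- tree$edge.length * cl$rates[c]
    P_edge <- edge_pmats(tr_c, list(eig), as.list(rep(1, nrow(tree$edge))))
    P_edge <- lapply(P_edge, `[[`, 1)
    states[, idx] <- evolve_states(tr_c, P_edge, model$base_freq,
                                   length(idx))
  }
  seqs <- apply(states, 1, function(row) paste(NUC[row], collapse = ""))
  seq_alignment(tree$tip.label, unname(seqs))
}

#' Preset working tree for the selection analyses
#'
#' A 15-taxon rooted tree mirroring the study system: two C3 outgroup
#' species, the cimicina/paniculata pair, two A. angusta accessions and a
#' clade of A. semialata accessions spanning C3, intermediate and C4
#' photosynthetic types.  Branch lengths are expected substitutions per
#' codon, of a magnitude typical for closely related grass nuclear genes.
#' @return rooted `phylo`.
#' @export
alloteropsis_codon_tree <- function() {
  txt <- paste0(
    "((P_pygmaeum:0.22,E_marginata:0.24):0.05,",
    "((A_cimicina:0.055,A_paniculata:0.06):0.125,",
    "((A_angusta_1:0.012,A_angusta_2:0.014):0.115,",
    "(A_semialata_C3:0.07,((A_semialata_I1:0.018,A_semialata_I2:0.02):0.025,",
    "(A_semialata_C4_1:0.012,(A_semialata_C4_2:0.01,(A_semialata_C4_3:0.008,",
    "(A_semialata_C4_4:0.006,(A_semialata_C4_5:0.005,A_semialata_C4_6:0.005)",
    ":0.003):0.003):0.004):0.004):0.02):0.012):0.06):0.02):0.05);")
  ape::read.tree(text = txt)
}

#' Preset origin scenarios on the working tree
#'
#' The candidate adaptive-origin scenarios: a single origin at the base of
#' the genus, two origins (cimicina lineage; angusta + semialata), three
#' independent origins, and each single-lineage scenario.
#' @return named list of [scenario_spec()] objects.
#' @export
alloteropsis_scenarios <- function() {
  cim <- c("A_cimicina", "A_paniculata")
  ang <- c("A_angusta_1", "A_angusta_2")
  sem <- c("A_semialata_C3", "A_semialata_I1", "A_semialata_I2",
           paste0("A_semialata_C4_", 1:6))
  list(
    one_origin = scenario_spec("one_origin", list(c(cim, ang, sem))),
    two_origins = scenario_spec("two_origins", list(cim, c(ang, sem))),
    three_origins = scenario_spec("three_origins", list(cim, ang, sem)),
    cimicina_only = scenario_spec("cimicina_only", list(cim)),
    angusta_only = scenario_spec("angusta_only", list(ang)),
    semialata_only = scenario_spec("semialata_only", list(sem)))
}

#' Preset species chronogram for divergence dating
#'
#' Five taxa with the Sorghum outgroup; node ages (Ma) sit inside the
#' genome-wide peak intervals of the study system: root 31, crown
#' Alloteropsis 11, angusta/semialata split 7, crown semialata 4.
#' @return rooted ultrametric `phylo` with ages in Ma.
#' @export
panicoid_chronogram <- function() {
  txt <- paste0("(Sorghum:31,(A_cimicina:11,(A_angusta:7,",
                "(A_semialata_1:4,A_semialata_2:4):3):4):20);")
  ape::read.tree(text = txt)
}

#' Node-label definitions for the preset chronogram
#'
#' Each label maps to two tip sets whose MRCA is the summarized node.
#' @return named list of two-element lists of tip-name vectors.
#' @export
dating_node_labels <- function() {
  list(
    crown_alloteropsis = list("A_cimicina",
                              c("A_angusta", "A_semialata_1", "A_semialata_2")),
    angusta_semialata_split = list("A_angusta",
                                   c("A_semialata_1", "A_semialata_2")),
    crown_semialata = list("A_semialata_1", "A_semialata_2"))
}

label_node <- function(tree, label_def) {
  sides <- lapply(label_def, intersect, y = tree$tip.label)
  if (any(vapply(sides, length, 0L) == 0)) return(NA_integer_)
  mrca_of(tree, unique(unlist(sides)))
}

#' Simulate per-gene histories along a species chronogram
#'
#' Per gene, node ages are copied from the chronogram except at designated
#' introgression events, where the labeled node's age is replaced by the
#' (younger) event age and descendant internal nodes are rescaled
#' proportionally to preserve parent > child ordering.  Branch substitution
#' lengths are duration x global rate x a lognormal per-gene multiplier;
#' sequences evolve under GTR+G.
#'
#' @param n_genes number of genes.
#' @param chronogram dated species tree (default [panicoid_chronogram()]).
#' @param rate global substitution rate (subs/site/Ma).
#' @param rate_sd_log SD of the per-gene lognormal rate multiplier
#'   (mean 1).
#' @param sites alignment length per gene.
#' @param model a [gtr_model()] for sequence evolution.
#' @param events data.frame(gene, node, age): introgressed genes, the
#'   affected node label (see [dating_node_labels()]) and replacement age.
#' @param node_labels label definitions used to resolve `events$node`.
#' @param seed RNG seed.
#' @return list: `genes` (per gene: id, alignment, tree, ages) and `truth`
#'   (gene, node label, true age, introgressed flag).
#' @export
simulate_gene_histories <- function(n_genes, chronogram = panicoid_chronogram(),
                                    rate = 0.005, rate_sd_log = 0.12,
                                    sites = 1500,
                                    model = gtr_model(
                                      rates = c(1, 4, 1, 1, 4, 1),
                                      base_freq = c(0.3, 0.2, 0.2, 0.3),
                                      alpha = 0.8, p_inv = 0),
                                    events = NULL,
                                    node_labels = dating_node_labels(),
                                    seed = 1) {
  validate_rooted_tree(chronogram)
  set.seed(seed)
  base_ages <- node_ages(chronogram)
  ntip <- length(chronogram$tip.label)
  mult <- exp(stats::rnorm(n_genes, 0, rate_sd_log) - rate_sd_log^2 / 2)
  genes <- vector("list", n_genes)
  truth <- list()
  for (g in seq_len(n_genes)) {
    gid <- sprintf("gene%04d", g)
    ages <- base_ages
    introgressed <- FALSE
    if (!is.null(events)) {
      ev <- events[events$gene == g | events$gene == gid, , drop = FALSE]
      for (r in seq_len(nrow(ev))) {
        node <- label_node(chronogram, node_labels[[ev$node[r]]])
        if (is.na(node)) stop("event node label not resolvable: ", ev$node[r])
        parent <- chronogram$edge[chronogram$edge[, 2] == node, 1]
        parent_age <- if (length(parent) == 0) Inf else ages[parent]
        if (ev$age[r] >= parent_age)
          stop("replacement age must be younger than the parent node")
        f <- ev$age[r] / ages[node]
        if (f > 1) stop("replacement age must be younger than the node age")
        sub_nodes <- c(node, descendant_nodes(chronogram, node))
        sub_nodes <- sub_nodes[sub_nodes > ntip]
        ages[sub_nodes] <- ages[sub_nodes] * f
        introgressed <- TRUE
      }
    }
    tr <- apply_node_ages(chronogram, ages)
    tr$edge.length <- tr$edge.length * rate * mult[g]
    aln <- simulate_nucleotide_alignment(tr, model, sites)
    genes[[g]] <- list(id = gid, alignment = aln,
                       tree = apply_node_ages(chronogram, ages),
                       ages = ages, multiplier = mult[g])
    for (lab in names(node_labels)) {
      nd <- label_node(chronogram, node_labels[[lab]])
      truth[[length(truth) + 1]] <-
        data.frame(gene = gid, node = lab, true_age = ages[nd],
                   introgressed = introgressed)
    }
  }
  list(genes = genes, truth = do.call(rbind, truth))
}

# ---- transcriptome simulation -------------------------------------------

#' Build a synthetic reference lineage package
#'
#' Per gene family: a reference alignment simulated along a family tree
#' whose labeled lineages are separated by at least the requested
#' divergence, the family tree itself, and the tip -> lineage label map.
#'
#' @param n_families number of gene families.
#' @param n_lineages labeled lineages per family.
#' @param n_members reference sequences per lineage.
#' @param seq_len reference CDS length (nt).
#' @param lineage_divergence stem length separating lineages (subs/site).
#' @param seed RNG seed.
#' @return list of families, each list(alignment, tree, labels).
#' @export
default_reference_package <- function(n_families = 2, n_lineages = 3,
                                      n_members = 2, seq_len = 900,
                                      lineage_divergence = 0.12, seed = 1) {
  set.seed(seed)
  model <- gtr_model(rates = c(1, 3, 1, 1, 3, 1),
                     base_freq = c(0.28, 0.22, 0.22, 0.28), alpha = 1.5)
  fams <- list()
  for (f in seq_len(n_families)) {
    fam_id <- paste0("fam", f)
    lineage_ids <- paste0(fam_id, "_L", seq_len(n_lineages))
    # rooted binary tree of lineages, each a small clade of members
    sub <- vapply(lineage_ids, function(lid) {
      tips <- paste0(lid, "_m", seq_len(n_members), ":0.015")
      paste0("(", paste(tips, collapse = ","), ")")
    }, "")
    while (length(sub) > 1) {
      pair <- paste0("(", sub[1], ":", lineage_divergence / 2, ",",
                     sub[2], ":", lineage_divergence / 2, ")")
      sub <- c(pair, sub[-(1:2)])
    }
    tree <- ape::read.tree(text = paste0(sub, ";"))
    aln <- simulate_nucleotide_alignment(tree, model, seq_len)
    labels <- stats::setNames(rep(lineage_ids, each = n_members),
                              tree$tip.label)
    fams[[fam_id]] <- list(family = fam_id, alignment = aln, tree = tree,
                           labels = labels)
  }
  fams
}

mutate_sequence <- function(seq, n_subs) {
  if (n_subs == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  pos <- sample.int(length(chars), min(n_subs, length(chars)))
  for (p in pos) chars[p] <- sample(setdiff(NUC, chars[p]), 1)
  paste(chars, collapse = "")
}

#' Simulate a transcriptome contig set from labeled lineages
#'
#' For each expressed lineage a source sequence is evolved along a pendant
#' branch from a random lineage member, fragmented into 1-3 contigs,
#' error-injected, and reads are apportioned to contigs proportional to
#' length with multinomial noise.
#'
#' @param ref_pkg a [default_reference_package()] result.
#' @param expression named vector of true read counts per lineage label
#'   (default: 40 contiguous lineages at geometrically spread levels).
#' @param pendant pendant divergence of the expressed copy (subs/site).
#' @param error_rate i.i.d. sequencing-error substitution rate.
#' @param frag_len contig length range (nt).
#' @param total_reads total mapped reads in the sample (default: sum of
#'   lineage reads, i.e. every mapped read is on an annotated contig).
#' @param sample_id sample identifier carried into the count table.
#' @param seed RNG seed.
#' @return list: `contigs` (named seqs), `counts` (contig_id, sample_id,
#'   reads), `truth` (contig -> lineage, true rpm per lineage),
#'   `total_reads`.
#' @export
simulate_transcriptome <- function(ref_pkg, expression = NULL,
                                   pendant = 0.02, error_rate = 0.002,
                                   frag_len = c(200, 500),
                                   total_reads = NULL, sample_id = "S1",
                                   seed = 1) {
  set.seed(seed)
  all_lineages <- unlist(lapply(ref_pkg, function(f) unique(f$labels)))
  if (is.null(expression)) {
    expression <- stats::setNames(
      round(10000 * 2^(-(seq_along(all_lineages) - 1) / 2)) + 50,
      all_lineages)
  }
  stopifnot(all(names(expression) %in% all_lineages))
  contigs <- character(0)
  rows <- list(); truth_rows <- list()
  cid <- 0
  for (lin in names(expression)) {
    fam <- ref_pkg[[which(vapply(ref_pkg,
                                 function(f) lin %in% f$labels, TRUE))[1]]]
    member <- sample(names(fam$labels)[fam$labels == lin], 1)
    src <- gsub("-", "", aln_strings(fam$alignment)[[member]])
    L <- nchar(src)
    src <- mutate_sequence(src, stats::rpois(1, pendant * L))
    n_frag <- sample(1:3, 1)
    # random starts; clip fragments to the source
    lens <- pmin(sample(frag_len[1]:frag_len[2], n_frag, replace = TRUE), L)
    starts <- vapply(lens, function(l) sample.int(L - l + 1, 1), 0L)
    frag_seqs <- substr(rep(src, n_frag), starts, starts + lens - 1)
    frag_seqs <- vapply(frag_seqs, function(s)
      mutate_sequence(s, stats::rbinom(1, nchar(s), error_rate)), "")
    reads <- as.vector(stats::rmultinom(1, expression[[lin]],
                                        prob = lens / sum(lens)))
    for (i in seq_len(n_frag)) {
      cid <- cid + 1
      id <- sprintf("contig%04d", cid)
      contigs[[id]] <- unname(frag_seqs[i])
      rows[[cid]] <- data.frame(contig_id = id, sample_id = sample_id,
                                reads = reads[i], length = lens[i])
      truth_rows[[cid]] <- data.frame(contig_id = id, lineage = lin,
                                      family = fam$family)
    }
  }
  counts <- do.call(rbind, rows)
  truth <- do.call(rbind, truth_rows)
  if (is.null(total_reads)) total_reads <- sum(counts$reads)
  truth_rpm <- stats::aggregate(
    rpm ~ lineage,
    data = data.frame(lineage = truth$lineage,
                      rpm = counts$reads / (total_reads / 1e6)),
    FUN = sum)
  list(contigs = contigs, counts = counts, truth = truth,
       truth_rpm = truth_rpm, total_reads = total_reads)
}
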