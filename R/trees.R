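# Rooted-tree handling built on ape's phylo representation.  Foreground
# branch flags (for branch-site models) live in attr(tree, "foreground"),
# a logical vector aligned with the rows of tree$edge; in Newick they are
# encoded as a "#FG" suffix on the label of the child node of the flagged
# branch.

validate_rooted_tree <- function(tree, require_binary = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (anyDuplicated(tree$tip.label)) stop("tip names must be unique")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed")
  if (require_binary && !ape::is.binary(tree))
    stop("a binary rooted tree is required")
  invisible(tree)
}

#' Read a rooted tree from Newick
#'
#' A `#FG` suffix on any label marks the branch leading to that node as
#' foreground; the suffix is stripped from the stored labels.
#'
#' @param path Newick file.
#' @param require_binary reject multifurcating trees (needed for dating).
#' @return An ape `phylo` with optional `foreground` attribute.
#' @export
read_newick <- function(path, require_binary = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick in ", path)
  ntip <- length(tree$tip.label)
  labels <- c(tree$tip.label,
              if (is.null(tree$node.label)) rep("", tree$Nnode)
              else tree$node.label)
  fg_nodes <- grepl("#FG$", labels)
  if (any(fg_nodes)) {
    labels <- sub("#FG$", "", labels)
    tree$tip.label <- labels[seq_len(ntip)]
    if (!is.null(tree$node.label)) tree$node.label <- labels[-seq_len(ntip)]
    fg <- fg_nodes[tree$edge[, 2]]
    attr(tree, "foreground") <- fg
  }
  validate_rooted_tree(tree, require_binary)
  tree
}

#' Write a rooted tree to Newick
#'
#' @param tree an ape `phylo`; a `foreground` attribute is written back as
#'   `#FG` label suffixes.
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  fg <- attr(tree, "foreground")
  if (!is.null(fg)) {
    ntip <- length(tree$tip.label)
    if (is.null(tree$node.label)) tree$node.label <- rep("", tree$Nnode)
    fg_nodes <- tree$edge[fg, 2]
    for (nd in fg_nodes) {
      if (nd <= ntip) tree$tip.label[nd] <- paste0(tree$tip.label[nd], "#FG")
      else tree$node.label[nd - ntip] <- paste0(tree$node.label[nd - ntip], "#FG")
    }
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}

# MRCA of a tip set (the tip itself for singletons); tips by name
mrca_of <- function(tree, tips) {
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx)) stop("tips not in tree: ",
                       paste(tips[is.na(idx)], collapse = ", "))
  if (length(idx) == 1) return(idx)
  ape::getMRCA(tree, idx)
}

# all descendant node indices of `node` (excluding itself)
descendant_nodes <- function(tree, node) {
  out <- integer(0)
  stack <- node
  while (length(stack) > 0) {
    nd <- stack[[1]]; stack <- stack[-1]
    ch <- tree$edge[tree$edge[, 1] == nd, 2]
    out <- c(out, ch)
    stack <- c(stack, ch[ch > length(tree$tip.label)])
  }
  out
}

# edge indices of the stem branch of a clade MRCA plus all descendant branches
clade_edge_set <- function(tree, tips, check_monophyletic = TRUE) {
  node <- mrca_of(tree, tips)
  ntip <- length(tree$tip.label)
  if (check_monophyletic && node > ntip) {
    clade_tips <- tree$tip.label[intersect(descendant_nodes(tree, node),
                                           seq_len(ntip))]
    if (!setequal(clade_tips, tips))
      stop("tip set is not monophyletic: {", paste(tips, collapse = ", "),
           "} resolves to clade {", paste(clade_tips, collapse = ", "), "}")
  }
  stem <- which(tree$edge[, 2] == node)
  desc <- which(tree$edge[, 2] %in% descendant_nodes(tree, node))
  sort(unique(c(stem, desc)))
}

#' Define an origin scenario as a set of foreground clades
#'
#' @param name scenario name.
#' @param clades named or unnamed list of tip-name vectors; each must be
#'   monophyletic in the working tree.  The induced foreground branch set is
#'   the stem branch of each clade's MRCA plus all descendant branches.
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, clades) {
  stopifnot(is.character(name), length(name) == 1, length(clades) >= 1)
  structure(list(name = name, clades = clades), class = "scenario_spec")
}

#' Flag scenario foreground branches on a tree
#'
#' @param tree rooted `phylo`.
#' @param scenario a [scenario_spec()] (or NULL to clear flags).
#' @return The tree with attribute `foreground` set (logical per edge row).
#' @export
label_foreground <- function(tree, scenario) {
  validate_rooted_tree(tree)
  if (is.null(scenario)) {
    attr(tree, "foreground") <- NULL
    return(tree)
  }
  stopifnot(inherits(scenario, "scenario_spec"))
  fg <- rep(FALSE, nrow(tree$edge))
  for (clade in scenario$clades) {
    missing <- setdiff(clade, tree$tip.label)
    if (length(missing) > 0)
      stop("scenario '", scenario$name, "': tips absent from tree: ",
           paste(missing, collapse = ", "))
    fg[clade_edge_set(tree, clade)] <- TRUE
  }
  attr(tree, "foreground") <- fg
  tree
}

#' Remove taxa from an alignment/tree pair
#'
#' Rows and tips are pruned consistently; branch lengths of suppressed
#' degree-2 nodes are summed (ape::drop.tip semantics).
#'
#' @param alignment a [seq_alignment()] (or NULL).
#' @param tree rooted `phylo`.
#' @param drop tip names to remove.
#' @return list(alignment, tree).
#' @export
prune_taxa <- function(alignment, tree, drop) {
  stopifnot(all(drop %in% tree$tip.label))
  keep <- setdiff(tree$tip.label, drop)
  if (length(keep) < 3) stop("pruning would leave fewer than 3 tips")
  if (length(drop) == 0) return(list(alignment = alignment, tree = tree))
  tree2 <- ape::drop.tip(tree, drop, collapse.singles = TRUE)
  aln2 <- if (is.null(alignment)) NULL else {
    ids <- intersect(alignment$ids, keep)
    aln_subset(alignment, ids = ids)
  }
  if (!is.null(aln2) && inherits(alignment, "codon_alignment"))
    aln2 <- as_codon_alignment(aln2)
  list(alignment = aln2, tree = tree2)
}

# flat representation used by the pruning engine: postorder edges, counts
tree_pruning_layout <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  # map original edge rows to postorder rows (to carry per-edge attributes)
  key <- function(e) paste(e[, 1], e[, 2])
  perm <- match(key(po$edge), key(tree$edge))
  list(edges = po$edge, perm = perm,
       lengths = if (is.null(po$edge.length)) NULL else po$edge.length,
       ntip = ntip, n_nodes = ntip + tree$Nnode, root = ntip + 1L)
}

# node ages for an ultrametric (or general dated) tree: vector over nodes
node_ages <- function(tree) {
  ntip <- length(tree$tip.label)
  n_nodes <- ntip + tree$Nnode
  depth <- numeric(n_nodes)
  po <- ape::reorder.phylo(tree, "postorder")
  # root-to-node distances via preorder
  for (e in rev(seq_len(nrow(po$edge)))) {
    pa <- po$edge[e, 1]; ch <- po$edge[e, 2]
    depth[ch] <- depth[pa] + po$edge.length[e]
  }
  max(depth) - depth
}

# build a dated phylo from topology + ages (ages indexed by node)
apply_node_ages <- function(tree, ages) {
  tree$edge.length <- ages[tree$edge[, 1]] - ages[tree$edge[, 2]]
  if (any(tree$edge.length < -1e-9)) stop("ages must decrease root->tip")
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}
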