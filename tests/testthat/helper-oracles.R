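# Independent oracles and small fixtures shared across tests.

# Brute-force site likelihood by exhaustive enumeration of ancestral states.
# P_edges: per class, a list over tree$edge rows of transition matrices
# (computed here with Matrix::expm, independent of the package's eigen
# path).  tip_states: ntip x nsites integer matrix (NA = missing).
bf_mixture_loglik <- function(tip_states, tree, P_classes, pi, props) {
  ntip <- length(tree$tip.label)
  n_nodes <- ntip + tree$Nnode
  internal <- (ntip + 1):n_nodes
  grid <- as.matrix(expand.grid(rep(list(seq_along(pi)), length(internal))))
  colnames(grid) <- as.character(internal)
  root <- ntip + 1
  nsites <- ncol(tip_states)
  total <- 0
  for (site in seq_len(nsites)) {
    lik_mix <- 0
    for (cl in seq_along(P_classes)) {
      P <- P_classes[[cl]]
      lik <- pi[grid[, as.character(root)]]
      for (e in seq_len(nrow(tree$edge))) {
        pa <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
        pa_states <- grid[, as.character(pa)]
        if (ch <= ntip) {
          s <- tip_states[ch, site]
          if (is.na(s)) next
          lik <- lik * P[[e]][cbind(pa_states, s)]
        } else {
          lik <- lik * P[[e]][cbind(pa_states, grid[, as.character(ch)])]
        }
      }
      lik_mix <- lik_mix + props[cl] * sum(lik)
    }
    total <- total + log(lik_mix)
  }
  total
}

# expm-based transition matrices for a codon model on a (possibly flagged)
# tree; returns list over classes of lists over edges
bf_codon_pmatrices <- function(tree, kappa, classes, pi) {
  mix <- codon_mixture_scale(classes, kappa, pi)
  fg <- attr(tree, "foreground")
  if (is.null(fg)) fg <- rep(FALSE, nrow(tree$edge))
  lapply(seq_len(nrow(classes)), function(cl) {
    lapply(seq_len(nrow(tree$edge)), function(e) {
      w <- if (fg[e]) classes$omega_fg[cl] else classes$omega_bg[cl]
      Q <- build_codon_rates(kappa, w, pi) / mix
      as.matrix(Matrix::expm(Q * tree$edge.length[e]))
    })
  })
}

bf_codon_loglik <- function(alignment, tree, model, scale = 1) {
  tr <- tree
  tr$edge.length <- tr$edge.length * scale
  st <- alloscan:::states_for_tree(alloscan:::codon_index_matrix(alignment),
                                   tr)
  P <- bf_codon_pmatrices(tr, model$kappa, model$classes, model$pi)
  bf_mixture_loglik(st, tr, P, unname(model$pi), model$classes$prop)
}

tiny_tree3 <- function() ape::read.tree(text = "((A:0.25,B:0.15):0.1,C:0.35);")
tiny_tree4 <- function() {
  ape::read.tree(text = "((A:0.2,B:0.3):0.12,(C:0.15,D:0.25):0.08);")
}

tiny_codon_model <- function(pi = codon_frequencies(equal = TRUE)) {
  codon_model(2.1, pi, site_classes("M1a", p0 = 0.6, omega0 = 0.3))
}

fake_age_posterior <- function(samples_by_node, tree) {
  samples <- do.call(cbind, samples_by_node)
  colnames(samples) <- names(samples_by_node)
  structure(list(samples = samples,
                 ess = stats::setNames(rep(1000, ncol(samples)),
                                       colnames(samples)),
                 tree = tree,
                 node_ids = as.integer(sub("age_", "",
                                           colnames(samples)))),
            class = "age_posterior")
}
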