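# Likelihood evaluation: thin R wrappers around the C++ pruning engine.

compress_patterns <- function(states) {
  key <- apply(states, 2, paste, collapse = ",")
  first <- !duplicated(key)
  w <- as.vector(table(factor(key, levels = key[first])))
  list(states = states[, first, drop = FALSE], weights = w)
}

# order alignment state rows by tree tip numbering; error on missing tips
states_for_tree <- function(states, tree) {
  idx <- match(tree$tip.label, rownames(states))
  if (anyNA(idx))
    stop("tree tips without sequence: ",
         paste(tree$tip.label[is.na(idx)], collapse = ", "))
  states[idx, , drop = FALSE]
}

#' Bundle the parameters of a codon site-class model
#'
#' @param kappa transition/transversion ratio.
#' @param pi 61 sense-codon frequencies.
#' @param classes data.frame from [site_classes()].
#' @return object of class `codon_model`.
#' @export
codon_model <- function(kappa, pi, classes) {
  stopifnot(kappa > 0, length(pi) == 61, abs(sum(pi) - 1) < 1e-6,
            abs(sum(classes$prop) - 1) < 1e-8, all(classes$omega_bg >= 0),
            all(classes$omega_fg >= 0))
  structure(list(kappa = kappa, pi = pi, classes = classes),
            class = "codon_model")
}

codon_loglik_engine <- function(states, tree, model, scale = 1,
                                site_values = FALSE) {
  lay <- tree_pruning_layout(tree)
  fg <- attr(tree, "foreground")
  if (is.null(fg)) fg <- rep(FALSE, nrow(tree$edge))
  fg <- fg[lay$perm]
  if (is.null(lay$lengths)) stop("tree has no branch lengths")

  cls <- model$classes
  omegas <- sort(unique(c(cls$omega_bg, if (any(fg)) cls$omega_fg)))
  mix_scale <- codon_mixture_scale(cls, model$kappa, model$pi)
  eig <- lapply(omegas, function(w) {
    Q <- build_codon_rates(model$kappa, w, model$pi) / mix_scale
    eig_rev(Q, model$pi)
  })
  nclass <- nrow(cls)
  nedge <- length(fg)
  trans <- matrix(0L, nclass, nedge)
  for (c in seq_len(nclass)) {
    wb <- match(cls$omega_bg[c], omegas)
    wf <- match(cls$omega_fg[c], omegas)
    trans[c, ] <- as.integer(ifelse(fg, wf, wb))
  }
  storage.mode(trans) <- "integer"
  pat <- compress_patterns(states)
  st <- pat$states
  st[is.na(st)] <- 0L
  res <- prune_loglik_cpp(st, pat$weights, lay$edges, lay$n_nodes, lay$root,
                          lay$lengths * scale, eig,
                          seq_along(omegas), rep(1, length(omegas)),
                          trans, cls$prop, unname(model$pi), site_values)
  if (site_values) res$pattern_weights <- pat$weights
  res
}

nuc_loglik_engine <- function(states, tree, model, scale = 1,
                              site_values = FALSE) {
  lay <- tree_pruning_layout(tree)
  if (is.null(lay$lengths)) stop("tree has no branch lengths")
  cl <- gtr_classes(model)
  eig <- list(eig_rev(model$Q, model$base_freq))
  nk <- length(cl$rates)
  trans <- matrix(rep(seq_len(nk), each = nrow(lay$edges)),
                  nrow = nk, byrow = TRUE)
  pat <- compress_patterns(states)
  st <- pat$states
  st[is.na(st)] <- 0L
  res <- prune_loglik_cpp(st, pat$weights, lay$edges, lay$n_nodes, lay$root,
                          lay$lengths * scale, eig,
                          rep(1L, nk), cl$rates,
                          trans, cl$props, model$base_freq, site_values)
  if (site_values) res$pattern_weights <- pat$weights
  res
}

nuc_states <- function(alignment) {
  st <- matrix(match(alignment$mat, NUC), nrow = nrow(alignment$mat))
  rownames(st) <- alignment$ids
  st
}

#' Phylogenetic log-likelihood by Felsenstein pruning
#'
#' Computes sum over sites of log sum over classes of
#' `prop_class * L(site | class)` by post-order pruning with per-branch
#' transition matrices, with per-site rescaling against underflow.  Sites
#' with gap/ambiguity at a tip contribute likelihood 1 at that tip.
#'
#' @param alignment a [seq_alignment()] (for `gtr_model`) or
#'   [as_codon_alignment()] result (for `codon_model`).
#' @param tree rooted `phylo` with branch lengths; for codon models the
#'   `foreground` attribute (see [label_foreground()]) selects where
#'   foreground ratios apply.
#' @param model a [gtr_model()] or [codon_model()].
#' @param scale multiplier applied to all branch lengths.
#' @return log-likelihood (numeric scalar).
#' @export
prune_loglik <- function(alignment, tree, model, scale = 1) {
  validate_rooted_tree(tree)
  if (inherits(model, "codon_model")) {
    stopifnot(inherits(alignment, "codon_alignment"))
    st <- states_for_tree(codon_index_matrix(alignment), tree)
    codon_loglik_engine(st, tree, model, scale)$loglik
  } else if (inherits(model, "gtr_model")) {
    st <- states_for_tree(nuc_states(alignment), tree)
    nuc_loglik_engine(st, tree, model, scale)$loglik
  } else stop("unknown model type")
}
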