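# Branch-site selection analysis: maximum-likelihood fits of the M1a null
# and the BSA / BSA1 branch-site alternatives under origin scenarios,
# AICc-based model selection with the dAICc >= 5.22 null-rejection rule,
# empirical-Bayes site posteriors, and robustness reruns.

sigmoid <- function(x) 1 / (1 + exp(-x))
logit <- function(p) log(p / (1 - p))

# free-parameter layout per model (substitution params + kappa + tree scale)
model_k <- c(M1a = 4L, BSA = 5L, BSA1 = 6L)

unpack_params <- function(theta, model) {
  kappa <- exp(theta[1])
  if (model == "M1a") {
    list(kappa = kappa, p0 = sigmoid(theta[2]), p1 = NA,
         omega0 = sigmoid(theta[3]), omega2 = NA, scale = exp(theta[4]))
  } else {
    p0 <- sigmoid(theta[2])
    p1 <- (1 - p0) * sigmoid(theta[3])
    omega0 <- sigmoid(theta[4])
    if (model == "BSA")
      list(kappa = kappa, p0 = p0, p1 = p1, omega0 = omega0, omega2 = 1,
           scale = exp(theta[5]))
    else
      list(kappa = kappa, p0 = p0, p1 = p1, omega0 = omega0,
           omega2 = 1 + (999 - 1) * sigmoid(theta[5]), scale = exp(theta[6]))
  }
}

pack_params <- function(p, model) {
  th <- c(log(p$kappa))
  if (model == "M1a") {
    th <- c(th, logit(p$p0), logit(p$omega0), log(p$scale))
  } else {
    th <- c(th, logit(p$p0), logit(p$p1 / (1 - p$p0)), logit(p$omega0))
    if (model == "BSA1")
      th <- c(th, logit(max(p$omega2 - 1, 1e-3) / 998))
    th <- c(th, log(p$scale))
  }
  th
}

params_to_classes <- function(p, model) {
  if (model == "M1a") site_classes("M1a", p0 = p$p0, omega0 = p$omega0)
  else site_classes(model, p0 = p$p0, p1 = p$p1, omega0 = p$omega0,
                    omega2 = p$omega2)
}

#' Small-sample-corrected Akaike information criterion
#'
#' `AICc = -2 lnL + 2k + 2k(k+1)/(n-k-1)` with `n` the number of codon
#' sites (the independent observations of the likelihood).
#'
#' @param lnL log-likelihood.
#' @param k number of free parameters.
#' @param n number of sites.
#' @export
aicc <- function(lnL, k, n) {
  stopifnot(n - k - 1 > 0)
  -2 * lnL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit a codon site/branch-site model by maximum likelihood
#'
#' Branch lengths are taken from the input tree and held fixed (estimate
#' them once with [estimate_branch_lengths_m0()] if absent), with one free
#' tree-scale factor per fit so relative lengths are shared across models.
#' Substitution parameters are optimized by bounded quasi-Newton from a
#' default start plus short probe runs from two fixed alternative starts;
#' a probe that undercuts the polished optimum is itself polished.
#'
#' @param alignment an [as_codon_alignment()] result.
#' @param tree rooted `phylo` with branch lengths (expected substitutions
#'   per codon).
#' @param model one of "M1a", "BSA", "BSA1".
#' @param scenario a [scenario_spec()]; required for BSA/BSA1.
#' @param pi_option codon frequencies: "F3x4" (default) or "equal".
#' @param n_starts number of optimization starts (>= 1, default 3).
#' @param init optional parameter list (kappa, p0, p1, omega0, omega2,
#'   scale) used as an additional fully polished start, e.g. the MLEs of a
#'   nested model already fitted to the same data.
#' @return object of class `model_fit`: lnL, k, n, AICc, MLEs, convergence.
#' @export
fit_model <- function(alignment, tree, model = c("M1a", "BSA", "BSA1"),
                      scenario = NULL, pi_option = c("F3x4", "equal"),
                      n_starts = 3, init = NULL) {
  model <- match.arg(model)
  pi_option <- match.arg(pi_option)
  stopifnot(inherits(alignment, "codon_alignment"))
  validate_rooted_tree(tree)
  if (length(tree$tip.label) < 3) stop("need at least 3 sequences")
  if (model != "M1a") {
    if (is.null(scenario)) stop(model, " requires a scenario")
    tree <- label_foreground(tree, scenario)
  } else {
    attr(tree, "foreground") <- NULL
  }
  pi <- codon_frequencies(alignment, equal = (pi_option == "equal"))
  st <- states_for_tree(codon_index_matrix(alignment), tree)

  nll <- function(theta) {
    p <- unpack_params(theta, model)
    cls <- params_to_classes(p, model)
    m <- codon_model(p$kappa, pi, cls)
    ll <- tryCatch(codon_loglik_engine(st, tree, m, scale = p$scale)$loglik,
                   error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  starts <- list(
    list(kappa = 2,   p0 = 0.7,  p1 = 0.2,  omega0 = 0.2,  omega2 = 2,   scale = 1),
    list(kappa = 4,   p0 = 0.5,  p1 = 0.3,  omega0 = 0.05, omega2 = 8,   scale = 0.5),
    list(kappa = 1.5, p0 = 0.85, p1 = 0.1,  omega0 = 0.5,  omega2 = 1.2, scale = 2))
  if (n_starts < 1 && is.null(init))
    stop("n_starts = 0 requires an init parameter list")
  base_start <- starts[[1]]
  starts <- starts[seq_len(min(max(n_starts, 0), length(starts)))]
  if (model == "BSA1" && is.null(init) && length(starts) > 0) {
    # boundary start protects the nested-model ordering when omega2 -> 1
    s <- starts[[1]]; s$omega2 <- 1.001
    starts <- c(starts, list(s))
  }

  polish <- function(theta0, iter_max = 200) {
    stats::nlminb(theta0, nll,
                  control = list(iter.max = iter_max, eval.max = 1000,
                                 rel.tol = 1e-8))
  }
  best <- if (length(starts) > 0) polish(pack_params(starts[[1]], model))
          else NULL
  if (!is.null(init)) {
    given <- init[!vapply(init, function(x) is.null(x) || all(is.na(x)),
                          TRUE)]
    p1_given <- "p1" %in% names(given)
    ini <- utils::modifyList(base_start, given)
    ini$p0 <- min(max(ini$p0, 1e-4), 1 - 1e-4)
    if (model != "M1a") {
      if (!p1_given)
        ini$p1 <- (1 - ini$p0) * 0.9999  # M1a boundary of the BSA family
      ini$p1 <- min(max(ini$p1, 1e-5), (1 - ini$p0) * (1 - 1e-5))
      if (model == "BSA1" && !isTRUE(ini$omega2 > 1))
        ini$omega2 <- 1.001
    }
    full <- polish(pack_params(ini, model))
    if (is.null(best) || full$objective < best$objective) best <- full
  }
  if (length(starts) > 1) {
    for (s in starts[-1]) {
      probe <- polish(pack_params(s, model), iter_max = 6)
      if (probe$objective < best$objective - 0.01) {
        full <- polish(probe$par)
        if (full$objective < best$objective) best <- full
      }
    }
  }
  p <- unpack_params(best$par, model)
  k <- model_k[[model]]
  n <- alignment$n_codons
  lnL <- -best$objective
  structure(list(model = model,
                 scenario = if (is.null(scenario)) NA_character_
                            else scenario$name,
                 lnL = lnL, k = k, n = n, AICc = aicc(lnL, k, n),
                 mle = p, pi = pi,
                 collapsed = (model == "BSA1" && p$omega2 < 1 + 1e-3),
                 convergence = best$convergence %in% c(0, 1),
                 message = best$message),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> %s%s  lnL=%.3f  k=%d  n=%d  AICc=%.3f\n",
              x$model,
              if (is.na(x$scenario)) "" else paste0(" / ", x$scenario),
              x$lnL, x$k, x$n, x$AICc))
  invisible(x)
}

fit_label <- function(model, scenario) {
  ifelse(is.na(scenario) | model == "M1a", model,
         paste(model, scenario, sep = "/"))
}

#' Select the best-fit model by AICc with a null-rejection threshold
#'
#' The null (M1a) is rejected only when its AICc exceeds the minimum by at
#' least `threshold` (default 5.22, the df = 2 likelihood-ratio equivalent
#' of P = 0.01); otherwise M1a is retained as the best model.  Ties within
#' 0.01 resolve toward fewer parameters, then toward M1a.
#'
#' @param fits list of `model_fit` objects (exactly one M1a), or a
#'   data.frame with columns `model`, `scenario`, `aicc` (absolute AICc or
#'   values relative to any common reference, e.g. printed dAICc tables).
#' @param threshold null-rejection margin in AICc units.
#' @return object of class `selection_report`.
#' @export
select_model <- function(fits, threshold = 5.22) {
  if (length(fits) == 0) stop("no fits supplied")
  if (is.data.frame(fits)) {
    tab <- data.frame(model = fits$model,
                      scenario = if ("scenario" %in% names(fits))
                        fits$scenario else NA_character_,
                      aicc = fits$aicc,
                      k = model_k[fits$model],
                      stringsAsFactors = FALSE)
    excluded <- character(0)
  } else {
    ok <- vapply(fits, function(f) isTRUE(f$convergence), logical(1))
    excluded <- vapply(fits[!ok], function(f) fit_label(f$model, f$scenario),
                       character(1))
    if (length(excluded) > 0)
      warning("non-converged fits excluded: ",
              paste(excluded, collapse = ", "))
    fits <- fits[ok]
    tab <- data.frame(model = vapply(fits, `[[`, "", "model"),
                      scenario = vapply(fits, `[[`, "", "scenario"),
                      aicc = vapply(fits, `[[`, 0, "AICc"),
                      k = vapply(fits, `[[`, 0L, "k"),
                      stringsAsFactors = FALSE)
  }
  if (sum(tab$model == "M1a") != 1)
    stop("fits must include exactly one M1a null")
  tab$delta <- tab$aicc - min(tab$aicc)
  tab <- tab[order(tab$delta), ]
  rownames(tab) <- NULL
  null_rejected <- tab$delta[tab$model == "M1a"] >= threshold
  best_row <- if (null_rejected) {
    cand <- which(tab$delta < 0.01)
    cand <- cand[order(tab$k[cand], tab$model[cand] != "M1a")]
    cand[1]
  } else {
    which(tab$model == "M1a")
  }
  structure(list(table = tab,
                 best_model = tab$model[best_row],
                 best_scenario = tab$scenario[best_row],
                 threshold = threshold,
                 null_rejected = null_rejected,
                 excluded = excluded),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> best: %s  null %s (threshold %.2f)\n",
              fit_label(x$best_model, x$best_scenario),
              if (x$null_rejected) "rejected" else "retained", x$threshold))
  print(x$table, digits = 4)
  invisible(x)
}

#' Empirical-Bayes posteriors for positive selection per codon site
#'
#' Conditions on the MLEs of a best BSA1 fit (naive empirical Bayes) and
#' reports, per codon site, the posterior probability of the foreground
#' positive-selection classes (2a + 2b), flagged at 0.90 and 0.95.  With
#' `grid = TRUE` a coarse grid over (p0, p1, omega2) is integrated with
#' likelihood weights, approximating the hierarchical-Bayes scheme.
#'
#' @param fit a `model_fit` with model "BSA1" and omega2 > 1.
#' @param alignment,tree the data the fit was produced from.
#' @param scenario the scenario used in the fit.
#' @param grid integrate over a coarse parameter grid.
#' @return data.frame: site, p_selected, flag90, flag95.
#' @export
site_posteriors <- function(fit, alignment, tree, scenario, grid = FALSE) {
  if (!inherits(fit, "model_fit") || fit$model != "BSA1")
    stop("site posteriors require a BSA1 best fit; got ",
         if (inherits(fit, "model_fit")) fit$model else class(fit)[1])
  if (fit$mle$omega2 <= 1)
    stop("BSA1 fit collapsed to omega2 = 1; no selection classes to report")
  tree <- label_foreground(tree, scenario)
  st <- states_for_tree(codon_index_matrix(alignment), tree)

  posterior_for <- function(p) {
    cls <- params_to_classes(p, "BSA1")
    m <- codon_model(p$kappa, fit$pi, cls)
    res <- codon_loglik_engine(st, tree, m, scale = p$scale,
                               site_values = TRUE)
    list(post = res$class_posterior[, 3] + res$class_posterior[, 4],
         loglik = res$loglik)
  }

  if (!grid) {
    post_pat <- posterior_for(fit$mle)$post
  } else {
    pts <- expand.grid(p0 = c(0.4, 0.7, 0.9), p1_frac = c(0.3, 0.6),
                       omega2 = c(1.5, 4, 16))
    lw <- numeric(nrow(pts)); pp <- vector("list", nrow(pts))
    for (i in seq_len(nrow(pts))) {
      p <- fit$mle
      p$p0 <- pts$p0[i]
      p$p1 <- (1 - pts$p0[i]) * pts$p1_frac[i]
      p$omega2 <- pts$omega2[i]
      r <- posterior_for(p)
      lw[i] <- r$loglik; pp[[i]] <- r$post
    }
    w <- exp(lw - max(lw)); w <- w / sum(w)
    post_pat <- Reduce(`+`, Map(`*`, pp, w))
  }
  # expand patterns back to sites
  key <- apply(st, 2, paste, collapse = ",")
  first <- !duplicated(key)
  site_post <- post_pat[match(key, key[first])]
  data.frame(site = seq_along(site_post), p_selected = site_post,
             flag90 = site_post > 0.90, flag95 = site_post > 0.95)
}

#' Estimate branch lengths under a single-ratio (M0) codon model
#'
#' Coordinate-wise Brent optimization of each branch length, alternating
#' with joint optimization of kappa and omega; used once per dataset, after
#' which all model fits share the lengths up to a scale factor.
#'
#' @param alignment an [as_codon_alignment()] result.
#' @param tree rooted `phylo` (lengths, if present, are the start point).
#' @param sweeps coordinate-ascent sweeps over branches.
#' @return The tree with estimated branch lengths (subst/codon).
#' @export
estimate_branch_lengths_m0 <- function(alignment, tree, sweeps = 2) {
  stopifnot(inherits(alignment, "codon_alignment"))
  pi <- codon_frequencies(alignment)
  st <- states_for_tree(codon_index_matrix(alignment), tree)
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0.1, nrow(tree$edge))
  kappa <- 2; omega <- 0.2
  m0 <- function(kappa, omega) {
    codon_model(kappa, pi, data.frame(prop = 1, omega_bg = omega,
                                      omega_fg = omega))
  }
  ll_tree <- function(tr, kappa, omega)
    codon_loglik_engine(st, tr, m0(kappa, omega))$loglik
  for (s in seq_len(sweeps)) {
    opt <- stats::optim(c(log(kappa), logit(min(omega, 0.99))),
                        function(th) -ll_tree(tree, exp(th[1]),
                                              sigmoid(th[2])),
                        method = "Nelder-Mead",
                        control = list(maxit = 40))
    kappa <- exp(opt$par[1]); omega <- sigmoid(opt$par[2])
    for (e in seq_len(nrow(tree$edge))) {
      f <- function(len) {
        tree$edge.length[e] <- len
        -ll_tree(tree, kappa, omega)
      }
      tree$edge.length[e] <- stats::optimize(f, c(1e-8, 20),
                                             tol = 1e-4)$minimum
    }
  }
  attr(tree, "m0") <- list(kappa = kappa, omega = omega)
  tree
}

#' Robustness of model selection to gene-tree uncertainty
#'
#' Codon columns are resampled with replacement, the topology re-estimated
#' per replicate by neighbour joining on nucleotide distances (rooted on
#' the outgroup), and the full fit + selection rerun; reports the fraction
#' of replicates selecting each model and the fraction agreeing with the
#' full-data selection.
#'
#' @param alignment an [as_codon_alignment()] result.
#' @param tree rooted `phylo` with branch lengths (full-data reference).
#' @param scenarios list of [scenario_spec()] candidates.
#' @param outgroup tip name used to root replicate trees.
#' @param n_reps bootstrap pseudo-replicates.
#' @param seed RNG seed.
#' @param threshold null-rejection margin.
#' @return list: per-model support fractions, agreement fraction,
#'   reference report, replicate table.
#' @export
bootstrap_robustness <- function(alignment, tree, scenarios, outgroup,
                                 n_reps = 100, seed = 1, threshold = 5.22) {
  stopifnot(n_reps >= 1, outgroup %in% alignment$ids)
  run_selection <- function(aln, tr) {
    fits <- list(fit_model(aln, tr, "M1a"))
    for (sc in scenarios) {
      fits <- c(fits, list(fit_model(aln, tr, "BSA", scenario = sc),
                           fit_model(aln, tr, "BSA1", scenario = sc)))
    }
    select_model(fits, threshold = threshold)
  }
  ref <- run_selection(alignment, tree)
  ref_label <- fit_label(ref$best_model, ref$best_scenario)

  set.seed(seed)
  labels <- character(0)
  n_failed <- 0
  nc <- alignment$n_codons
  for (r in seq_len(n_reps)) {
    res <- tryCatch({
      codons <- sample.int(nc, nc, replace = TRUE)
      cols <- as.vector(rbind(3 * codons - 2, 3 * codons - 1, 3 * codons))
      aln_b <- as_codon_alignment(aln_subset(alignment, cols = cols))
      dnab <- ape::as.DNAbin(t(sapply(aln_b$ids,
                                      function(id) aln_b$mat[id, ])))
      d <- ape::dist.dna(dnab, model = "TN93", pairwise.deletion = TRUE)
      d[!is.finite(d)] <- max(d[is.finite(d)], 0.5)
      tr_b <- ape::nj(d)
      tr_b <- ape::root(tr_b, outgroup = outgroup, resolve.root = TRUE)
      tr_b$edge.length <- pmax(tr_b$edge.length, 1e-8) * 3  # per codon
      sel <- run_selection(aln_b, tr_b)
      fit_label(sel$best_model, sel$best_scenario)
    }, error = function(e) NA_character_)
    if (is.na(res)) n_failed <- n_failed + 1 else labels <- c(labels, res)
  }
  denom <- max(length(labels), 1)
  support <- table(labels) / denom
  list(support = support,
       same_model_fraction = sum(labels == ref_label) / denom,
       reference = ref, n_effective = length(labels), n_failed = n_failed)
}
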