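# Stage (iv), part 1: Bayesian node-age estimation per gene on third codon
# positions under an uncorrelated lognormal relaxed clock (or strict clock),
# GTR+G+I, a constant-size coalescent prior, and a narrow normal root
# calibration.  The topology is fixed per gene; the sampler explores node
# ages, per-branch rates, clock and substitution parameters.

#' Configuration for a dating run
#'
#' Defaults pin the published analysis settings: a lognormal relaxed clock,
#' root calibration normal(31 Ma, SD 0.0001), a constant-theta coalescent
#' prior with theta sampled under a uniform prior on log theta over
#' [1e-3, 1e2], chain 2,000,000 / burn-in 1,000,000 / thinning 1,000.
#' `dating_preset("desk")` shortens the chain to 200,000 / 100,000 / 100
#' for routine use.
#'
#' @param clock "lognormal" or "strict".
#' @param root_age,root_sd root calibration (Ma).
#' @param theta_bounds bounds of the uniform-log coalescent theta prior.
#' @param chain,burnin,thin chain length, burn-in, sampling interval
#'   (generations).
#' @param ncat discrete gamma categories.
#' @param seed RNG seed.
#' @return object of class `clock_config`.
#' @export
clock_config <- function(clock = c("lognormal", "strict"),
                         root_age = 31, root_sd = 0.0001,
                         theta_bounds = c(1e-3, 1e2),
                         chain = 2e6, burnin = 1e6, thin = 1000,
                         ncat = 4, seed = 1) {
  clock <- match.arg(clock)
  stopifnot(burnin < chain, thin >= 1, (chain - burnin) %% thin == 0,
            root_sd > 0, theta_bounds[1] > 0,
            theta_bounds[2] > theta_bounds[1])
  structure(list(clock = clock, root_age = root_age, root_sd = root_sd,
                 theta_bounds = theta_bounds, chain = as.integer(chain),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 ncat = as.integer(ncat), seed = as.integer(seed)),
            class = "clock_config")
}

#' @rdname clock_config
#' @param name "published" (the study's chain settings) or "desk" (short chain).
#' @param ... overrides passed to [clock_config()].
#' @export
dating_preset <- function(name = c("desk", "published"), ...) {
  name <- match.arg(name)
  args <- list(...)
  if (name == "desk")
    args <- utils::modifyList(list(chain = 2e5, burnin = 1e5, thin = 100),
                              args)
  do.call(clock_config, args)
}

# effective sample size via the initial-positive-sequence estimator
ess <- function(x) {
  n <- length(x)
  if (n < 10 || stats::var(x) == 0) return(n)
  acf_x <- stats::acf(x, lag.max = min(n - 1, 500), plot = FALSE)$acf[-1]
  s <- 0
  for (k in seq_along(acf_x)) {
    if (acf_x[k] < 0) break
    s <- s + acf_x[k]
  }
  max(1, n / (1 + 2 * s))
}

#' Sample node-age posteriors for one gene
#'
#' Metropolis-Hastings over node ages (slide moves respecting
#' parent > child), i.i.d. lognormal per-branch rates with the clock SD
#' sampled (strict clock: single rate), GTR+G+I parameters, and the
#' coalescent theta.  Proposal scales adapt during burn-in only.  Initial
#' internal ages are taken from the input tree when it is dated, otherwise
#' node depths are scaled so the root starts at the calibration age.
#'
#' @param alignment a [seq_alignment()] (use [third_positions()] output for
#'   coding genes).
#' @param tree rooted binary `phylo` giving the fixed topology.
#' @param config a [clock_config()].
#' @param outgroup outgroup tip name (must be a child of the root).
#' @return object of class `age_posterior`: samples (one column per
#'   internal node age plus parameters), ESS per column, acceptance rates.
#' @export
run_dating <- function(alignment, tree, config = dating_preset("desk"),
                       outgroup = NULL) {
  validate_rooted_tree(tree, require_binary = TRUE)
  stopifnot(inherits(config, "clock_config"))
  ntip <- length(tree$tip.label)
  if (ntip < 4) stop("dating requires at least 4 taxa")
  if (!is.null(outgroup)) {
    if (!outgroup %in% tree$tip.label)
      stop("outgroup not in tree: ", outgroup)
    root_children <- tree$edge[tree$edge[, 1] == ntip + 1L, 2]
    if (!match(outgroup, tree$tip.label) %in% root_children)
      warning("outgroup is not a child of the root; the root calibration ",
              "applies to the tree's root as given")
  }
  lay <- tree_pruning_layout(tree)
  st <- states_for_tree(nuc_states(alignment), tree)
  pat <- compress_patterns(st)
  states <- pat$states
  states[is.na(states)] <- 0L
  if (all(apply(states, 2, function(col) {
    v <- col[col > 0]
    length(unique(v)) <= 1
  }))) message("zero-variation alignment: posterior is prior-dominated")

  # initial ages: from the tree if dated, else scaled node depths
  ages <- tryCatch({
    a <- node_ages(tree)
    if (is.null(tree$edge.length) || max(a) <= 0) stop("undated")
    a * (config$root_age / max(a))
  }, error = function(e) NULL)
  if (is.null(ages)) {
    tr0 <- tree
    tr0$edge.length <- rep(1, nrow(tree$edge))
    a <- node_ages(tr0)
    ages <- a * (config$root_age / max(a))
  }
  ages[seq_len(ntip)] <- 0

  cnt <- table(factor(st, levels = 1:4))
  base_freq <- as.vector((cnt + 1) / sum(cnt + 1))

  # crude initial clock rate from mean tip divergence
  p_diff <- mean(vapply(seq_len(ncol(states)), function(j) {
    v <- states[, j]; v <- v[v > 0]
    if (length(v) < 2) return(0)
    mean(v != v[1])
  }, 0) * pat$weights) * length(pat$weights) / sum(pat$weights)
  mu_init <- max(p_diff / (2 * config$root_age), 1e-5)

  res <- dating_mcmc_cpp(states, pat$weights, lay$edges, ntip,
                         lay$n_nodes, lay$root, ages, base_freq,
                         config$root_age, config$root_sd,
                         log(config$theta_bounds[1]),
                         log(config$theta_bounds[2]),
                         config$chain, config$burnin, config$thin,
                         config$clock == "lognormal", mu_init,
                         config$ncat, config$seed)
  node_ids <- (ntip + 1):lay$n_nodes
  cn <- c(paste0("age_", node_ids), "mu", "S", "alpha", "p_inv", "theta",
          paste0("exch_", c("AC", "AG", "AT", "CG", "CT", "GT")),
          "loglik", "logprior")
  samples <- res$samples
  colnames(samples) <- cn
  ess_vals <- vapply(seq_len(ncol(samples)), function(j) ess(samples[, j]),
                     0)
  names(ess_vals) <- cn
  low <- ess_vals[grep("^age_", cn)] < 100
  if (any(low))
    warning("ESS below 100 for nodes: ",
            paste(sub("age_", "", names(low)[low]), collapse = ", "))
  structure(list(samples = samples, ess = ess_vals,
                 acceptance = res$acceptance, tree = tree,
                 config = config, node_ids = node_ids),
            class = "age_posterior")
}

#' @export
print.age_posterior <- function(x, ...) {
  cat(sprintf("<age_posterior> %d samples, %d internal nodes (min ESS %.0f)\n",
              nrow(x$samples), length(x$node_ids),
              min(x$ess[grep('^age_', names(x$ess))])))
  invisible(x)
}

#' Summarize node-age posteriors into per-gene records
#'
#' Each label resolves to the MRCA of the *available* representatives of
#' its two defining tip sets (monophyly is not enforced); labels with an
#' unrepresented side are skipped.  Quantiles are empirical with linear
#' interpolation.
#'
#' @param posterior an [run_dating()] result.
#' @param node_labels named list: label -> list(tips_a, tips_b).
#' @param gene gene id recorded in the output.
#' @return data.frame: gene, node, n_taxa, median, q025, q25, q75, q975,
#'   ess.
#' @export
summarize_ages <- function(posterior, node_labels, gene = "gene") {
  stopifnot(inherits(posterior, "age_posterior"))
  tree <- posterior$tree
  out <- list()
  for (lab in names(node_labels)) {
    sides <- lapply(node_labels[[lab]], intersect, y = tree$tip.label)
    if (any(vapply(sides, length, 0L) == 0)) {
      message("label ", lab, " skipped: side unrepresented")
      next
    }
    node <- mrca_of(tree, unique(unlist(sides)))
    col <- paste0("age_", node)
    x <- posterior$samples[, col]
    q <- stats::quantile(x, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE)
    out[[lab]] <- data.frame(gene = gene, node = lab,
                             n_taxa = length(unlist(sides)),
                             median = q[3], q025 = q[1], q25 = q[2],
                             q75 = q[4], q975 = q[5],
                             ess = unname(posterior$ess[col]))
  }
  if (length(out) == 0)
    return(data.frame(gene = character(0), node = character(0),
                      n_taxa = integer(0), median = numeric(0),
                      q025 = numeric(0), q25 = numeric(0),
                      q75 = numeric(0), q975 = numeric(0),
                      ess = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
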