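# Substitution models: GTR+G+I for nucleotides and a GY94-style codon model
# with site classes for the M1a / branch-site (BSA, BSA1) family.
# Universal genetic code, 61 sense codons.

NUC <- c("A", "C", "G", "T")

.codon_env <- new.env(parent = emptyenv())

codon_tables <- function() {
  if (!is.null(.codon_env$tab)) return(.codon_env$tab)
  gc <- Biostrings::GENETIC_CODE
  all64 <- names(gc)
  sense <- all64[gc != "*"]
  aa <- gc[sense]
  # single-nucleotide neighbour structure
  n <- length(sense)
  split3 <- do.call(rbind, strsplit(sense, ""))
  pairs_i <- integer(0); pairs_j <- integer(0)
  is_ts <- logical(0); is_syn <- logical(0); pos <- integer(0)
  transitions <- c(AG = TRUE, GA = TRUE, CT = TRUE, TC = TRUE)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    diff <- which(split3[i, ] != split3[j, ])
    if (length(diff) != 1) next
    pairs_i <- c(pairs_i, i); pairs_j <- c(pairs_j, j)
    key <- paste0(split3[i, diff], split3[j, diff])
    is_ts <- c(is_ts, isTRUE(transitions[key]))
    is_syn <- c(is_syn, aa[i] == aa[j])
    pos <- c(pos, diff)
  }
  lookup <- stats::setNames(rep(NA_integer_, 0), character(0))
  lookup <- stats::setNames(match(all64, sense), all64)
  lookup[gc == "*"] <- 0L
  .codon_env$tab <- list(codons = sense, aa = aa, split3 = split3,
                         i = pairs_i, j = pairs_j, ts = is_ts,
                         syn = is_syn, pos = pos, lookup = lookup)
  .codon_env$tab
}

# full lookup vector: codon string -> 1..61, 0 for stops, NA otherwise
codon_lookup <- function() codon_tables()$lookup

#' Codon equilibrium frequencies by the F3x4 convention
#'
#' Position-specific base frequencies multiplied across the three codon
#' positions, renormalized over the 61 sense codons.  `equal = TRUE` returns
#' the uniform distribution instead.
#'
#' @param x a `codon_alignment` (ignored when `equal = TRUE`).
#' @param equal use equal frequencies.
#' @return numeric vector of 61 frequencies summing to 1.
#' @export
codon_frequencies <- function(x = NULL, equal = FALSE) {
  tab <- codon_tables()
  if (equal) return(stats::setNames(rep(1 / 61, 61), tab$codons))
  stopifnot(inherits(x, "codon_alignment"))
  f <- matrix(0, 3, 4, dimnames = list(NULL, NUC))
  for (p in 1:3) {
    cols <- x$mat[, seq(p, ncol(x$mat), by = 3), drop = FALSE]
    cnt <- table(factor(cols[cols %in% NUC], levels = NUC))
    f[p, ] <- (cnt + 1) / sum(cnt + 1)  # add-one smoothing
  }
  pi <- f[1, tab$split3[, 1]] * f[2, tab$split3[, 2]] * f[3, tab$split3[, 3]]
  stats::setNames(pi / sum(pi), tab$codons)
}

#' GY94-style codon rate generator
#'
#' Off-diagonal rate i->j is nonzero only for single-nucleotide changes to a
#' sense codon, and equals `pi[j] * kappa^[transition] * omega^[nonsynonymous]`.
#' Rows sum to zero.  No scaling is applied here; see
#' [codon_mixture_scale()].
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega nonsynonymous/synonymous rate ratio (>= 0).
#' @param pi 61 sense-codon frequencies.
#' @return 61 x 61 rate matrix.
#' @export
build_codon_rates <- function(kappa, omega, pi) {
  stopifnot(kappa > 0, omega >= 0, length(pi) == 61)
  tab <- codon_tables()
  Q <- matrix(0, 61, 61, dimnames = list(tab$codons, tab$codons))
  rate <- pi[tab$j] * ifelse(tab$ts, kappa, 1) * ifelse(tab$syn, 1, omega)
  Q[cbind(tab$i, tab$j)] <- rate
  diag(Q) <- -rowSums(Q)
  Q
}

# expected flux -sum pi_i Q_ii of one generator
generator_rate <- function(Q, pi) -sum(pi * diag(Q))

#' Mixture scaling factor for a set of codon site classes
#'
#' Branch lengths are expected substitutions per codon under the site-class
#' mixture on background branches; all class generators (background and
#' foreground) are divided by this one factor so classes share a time scale.
#'
#' @param classes data.frame with columns `prop`, `omega_bg`.
#' @param kappa,pi as in [build_codon_rates()].
#' @export
codon_mixture_scale <- function(classes, kappa, pi) {
  s <- 0
  for (k in seq_len(nrow(classes))) {
    Q <- build_codon_rates(kappa, classes$omega_bg[k], pi)
    s <- s + classes$prop[k] * generator_rate(Q, pi)
  }
  s
}

# eigen system of a reversible generator via pi-symmetrization
eig_rev <- function(Q, pi) {
  sq <- sqrt(pi)
  B <- (sq * Q) %*% diag(1 / sq)  # diag(sq) %*% Q %*% diag(1/sq)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(U = (1 / sq) * e$vectors,
       Uinv = t(e$vectors) * rep(sq, each = ncol(Q)),
       lambda = e$values)
}

#' Discrete gamma category rates (category means)
#'
#' @param alpha gamma shape (> 0).
#' @param ncat number of categories.
#' @return rates with mean 1.
#' @export
discrete_gamma_rates <- function(alpha, ncat = 4) {
  stopifnot(alpha > 0, ncat >= 1)
  if (ncat == 1) return(1)
  b <- stats::qgamma(seq(0, 1, length.out = ncat + 1), shape = alpha,
                     rate = alpha)
  p <- stats::pgamma(b, shape = alpha + 1, rate = alpha)
  ncat * diff(p)
}

#' GTR+G+I nucleotide model
#'
#' @param rates six relative exchangeabilities (AC, AG, AT, CG, CT, GT).
#' @param base_freq equilibrium base frequencies (A, C, G, T).
#' @param alpha gamma shape for among-site rate variation.
#' @param ncat discrete gamma categories.
#' @param p_inv proportion of invariant sites in [0, 1).
#' @return object of class `gtr_model` holding the normalized generator.
#' @export
gtr_model <- function(rates = rep(1, 6), base_freq = rep(0.25, 4),
                      alpha = 1, ncat = 4, p_inv = 0) {
  stopifnot(length(rates) == 6, all(rates > 0),
            length(base_freq) == 4, abs(sum(base_freq) - 1) < 1e-8,
            alpha > 0, p_inv >= 0, p_inv < 1)
  Q <- matrix(0, 4, 4, dimnames = list(NUC, NUC))
  idx <- 1
  for (i in 1:3) for (j in (i + 1):4) {
    Q[i, j] <- rates[idx] * base_freq[j]
    Q[j, i] <- rates[idx] * base_freq[i]
    idx <- idx + 1
  }
  diag(Q) <- -rowSums(Q)
  Q <- Q / generator_rate(Q, base_freq)
  structure(list(Q = Q, rates = rates, base_freq = base_freq,
                 alpha = alpha, ncat = ncat, p_inv = p_inv),
            class = "gtr_model")
}

# mixture-class description of a GTR+G+I model for the pruning engine:
# ncat gamma classes (rates scaled by 1/(1-p_inv)) plus an invariant class
gtr_classes <- function(model) {
  g <- discrete_gamma_rates(model$alpha, model$ncat)
  if (model$p_inv > 0) {
    list(rates = c(g / (1 - model$p_inv), 0),
         props = c(rep((1 - model$p_inv) / model$ncat, model$ncat),
                   model$p_inv))
  } else {
    list(rates = g, props = rep(1 / model$ncat, model$ncat))
  }
}

#' Site-class layout of the M1a / BSA / BSA1 codon models
#'
#' M1a: two classes, (p0, omega0 < 1) and (1 - p0, 1), identical on all
#' branches.  The branch-site alternatives add classes 2a/2b whose
#' foreground ratio omega2 is free (BSA1) or fixed at 1 (BSA), with the
#' remainder mass split proportionally p0 : p1.
#'
#' @param model one of "M1a", "BSA", "BSA1".
#' @param p0,p1 class proportions (p1 ignored for M1a).
#' @param omega0 purifying-class ratio in (0, 1).
#' @param omega2 foreground positive-selection ratio (BSA1 only, >= 1).
#' @return data.frame with columns prop, omega_bg, omega_fg.
#' @export
site_classes <- function(model, p0, omega0, p1 = NULL, omega2 = NULL) {
  model <- match.arg(model, c("M1a", "BSA", "BSA1"))
  if (model == "M1a") {
    stopifnot(p0 > 0, p0 < 1, omega0 >= 0, omega0 < 1)
    return(data.frame(prop = c(p0, 1 - p0),
                      omega_bg = c(omega0, 1),
                      omega_fg = c(omega0, 1)))
  }
  stopifnot(!is.null(p1), p0 > 0, p1 > 0, p0 + p1 < 1)
  w2 <- if (model == "BSA") 1 else omega2
  stopifnot(!is.null(w2), w2 >= 1)
  p2 <- 1 - p0 - p1
  data.frame(prop = c(p0, p1, p2 * p0 / (p0 + p1), p2 * p1 / (p0 + p1)),
             omega_bg = c(omega0, 1, omega0, 1),
             omega_fg = c(omega0, 1, w2, w2))
}
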