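## Per-site codon likelihoods by Felsenstein pruning under a discrete
## omega-class mixture. Gaps/ambiguities are missing data (partial
## likelihood 1 over all 61 states); per-node rescaling guards underflow.

# Compress alignment columns into unique site patterns.
site_patterns <- function(m) {
  key <- apply(m, 2, paste, collapse = "\r")
  u <- !duplicated(key)
  list(pattern = m[, u, drop = FALSE],
       weight = as.vector(table(factor(key, levels = key[u]))),
       map = match(key, key[u]))
}

# Indicator (61 x npat) partial-likelihood matrices for every tip.
tip_indicators <- function(tipstate) {
  npat <- ncol(tipstate)
  lapply(seq_len(nrow(tipstate)), function(tip) {
    s <- tipstate[tip, ]
    Lc <- matrix(1, 61, npat)
    ok <- !is.na(s)
    Lc[, ok] <- 0
    Lc[cbind(s[ok], which(ok))] <- 1
    Lc
  })
}

# Pruning for one set of per-edge transition matrices.
# Returns log site likelihood per pattern.
prune_loglik <- function(tipind, tree, Plist, pi) {
  ntip <- length(tree$tip.label)
  npat <- ncol(tipind[[1]])
  edge <- tree$edge
  nnode <- max(edge)
  partial <- vector("list", nnode)
  logscale <- rep(0, npat)
  # postorder guarantees every edge below a node precedes the node's own edge
  for (i in seq_len(nrow(edge))) {
    pa <- edge[i, 1]
    ch <- edge[i, 2]
    if (ch <= ntip) {
      Lc <- tipind[[ch]]
    } else {
      Lc <- partial[[ch]]
      f <- .colSums(Lc, 61, npat)   # positive-sum rescaling against underflow
      f[f <= 0] <- 1
      Lc <- Lc / rep(f, each = 61)
      logscale <- logscale + log(f)
    }
    contrib <- Plist[[i]] %*% Lc
    partial[[pa]] <- if (is.null(partial[[pa]])) contrib else partial[[pa]] * contrib
  }
  root <- edge[nrow(edge), 1]
  drop(log(pi %*% partial[[root]])) + logscale
}

# Core mixture log-likelihood. Returns total lnL plus per-site per-class
# log-likelihoods (sites x classes) and the class table.
codon_mixture_loglik <- function(aln, tree, kappa, pi, classes,
                                 warn_missing = TRUE) {
  stopifnot(inherits(aln, "codon_alignment"), inherits(tree, "phylo"))
  miss <- setdiff(tree$tip.label, aln$ids)
  if (length(miss))
    stop("tree leaves absent from alignment: ", paste(miss, collapse = ", "))
  tree <- ape::reorder.phylo(tree, "postorder")
  m <- aln$codon[tree$tip.label, , drop = FALSE]
  if (warn_missing && any(colSums(!is.na(m)) == 0))
    warning("site(s) with all-missing data contribute log-likelihood 0")
  pats <- site_patterns(m)
  bl <- tree$edge.length
  if (is.null(bl)) stop("tree has no branch lengths")
  bl <- pmax(bl, 0)
  Qs <- class_rate_matrices(classes, kappa, pi)
  nclass <- nrow(classes)
  tipind <- tip_indicators(pats$pattern)
  patll <- matrix(0, ncol(pats$pattern), nclass)
  for (k in seq_len(nclass)) {
    dec <- rate_matrix_eigen(Qs[[k]], pi)
    Plist <- lapply(bl, function(t) transition_probs(dec, t))
    patll[, k] <- prune_loglik(tipind, tree, Plist, pi)
  }
  # log( sum_k prop_k exp(patll_k) ) via log-sum-exp
  lw <- log(pmax(classes$prop, 1e-300))
  a <- sweep(patll, 2, lw, "+")
  mx <- apply(a, 1, max)
  site_mix <- mx + log(rowSums(exp(a - mx)))
  loglik <- sum(pats$weight * site_mix)
  site_class_ll <- patll[pats$map, , drop = FALSE]
  site_ll <- site_mix[pats$map]
  post <- exp(sweep(site_class_ll, 2, lw, "+") - site_ll)
  list(loglik = loglik, site_loglik = site_ll,
       site_class_loglik = site_class_ll, posterior = post,
       classes = classes)
}

#' Per-site codon likelihoods under a site model
#'
#' Computes, for a fixed parameterization of one of the codon site models,
#' the per-site per-class likelihood contributions, the total
#' log-likelihood, and the naive empirical Bayes (NEB) posterior
#' probabilities of class membership for every site.
#'
#' @param aln A \code{\link{codon_alignment}}.
#' @param tree An \code{ape} \code{phylo} tree with branch lengths in
#'   expected substitutions per codon; its leaves must be a subset of the
#'   alignment ids.
#' @param model Site model name (\code{"M0"} ... \code{"M8"}).
#' @param params Named list of model parameters
#'   (see \code{\link{site_class_distribution}}).
#' @param kappa Transition/transversion ratio.
#' @param pi Codon frequencies; defaults to equal.
#' @param ncat Beta discretization categories for M7/M8.
#' @return List with \code{loglik}, \code{site_loglik} (length = sites),
#'   \code{posterior} (sites x classes NEB matrix, rows sum to 1) and the
#'   expanded \code{classes} table.
#' @export
site_likelihoods <- function(aln, tree, model, params, kappa = 2,
                             pi = NULL, ncat = 10L) {
  if (is.null(pi)) pi <- codon_frequencies(method = "equal")
  classes <- site_class_distribution(model, params, ncat = ncat)
  codon_mixture_loglik(aln, tree, kappa, pi, classes)
}
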