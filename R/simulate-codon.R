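## Forward simulation of codon alignments under discrete omega-class
## site models on a fixed tree.

#' Simulate a codon alignment under a site model
#'
#' Evolves codon sites down a tree under a GY94 site-class mixture: each
#' site draws an omega class from the class proportions, a root codon from
#' the equilibrium frequencies, and descendant states through the
#' class-specific transition probabilities. The true class label of every
#' site is recorded, so simulated data carry full ground truth for
#' recovery experiments.
#'
#' @param tree \code{phylo} tree with branch lengths (expected substitutions
#'   per codon per unit time; the mixture is scaled to rate 1).
#' @param model,params Site model and parameters
#'   (see \code{\link{site_class_distribution}}).
#' @param n_sites Number of codon sites.
#' @param kappa Transition/transversion ratio.
#' @param pi Codon frequencies (default equal).
#' @param seed Integer seed; the simulation is deterministic given it.
#' @param ncat Beta discretization categories for M7/M8.
#' @return A \code{\link{codon_alignment}} with attributes
#'   \code{class_labels} (true class index per site) and \code{classes}
#'   (the class table used).
#' @export
simulate_codon_alignment <- function(tree, model, params, n_sites,
                                     kappa = 2, pi = NULL, seed = NULL,
                                     ncat = 10L) {
  stopifnot(inherits(tree, "phylo"), n_sites >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(pi)) pi <- codon_frequencies(method = "equal")
  classes <- site_class_distribution(model, params, ncat = ncat)
  Qs <- class_rate_matrices(classes, kappa, pi)
  decs <- lapply(Qs, function(Q) rate_matrix_eigen(Q, pi))
  tree <- ape::reorder.phylo(tree, "postorder")
  edge <- tree$edge[rev(seq_len(nrow(tree$edge))), , drop = FALSE]  # preorder
  bl <- pmax(tree$edge.length[rev(seq_len(nrow(tree$edge)))], 0)
  ntip <- length(tree$tip.label)
  nnode <- max(edge)
  root <- edge[1, 1]
  lab <- sample.int(nrow(classes), n_sites, replace = TRUE, prob = classes$prop)
  state <- matrix(NA_integer_, nnode, n_sites)
  state[root, ] <- sample.int(61, n_sites, replace = TRUE, prob = pi)
  # per class, per edge transition matrices with row-wise cumulative sums
  for (k in seq_len(nrow(classes))) {
    sites_k <- which(lab == k)
    if (!length(sites_k)) next
    for (i in seq_len(nrow(edge))) {
      P <- transition_probs(decs[[k]], bl[i])
      P <- P / rowSums(P)
      pa <- edge[i, 1]; ch <- edge[i, 2]
      from <- state[pa, sites_k]
      state[ch, sites_k] <- vapply(from, function(s)
        sample.int(61, 1, prob = P[s, ]), integer(1))
    }
  }
  m <- state[seq_len(ntip), , drop = FALSE]
  rownames(m) <- tree$tip.label
  structure(list(ids = tree$tip.label, codon = m),
            class = "codon_alignment",
            class_labels = lab, classes = classes)
}
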