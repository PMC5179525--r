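## Seeded simulation-recovery experiments for the site models: simulate
## replicate alignments under known parameters on random trees and refit,
## returning the per-replicate estimates. Used to validate estimator
## calibration at study-like problem sizes.

# random unrooted tree with total branch length rescaled to a target
random_scaled_tree <- function(n_taxa, total_length = 2) {
  tr <- ape::rtree(n_taxa, rooted = FALSE)
  tr$edge.length <- tr$edge.length / sum(tr$edge.length) * total_length
  tr
}

#' M0 omega recovery experiment
#'
#' Simulates replicate codon alignments under the one-ratio model M0 on
#' random trees and refits M0 to each, returning the maximum-likelihood
#' omega estimates. Each replicate draws its own tree and alignment from a
#' seed derived deterministically from \code{base_seed}.
#'
#' @param omega Generating dN/dS.
#' @param n_rep Number of replicates (default 20).
#' @param n_taxa Taxa per alignment (default 8).
#' @param n_codons Codon sites per alignment (default 300).
#' @param kappa Generating (and starting) transition/transversion ratio.
#' @param tree_length Total tree length in expected substitutions per codon
#'   (default 2).
#' @param base_seed Master seed.
#' @return data.frame with one row per replicate: \code{rep}, \code{seed},
#'   \code{omega_hat}, \code{kappa_hat}, \code{lnl}, \code{converged}.
#' @export
m0_recovery_experiment <- function(omega, n_rep = 20, n_taxa = 8,
                                   n_codons = 300, kappa = 2,
                                   tree_length = 2, base_seed = 1) {
  pi <- codon_frequencies(method = "equal")
  out <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    seed_r <- (base_seed * 100 + r) %% .Machine$integer.max
    set.seed(seed_r)
    tr <- random_scaled_tree(n_taxa, tree_length)
    aln <- simulate_codon_alignment(tr, "M0", list(omega = omega),
                                    n_sites = n_codons, kappa = kappa, pi = pi)
    fit <- fit_site_model(aln, tr, "M0", pi = pi, kappa_init = kappa,
                          nstarts = 1)
    out[[r]] <- data.frame(rep = r, seed = seed_r,
                           omega_hat = fit$params$omega,
                           kappa_hat = fit$kappa, lnl = fit$logLik,
                           converged = fit$converged)
  }
  do.call(rbind, out)
}

#' M1 (nearly neutral) parameter recovery experiment
#'
#' As \code{\link{m0_recovery_experiment}}, simulating and refitting the
#' two-class nearly-neutral model M1a with purifying-class ratio
#' \code{omega0} and proportion \code{p0}.
#'
#' @param omega0 Generating purifying-class dN/dS (in (0,1)).
#' @param p0 Generating purifying-class proportion.
#' @param n_rep,n_taxa,n_codons,kappa,tree_length,base_seed See
#'   \code{\link{m0_recovery_experiment}}; defaults: 20 replicates, 8 taxa,
#'   500 codons.
#' @return data.frame with per-replicate \code{omega0_hat}, \code{p0_hat},
#'   \code{kappa_hat}, \code{lnl}, \code{converged}.
#' @export
m1_recovery_experiment <- function(omega0, p0, n_rep = 20, n_taxa = 8,
                                   n_codons = 500, kappa = 2,
                                   tree_length = 2, base_seed = 1) {
  pi <- codon_frequencies(method = "equal")
  out <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    seed_r <- (base_seed * 100 + r) %% .Machine$integer.max
    set.seed(seed_r)
    tr <- random_scaled_tree(n_taxa, tree_length)
    aln <- simulate_codon_alignment(tr, "M1",
                                    list(omega0 = omega0, p0 = p0),
                                    n_sites = n_codons, kappa = kappa, pi = pi)
    fit <- fit_site_model(aln, tr, "M1", pi = pi, kappa_init = kappa,
                          nstarts = 1)
    out[[r]] <- data.frame(rep = r, seed = seed_r,
                           omega0_hat = fit$params$omega0,
                           p0_hat = fit$params$p0,
                           kappa_hat = fit$kappa, lnl = fit$logLik,
                           converged = fit$converged)
  }
  do.call(rbind, out)
}
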