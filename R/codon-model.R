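## Codon substitution machinery: GY94-style rate matrices over the 61 sense
## codons of the universal genetic code, reversible transition probabilities,
## and discrete site-class (omega) mixtures.

# Internal cache for the codon-state bookkeeping (built once on first use).
.codon_env <- new.env(parent = emptyenv())

#' Sense codons of the universal genetic code
#'
#' Returns the 61 sense codons (universal code, stops TAA/TAG/TGA excluded)
#' in the fixed internal state order used by all rate-matrix and likelihood
#' functions of the package.
#'
#' @return Character vector of length 61, e.g. \code{"AAA"}, \code{"AAC"}, ...
#' @export
codon_states <- function() {
  codon_tables()$codons
}

# Build (and cache) the static codon tables: the 61 sense codons, their amino
# acids, and for every single-nucleotide codon pair whether the change is a
# transition and whether it is synonymous.
codon_tables <- function() {
  if (!is.null(.codon_env$tab)) return(.codon_env$tab)
  nt <- c("A", "C", "G", "T")
  grid <- expand.grid(p3 = nt, p2 = nt, p1 = nt, stringsAsFactors = FALSE)
  codons <- paste0(grid$p1, grid$p2, grid$p3)
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  keep <- aa != "*"
  codons <- codons[keep]
  aa <- aa[keep]
  n <- length(codons)
  stopifnot(n == 61L)
  cm <- matrix(unlist(strsplit(codons, "")), nrow = n, byrow = TRUE)
  # pairwise single-nucleotide neighbours
  ndiff <- matrix(0L, n, n)
  for (k in 1:3) ndiff <- ndiff + outer(cm[, k], cm[, k], "!=")
  single <- ndiff == 1L
  is_ti <- matrix(FALSE, n, n)   # transition (A<->G or C<->T) at the differing site
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  for (k in 1:3) {
    diff_k <- outer(cm[, k], cm[, k], "!=")
    ti_k <- outer(purine[cm[, k]], purine[cm[, k]], "==")
    is_ti <- is_ti | (single & diff_k & ti_k)
  }
  is_syn <- outer(aa, aa, "==")
  .codon_env$tab <- list(codons = codons, aa = aa, single = single,
                         is_ti = is_ti, is_syn = is_syn)
  .codon_env$tab
}

#' Codon equilibrium frequencies
#'
#' Computes codon frequencies either as equal (1/61) or by the F3x4 scheme
#' (products of the empirical nucleotide frequencies at the three codon
#' positions, renormalized over the sense codons).
#'
#' @param aln A \code{codon_alignment} (needed for \code{"F3x4"}), or
#'   \code{NULL} for \code{"equal"}.
#' @param method \code{"equal"} or \code{"F3x4"}.
#' @return Numeric vector of 61 frequencies summing to 1, named by codon.
#' @export
codon_frequencies <- function(aln = NULL, method = c("F3x4", "equal")) {
  method <- match.arg(method)
  tab <- codon_tables()
  if (method == "equal") {
    pi <- rep(1 / 61, 61)
    names(pi) <- tab$codons
    return(pi)
  }
  if (is.null(aln)) stop("an alignment is required for F3x4 frequencies")
  stopifnot(inherits(aln, "codon_alignment"))
  states <- aln$codon[!is.na(aln$codon)]
  if (!length(states)) stop("alignment has no resolved codons")
  cm <- matrix(unlist(strsplit(tab$codons[states], "")), ncol = 3, byrow = TRUE)
  nt <- c("A", "C", "G", "T")
  posfreq <- sapply(1:3, function(k) {
    f <- table(factor(cm[, k], levels = nt))
    as.numeric(f) / sum(f)
  })  # 4 x 3
  rownames(posfreq) <- nt
  cmall <- matrix(unlist(strsplit(tab$codons, "")), ncol = 3, byrow = TRUE)
  pi <- posfreq[cmall[, 1], 1] * posfreq[cmall[, 2], 2] * posfreq[cmall[, 3], 3]
  pi <- pi / sum(pi)
  names(pi) <- tab$codons
  pi
}

#' GY94 instantaneous rate matrix
#'
#' Builds the 61x61 Goldman-Yang codon rate matrix: the rate of a
#' single-nucleotide codon change i -> j is \eqn{\pi_j}, multiplied by
#' \eqn{\kappa} for transitions and by \eqn{\omega} for non-synonymous
#' changes; multi-nucleotide changes have rate 0 and the diagonal makes rows
#' sum to zero.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Non-synonymous/synonymous rate ratio dN/dS (>= 0).
#' @param pi Codon equilibrium frequencies (length 61, positive, sum 1).
#' @param scale If \code{TRUE} (default) the matrix is rescaled so that the
#'   expected number of substitutions per codon per unit time is 1. Pass
#'   \code{FALSE} to get the unscaled matrix (used internally when several
#'   site classes share a common mixture-level scaling).
#' @return 61x61 numeric matrix with zero row sums.
#' @export
build_rate_matrix <- function(kappa, omega, pi, scale = TRUE) {
  stopifnot(kappa > 0, omega >= 0, length(pi) == 61)
  if (any(pi <= 0) || abs(sum(pi) - 1) > 1e-8)
    stop("pi must be positive and sum to 1")
  tab <- codon_tables()
  if (is.null(.codon_env$idx)) {
    .codon_env$idx <- list(single = which(tab$single),
                           ti = which(tab$single & tab$is_ti),
                           ns = which(tab$single & !tab$is_syn))
  }
  idx <- .codon_env$idx
  Q <- matrix(0, 61, 61)
  Q[idx$single] <- rep(pi, each = 61)[idx$single]
  Q[idx$ti] <- Q[idx$ti] * kappa
  Q[idx$ns] <- Q[idx$ns] * omega
  diag(Q) <- -rowSums(Q)
  if (scale) {
    r <- -sum(pi * diag(Q))
    if (r > 0) Q <- Q / r
  }
  dimnames(Q) <- list(tab$codons, tab$codons)
  Q
}

# Symmetric eigendecomposition of a reversible rate matrix. Returns closures
# able to produce P(t) cheaply for many branch lengths.
rate_matrix_eigen <- function(Q, pi) {
  sp <- sqrt(pi)
  # S = D^{1/2} Q D^{-1/2}: element-wise S[i,j] = sp[i] * Q[i,j] / sp[j]
  S <- Q * outer(sp, 1 / sp)
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(values = e$values,
       left = e$vectors * rep(1 / sp, times = length(sp)),  # D^{-1/2} U
       right = t(e$vectors * rep(sp, times = length(sp))))  # U' D^{1/2}
}

# P(t) from a cached decomposition; rows clamped to [0,1] against round-off.
transition_probs <- function(decomp, t) {
  P <- (decomp$left * rep(exp(decomp$values * t), each = nrow(decomp$left))) %*%
    decomp$right
  P[P < 0] <- 0
  P
}

#' Site-class distribution of a codon site model
#'
#' Expands a site-model specification into its discrete omega classes.
#' Beta-distributed models (M7, M8) are discretized into
#' \code{ncat} equal-probability categories, each represented by its
#' conditional mean.
#'
#' @param model One of \code{"M0"}, \code{"M1"}, \code{"M2"}, \code{"M3"},
#'   \code{"M7"}, \code{"M8"}.
#' @param params Named list of model parameters:
#'   \describe{
#'     \item{M0}{\code{omega}}
#'     \item{M1}{\code{omega0} in (0,1), \code{p0}}
#'     \item{M2}{\code{omega0}, \code{p0}, \code{p1}, \code{omega2} >= 1}
#'     \item{M3}{\code{omega} (length 3), \code{p} (length 3, sums to 1)}
#'     \item{M7}{beta shape \code{p}, \code{q}}
#'     \item{M8}{\code{p}, \code{q}, \code{p0}, \code{omega_s} >= 1}
#'   }
#' @param ncat Number of beta discretization categories (default 10).
#' @return data.frame with columns \code{prop} and \code{omega}.
#' @export
site_class_distribution <- function(model, params, ncat = 10L) {
  model <- match.arg(model, c("M0", "M1", "M2", "M3", "M7", "M8"))
  out <- switch(model,
    M0 = data.frame(prop = 1, omega = params$omega),
    M1 = data.frame(prop = c(params$p0, 1 - params$p0),
                    omega = c(params$omega0, 1)),
    M2 = data.frame(prop = c(params$p0, params$p1, 1 - params$p0 - params$p1),
                    omega = c(params$omega0, 1, params$omega2)),
    M3 = data.frame(prop = params$p, omega = params$omega),
    M7 = data.frame(prop = rep(1 / ncat, ncat),
                    omega = beta_category_means(params$p, params$q, ncat)),
    M8 = data.frame(prop = c(rep(params$p0 / ncat, ncat), 1 - params$p0),
                    omega = c(beta_category_means(params$p, params$q, ncat),
                              params$omega_s))
  )
  if (any(out$prop < -1e-9) || abs(sum(out$prop) - 1) > 1e-6)
    stop("class proportions must be non-negative and sum to 1")
  out$prop <- pmax(out$prop, 0)
  out$prop <- out$prop / sum(out$prop)
  out
}

# Conditional means of a Beta(p,q) within ncat equal-probability bins:
# E[X | bin] = (p/(p+q)) * (I(b_hi; p+1, q) - I(b_lo; p+1, q)) * ncat
# where I is the regularized incomplete beta (pbeta).
beta_category_means <- function(p, q, ncat = 10L) {
  stopifnot(p > 0, q > 0, ncat >= 1)
  b <- suppressWarnings(stats::qbeta(seq(0, 1, length.out = ncat + 1), p, q))
  m <- (p / (p + q)) * diff(stats::pbeta(b, p + 1, q)) * ncat
  # guard degenerate bins from extreme shapes
  m[!is.finite(m)] <- 0
  pmin(pmax(m, 0), 1)
}

# Scaled per-class rate matrices for a mixture: the common scale factor makes
# the mixture-expected substitution rate per codon equal 1 (codeml style).
class_rate_matrices <- function(classes, kappa, pi) {
  Qs <- lapply(classes$omega, function(w) build_rate_matrix(kappa, w, pi, scale = FALSE))
  rates <- vapply(Qs, function(Q) -sum(pi * diag(Q)), numeric(1))
  mix_rate <- sum(classes$prop * rates)
  if (mix_rate <= 0) mix_rate <- 1
  lapply(Qs, function(Q) Q / mix_rate)
}
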