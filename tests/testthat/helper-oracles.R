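# Independent oracles used across tests. These deliberately avoid the
# package's own computational paths: matrix exponentials come from series
# summation, likelihoods from explicit ancestral-state enumeration, and
# clusterings from graph components.

# matrix exponential by scaling-and-squaring on a plain Taylor series
# (independent of the package's eigendecomposition path)
expm_taylor <- function(A, order = 24L, squarings = 12L) {
  A <- A / 2^squarings
  S <- diag(nrow(A))
  term <- diag(nrow(A))
  for (k in seq_len(order)) {
    term <- term %*% A / k
    S <- S + term
  }
  for (i in seq_len(squarings)) S <- S %*% S
  S
}

# Brute-force mixture log-likelihood by enumerating ancestral codon states.
# Supports the two shapes used in the oracle tests:
#   2 taxa:  (a:t1, b:t2);         L = sum_r pi_r P_r,a(t1) P_r,b(t2)
#   3 taxa:  ((a:t1, b:t2):t3, c:t4);
#            L = sum_r sum_u pi_r P_ru(t3) P_ua(t1) P_ub(t2) P_rc(t4)
# Gaps (NA states) marginalize by summing the corresponding P row to 1.
brute_force_loglik <- function(aln, tree, kappa, pi, classes) {
  Qs <- lrrkit:::class_rate_matrices(classes, kappa, pi)
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  m <- aln$codon[tree$tip.label, , drop = FALSE]
  n_sites <- ncol(m)
  total <- 0
  site_lik_class <- function(P, site) {
    prob_tip <- function(Pmat, row_states, s) {
      if (is.na(s)) rep(1, length(row_states)) else Pmat[row_states, s]
    }
    if (ntip == 2) {
      e1 <- which(tree$edge[, 2] == 1); e2 <- which(tree$edge[, 2] == 2)
      sum(pi * prob_tip(P[[e1]], 1:61, site[1]) *
            prob_tip(P[[e2]], 1:61, site[2]))
    } else {
      # locate the cherry internal node and the lone tip
      inner <- setdiff(tree$edge[, 1], ntip + 1)
      cherry_tips <- tree$edge[tree$edge[, 1] == inner, 2]
      lone <- setdiff(1:3, cherry_tips)
      e_inner <- which(tree$edge[, 2] == inner)
      e_lone <- which(tree$edge[, 2] == lone)
      ec <- vapply(cherry_tips, function(tp) which(tree$edge[, 2] == tp), 1L)
      acc <- 0
      for (r in 1:61) {
        inner_vec <- prob_tip(P[[ec[1]]], 1:61, site[cherry_tips[1]]) *
          prob_tip(P[[ec[2]]], 1:61, site[cherry_tips[2]])
        acc <- acc + pi[r] * prob_tip(P[[e_lone]], r, site[lone]) *
          sum(P[[e_inner]][r, ] * inner_vec)
      }
      acc
    }
  }
  Pall <- lapply(Qs, function(Q)
    lapply(tree$edge.length, function(t) expm_taylor(Q * t)))
  for (s in seq_len(n_sites)) {
    site <- m[, s]
    lik <- 0
    for (k in seq_len(nrow(classes)))
      lik <- lik + classes$prop[k] * site_lik_class(Pall[[k]], site)
    total <- total + log(lik)
  }
  total
}

# single-linkage proximity clustering oracle via graph components
single_linkage_oracle <- function(loci, window_bp) {
  out <- list()
  for (sc in unique(loci$scaffold)) {
    d <- loci[loci$scaffold == sc, ]
    n <- nrow(d)
    if (n < 2) next
    adj <- abs(outer(d$start, d$start, "-")) <= window_bp
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (adj[i, j] && comp[j] != comp[i]) {
          comp[comp == comp[j]] <- comp[i]; changed <- TRUE
        }
      }
      if (!changed) break
    }
    for (cc in unique(comp)) {
      ids <- d$gene_id[comp == cc]
      if (length(ids) >= 2)
        out[[length(out) + 1]] <- sort(ids)
    }
  }
  out
}

# random domain architecture generator for the membership property test
random_architecture <- function(id) {
  n_lrr <- sample(0:4, 1)
  n_tm <- sample(0:2, 1)
  n_kd <- sample(0:2, 1)
  pos <- 1
  mk <- function(n, w) {
    if (n == 0) return(NULL)
    iv <- matrix(0, n, 2)
    for (i in seq_len(n)) {
      gap <- sample(1:30, 1)
      iv[i, ] <- c(pos + gap, pos + gap + w)
      pos <<- iv[i, 2]
    }
    iv
  }
  # random order of blocks so topology violations occur often
  blocks <- sample(c("lrr", "tm", "kd"))
  iv <- list(lrr = NULL, tm = NULL, kd = NULL)
  for (b in blocks)
    iv[[b]] <- switch(b, lrr = mk(n_lrr, 22), tm = mk(n_tm, 20),
                      kd = mk(n_kd, 250))
  domain_architecture(id, lrr = iv$lrr, tm = iv$tm, kinase = iv$kd)
}

# literal re-check of the four membership conditions
membership_oracle <- function(arch) {
  has_lrr <- nrow(arch$lrr) >= 1
  has_tm <- nrow(arch$tm) >= 1
  one_kd <- nrow(arch$kinase) == 1
  topo <- has_lrr && has_tm && one_kd &&
    all(arch$lrr[, 2] < min(arch$tm[, 1])) &&
    arch$kinase[1, 1] > max(arch$tm[, 2])
  has_lrr && has_tm && one_kd && topo
}

# maximum bipartite matching of intron positions (tolerance + equal phase),
# by exhaustive recursion -- the oracle for the greedy matcher
max_intron_matching <- function(a, b, tol) {
  compat <- outer(a$offset, b$offset, function(x, y) abs(x - y) <= tol) &
    outer(a$phase, b$phase, "==")
  best <- 0
  recurse <- function(i, used_b, count) {
    if (i > nrow(a)) { best <<- max(best, count); return(invisible()) }
    recurse(i + 1, used_b, count)
    for (j in seq_len(nrow(b))) {
      if (!used_b[j] && compat[i, j]) {
        used_b[j] <- TRUE
        recurse(i + 1, used_b, count + 1)
        used_b[j] <- FALSE
      }
    }
  }
  if (nrow(a) && nrow(b)) recurse(1, rep(FALSE, nrow(b)), 0)
  best
}
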