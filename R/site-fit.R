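## Maximum-likelihood fitting of codon site models (M0, M1a, M2a, M3, M7,
## M8), likelihood-ratio tests between nested pairs, and NEB identification
## of positively selected sites.

# --- parameter packing -----------------------------------------------------
# Each model's free site-class parameters are mapped to an unconstrained
# vector: log for positive quantities, logit for (0,1), additive log-ratio
# for simplexes, and log(x - 1) for the omega >= 1 classes of M2/M8.

.logit <- function(p) log(p / (1 - p))
.inv_logit <- function(x) 1 / (1 + exp(-x))

# simplex (p1..pK) <-> alr relative to the last component
.alr <- function(p) log(p[-length(p)] / p[length(p)])
.inv_alr <- function(x) {
  e <- c(exp(x), 1)
  e / sum(e)
}

model_np <- c(M0 = 1L, M1 = 2L, M2 = 4L, M3 = 5L, M7 = 2L, M8 = 4L)

pack_params <- function(model, params) {
  switch(model,
    M0 = log(max(params$omega, 1e-6)),
    M1 = c(.logit(params$omega0), .logit(params$p0)),
    M2 = c(.logit(params$omega0),
           .alr(c(params$p0, params$p1, 1 - params$p0 - params$p1)),
           log(max(params$omega2 - 1, 1e-9))),
    M3 = c(log(pmax(params$omega, 1e-6)), .alr(params$p)),
    M7 = c(log(params$p), log(params$q)),
    M8 = c(log(params$p), log(params$q), .logit(params$p0),
           log(max(params$omega_s - 1, 1e-9)))
  )
}

unpack_params <- function(model, x) {
  switch(model,
    M0 = list(omega = exp(x[1])),
    M1 = list(omega0 = .inv_logit(x[1]), p0 = .inv_logit(x[2])),
    M2 = {
      p <- .inv_alr(x[2:3])
      list(omega0 = .inv_logit(x[1]), p0 = p[1], p1 = p[2],
           omega2 = 1 + exp(x[4]))
    },
    M3 = list(omega = exp(x[1:3]), p = .inv_alr(x[4:5])),
    M7 = list(p = exp(x[1]), q = exp(x[2])),
    M8 = list(p = exp(x[1]), q = exp(x[2]), p0 = .inv_logit(x[3]),
              omega_s = 1 + exp(x[4]))
  )
}

default_init <- function(model) {
  switch(model,
    M0 = list(omega = 0.3),
    M1 = list(omega0 = 0.2, p0 = 0.6),
    M2 = list(omega0 = 0.2, p0 = 0.55, p1 = 0.35, omega2 = 1.5),
    M3 = list(omega = c(0.05, 0.3, 0.8), p = c(0.4, 0.4, 0.2)),
    M7 = list(p = 0.5, q = 1.5),
    M8 = list(p = 0.5, q = 1.5, p0 = 0.9, omega_s = 1.5)
  )
}

jitter_init <- function(model, params) {
  x <- pack_params(model, params)
  unpack_params(model, x + stats::rnorm(length(x), 0, 0.5))
}

# --- fitting ---------------------------------------------------------------

#' Fit a codon site model by maximum likelihood
#'
#' Fits one of the six classic site models to a codon alignment on a fixed
#' tree topology, maximizing the log-likelihood over kappa, the omega-class
#' parameters (proportions on the simplex via an additive log-ratio
#' transform, omega >= 1 classes via a shifted log transform) and,
#' optionally, all branch lengths. Optimization uses quasi-Newton BFGS on
#' the transformed parameters with seeded multi-start to mitigate local
#' optima; the best start wins and the fit is never worse than its
#' initialization.
#'
#' @param aln A \code{\link{codon_alignment}}.
#' @param tree \code{phylo} tree; leaves must be alignment ids. Its branch
#'   lengths seed the branch-length estimates.
#' @param model One of \code{"M0"}, \code{"M1"}, \code{"M2"}, \code{"M3"},
#'   \code{"M7"}, \code{"M8"} (M1 = M1a nearly neutral, M2 = M2a positive
#'   selection).
#' @param codon_freq \code{"F3x4"} (default, frequencies from the data) or
#'   \code{"equal"}; ignored when \code{pi} is given.
#' @param pi Optional fixed codon frequency vector (length 61).
#' @param kappa_init Starting transition/transversion ratio.
#' @param init Optional named list of starting site-class parameters (e.g.
#'   mapped from a nested null fit via \code{\link{nested_start}}); may
#'   contain \code{kappa}.
#' @param optimize_branch_lengths Estimate branch lengths (default) or keep
#'   the input tree's fixed.
#' @param nstarts Number of seeded optimization starts (default 3).
#' @param seed Seed for the multi-start jitter.
#' @param ncat Beta discretization categories for M7/M8.
#' @param control Passed to \code{\link[stats]{optim}} (\code{maxit},
#'   \code{reltol}).
#' @return Object of class \code{site_model_fit} with the estimated
#'   parameters, class table, log-likelihood, NEB posteriors, fitted tree
#'   and convergence flag. Non-convergence is reported via the
#'   \code{converged} flag, never silently.
#' @seealso \code{\link{lrt}}, \code{\link{neb_positive_sites}},
#'   \code{\link{site_likelihoods}}
#' @export
fit_site_model <- function(aln, tree, model = c("M0", "M1", "M2", "M3", "M7", "M8"),
                           codon_freq = c("F3x4", "equal"), pi = NULL,
                           kappa_init = 2, init = NULL,
                           optimize_branch_lengths = TRUE,
                           nstarts = 3, seed = NULL, ncat = 10L,
                           control = list()) {
  model <- match.arg(model)
  codon_freq <- match.arg(codon_freq)
  freq_label <- if (is.null(pi)) codon_freq else "fixed"
  if (is.null(pi)) pi <- codon_frequencies(aln, method = codon_freq)
  tree <- ape::reorder.phylo(tree, "postorder")
  bl0 <- pmax(tree$edge.length, 1e-6)
  ctrl <- utils::modifyList(list(maxit = 500L, reltol = 1e-8), control)

  nb <- if (optimize_branch_lengths) length(bl0) else 0L
  make_theta <- function(params, kappa, bl) {
    c(log(kappa), pack_params(model, params),
      if (nb) log(pmax(bl, 1e-6)))
  }
  negll <- function(theta) {
    kappa <- exp(theta[1])
    pars <- unpack_params(model, theta[-1])
    tr <- tree
    if (nb) tr$edge.length <- exp(theta[(length(theta) - nb + 1):length(theta)])
    cl <- try(site_class_distribution(model, pars, ncat = ncat), silent = TRUE)
    if (inherits(cl, "try-error")) return(1e10)
    ll <- try(codon_mixture_loglik(aln, tr, kappa, pi, cl,
                                   warn_missing = FALSE)$loglik, silent = TRUE)
    if (inherits(ll, "try-error") || !is.finite(ll)) return(1e10)
    -ll
  }

  p0 <- if (is.null(init)) default_init(model) else
    utils::modifyList(default_init(model), init[setdiff(names(init), "kappa")])
  k0 <- if (!is.null(init$kappa)) init$kappa else kappa_init
  if (!is.null(seed)) set.seed(seed)
  starts <- list(list(params = p0, kappa = k0))
  if (nstarts > 1) {
    for (s in seq_len(nstarts - 1))
      starts[[s + 1]] <- list(params = jitter_init(model, p0),
                              kappa = k0 * exp(stats::rnorm(1, 0, 0.3)))
  }
  best <- NULL
  for (st in starts) {
    th0 <- make_theta(st$params, st$kappa, bl0)
    f0 <- negll(th0)
    opt <- try(stats::optim(th0, negll, method = "BFGS",
                            control = list(maxit = ctrl$maxit,
                                           reltol = ctrl$reltol)),
               silent = TRUE)
    if (inherits(opt, "try-error"))
      opt <- list(par = th0, value = f0, convergence = 1L)
    if (opt$value > f0) opt <- list(par = th0, value = f0, convergence = 1L)
    if (is.null(best) || opt$value < best$value) best <- opt
  }

  theta <- best$par
  kappa <- exp(theta[1])
  params <- unpack_params(model, theta[-1])
  fit_tree <- tree
  if (nb) fit_tree$edge.length <-
    exp(theta[(length(theta) - nb + 1):length(theta)])
  # report omega classes constrained >= 1 as exactly 1 when at the boundary
  if (model == "M2" && params$omega2 - 1 < 1e-4) params$omega2 <- 1
  if (model == "M8" && params$omega_s - 1 < 1e-4) params$omega_s <- 1
  # canonical class order for M3: ascending omega
  if (model == "M3") {
    o <- order(params$omega)
    params$omega <- params$omega[o]
    params$p <- params$p[o]
  }
  classes <- site_class_distribution(model, params, ncat = ncat)
  res <- codon_mixture_loglik(aln, fit_tree, kappa, pi, classes,
                              warn_missing = FALSE)
  structure(list(
    model = model, params = params, kappa = kappa, pi = pi,
    codon_freq = freq_label,
    classes = classes,
    logLik = res$loglik,
    np = model_np[[model]] + 1L + nb,  # class params + kappa + branch lengths
    n_sites = ncol(aln$codon), n_taxa = length(aln$ids),
    posterior = res$posterior,
    tree = fit_tree, ncat = ncat,
    converged = best$convergence == 0L,
    call = match.call()), class = "site_model_fit")
}

#' Map a nested null fit to starting values for its alternative model
#'
#' Produces starting parameters for an alternative model that reproduce a
#' fitted null model exactly (M0 -> M3 with three equal-omega classes,
#' M1 -> M2 with a vanishing third class at omega = 1, M7 -> M8 with a
#' vanishing extra class), so warm-started fits can only improve on the
#' null log-likelihood.
#'
#' @param fit_null A \code{site_model_fit} for M0, M1 or M7.
#' @param alt Name of the alternative model.
#' @return Named list of starting parameters (including \code{kappa}).
#' @export
nested_start <- function(fit_null, alt) {
  stopifnot(inherits(fit_null, "site_model_fit"))
  pair <- paste(fit_null$model, alt)
  p <- fit_null$params
  out <- switch(pair,
    "M0 M3" = list(omega = pmax(p$omega, 1e-5) * c(1 - 1e-5, 1, 1 + 1e-5),
                   p = c(1, 1, 1) / 3),
    "M1 M2" = list(omega0 = p$omega0, p0 = p$p0,
                   p1 = (1 - p$p0) * 0.99, omega2 = 1 + 1e-9),
    "M7 M8" = list(p = p$p, q = p$q, p0 = 1 - 1e-8, omega_s = 1 + 1e-9),
    stop("no nested mapping from ", fit_null$model, " to ", alt))
  out$kappa <- fit_null$kappa
  out
}

# --- methods ---------------------------------------------------------------

#' @export
print.site_model_fit <- function(x, ...) {
  cat("Codon site model", x$model, "fit:",
      x$n_taxa, "taxa x", x$n_sites, "codon sites\n")
  cat(sprintf("  lnL = %.4f  kappa = %.3f  np = %d%s\n", x$logLik, x$kappa,
              x$np, if (x$converged) "" else "  [did not converge]"))
  cl <- x$classes
  cat("  site classes:\n")
  for (i in seq_len(nrow(cl)))
    cat(sprintf("    class %d: p = %.4f, omega = %.4f\n", i, cl$prop[i],
                cl$omega[i]))
  invisible(x)
}

#' @method coef site_model_fit
#' @export
coef.site_model_fit <- function(object, ...) {
  c(kappa = object$kappa, unlist(object$params))
}

#' @method logLik site_model_fit
#' @export
logLik.site_model_fit <- function(object, ...) {
  structure(object$logLik, df = object$np, nobs = object$n_sites,
            class = "logLik")
}

#' @method summary site_model_fit
#' @export
summary.site_model_fit <- function(object, cutoff = 0.95, ...) {
  structure(list(fit = object,
                 positive = neb_positive_sites(object, cutoff = cutoff),
                 cutoff = cutoff),
            class = "summary.site_model_fit")
}

#' @export
print.summary.site_model_fit <- function(x, ...) {
  print(x$fit)
  pos <- x$positive
  if (nrow(pos)) {
    cat(sprintf("  %d site(s) with NEB posterior > %.2f for omega > 1:\n",
                nrow(pos), x$cutoff))
    cat("   ", paste(sprintf("%d (%.3f)", pos$site, pos$posterior),
                     collapse = ", "), "\n")
  } else {
    cat("  no sites with NEB support for positive selection",
        sprintf("(cutoff %.2f)\n", x$cutoff))
  }
  invisible(x)
}

#' @export
simulate.site_model_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i)
    simulate_codon_alignment(object$tree, object$model, object$params,
                             n_sites = object$n_sites, kappa = object$kappa,
                             pi = object$pi, ncat = object$ncat))
}

# --- likelihood ratio test -------------------------------------------------

.nested_pairs <- list(c("M0", "M3"), c("M1", "M2"), c("M7", "M8"))

#' Likelihood-ratio test between nested site models
#'
#' Compares a null and an alternative site-model fit with the statistic
#' 2|dlnL| (floored at zero) against a chi-square reference. Allowed pairs
#' and degrees of freedom: M0 vs M3 (df 4), M1 vs M2 (df 2), M7 vs M8
#' (df 2).
#'
#' @param fit_null,fit_alt \code{site_model_fit} objects, or bare numeric
#'   log-likelihoods (in which case \code{df} must be given).
#' @param df Degrees of freedom; inferred from the model pair when fits are
#'   supplied.
#' @param alpha Significance threshold (default 0.01).
#' @return List of class \code{codon_lrt}: \code{two_delta_lnl}, \code{df},
#'   \code{p_value}, \code{significant}.
#' @export
lrt <- function(fit_null, fit_alt, df = NULL, alpha = 0.01) {
  if (inherits(fit_null, "site_model_fit")) {
    pair <- c(fit_null$model, fit_alt$model)
    ok <- vapply(.nested_pairs, function(p) identical(p, pair), logical(1))
    if (!any(ok))
      stop("models ", pair[1], " and ", pair[2], " are not a supported nested pair")
    df <- c(4L, 2L, 2L)[which(ok)]
    ll0 <- fit_null$logLik; ll1 <- fit_alt$logLik
  } else {
    if (is.null(df)) stop("df must be supplied with bare log-likelihoods")
    ll0 <- fit_null; ll1 <- fit_alt
  }
  stat <- max(0, 2 * (ll1 - ll0))
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  structure(list(two_delta_lnl = stat, df = df, p_value = p,
                 significant = p < alpha, alpha = alpha),
            class = "codon_lrt")
}

#' @export
print.codon_lrt <- function(x, ...) {
  cat(sprintf("LRT: 2|dlnL| = %.5f, df = %d, P = %.4g (%s at alpha = %g)\n",
              x$two_delta_lnl, x$df, x$p_value,
              if (x$significant) "significant" else "not significant",
              x$alpha))
  invisible(x)
}

#' Positively selected sites by naive empirical Bayes
#'
#' Reports the alignment sites whose NEB posterior probability of belonging
#' to an omega > 1 class exceeds the cutoff.
#'
#' @param fit A \code{site_model_fit}.
#' @param cutoff Posterior probability cutoff (default 0.95).
#' @return data.frame with columns \code{site} (1-based codon position) and
#'   \code{posterior}. Empty, with a message, when the model has no
#'   omega > 1 class.
#' @export
neb_positive_sites <- function(fit, cutoff = 0.95) {
  stopifnot(inherits(fit, "site_model_fit"))
  pos_class <- which(fit$classes$omega > 1)
  if (!length(pos_class)) {
    message("model ", fit$model, " has no omega > 1 class; no sites to report")
    return(data.frame(site = integer(0), posterior = numeric(0)))
  }
  post <- rowSums(fit$posterior[, pos_class, drop = FALSE])
  keep <- which(post > cutoff)
  data.frame(site = keep, posterior = post[keep], row.names = NULL)
}
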