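# ML fitting of the site models, LRT plumbing, NEB site calls and the
# simulator's moment/stationarity properties.

test_that("M0 refit recovers the generating omega on a small alignment", {
  set.seed(31)
  tr <- ape::rtree(4, rooted = FALSE)
  tr$edge.length <- tr$edge.length / sum(tr$edge.length) * 1.5
  pi <- codon_frequencies(method = "equal")
  aln <- simulate_codon_alignment(tr, "M0", list(omega = 0.5), 200,
                                  kappa = 2, pi = pi, seed = 32)
  fit <- fit_site_model(aln, tr, "M0", pi = pi, nstarts = 1)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$omega - 0.5), 0.15)
  expect_s3_class(fit, "site_model_fit")
  expect_equal(unname(coef(fit)["omega"]), fit$params$omega)
  expect_equal(attr(logLik(fit), "df"), fit$np)
})

test_that("likelihood-ratio test handles the trivial and error cases", {
  z <- lrt(-100, -100, df = 4)
  expect_equal(z$two_delta_lnl, 0)
  expect_equal(z$p_value, 1)
  expect_false(z$significant)
  # floored at zero when the 'alternative' is worse numerically
  expect_equal(lrt(-100, -100.5, df = 2)$two_delta_lnl, 0)
  expect_error(lrt(-100, -90), "df must be supplied")
  stat <- lrt(-200, -180, df = 2)
  expect_equal(stat$two_delta_lnl, 40)
  expect_equal(stat$p_value, pchisq(40, 2, lower.tail = FALSE))
  expect_true(stat$significant)
})

test_that("non-nested model pairs are rejected", {
  set.seed(33)
  tr <- ape::read.tree(text = "((a:0.1,b:0.2):0.1,c:0.3);")
  pi <- codon_frequencies(method = "equal")
  aln <- simulate_codon_alignment(tr, "M0", list(omega = 0.3), 40,
                                  pi = pi, seed = 34)
  f0 <- fit_site_model(aln, tr, "M0", pi = pi, nstarts = 1,
                       control = list(maxit = 50))
  f1 <- fit_site_model(aln, tr, "M1", pi = pi, nstarts = 1,
                       control = list(maxit = 50))
  expect_error(lrt(f0, f1), "not a supported nested pair")
})

test_that("NEB reporting: no omega>1 class means an empty, flagged result", {
  set.seed(35)
  tr <- ape::read.tree(text = "(a:0.2,b:0.3);")
  pi <- codon_frequencies(method = "equal")
  aln <- simulate_codon_alignment(tr, "M0", list(omega = 0.3), 30,
                                  pi = pi, seed = 36)
  fit <- fit_site_model(aln, tr, "M0", pi = pi, nstarts = 1,
                        control = list(maxit = 50))
  expect_message(pos <- neb_positive_sites(fit), "no omega > 1 class")
  expect_equal(nrow(pos), 0)
})

test_that("NEB recovers planted positively selected sites under M2", {
  set.seed(37)
  tr <- ape::rtree(8, rooted = FALSE)
  tr$edge.length <- tr$edge.length / sum(tr$edge.length) * 4
  pi <- codon_frequencies(method = "equal")
  params <- list(omega0 = 0.05, p0 = 0.6, p1 = 0.2, omega2 = 8)
  aln <- simulate_codon_alignment(tr, "M2", params, 150, pi = pi, seed = 38)
  truth <- attr(aln, "class_labels") == 3
  # fixed-parameter NEB (no refit): posterior of the omega>1 class
  res <- site_likelihoods(aln, tr, "M2", params, kappa = 2, pi = pi)
  called <- res$posterior[, 3] > 0.95
  expect_gt(sum(called & truth), 0)              # non-trivial power
  expect_gt(mean(truth[called]), 0.9)            # calls are mostly true
})

test_that("simulation under omega = 0 produces no amino-acid change", {
  tr <- ape::read.tree(text = "(a:1.5,b:1.5);")
  pi <- codon_frequencies(method = "equal")
  aln <- simulate_codon_alignment(tr, "M0", list(omega = 0), 120,
                                  pi = pi, seed = 39)
  seqs <- as.character(aln)
  aa <- vapply(seqs, function(s)
    as.character(Biostrings::translate(Biostrings::DNAString(s))), "")
  expect_equal(unname(aa[1]), unname(aa[2]))
})

test_that("simulated codon frequencies approach pi on long branches", {
  tr <- ape::read.tree(text = "(a:60,b:60);")
  pi <- codon_frequencies(method = "equal")
  aln <- simulate_codon_alignment(tr, "M0", list(omega = 1), 2500,
                                  pi = pi, seed = 40)
  f <- tabulate(aln$codon, nbins = 61) / length(aln$codon)
  expect_lt(max(abs(f - 1 / 61)), 0.015)
})

test_that("transition/transversion balance in simulations tracks kappa", {
  tr <- ape::read.tree(text = "(a:0.08,b:0.08);")
  pi <- codon_frequencies(method = "equal")
  count_ti_tv <- function(kappa, seed) {
    aln <- simulate_codon_alignment(tr, "M0", list(omega = 1), 3000,
                                    kappa = kappa, pi = pi, seed = seed)
    tab <- lrrkit:::codon_tables()
    a <- aln$codon[1, ]; b <- aln$codon[2, ]
    diff1 <- which(a != b & tab$single[cbind(a, b)])
    ti <- sum(tab$is_ti[cbind(a[diff1], b[diff1])])
    c(ti = ti, tv = length(diff1) - ti)
  }
  hi <- count_ti_tv(8, 41)
  lo <- count_ti_tv(1, 42)
  expect_gt(hi["ti"] / max(hi["tv"], 1), 2 * lo["ti"] / max(lo["tv"], 1))
})

test_that("simulate() method and seed determinism", {
  set.seed(43)
  tr <- ape::read.tree(text = "(a:0.2,b:0.3);")
  pi <- codon_frequencies(method = "equal")
  aln <- simulate_codon_alignment(tr, "M0", list(omega = 0.4), 25,
                                  pi = pi, seed = 44)
  aln2 <- simulate_codon_alignment(tr, "M0", list(omega = 0.4), 25,
                                   pi = pi, seed = 44)
  aln3 <- simulate_codon_alignment(tr, "M0", list(omega = 0.4), 25,
                                   pi = pi, seed = 45)
  expect_identical(aln$codon, aln2$codon)
  expect_false(identical(aln$codon, aln3$codon))
  fit <- fit_site_model(aln, tr, "M0", pi = pi, nstarts = 1,
                        control = list(maxit = 30))
  sims <- simulate(fit, nsim = 2, seed = 46)
  expect_length(sims, 2)
  expect_equal(dim(sims[[1]]$codon), dim(aln$codon))
})

test_that("codon FASTA round-trip preserves the alignment", {
  tr <- ape::read.tree(text = "(a:0.2,b:0.3);")
  pi <- codon_frequencies(method = "equal")
  aln <- simulate_codon_alignment(tr, "M0", list(omega = 0.4), 20,
                                  pi = pi, seed = 47)
  aln$codon[2, 3] <- NA
  f <- tempfile(fileext = ".fasta")
  write_codon_fasta(aln, f)
  back <- read_codon_fasta(f)
  expect_identical(back$codon, aln$codon)
  # internal stops are rejected unless masked
  writeLines(c(">x", "ATGTAAAAA", ">y", "ATGAAAAAA"), f)
  expect_error(read_codon_fasta(f), "stop codon")
  expect_warning(masked <- read_codon_fasta(f, allow_stop = "mask"), "masked")
  expect_true(is.na(masked$codon["x", 2]))
})
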