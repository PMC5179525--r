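# Intron profiles from CDS intervals, per-subfamily structure summaries and
# pairwise intron sharing.

test_that("single-CDS genes have no introns; offsets and phases are exact", {
  p0 <- introns_from_cds(list(gene_id = "g", strand = "+",
                              cds = cbind(1, 300)))
  expect_equal(p0$n_introns, 0)
  p1 <- introns_from_cds(list(gene_id = "g", strand = "+",
                              cds = cbind(c(1, 401), c(300, 700))))
  expect_equal(p1$n_introns, 1)
  expect_equal(p1$positions$offset, 300)
  expect_equal(p1$positions$phase, 0L)
  # asymmetric exons distinguish the strands
  pp <- introns_from_cds(list(gene_id = "g", strand = "+",
                              cds = cbind(c(1, 201), c(100, 500))))
  expect_equal(pp$positions$offset, 100)
  expect_equal(pp$positions$phase, 1L)
  pm <- introns_from_cds(list(gene_id = "g", strand = "-",
                              cds = cbind(c(1, 201), c(100, 500))))
  expect_equal(pm$positions$offset, 300)
  expect_equal(pm$positions$phase, 0L)
  expect_error(introns_from_cds(list(gene_id = "g", strand = "+",
                                     cds = cbind(c(1, 50), c(60, 90)))),
               "overlapping")
})

test_that("random multi-exon genes match a coordinate-mapping oracle", {
  set.seed(91)
  for (i in 1:20) {
    n_ex <- sample(1:6, 1)
    lens <- sample(30:200, n_ex, replace = TRUE)
    gaps <- sample(50:500, n_ex, replace = TRUE)
    start <- 1000
    iv <- matrix(0, n_ex, 2)
    p <- start
    for (e in seq_len(n_ex)) {
      iv[e, ] <- c(p, p + lens[e] - 1)
      p <- iv[e, 2] + gaps[e] + 1
    }
    strand <- sample(c("+", "-"), 1)
    prof <- introns_from_cds(list(gene_id = "g", strand = strand, cds = iv))
    # oracle: enumerate genomic coding positions in transcription order and
    # record junctions where consecutive coding bases are non-adjacent
    genomic <- unlist(lapply(seq_len(n_ex), function(e) iv[e, 1]:iv[e, 2]))
    if (strand == "-") genomic <- rev(genomic)
    jumps <- which(abs(diff(genomic)) != 1)
    expect_equal(prof$positions$offset, as.numeric(jumps))
    expect_equal(prof$positions$phase, as.integer(jumps %% 3))
    expect_equal(prof$cds_length, sum(lens))
    if (prof$n_introns)
      expect_true(all(prof$positions$offset < prof$cds_length))
  }
})

test_that("per-subfamily intron summaries; empty subfamilies warn", {
  profs <- list(
    a = introns_from_cds(list(gene_id = "a", strand = "+",
                              cds = cbind(c(1, 201), c(100, 500)))),
    b = introns_from_cds(list(gene_id = "b", strand = "+",
                              cds = cbind(c(1, 151), c(90, 400)))))
  calls <- data.frame(gene_id = c("a", "b", "c"),
                      subfamily = c("XII", "XII", "Empty"))
  expect_warning(s <- structure_mode_by_subfamily(profs, calls), "Empty")
  expect_equal(unlist(s[s$subfamily == "XII", c("min", "max", "mode")],
                      use.names = FALSE), c("1", "1", "1"))
})

test_that("shared structure: identity, disjointness and symmetry", {
  pa <- introns_from_cds(list(gene_id = "a", strand = "+",
                              cds = cbind(c(1, 101, 301), c(90, 250, 600))))
  expect_equal(shared_structure(pa, pa)$jaccard, 1)
  pb <- introns_from_cds(list(gene_id = "b", strand = "+",
                              cds = cbind(c(1, 113, 331), c(100, 280, 700))))
  s_ab <- shared_structure(pa, pb)
  s_ba <- shared_structure(pb, pa)
  expect_equal(s_ab$n_shared_introns, s_ba$n_shared_introns)
  expect_equal(s_ab$jaccard, s_ba$jaccard)
  none <- introns_from_cds(list(gene_id = "c", strand = "+",
                                cds = cbind(1, 300)))
  expect_equal(shared_structure(pa, none)$jaccard, 0)
  expect_equal(shared_structure(none, none)$jaccard, 1)  # both intronless
})

test_that("greedy in-order matching equals exhaustive matching", {
  set.seed(92)
  mk_prof <- function(offsets) {
    offsets <- sort(unique(offsets))
    structure(list(gene_id = "x", n_introns = length(offsets),
                   cds_length = max(offsets) + 100,
                   positions = data.frame(offset = as.numeric(offsets),
                                          phase = as.integer(offsets %% 3))),
              class = "intron_profile")
  }
  for (i in 1:20) {
    a <- mk_prof(sample(30:400, sample(1:5, 1)))
    b <- mk_prof(sample(30:400, sample(1:5, 1)))
    tol <- sample(c(0, 1, 3, 10), 1)
    got <- shared_structure(a, b, tolerance_nt = tol)
    want <- max_intron_matching(a$positions, b$positions, tol)
    expect_equal(got$n_shared_introns, want)
    expect_equal(got$jaccard,
                 if (want == 0 && a$n_introns + b$n_introns == 0) 1 else
                   want / (a$n_introns + b$n_introns - want))
  }
})

test_that("generator gene models satisfy the coding-length invariants", {
  sim <- simulate_family(family_sim_config(seed = 93))
  profs <- introns_from_gff(sim$loci)
  truth <- sim$truth$subfamily
  cfg <- sim$config$subfamilies
  for (g in names(profs)) {
    sf <- truth$subfamily[truth$gene_id == g]
    expect_equal(profs[[g]]$n_introns, cfg$introns[cfg$name == sf])
    expect_equal(profs[[g]]$cds_length, unname(sim$lengths[g]))
    expect_equal(nchar(sim$cds[g]), unname(sim$lengths[g]), ignore_attr = TRUE)
  }
})
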