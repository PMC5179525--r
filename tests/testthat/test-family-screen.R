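# Membership screening: E-value filtering, the LRR/TM/KD architecture rule
# and redundancy removal.

test_that("filter_hits applies a strict E-value inequality", {
  hits <- data.frame(query_id = c("g1", "g2"), subject_id = "s",
                     evalue = c(1e-12, 1e-9))
  expect_equal(filter_hits(hits, 1e-10), "g1")
  # a hit exactly at the cutoff is excluded
  hits$evalue <- c(1e-10, 1e-12)
  expect_equal(filter_hits(hits, 1e-10), "g2")
  expect_equal(filter_hits(data.frame(query_id = character(0),
                                      evalue = numeric(0)), 1e-10),
               character(0))
})

test_that("filter_hits equals an exhaustive scan, deduplicated and order-free", {
  set.seed(51)
  for (i in 1:5) {
    hits <- data.frame(
      query_id = sample(paste0("q", 1:4), 10, replace = TRUE),
      subject_id = "s",
      evalue = 10^runif(10, -20, 0))
    cutoff <- 10^runif(1, -15, -5)
    want <- sort(unique(hits$query_id[sapply(seq_len(nrow(hits)), function(i)
      hits$evalue[i] < cutoff)]))
    expect_equal(filter_hits(hits, cutoff), want)
    shuffled <- hits[sample(nrow(hits)), ]
    expect_equal(filter_hits(shuffled, cutoff), want)
    expect_equal(filter_hits(hits[hits$query_id %in% want, ], cutoff), want)
  }
})

test_that("hit tables reject malformed and negative rows with row numbers", {
  f <- tempfile()
  writeLines(c("query_id\tsubject_id\tevalue", "g1\ts\t1e-5", "g2\ts\t-1"), f)
  expect_error(read_hit_table(f), "row 2")
  writeLines(c("g1\ts\t90\t50\t0\t0\t1\t50\t3\t52\t1e-20\t100"), f)
  d <- read_hit_table(f, blast_outfmt6 = TRUE)
  expect_equal(d$evalue, 1e-20)
  expect_error(filter_hits(data.frame(query_id = "a", evalue = -2), 1e-3),
               "non-negative")
})

test_that("canonical receptor architecture is accepted; defects are coded", {
  ok <- domain_architecture("p1",
                            lrr = cbind(c(20, 44, 68), c(42, 66, 90)),
                            tm = cbind(200, 222), kinase = cbind(300, 560))
  res <- classify_membership(ok)
  expect_true(res$accept)
  expect_length(res$reasons, 0)

  no_tm <- domain_architecture("p2", lrr = cbind(20, 90),
                               kinase = cbind(300, 560))
  expect_equal(classify_membership(no_tm)$reasons, "no_TM")

  two_kd <- domain_architecture("p3", lrr = cbind(20, 90), tm = cbind(200, 222),
                                kinase = cbind(c(300, 600), c(560, 880)))
  expect_true("multiple_KD" %in% classify_membership(two_kd)$reasons)

  # kinase before the TM violates the topology rule
  inverted <- domain_architecture("p4", lrr = cbind(20, 90),
                                  tm = cbind(600, 622), kinase = cbind(300, 560))
  expect_equal(classify_membership(inverted)$reasons, "bad_topology")
  expect_true(classify_membership(inverted, require_topology = FALSE)$accept)
})

test_that("membership decisions equal a literal re-check of the conditions", {
  set.seed(52)
  for (i in 1:50) {
    arch <- random_architecture(paste0("p", i))
    got <- classify_membership(arch)
    expect_equal(got$accept, membership_oracle(arch))
    if (!got$accept) expect_gte(length(got$reasons), 1)
  }
})

test_that("domain_architecture validates its intervals", {
  expect_error(domain_architecture("p", lrr = cbind(10, 5)), "start <= end")
  expect_error(domain_architecture("p", lrr = cbind(c(1, 15), c(20, 40))),
               "overlap")
  expect_error(domain_architecture("p", lrr = cbind(10, 200),
                                   protein_length = 100), "exceeds")
})

test_that("drop_redundant collapses duplicates and removes defectives", {
  r <- drop_redundant(c(A = paste(rep("MKV", 40), collapse = ""),
                        B = paste(rep("MKV", 40), collapse = ""),
                        C = paste(rep("MLV", 40), collapse = "")),
                      min_aa = 100)
  expect_equal(names(r$kept), c("A", "C"))
  expect_equal(r$duplicates, "B")

  r2 <- drop_redundant(c(X = paste0(strrep("M", 60), "*", strrep("K", 60)),
                         Y = strrep("MK", 60)), min_aa = 100)
  expect_equal(r2$defective, "X")
  expect_equal(names(r2$kept), "Y")
  # short sequences are defective; trailing stop alone is tolerated
  r3 <- drop_redundant(c(S = "MKV", T = paste0(strrep("A", 120), "*")),
                       min_aa = 100)
  expect_equal(r3$defective, "S")
  expect_equal(names(r3$kept), "T")
  expect_equal(drop_redundant(character(0))$kept,
               setNames(character(0), character(0)))
})

test_that("redundancy removal equals a hash-grouping oracle", {
  set.seed(53)
  base <- replicate(40, paste(sample(c("A", "C", "D", "E"), 120, TRUE),
                              collapse = ""))
  seqs <- c(base, base[sample(40, 60, TRUE)])  # planted duplicates
  names(seqs) <- sprintf("s%03d", sample(100))
  r <- drop_redundant(seqs, min_aa = 100)
  oracle <- vapply(split(names(seqs), unname(seqs)),
                   function(ids) sort(ids)[1], "")
  expect_setequal(names(r$kept), unname(oracle))
  expect_false(anyDuplicated(unname(r$kept)) > 0)
})

test_that("screen_family integrates filter, architecture and redundancy", {
  hits <- data.frame(query_id = c("p1", "p2", "p3", "p4"), subject_id = "s",
                     evalue = c(1e-20, 1e-15, 1e-30, 1e-2))
  archs <- list(
    p1 = domain_architecture("p1", lrr = cbind(20, 90), tm = cbind(200, 222),
                             kinase = cbind(300, 560)),
    p2 = domain_architecture("p2", lrr = cbind(20, 90),
                             kinase = cbind(300, 560)))
  seqs <- c(p1 = strrep("MK", 300), p2 = strrep("ML", 300),
            p3 = strrep("MN", 300), p4 = strrep("MQ", 300))
  rep <- screen_family(hits, archs, seqs, extra_candidates = "p5")
  expect_equal(rep$accepted[rep$protein_id == "p1"], TRUE)
  expect_equal(rep$reason[rep$protein_id == "p2"], "no_TM")
  expect_equal(rep$reason[rep$protein_id == "p3"], "no_architecture")
  expect_false("p4" %in% rep$protein_id)  # fails the E-value filter
  expect_true("p5" %in% rep$protein_id)   # union with pre-annotated genes
})
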