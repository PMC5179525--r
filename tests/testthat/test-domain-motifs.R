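# LRR count summaries, motif presence categories, information content and
# the consensus emphasis coding.

test_that("LRR count summaries report min, max and (bolded) mode", {
  archs <- lapply(1:6, function(i) {
    n <- c(3, 3, 3, 3, 4, 6)[i]
    domain_architecture(paste0("p", i),
                        lrr = cbind(25 + (seq_len(n) - 1) * 24,
                                    45 + (seq_len(n) - 1) * 24),
                        tm = cbind(300, 322), kinase = cbind(400, 660))
  })
  names(archs) <- paste0("p", 1:6)
  calls <- data.frame(gene_id = paste0("p", 1:6),
                      subfamily = c(rep("I", 5), "VI"))
  s <- lrr_range_by_subfamily(archs, calls)
  expect_equal(s$min[s$subfamily == "I"], 3)
  expect_equal(s$max[s$subfamily == "I"], 4)
  expect_equal(s$mode[s$subfamily == "I"], "3")
  expect_equal(unlist(s[s$subfamily == "VI", c("min", "max", "mode")],
                      use.names = FALSE), c("6", "6", "6"))
})

test_that("tied modes are all reported", {
  counts <- c(a = 3, b = 3, c = 4, d = 4)
  calls <- data.frame(gene_id = letters[1:4], subfamily = "II")
  s <- lrrkit:::summarize_counts_by_subfamily(counts, calls)
  expect_equal(s$mode, "3,4")
})

test_that("random groupings match brute-force per-group aggregation", {
  set.seed(81)
  for (i in 1:5) {
    ids <- sprintf("g%02d", 1:30)
    counts <- setNames(sample(1:8, 30, TRUE), ids)
    calls <- data.frame(gene_id = ids,
                        subfamily = sample(c("I", "II", "III"), 30, TRUE))
    s <- lrrkit:::summarize_counts_by_subfamily(counts, calls)
    for (sf in unique(calls$subfamily)) {
      x <- counts[calls$gene_id[calls$subfamily == sf]]
      expect_equal(s$min[s$subfamily == sf], min(x))
      expect_equal(s$max[s$subfamily == sf], max(x))
      tab <- table(x)
      expect_equal(s$mode[s$subfamily == sf],
                   paste(sort(as.numeric(names(tab)[tab == max(tab)])),
                         collapse = ","))
    }
  }
})

test_that("motif presence categories and subfamily-specific motifs", {
  calls <- data.frame(gene_id = sprintf("p%d", 1:12),
                      subfamily = rep(c("I", "II"), each = 6))
  occ <- rbind(
    data.frame(protein_id = sprintf("p%d", 1:12), motif_id = "M1"),  # all/all
    data.frame(protein_id = sprintf("p%d", 7:12), motif_id = "M9"),  # II only
    data.frame(protein_id = sprintf("p%d", c(1:4)), motif_id = "M13"), # most I
    data.frame(protein_id = "p1", motif_id = "M6"))                  # some I
  mp <- motif_presence(occ, calls)
  expect_equal(mp$matrix["I", "M1"], "all")
  expect_equal(mp$matrix["II", "M1"], "all")
  expect_equal(mp$matrix["I", "M9"], "none")
  expect_equal(mp$matrix["II", "M9"], "all")
  expect_equal(mp$matrix["I", "M13"], "most")
  expect_equal(mp$matrix["I", "M6"], "some")
  # M9 (all of II, none of I) and M13 (most of I, none of II) both qualify
  expect_setequal(mp$subfamily_specific$motif, c("M9", "M13"))
  expect_equal(mp$subfamily_specific$subfamily[mp$subfamily_specific$motif == "M9"],
               "II")
})

test_that("presence categories equal brute-force counting on random tables", {
  set.seed(82)
  for (i in 1:5) {
    ids <- sprintf("p%02d", 1:20)
    calls <- data.frame(gene_id = ids, subfamily = sample(c("A", "B"), 20, TRUE))
    occ <- data.frame(protein_id = sample(ids, 40, TRUE),
                      motif_id = sample(paste0("M", 1:4), 40, TRUE))
    mp <- motif_presence(occ, calls)
    for (sf in c("A", "B")) for (mo in paste0("M", 1:4)) {
      members <- calls$gene_id[calls$subfamily == sf]
      f <- mean(members %in% occ$protein_id[occ$motif_id == mo])
      want <- if (f == 0) "none" else if (f == 1) "all" else
        if (f > 0.5) "most" else "some"
      expect_equal(unname(mp$matrix[sf, mo]), want)
      expect_equal(unname(mp$fraction[sf, mo]), f)
    }
  }
})

test_that("column information content: invariant and uniform extremes", {
  expect_equal(column_bits(rep("L", 10)), log2(20), tolerance = 1e-12)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  expect_equal(column_bits(aas), 0, tolerance = 1e-12)
  # gaps are excluded by default but can be counted as a symbol
  expect_equal(column_bits(c("L", "L", "-", "-")), log2(20))
  expect_equal(column_bits(c("L", "L", "-", "-"), gap_as_symbol = TRUE),
               log2(21) - 1)
  expect_error(column_bits(c("-", "-")), "no non-gap")
})

test_that("column bits equal a direct entropy computation, permutation-free", {
  set.seed(83)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:10) {
    col <- sample(aas, sample(5:40, 1), replace = TRUE)
    p <- as.numeric(table(col)) / length(col)
    want <- log2(20) + sum(p * log2(p))
    expect_equal(column_bits(col), want, tolerance = 1e-12)
    expect_equal(column_bits(sample(col)), want, tolerance = 1e-12)
    expect_gte(column_bits(col), 0)
    expect_lte(column_bits(col), log2(20))
  }
})

test_that("consensus emphasis follows the bits thresholds exactly", {
  expect_equal(consensus_code("L", 0.5)$emphasis, "x")
  expect_equal(consensus_code("L", 0.999)$emphasis, "x")
  expect_equal(consensus_code("L", 1)$emphasis, "lowercase")
  expect_equal(consensus_code("L", 2)$emphasis, "uppercase")
  expect_equal(consensus_code("L", 3)$emphasis, "bold")
  expect_equal(consensus_code("L", 4.3)$emphasis, "bold")
  expect_equal(consensus_code("k", 2.2)$rendered, "K")
  expect_equal(consensus_code("k", 1.2)$rendered, "k")
  expect_equal(consensus_code("k", 3.2)$rendered, "*K*")
  # monotone in bits over a sweep
  lv <- c(x = 0, lowercase = 1, uppercase = 2, bold = 3)
  em <- vapply(seq(0, 4.3, by = 0.05),
               function(b) lv[[consensus_code("A", b)$emphasis]], 0)
  expect_true(all(diff(em) >= 0))
})

test_that("consensus sequence renders modal residues with markup", {
  aln <- c(s1 = "LLKA", s2 = "LLRA", s3 = "LIRC", s4 = "LLRA")
  cs <- consensus_sequence(aln)
  expect_equal(nrow(cs$columns), 4)
  expect_equal(cs$columns$residue[1], "L")          # invariant column
  expect_equal(cs$columns$emphasis[1], "bold")
  expect_equal(cs$columns$residue[3], "R")          # modal residue
  expect_equal(nchar(gsub("\\*", "", cs$consensus)), 4)
})
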