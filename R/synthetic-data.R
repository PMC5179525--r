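## Synthetic study generator: a complete receptor-kinase gene family with
## known duplication history, domain architectures, gene structures, motif
## occurrences, codon alignments evolved under known site models, a
## support-annotated phylogeny, and tissue expression counts -- so every
## pipeline stage can be validated against ground truth without external
## data.

#' Configuration for a synthetic gene family
#'
#' @param subfamilies data.frame with one row per subfamily: \code{name},
#'   \code{n} (member count), \code{lrr} (LRR repeat count), \code{introns}
#'   (intron count), \code{omega} (M0 dN/dS used to evolve the subfamily's
#'   codon alignment). Optional column \code{expr} (\code{"high"},
#'   \code{"moderate"}, \code{"low"}) for the whole-plant tissue.
#' @param n_scaffolds Number of scaffolds.
#' @param scaffold_length Length of every scaffold in bp.
#' @param tandem_clusters Integer vector of tandem cluster sizes (each
#'   cluster's genes are placed within \code{tandem_offset_max} bp of each
#'   other and form a clade).
#' @param tandem_offset_max Maximal start-to-start offset between adjacent
#'   tandem copies (default 50000, well inside the 200-kb window so that
#'   boundary behaviour can be probed separately).
#' @param dispersed_frac Fraction of non-tandem genes labelled as dispersed
#'   duplicates (placement on scaffolds of their own, like ancestral
#'   copies).
#' @param site_models Optional named list (by subfamily) of
#'   \code{list(model =, params =)} overriding the per-subfamily M0
#'   simulation.
#' @param kappa Transition/transversion ratio for sequence evolution.
#' @param tissues Tissue names for the expression table.
#' @param library_size Total mapped fragments per tissue.
#' @param nb_size Negative-binomial dispersion (size) of counts.
#' @param seed Master seed; all outputs are deterministic given it.
#' @return List of class \code{family_sim_config}.
#' @export
family_sim_config <- function(subfamilies = NULL,
                              n_scaffolds = 12,
                              scaffold_length = 2e6,
                              tandem_clusters = c(2L, 2L),
                              tandem_offset_max = 5e4,
                              dispersed_frac = 0.25,
                              site_models = NULL,
                              kappa = 2,
                              tissues = c("whole_plant", "AMYL", "female_bud"),
                              library_size = 2e7,
                              nb_size = 10,
                              seed = 1L) {
  if (is.null(subfamilies)) {
    subfamilies <- data.frame(
      name = c("A", "B", "C", "D"),
      n = c(6L, 5L, 4L, 3L),
      lrr = c(3L, 5L, 11L, 16L),
      introns = c(10L, 2L, 1L, 0L),
      omega = c(0.35, 0.1, 0.25, 0.2),
      expr = c("high", "low", "moderate", "high"),
      stringsAsFactors = FALSE)
  }
  if (!"expr" %in% names(subfamilies)) subfamilies$expr <- "moderate"
  stopifnot(all(subfamilies$n >= 1), all(subfamilies$lrr >= 1),
            all(subfamilies$introns >= 0), all(subfamilies$omega >= 0),
            tandem_offset_max >= 1)
  if (sum(tandem_clusters) > 0 &&
      !any(subfamilies$n >= max(tandem_clusters) + 1))
    stop("no subfamily is large enough to host the largest tandem cluster")
  structure(list(subfamilies = subfamilies, n_scaffolds = n_scaffolds,
                 scaffold_length = scaffold_length,
                 tandem_clusters = as.integer(tandem_clusters),
                 tandem_offset_max = tandem_offset_max,
                 dispersed_frac = dispersed_frac,
                 site_models = site_models, kappa = kappa,
                 tissues = tissues, library_size = library_size,
                 nb_size = nb_size, seed = as.integer(seed)),
            class = "family_sim_config")
}

# random binary newick over the given labels; edge lengths from bl_fun
random_clade_newick <- function(labels, bl_fun) {
  nodes <- as.list(labels)
  while (length(nodes) > 1) {
    k <- sample.int(length(nodes), 2)
    merged <- sprintf("(%s:%.6f,%s:%.6f)", nodes[[k[1]]], bl_fun(),
                      nodes[[k[2]]], bl_fun())
    nodes <- c(nodes[-k], merged)
  }
  nodes[[1]]
}

#' Simulate a complete synthetic gene family
#'
#' Generates, deterministically given the config seed: gene placements on
#' scaffolds (tandem clusters within the configured offset, all other genes
#' spaced well apart), a family phylogeny in which subfamilies and tandem
#' clusters are monophyletic with bootstrap-style supports, per-subfamily
#' codon alignments evolved under the configured site models, CDS/protein
#' sequences, exon/intron structures, domain architectures, motif
#' occurrences, tissue expression counts, and the full ground truth.
#'
#' @param config A \code{\link{family_sim_config}}.
#' @param dir Optional directory; when given, standard-format files (GFF3,
#'   FASTA, Newick, TSV) are written there.
#' @return List of class \code{family_sim}; see Details.
#' @details The returned object contains \code{loci} (data.frame as from
#'   \code{\link{read_gene_loci}}), \code{tree} (rooted \code{phylo} with
#'   support node labels), \code{alignments} (per-subfamily
#'   \code{codon_alignment}s with true site-class labels), \code{cds} and
#'   \code{protein} (named character vectors), \code{architectures},
#'   \code{motifs} (occurrence data.frame), \code{counts}/\code{lengths}/
#'   \code{totals} (expression inputs), and \code{truth} with per-gene
#'   subfamily and duplication origin, the tandem clusters, and per-site
#'   omega-class labels.
#' @export
simulate_family <- function(config = family_sim_config(), dir = NULL) {
  stopifnot(inherits(config, "family_sim_config"))
  set.seed(config$seed)
  sf <- config$subfamilies
  n_genes <- sum(sf$n)
  gene_ids <- sprintf("g%03d", seq_len(n_genes))
  subfam <- rep(sf$name, sf$n)
  names(subfam) <- gene_ids

  ## --- duplication history: tandem clusters hosted by subfamilies -------
  origin <- stats::setNames(rep("ancestral", n_genes), gene_ids)
  clusters_truth <- list()
  used <- character(0)
  host_load <- stats::setNames(rep(0L, nrow(sf)), sf$name)
  for (s in config$tandem_clusters) {
    cap <- sf$n - host_load - 1L  # keep >= 1 non-cluster member per host
    ok <- which(cap >= s)
    if (!length(ok)) stop("cannot host a tandem cluster of size ", s)
    host <- sf$name[ok[which.max(cap[ok])]]
    members <- setdiff(gene_ids[subfam == host], used)[seq_len(s)]
    used <- c(used, members)
    origin[members] <- "tandem"
    clusters_truth[[length(clusters_truth) + 1]] <-
      list(subfamily = host, members = members)
    host_load[host] <- host_load[host] + s
  }
  free <- setdiff(gene_ids, used)
  n_disp <- round(config$dispersed_frac * length(free))
  if (n_disp > 0)
    origin[sample(free, n_disp)] <- "dispersed"

  ## --- family tree: subfamily clades, tandem clusters as sub-clades -----
  sub_newick <- character(nrow(sf))
  for (i in seq_len(nrow(sf))) {
    nm <- sf$name[i]
    members <- gene_ids[subfam == nm]
    blocks <- Filter(function(cl) cl$subfamily == nm, clusters_truth)
    unit_labels <- setdiff(members, unlist(lapply(blocks, `[[`, "members")))
    for (b in blocks) {
      unit_labels <- c(unit_labels,
                       if (length(b$members) == 1) b$members else
                         random_clade_newick(b$members,
                                             function() stats::runif(1, 0.005, 0.03)))
    }
    sub_newick[i] <- if (length(unit_labels) == 1) unit_labels[[1]] else
      random_clade_newick(unit_labels, function() stats::runif(1, 0.03, 0.12))
  }
  backbone <- if (nrow(sf) == 1) sub_newick[1] else
    random_clade_newick(sub_newick, function() stats::runif(1, 0.15, 0.5))
  tree <- ape::read.tree(text = paste0(backbone, ";"))
  ntip <- length(tree$tip.label)
  # supports: high on subfamily crowns and within them, low on the backbone
  supports <- round(stats::runif(tree$Nnode, 25, 70))
  for (nm in sf$name) {
    members <- gene_ids[subfam == nm]
    if (length(members) < 2) next
    crown <- ape::getMRCA(tree, members)
    inner <- intersect(unlist(phangorn::Descendants(tree, crown, "all")),
                       (ntip + 1):(ntip + tree$Nnode))
    supports[c(crown, inner) - ntip] <- round(stats::runif(length(inner) + 1, 88, 100))
  }
  tree$node.label <- as.character(supports)

  ## --- codon evolution per subfamily ------------------------------------
  n_codons <- 30 + 24 * sf$lrr + 10 + 23 + 15 + 270 + 10
  alignments <- list()
  cds <- character(0)
  for (i in seq_len(nrow(sf))) {
    nm <- sf$name[i]
    members <- gene_ids[subfam == nm]
    smod <- if (!is.null(config$site_models[[nm]])) config$site_models[[nm]]
            else list(model = "M0", params = list(omega = sf$omega[i]))
    if (length(members) >= 2) {
      crown <- ape::getMRCA(tree, members)
      subtree <- ape::extract.clade(tree, crown)
      aln <- simulate_codon_alignment(subtree, smod$model, smod$params,
                                      n_sites = n_codons[i],
                                      kappa = config$kappa)
    } else {
      m <- matrix(sample.int(61, n_codons[i], replace = TRUE), nrow = 1)
      rownames(m) <- members
      aln <- structure(list(ids = members, codon = m),
                       class = "codon_alignment",
                       class_labels = rep(1L, n_codons[i]),
                       classes = site_class_distribution(smod$model, smod$params))
    }
    alignments[[nm]] <- aln
    cds <- c(cds, as.character(aln))
  }
  cds <- cds[gene_ids]
  protein <- vapply(cds, function(s)
    as.character(Biostrings::translate(Biostrings::DNAString(s))), character(1))
  names(protein) <- gene_ids

  ## --- genomic placement ------------------------------------------------
  scaffolds <- sprintf("scf%02d", seq_len(config$n_scaffolds))
  n_singles <- length(gene_ids) - length(used)
  n_cluster_scf <- length(clusters_truth)
  if (n_cluster_scf + ceiling(n_singles / 2) > config$n_scaffolds)
    stop("not enough scaffolds: ", config$n_scaffolds, " for ",
         n_cluster_scf, " clusters and ", n_singles, " single genes")
  scf_assign <- stats::setNames(character(n_genes), gene_ids)
  start_pos <- stats::setNames(numeric(n_genes), gene_ids)
  cl_scf <- sample(scaffolds, n_cluster_scf)
  for (k in seq_along(clusters_truth)) {
    mem <- clusters_truth[[k]]$members
    pos <- stats::runif(1, 5e4, config$scaffold_length * 0.3)
    for (g in mem) {
      scf_assign[g] <- cl_scf[k]
      start_pos[g] <- pos
      pos <- pos + stats::runif(1, 5e3, config$tandem_offset_max)
    }
    clusters_truth[[k]]$scaffold <- cl_scf[k]
  }
  single_scf <- setdiff(scaffolds, cl_scf)
  singles <- setdiff(gene_ids, used)
  # at most two singles per scaffold, spaced far beyond the 200-kb window
  n_two <- length(singles) - length(single_scf)
  slots <- c(single_scf,
             if (n_two > 0) sample(single_scf, n_two))
  slots <- slots[seq_along(singles)]
  seen <- character(0)
  for (j in seq_along(singles)) {
    g <- singles[j]
    scf_assign[g] <- slots[j]
    first_on_scf <- !(slots[j] %in% seen)
    start_pos[g] <- if (first_on_scf) stats::runif(1, 5e4, 2e5) else
      stats::runif(1, config$scaffold_length * 0.55,
                   config$scaffold_length * 0.85)
    seen <- c(seen, slots[j])
  }

  ## --- gene structures --------------------------------------------------
  loci_rows <- list()
  for (i in seq_len(nrow(sf))) {
    nm <- sf$name[i]
    for (g in gene_ids[subfam == nm]) {
      cds_len <- 3 * n_codons[i]
      n_int <- sf$introns[i]
      if (n_int > 0) {
        cuts <- sort(sample(seq(30, cds_len - 30), n_int))
        exon_len <- diff(c(0, cuts, cds_len))
        intron_len <- sample(100:2000, n_int, replace = TRUE)
      } else {
        exon_len <- cds_len
        intron_len <- integer(0)
      }
      gstart <- round(start_pos[g])
      iv <- matrix(0, length(exon_len), 2)
      p <- gstart
      for (e in seq_along(exon_len)) {
        iv[e, ] <- c(p, p + exon_len[e] - 1)
        p <- iv[e, 2] + (if (e < length(exon_len)) intron_len[e] else 0) + 1
      }
      loci_rows[[g]] <- list(gene_id = g, scaffold = scf_assign[g],
                             start = gstart, end = iv[nrow(iv), 2],
                             strand = sample(c("+", "-"), 1), iv = iv)
    }
  }
  loci <- data.frame(
    gene_id = gene_ids,
    scaffold = vapply(loci_rows[gene_ids], `[[`, character(1), "scaffold"),
    start = vapply(loci_rows[gene_ids], `[[`, numeric(1), "start"),
    end = vapply(loci_rows[gene_ids], `[[`, numeric(1), "end"),
    strand = vapply(loci_rows[gene_ids], `[[`, character(1), "strand"),
    stringsAsFactors = FALSE)
  loci$exons <- lapply(loci_rows[gene_ids], `[[`, "iv")
  loci$cds <- loci$exons

  ## --- domain architectures --------------------------------------------
  architectures <- list()
  for (i in seq_len(nrow(sf))) {
    nlrr <- sf$lrr[i]
    lrr_iv <- cbind(25 + (seq_len(nlrr) - 1) * 24, 25 + (seq_len(nlrr) - 1) * 24 + 22)
    tm_start <- 25 + nlrr * 24 + 10
    tm_iv <- cbind(tm_start, tm_start + 22)
    kd_start <- tm_start + 23 + 15
    kd_iv <- cbind(kd_start, kd_start + 269)
    for (g in gene_ids[subfam == sf$name[i]])
      architectures[[g]] <- domain_architecture(g, lrr = lrr_iv, tm = tm_iv,
                                                kinase = kd_iv,
                                                protein_length = n_codons[i])
  }

  ## --- motif occurrences ------------------------------------------------
  core <- c("M1", "M2", "M4", "M5", "M7", "M10", "M12", "M15")
  specific_host <- sf$name[which.min(sf$n)]
  motif_rows <- list()
  for (i in seq_len(nrow(sf))) {
    nm <- sf$name[i]
    kd_start <- 25 + sf$lrr[i] * 24 + 10 + 23 + 15
    for (g in gene_ids[subfam == nm]) {
      motifs_g <- core
      if (nm == specific_host) motifs_g <- c(motifs_g, "M9")
      if (stats::runif(1) < 0.8) motifs_g <- c(motifs_g, "M14")
      for (k in seq_along(motifs_g)) {
        st <- kd_start + (k - 1) * 18
        motif_rows[[length(motif_rows) + 1]] <-
          data.frame(protein_id = g, motif_id = motifs_g[k],
                     start = st, end = st + 14,
                     score = round(stats::runif(1, 20, 60), 2),
                     stringsAsFactors = FALSE)
      }
    }
  }
  motifs <- do.call(rbind, c(motif_rows, list(make.row.names = FALSE)))

  ## --- expression counts ------------------------------------------------
  level_fpkm <- c(high = 50, moderate = 5, low = 0.3)
  mean_fpkm <- matrix(0, n_genes, length(config$tissues),
                      dimnames = list(gene_ids, config$tissues))
  for (i in seq_len(nrow(sf))) {
    base <- level_fpkm[[sf$expr[i]]]
    for (j in seq_along(config$tissues)) {
      lvl <- if (j == 1) base else
        level_fpkm[[sample(names(level_fpkm), 1)]]
      mean_fpkm[gene_ids[subfam == sf$name[i]], j] <- lvl
    }
  }
  lengths_bp <- stats::setNames(3 * n_codons[match(subfam, sf$name)], gene_ids)
  mu <- sweep(mean_fpkm, 1, lengths_bp / 1e3, "*") * config$library_size / 1e6
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = config$nb_size),
                   nrow = n_genes, dimnames = dimnames(mu))
  totals <- stats::setNames(rep(config$library_size, length(config$tissues)),
                            config$tissues)

  sim <- structure(list(
    config = config, loci = loci, tree = tree, alignments = alignments,
    cds = cds, protein = protein, architectures = architectures,
    motifs = motifs, counts = counts, lengths = lengths_bp, totals = totals,
    truth = list(
      subfamily = data.frame(gene_id = gene_ids, subfamily = unname(subfam),
                             origin = unname(origin[gene_ids]),
                             stringsAsFactors = FALSE),
      clusters = clusters_truth,
      site_classes = lapply(alignments, attr, "class_labels"),
      mean_fpkm = mean_fpkm)),
    class = "family_sim")
  if (!is.null(dir)) write_family_files(sim, dir)
  sim
}

#' @export
print.family_sim <- function(x, ...) {
  cat("family_sim:", nrow(x$loci), "genes,",
      length(unique(x$loci$scaffold)), "scaffolds,",
      nrow(x$config$subfamilies), "subfamilies,",
      length(x$truth$clusters), "tandem clusters\n")
  invisible(x)
}

#' Write a simulated family to standard-format files
#'
#' Emits \code{genes.gff3}, \code{cds.fasta}, \code{protein.fasta},
#' \code{tree.nwk}, \code{domains.tsv}, \code{motifs.tsv},
#' \code{counts.tsv}, \code{lengths.tsv}, \code{totals.tsv},
#' \code{truth.tsv} and one \code{aln_<subfamily>.fasta} per subfamily.
#'
#' @param sim A \code{family_sim}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_family_files <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  p <- function(f) file.path(dir, f)
  ## GFF3
  lines <- "##gff-version 3"
  loci <- sim$loci[order(sim$loci$scaffold, sim$loci$start), ]
  for (i in seq_len(nrow(loci))) {
    g <- loci$gene_id[i]
    row9 <- function(type, s, e, attrs)
      paste(loci$scaffold[i], "sim", type, s, e, ".", loci$strand[i], ".",
            attrs, sep = "\t")
    lines <- c(lines,
               row9("gene", loci$start[i], loci$end[i], paste0("ID=", g)),
               row9("mRNA", loci$start[i], loci$end[i],
                    paste0("ID=", g, ".t1;Parent=", g)))
    iv <- loci$exons[[i]]
    for (e in seq_len(nrow(iv))) {
      lines <- c(lines,
                 row9("exon", iv[e, 1], iv[e, 2], paste0("Parent=", g, ".t1")),
                 row9("CDS", iv[e, 1], iv[e, 2], paste0("Parent=", g, ".t1")))
    }
  }
  writeLines(lines, p("genes.gff3")); paths["gff3"] <- p("genes.gff3")
  ## FASTA
  writeLines(paste0(">", names(sim$cds), "\n", sim$cds), p("cds.fasta"))
  writeLines(paste0(">", names(sim$protein), "\n", sim$protein), p("protein.fasta"))
  paths["cds"] <- p("cds.fasta"); paths["protein"] <- p("protein.fasta")
  ## tree
  ape::write.tree(sim$tree, p("tree.nwk")); paths["tree"] <- p("tree.nwk")
  ## domains
  dom <- do.call(rbind, lapply(sim$architectures, function(a) {
    rbind(
      if (nrow(a$lrr)) data.frame(protein_id = a$protein_id, domain_name = "LRR",
                                  start = a$lrr[, 1], end = a$lrr[, 2]),
      if (nrow(a$tm)) data.frame(protein_id = a$protein_id, domain_name = "TM",
                                 start = a$tm[, 1], end = a$tm[, 2]),
      if (nrow(a$kinase)) data.frame(protein_id = a$protein_id,
                                     domain_name = "kinase",
                                     start = a$kinase[, 1], end = a$kinase[, 2]))
  }))
  utils::write.table(dom, p("domains.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths["domains"] <- p("domains.tsv")
  utils::write.table(sim$motifs, p("motifs.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths["motifs"] <- p("motifs.tsv")
  ## expression
  cnt <- data.frame(gene_id = rownames(sim$counts), sim$counts,
                    check.names = FALSE)
  utils::write.table(cnt, p("counts.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(gene_id = names(sim$lengths),
                                length_bp = sim$lengths),
                     p("lengths.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(tissue = names(sim$totals),
                                total_fragments = sim$totals),
                     p("totals.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths["counts"] <- p("counts.tsv")
  ## truth
  utils::write.table(sim$truth$subfamily, p("truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths["truth"] <- p("truth.tsv")
  ## per-subfamily alignments
  for (nm in names(sim$alignments)) {
    f <- p(paste0("aln_", gsub("[^A-Za-z0-9._-]", "_", nm), ".fasta"))
    write_codon_fasta(sim$alignments[[nm]], f)
    paths[paste0("aln_", nm)] <- f
  }
  invisible(paths)
}

#' Study-scale synthetic fixture
#'
#' A synthetic family shaped like a basal-angiosperm LRR-RLK complement:
#' 94 genes in 18 subfamilies with a realistic size spectrum (largest
#' subfamilies 24 and 16 members, four singletons), spread over 60
#' scaffolds with 5 tandem clusters of 2-3 genes (12 tandem genes, about
#' 12.8\% of the family).
#'
#' @param seed Master seed (same seed, byte-identical outputs).
#' @param dir Optional output directory, as in \code{\link{simulate_family}}.
#' @return A \code{family_sim}.
#' @export
fixture_paper_scale <- function(seed = 1L, dir = NULL) {
  subfamilies <- data.frame(
    name = c("I", "II", "III", "IV", "V", "VI-1", "VI-2", "VII-1", "VII-2",
             "VIII-1", "VIII-2", "IX", "X", "XI", "XII", "XIII-1", "XIII-2",
             "XV"),
    n = c(5L, 6L, 16L, 1L, 2L, 3L, 1L, 1L, 3L, 4L, 3L, 3L, 9L, 24L, 7L, 3L,
          1L, 2L),
    lrr = c(3L, 4L, 5L, 6L, 6L, 8L, 4L, 23L, 15L, 11L, 8L, 9L, 25L, 20L,
            16L, 4L, 19L, 15L),
    introns = c(10L, 10L, 1L, 3L, 15L, 6L, 11L, 0L, 2L, 18L, 16L, 1L, 0L,
                1L, 1L, 12L, 26L, 0L),
    omega = c(0.3743, 0.0920, 0.2292, 0.25, 0.25, 0.25, 0.25, 0.25, 0.25,
              0.2949, 0.25, 0.25, 0.25, 0.25, 0.2182, 0.25, 0.25, 0.25),
    expr = c("high", "high", "moderate", "moderate", "low", "low", "high",
             "moderate", "low", "high", "low", "moderate", "moderate",
             "moderate", "moderate", "low", "low", "moderate"),
    stringsAsFactors = FALSE)
  cfg <- family_sim_config(subfamilies = subfamilies,
                           n_scaffolds = 60,
                           scaffold_length = 2e6,
                           tandem_clusters = c(3L, 3L, 2L, 2L, 2L),
                           tandem_offset_max = 5e4,
                           dispersed_frac = 0.3,
                           seed = seed)
  simulate_family(cfg, dir = dir)
}
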