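## Scaffold mapping of family members: proximity-cluster chaining,
## phylogeny-validated tandem duplication, and expansion-rate statistics.

#' Read gene loci from a GFF3 file
#'
#' Extracts one row per gene (feature type \code{gene}) plus the exon and
#' CDS intervals of its first mRNA. Coordinates are 1-based inclusive as in
#' GFF3.
#'
#' @param path Path to a GFF3 file.
#' @return data.frame of loci: \code{gene_id}, \code{scaffold},
#'   \code{start}, \code{end}, \code{strand}, with list-columns
#'   \code{exons} and \code{cds} of two-column interval matrices.
#' @export
read_gene_loci <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) != 9)
  if (length(bad)) stop("malformed GFF3 row(s): ", paste(bad, collapse = ", "))
  m <- do.call(rbind, f)
  attr_field <- function(attrs, key) {
    has <- grepl(paste0("(^|;)", key, "="), attrs)
    v <- sub(paste0("(^|.*;)", key, "=([^;]*).*"), "\\2", attrs)
    ifelse(has, v, NA_character_)
  }
  type <- m[, 3]
  genes <- which(type == "gene")
  gene_id <- attr_field(m[genes, 9], "ID")
  mrna <- which(type == "mRNA")
  mrna_id <- attr_field(m[mrna, 9], "ID")
  mrna_parent <- attr_field(m[mrna, 9], "Parent")
  # first mRNA per gene, in file order
  first_mrna <- mrna_id[match(gene_id, mrna_parent)]
  sub_iv <- function(t, parent) {
    rows <- which(type == t)
    par <- attr_field(m[rows, 9], "Parent")
    lapply(parent, function(p) {
      r <- rows[par == p & !is.na(par)]
      iv <- cbind(as.numeric(m[r, 4]), as.numeric(m[r, 5]))
      iv[order(iv[, 1]), , drop = FALSE]
    })
  }
  out <- data.frame(gene_id = gene_id,
                    scaffold = m[genes, 1],
                    start = as.numeric(m[genes, 4]),
                    end = as.numeric(m[genes, 5]),
                    strand = m[genes, 7],
                    stringsAsFactors = FALSE)
  out$exons <- sub_iv("exon", first_mrna)
  out$cds <- sub_iv("CDS", first_mrna)
  if (anyDuplicated(out$gene_id))
    stop("duplicate gene identifiers in GFF3")
  out
}

#' Chain genes into proximity clusters
#'
#' Per scaffold, genes are sorted by start coordinate and consecutive genes
#' whose start-to-start distance is at most \code{window_bp} are linked;
#' connected chains of two or more genes become clusters. The threshold is
#' inclusive (a pair exactly \code{window_bp} apart is linked) and the
#' result is invariant under permutation of the input.
#'
#' @param loci data.frame with columns \code{gene_id}, \code{scaffold},
#'   \code{start} (and optionally \code{end}).
#' @param window_bp Chaining window in bp (default 200000, the 200-kb rule).
#' @return List of clusters; each is a list with \code{scaffold},
#'   \code{members} (gene ids ordered by position) and \code{span_bp}
#'   (start-to-start span).
#' @export
chain_clusters <- function(loci, window_bp = 200000) {
  stopifnot(window_bp > 0)
  if (anyDuplicated(loci$gene_id)) stop("duplicate gene_id in loci")
  clusters <- list()
  for (sc in sort(unique(loci$scaffold))) {
    d <- loci[loci$scaffold == sc, , drop = FALSE]
    d <- d[order(d$start, d$gene_id), , drop = FALSE]
    if (nrow(d) < 2) next
    gap_link <- diff(d$start) <= window_bp
    run_id <- cumsum(c(TRUE, !gap_link))
    for (run in split(seq_len(nrow(d)), run_id)) {
      if (length(run) < 2) next
      clusters[[length(clusters) + 1]] <- list(
        scaffold = sc,
        members = d$gene_id[run],
        span_bp = d$start[run[length(run)]] - d$start[run[1]])
    }
  }
  clusters
}

#' Validate clusters as tandem duplications against a phylogeny
#'
#' A proximity cluster is flagged tandem iff its members form a strictly
#' monophyletic group on the rooted tree: the most recent common ancestor
#' of the members has exactly the cluster members as leaf descendants. A
#' lenient mode instead requires only that all members share the same
#' subfamily call.
#'
#' @param clusters List of clusters from \code{\link{chain_clusters}}.
#' @param tree Rooted \code{phylo} containing every cluster member as a
#'   leaf.
#' @param mode \code{"monophyly"} (default) or \code{"subfamily"}.
#' @param calls For \code{mode = "subfamily"}: data.frame of subfamily
#'   calls (\code{gene_id}, \code{subfamily}).
#' @return The clusters, each gaining a logical \code{tandem} flag (and,
#'   for clusters of more than two genes that are not wholly monophyletic,
#'   \code{tandem_subpairs}: member pairs that are cherries on the tree).
#' @export
validate_tandem <- function(clusters, tree, mode = c("monophyly", "subfamily"),
                            calls = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  for (i in seq_along(clusters)) {
    cl <- clusters[[i]]
    missing <- setdiff(cl$members, tree$tip.label)
    if (length(missing))
      stop("cluster member(s) absent from tree: ", paste(missing, collapse = ", "))
    if (mode == "subfamily") {
      if (is.null(calls)) stop("subfamily mode requires calls")
      sf <- calls$subfamily[match(cl$members, calls$gene_id)]
      clusters[[i]]$tandem <- !anyNA(sf) && length(unique(sf)) == 1
      next
    }
    idx <- match(cl$members, tree$tip.label)
    mrca <- if (length(idx) == 1) idx else ape::getMRCA(tree, idx)
    below <- sort(unlist(phangorn::Descendants(tree, mrca, "tips")))
    tandem <- identical(below, sort(idx))
    clusters[[i]]$tandem <- tandem
    if (!tandem && length(idx) > 2) {
      prs <- utils::combn(cl$members, 2, simplify = FALSE)
      cherries <- Filter(function(p) {
        j <- match(p, tree$tip.label)
        mm <- ape::getMRCA(tree, j)
        identical(sort(unlist(phangorn::Descendants(tree, mm, "tips"))), sort(j))
      }, prs)
      clusters[[i]]$tandem_subpairs <- cherries
    }
  }
  clusters
}

#' Tandem-duplication fraction of a gene family
#'
#' @param loci Loci data.frame (defines the family size).
#' @param clusters Flagged clusters from \code{\link{validate_tandem}}.
#' @return List: \code{n_tandem_genes}, \code{n_total}, \code{fraction}.
#' @export
tandem_fraction <- function(loci, clusters) {
  n_total <- nrow(loci)
  if (!n_total) stop("no genes in loci")
  tandem_genes <- unique(unlist(lapply(clusters, function(cl)
    if (isTRUE(cl$tandem)) cl$members else NULL)))
  list(n_tandem_genes = length(tandem_genes), n_total = n_total,
       fraction = length(tandem_genes) / n_total)
}

#' Per-subfamily expansion rates between two genomes
#'
#' Ratio of reference-genome to query-genome member counts per subfamily
#' (e.g. the R = N_reference / N_query statistic used to compare a derived
#' lineage against a basal one), reported rounded to one decimal.
#'
#' @param counts_reference,counts_query Named numeric vectors
#'   (subfamily -> count).
#' @return data.frame: \code{subfamily}, \code{n_reference},
#'   \code{n_query}, \code{ratio} (exact), \code{ratio_reported} (1
#'   decimal), \code{missing_partner} flag for subfamilies present in only
#'   one table (their ratio is \code{NA}).
#' @export
expansion_rates <- function(counts_reference, counts_query) {
  subs <- sort(union(names(counts_reference), names(counts_query)))
  n_ref <- counts_reference[subs]
  n_qry <- counts_query[subs]
  missing <- is.na(n_ref) | is.na(n_qry)
  ratio <- ifelse(missing | n_qry < 1, NA_real_, as.numeric(n_ref) / as.numeric(n_qry))
  data.frame(subfamily = subs,
             n_reference = as.numeric(n_ref),
             n_query = as.numeric(n_qry),
             ratio = ratio,
             ratio_reported = round(ratio, 1),
             missing_partner = missing,
             row.names = NULL, stringsAsFactors = FALSE)
}
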