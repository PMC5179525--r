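## Intron/exon structure: CDS-relative intron positions and phases from
## gene models, per-subfamily summaries, and pairwise structure sharing.

#' Intron profile of a gene from its CDS intervals
#'
#' Derives the intron count and the coding-relative intron positions of a
#' gene from its genomic CDS intervals. Positions are expressed as the
#' cumulative coding-nucleotide offset before each intron, in transcription
#' order (reverse-complement logic on the minus strand), with phase =
#' offset mod 3. UTR introns are invisible to this representation: only
#' gaps between CDS intervals count.
#'
#' @param locus A single row of a loci data.frame (see
#'   \code{\link{read_gene_loci}}) or a list with \code{gene_id},
#'   \code{strand} and a two-column \code{cds} interval matrix (1-based
#'   inclusive, sorted by start, non-overlapping).
#' @return List of class \code{intron_profile}: \code{gene_id},
#'   \code{n_introns}, \code{cds_length}, and \code{positions}
#'   (data.frame \code{offset}, \code{phase}).
#' @export
introns_from_cds <- function(locus) {
  cds <- locus$cds
  if (is.list(cds) && !is.matrix(cds)) cds <- cds[[1]]
  if (is.null(cds) || !nrow(cds)) stop("locus has no CDS intervals")
  cds <- cds[order(cds[, 1]), , drop = FALSE]
  if (nrow(cds) > 1 && any(cds[-1, 1] <= cds[-nrow(cds), 2]))
    stop("overlapping CDS intervals in gene ", locus$gene_id)
  lens <- cds[, 2] - cds[, 1] + 1
  if (identical(locus$strand, "-")) lens <- rev(lens)
  offs <- cumsum(lens)
  total <- offs[length(offs)]
  offs <- offs[-length(offs)]  # no intron after the last exon
  structure(list(gene_id = locus$gene_id,
                 n_introns = length(offs),
                 cds_length = total,
                 positions = data.frame(offset = as.numeric(offs),
                                        phase = as.integer(offs %% 3))),
            class = "intron_profile")
}

#' Intron profiles for a set of gene loci
#'
#' @param loci Loci data.frame from \code{\link{read_gene_loci}}. Genes
#'   without CDS intervals are skipped with a warning (mirroring genes
#'   whose structures are unavailable in the annotation).
#' @return Named list of \code{intron_profile}s.
#' @export
introns_from_gff <- function(loci) {
  out <- list()
  for (i in seq_len(nrow(loci))) {
    row <- list(gene_id = loci$gene_id[i], strand = loci$strand[i],
                cds = loci$cds[[i]])
    if (is.null(row$cds) || !nrow(row$cds)) {
      warning("gene ", row$gene_id, " has no CDS intervals; skipped")
      next
    }
    out[[row$gene_id]] <- introns_from_cds(row)
  }
  out
}

# min/max/mode summary of a count multiset; ties in the mode keep all tied
# values (ascending).
count_summary <- function(x) {
  tab <- table(x)
  modes <- as.numeric(names(tab)[tab == max(tab)])
  list(min = min(x), max = max(x), mode = sort(modes))
}

#' Per-subfamily summary of intron counts
#'
#' @param profiles Named list of \code{intron_profile}s.
#' @param calls data.frame with \code{gene_id} and \code{subfamily}.
#' @return data.frame: \code{subfamily}, \code{n}, \code{min}, \code{max},
#'   and \code{mode} (comma-joined when tied). Subfamilies with no profiled
#'   member are omitted with a warning.
#' @export
structure_mode_by_subfamily <- function(profiles, calls) {
  counts <- vapply(profiles, function(p) p$n_introns, numeric(1))
  summarize_counts_by_subfamily(counts, calls, what = "intron profiles")
}

summarize_counts_by_subfamily <- function(counts, calls, what = "counts") {
  rows <- list()
  for (sf in sort(unique(calls$subfamily))) {
    ids <- calls$gene_id[calls$subfamily == sf]
    x <- counts[names(counts) %in% ids]
    if (!length(x)) {
      warning("subfamily ", sf, " has no ", what, "; omitted")
      next
    }
    s <- count_summary(x)
    rows[[sf]] <- data.frame(subfamily = sf, n = length(x),
                             min = s$min, max = s$max,
                             mode = paste(s$mode, collapse = ","),
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Shared intron structure between two genes
#'
#' Matches the introns of two profiles greedily in coding order: two
#' introns match when their coding offsets differ by at most
#' \code{tolerance_nt} and their phases are equal. Returns the number of
#' shared introns and the Jaccard similarity
#' shared / (n_a + n_b - shared). Symmetric in its arguments.
#'
#' @param profile_a,profile_b \code{intron_profile}s.
#' @param tolerance_nt Offset tolerance in coding nucleotides (default 0,
#'   exact matching).
#' @return List: \code{n_shared_introns}, \code{jaccard} (1 when both
#'   profiles are intronless).
#' @export
shared_structure <- function(profile_a, profile_b, tolerance_nt = 0) {
  stopifnot(tolerance_nt >= 0)
  # equal phase means offsets congruent mod 3, so the matching decomposes by
  # phase class; within a class the in-order greedy sweep is optimal
  shared <- 0L
  for (ph in 0:2) {
    a <- profile_a$positions$offset[profile_a$positions$phase == ph]
    b <- profile_b$positions$offset[profile_b$positions$phase == ph]
    i <- j <- 1L
    while (i <= length(a) && j <= length(b)) {
      d <- a[i] - b[j]
      if (abs(d) <= tolerance_nt) {
        shared <- shared + 1L
        i <- i + 1L; j <- j + 1L
      } else if (d < 0) i <- i + 1L else j <- j + 1L
    }
  }
  tot <- profile_a$n_introns + profile_b$n_introns - shared
  list(n_shared_introns = shared,
       jaccard = if (tot == 0) 1 else shared / tot)
}
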