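## Family membership screening: E-value filtering of homology hits,
## the LRR + TM + kinase domain-architecture rule, and removal of
## redundant or defective protein sequences.

#' Read a homology hit table
#'
#' Reads a TSV of homology hits with columns \code{query_id},
#' \code{subject_id}, \code{evalue}. With \code{blast_outfmt6 = TRUE} the
#' file is read as 12-column tabular BLAST output (outfmt 6) and columns
#' 1, 2 and 11 are used.
#'
#' @param path Path to the table.
#' @param blast_outfmt6 Interpret as headerless BLAST outfmt-6.
#' @return data.frame with columns \code{query_id}, \code{subject_id},
#'   \code{evalue}. Malformed rows are reported with their row numbers.
#' @export
read_hit_table <- function(path, blast_outfmt6 = FALSE) {
  if (blast_outfmt6) {
    d <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
    if (ncol(d) < 11) stop("BLAST outfmt-6 input needs at least 11 columns")
    d <- data.frame(query_id = as.character(d[[1]]),
                    subject_id = as.character(d[[2]]),
                    evalue = d[[11]], stringsAsFactors = FALSE)
  } else {
    d <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
    need <- c("query_id", "subject_id", "evalue")
    if (!all(need %in% names(d)))
      stop("hit table must have columns: ", paste(need, collapse = ", "))
    d <- d[need]
  }
  ev <- suppressWarnings(as.numeric(d$evalue))
  bad <- which(is.na(ev) | ev < 0)
  if (length(bad))
    stop("malformed hit rows (missing or negative E-value): row ",
         paste(bad, collapse = ", "))
  d$evalue <- ev
  d
}

#' Filter homology hits by E-value
#'
#' @param hits data.frame with columns \code{query_id} and \code{evalue}.
#' @param cutoff E-value cutoff (> 0); hits are kept on \emph{strict}
#'   inequality (\code{evalue < cutoff}), the usual reporting convention.
#' @return Sorted character vector of unique query identifiers with at
#'   least one passing hit.
#' @export
filter_hits <- function(hits, cutoff = 1e-10) {
  stopifnot(is.numeric(cutoff), cutoff > 0)
  if (!all(c("query_id", "evalue") %in% names(hits)))
    stop("hits must have query_id and evalue columns")
  if (any(is.na(hits$evalue)) || any(hits$evalue < 0))
    stop("E-values must be non-negative and non-missing")
  sort(unique(as.character(hits$query_id[hits$evalue < cutoff])))
}

#' Construct a domain architecture
#'
#' Ordered domain annotations for one protein: LRR repeats, transmembrane
#' spans, kinase domains and any extra domains (e.g. malectin-like), each
#' as 1-based inclusive intervals in protein coordinates. Intervals within
#' each list must be non-overlapping; they are stored sorted by start.
#'
#' @param protein_id Protein identifier.
#' @param lrr,tm,kinase,extra Two-column matrices (start, end) or NULL;
#'   \code{extra} may carry domain names as row names.
#' @param protein_length Optional protein length for bounds checking.
#' @return Object of class \code{domain_architecture}.
#' @export
domain_architecture <- function(protein_id, lrr = NULL, tm = NULL,
                                kinase = NULL, extra = NULL,
                                protein_length = NULL) {
  as_iv <- function(x, what) {
    if (is.null(x) || !length(x)) return(matrix(numeric(0), 0, 2))
    x <- matrix(as.numeric(x), ncol = 2,
                dimnames = list(rownames(x), NULL))
    if (any(x[, 1] > x[, 2]) || any(x[, 1] < 1))
      stop(what, " intervals must satisfy 1 <= start <= end")
    if (!is.null(protein_length) && any(x[, 2] > protein_length))
      stop(what, " interval exceeds protein length")
    x <- x[order(x[, 1]), , drop = FALSE]
    if (nrow(x) > 1 && any(x[-1, 1] <= x[-nrow(x), 2]))
      stop(what, " intervals overlap")
    x
  }
  structure(list(protein_id = protein_id,
                 lrr = as_iv(lrr, "LRR"), tm = as_iv(tm, "TM"),
                 kinase = as_iv(kinase, "kinase"),
                 extra = as_iv(extra, "extra"),
                 protein_length = protein_length),
            class = "domain_architecture")
}

#' Read a domain annotation table into architectures
#'
#' Reads a TSV with columns \code{protein_id}, \code{domain_name},
#' \code{start}, \code{end} (1-based inclusive). Domain names containing
#' \code{"LRR"}, \code{"TM"} and \code{"kinase"}/\code{"KD"}
#' (case-insensitive) are mapped to the three architecture slots; other
#' names become extra domains.
#'
#' @param path Path to the table.
#' @return Named list of \code{\link{domain_architecture}} objects.
#' @export
read_domain_table <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("protein_id", "domain_name", "start", "end")
  if (!all(need %in% names(d)))
    stop("domain table must have columns: ", paste(need, collapse = ", "))
  split_d <- split(d, d$protein_id)
  lapply(split_d, function(dd) {
    kind <- function(name) {
      n <- tolower(name)
      if (grepl("lrr", n)) "lrr"
      else if (grepl("^tm|transmembrane", n)) "tm"
      else if (grepl("kinase|^kd$|pkinase", n)) "kinase"
      else "extra"
    }
    ks <- vapply(dd$domain_name, kind, character(1))
    iv <- function(sel) {
      if (!any(sel)) return(NULL)
      m <- cbind(dd$start[sel], dd$end[sel])
      rownames(m) <- dd$domain_name[sel]
      m
    }
    domain_architecture(dd$protein_id[1], lrr = iv(ks == "lrr"),
                        tm = iv(ks == "tm"), kinase = iv(ks == "kinase"),
                        extra = iv(ks == "extra"))
  })
}

#' Decide family membership from a domain architecture
#'
#' A protein is accepted as an LRR-RLK iff it has at least one LRR repeat,
#' at least one transmembrane span, exactly one kinase domain, and the
#' receptor topology holds: every LRR ends before the first TM begins
#' (extracellular LRRs) and the kinase domain starts after the last TM ends
#' (intracellular kinase). Rejections carry one reason code per failed
#' condition.
#'
#' @param arch A \code{\link{domain_architecture}}.
#' @param require_topology Enforce the LRR-TM-kinase ordering rule
#'   (default TRUE); disable to accept any protein with the three domain
#'   kinds present.
#' @return List with \code{accept} (logical) and \code{reasons} (character
#'   vector of codes among \code{no_LRR}, \code{no_TM}, \code{no_KD},
#'   \code{multiple_KD}, \code{bad_topology}; empty when accepted).
#' @export
classify_membership <- function(arch, require_topology = TRUE) {
  stopifnot(inherits(arch, "domain_architecture"))
  reasons <- character(0)
  if (nrow(arch$lrr) < 1) reasons <- c(reasons, "no_LRR")
  if (nrow(arch$tm) < 1) reasons <- c(reasons, "no_TM")
  if (nrow(arch$kinase) < 1) reasons <- c(reasons, "no_KD")
  if (nrow(arch$kinase) > 1) reasons <- c(reasons, "multiple_KD")
  if (require_topology && !length(reasons)) {
    first_tm <- min(arch$tm[, 1])
    last_tm <- max(arch$tm[, 2])
    if (any(arch$lrr[, 2] >= first_tm) || arch$kinase[1, 1] <= last_tm)
      reasons <- c(reasons, "bad_topology")
  }
  list(accept = !length(reasons), reasons = reasons)
}

#' Drop redundant and defective protein sequences
#'
#' Collapses exact-duplicate sequences to one representative (the
#' lexicographically smallest identifier) and removes defective sequences:
#' those containing an internal stop symbol \code{*} or shorter than
#' \code{min_aa} residues.
#'
#' @param seqs Named character vector of amino-acid sequences.
#' @param min_aa Minimum length in residues (default 100).
#' @return List with \code{kept} (named character vector),
#'   \code{duplicates} (ids dropped as duplicates) and \code{defective}
#'   (ids dropped as defective).
#' @export
drop_redundant <- function(seqs, min_aa = 100) {
  if (!length(seqs))
    return(list(kept = stats::setNames(character(0), character(0)),
                duplicates = character(0), defective = character(0)))
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must have unique names")
  s <- toupper(seqs)
  core <- sub("\\*$", "", s)  # a single trailing stop is tolerated
  defective <- names(s)[grepl("\\*", core) | nchar(core) < min_aa]
  s <- s[!names(s) %in% defective]
  dup <- character(0)
  if (length(s)) {
    grp <- split(names(s), unname(s))
    keep <- vapply(grp, function(ids) sort(ids)[1], character(1))
    dup <- setdiff(names(s), keep)
    s <- s[sort(keep)]
  }
  list(kept = seqs[names(s)], duplicates = sort(dup), defective = sort(defective))
}

#' Screen a candidate set for family membership
#'
#' End-to-end screening: E-value filter on the hit table, union with any
#' pre-annotated candidates, architecture classification, and removal of
#' redundant/defective sequences. This mirrors the standard receptor-kinase
#' identification protocol in which homology search and domain annotation
#' are produced by external tools and only their tabular outputs are
#' consumed.
#'
#' @param hits Hit data.frame (see \code{\link{filter_hits}}).
#' @param architectures Named list of \code{\link{domain_architecture}}s.
#' @param seqs Named character vector of protein sequences.
#' @param cutoff E-value cutoff.
#' @param extra_candidates Identifiers to include regardless of the hit
#'   filter (e.g. genes pre-annotated with the family's domains).
#' @param min_aa Passed to \code{\link{drop_redundant}}.
#' @return data.frame report: \code{protein_id}, \code{accepted}, and
#'   \code{reason} (comma-separated codes, \code{""} when accepted).
#' @export
screen_family <- function(hits, architectures, seqs, cutoff = 1e-10,
                          extra_candidates = character(0), min_aa = 100) {
  cand <- sort(union(filter_hits(hits, cutoff), extra_candidates))
  red <- drop_redundant(seqs[names(seqs) %in% cand], min_aa = min_aa)
  rows <- lapply(cand, function(id) {
    if (id %in% red$defective)
      return(data.frame(protein_id = id, accepted = FALSE, reason = "defective"))
    if (id %in% red$duplicates)
      return(data.frame(protein_id = id, accepted = FALSE, reason = "duplicate"))
    if (!id %in% names(architectures))
      return(data.frame(protein_id = id, accepted = FALSE, reason = "no_architecture"))
    cm <- classify_membership(architectures[[id]])
    data.frame(protein_id = id, accepted = cm$accept,
               reason = paste(cm$reasons, collapse = ","))
  })
  do.call(rbind, rows)
}
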