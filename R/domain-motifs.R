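## LRR-repeat count summaries, motif-presence matrices, and per-column
## information content with the bits-threshold consensus coding.

#' Per-subfamily range and mode of LRR repeat counts
#'
#' @param architectures Named list of \code{\link{domain_architecture}}s.
#' @param calls data.frame with \code{gene_id} and \code{subfamily}; every
#'   architecture's protein should have a call.
#' @return data.frame: \code{subfamily}, \code{n}, \code{min}, \code{max},
#'   \code{mode} (comma-joined when tied).
#' @export
lrr_range_by_subfamily <- function(architectures, calls) {
  counts <- vapply(architectures, function(a) nrow(a$lrr), numeric(1))
  names(counts) <- vapply(architectures, function(a) a$protein_id, character(1))
  summarize_counts_by_subfamily(counts, calls, what = "architectures")
}

#' Read a motif occurrence table
#'
#' TSV with columns \code{protein_id}, \code{motif_id}, \code{start},
#' \code{end}, \code{score} (the usual motif-scan output layout).
#'
#' @param path Path to the table.
#' @return data.frame of occurrences.
#' @export
read_motif_table <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("protein_id", "motif_id", "start", "end")
  if (!all(need %in% names(d)))
    stop("motif table must have columns: ", paste(need, collapse = ", "))
  if (any(d$start > d$end)) stop("motif occurrence with start > end")
  d
}

#' Motif presence categories per subfamily
#'
#' Classifies each subfamily x motif combination by the fraction of
#' members carrying at least one occurrence: \code{all} (every member),
#' \code{most} (more than \code{most_threshold} but not all), \code{some}
#' (more than none, at most the threshold), \code{none}. Also lists
#' subfamily-specific motifs: those at category all/most in exactly one
#' subfamily and absent (\code{none}) everywhere else.
#'
#' @param occurrences Occurrence data.frame (\code{protein_id},
#'   \code{motif_id}).
#' @param calls data.frame with \code{gene_id}, \code{subfamily}.
#' @param motifs Motif vocabulary; defaults to the motifs observed.
#' @param most_threshold Fraction separating \code{some} from \code{most}
#'   (default 0.5).
#' @return List: \code{matrix} (subfamily x motif character matrix of
#'   categories), \code{fraction} (numeric matrix of member fractions), and
#'   \code{subfamily_specific} (data.frame \code{motif}, \code{subfamily}).
#' @export
motif_presence <- function(occurrences, calls, motifs = NULL,
                           most_threshold = 0.5) {
  if (is.null(motifs)) motifs <- sort(unique(occurrences$motif_id))
  subs <- sort(unique(calls$subfamily))
  frac <- matrix(0, length(subs), length(motifs),
                 dimnames = list(subs, motifs))
  for (sf in subs) {
    members <- calls$gene_id[calls$subfamily == sf]
    for (mo in motifs) {
      carriers <- unique(occurrences$protein_id[occurrences$motif_id == mo])
      frac[sf, mo] <- mean(members %in% carriers)
    }
  }
  cat_of <- function(f) {
    if (f == 0) "none"
    else if (f == 1) "all"
    else if (f > most_threshold) "most"
    else "some"
  }
  cats <- apply(frac, c(1, 2), cat_of)
  specific <- list()
  for (mo in motifs) {
    strong <- subs[cats[, mo] %in% c("all", "most")]
    absent_elsewhere <- all(cats[setdiff(subs, strong), mo] == "none")
    if (length(strong) == 1 && absent_elsewhere)
      specific[[mo]] <- data.frame(motif = mo, subfamily = strong,
                                   stringsAsFactors = FALSE)
  }
  list(matrix = cats, fraction = frac,
       subfamily_specific = if (length(specific))
         do.call(rbind, c(specific, list(make.row.names = FALSE)))
       else data.frame(motif = character(0), subfamily = character(0)))
}

#' Information content of an alignment column
#'
#' Bits of a protein alignment column: \eqn{\log_2 20 - H}, where H is the
#' Shannon entropy of the amino-acid frequencies over the non-gap symbols
#' (no small-sample correction). Ranges from 0 (uniform) to
#' \eqn{\log_2 20 \approx 4.322} (invariant column).
#'
#' @param column Character vector of amino-acid symbols; \code{"-"},
#'   \code{"."} and \code{NA} are gaps.
#' @param gap_as_symbol Count gaps as a 21st symbol instead of excluding
#'   them (then the maximum is \eqn{\log_2 21}).
#' @return Bits (non-negative scalar).
#' @export
column_bits <- function(column, gap_as_symbol = FALSE) {
  x <- toupper(as.character(column))
  gap <- is.na(x) | x %in% c("-", ".")
  if (!gap_as_symbol) x <- x[!gap] else x[gap] <- "-"
  if (!length(x)) stop("column has no non-gap symbols")
  p <- table(x) / length(x)
  H <- -sum(p * log2(p))
  n_alpha <- if (gap_as_symbol) 21 else 20
  max(log2(n_alpha) - H, 0)
}

#' Consensus emphasis coding from column bits
#'
#' The consensus residue of a column is its modal residue (ties broken
#' lexicographically) and its rendering emphasis follows the bits
#' thresholds: \code{x} below 1 bit, lowercase in [1, 2), uppercase in
#' [2, 3), bold capital at 3 bits and above.
#'
#' @param residue Consensus residue (single amino-acid symbol), or a full
#'   column (character vector) from which the modal residue is taken.
#' @param bits Information content of the column; computed from the column
#'   when a full column is given and \code{bits} is missing.
#' @return List of class \code{consensus_column}: \code{residue},
#'   \code{bits}, \code{emphasis} in \{x, lowercase, uppercase, bold\} and
#'   \code{rendered} (the markup form: \code{x}, \code{a}, \code{A} or
#'   \code{*A*}).
#' @export
consensus_code <- function(residue, bits = NULL) {
  if (length(residue) > 1) {
    col <- toupper(residue[!is.na(residue) & !residue %in% c("-", ".")])
    if (is.null(bits)) bits <- column_bits(residue)
    tab <- table(col)
    residue <- sort(names(tab)[tab == max(tab)])[1]
  }
  stopifnot(is.numeric(bits), bits >= 0)
  emphasis <- if (bits < 1) "x" else if (bits < 2) "lowercase" else
    if (bits < 3) "uppercase" else "bold"
  rendered <- switch(emphasis,
                     x = "x",
                     lowercase = tolower(residue),
                     uppercase = toupper(residue),
                     bold = paste0("*", toupper(residue), "*"))
  structure(list(residue = residue, bits = bits, emphasis = emphasis,
                 rendered = rendered), class = "consensus_column")
}

#' Consensus rendering of a protein alignment
#'
#' Applies \code{\link{column_bits}} and \code{\link{consensus_code}} to
#' every column of an alignment and concatenates the rendered symbols.
#'
#' @param aln Character matrix (sequences x positions) or named character
#'   vector of equal-length aligned sequences.
#' @param gap_as_symbol Passed to \code{\link{column_bits}}.
#' @return List: \code{consensus} (rendered string) and \code{columns}
#'   (data.frame \code{position}, \code{residue}, \code{bits},
#'   \code{emphasis}).
#' @export
consensus_sequence <- function(aln, gap_as_symbol = FALSE) {
  if (!is.matrix(aln)) {
    len <- unique(nchar(aln))
    if (length(len) != 1) stop("aligned sequences must have equal length")
    aln <- do.call(rbind, strsplit(aln, ""))
  }
  cols <- lapply(seq_len(ncol(aln)), function(j) {
    b <- column_bits(aln[, j], gap_as_symbol = gap_as_symbol)
    cc <- consensus_code(aln[, j], bits = b)
    data.frame(position = j, residue = cc$residue, bits = b,
               emphasis = cc$emphasis, rendered = cc$rendered,
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, cols)
  list(consensus = paste(d$rendered, collapse = ""),
       columns = d[c("position", "residue", "bits", "emphasis")])
}
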