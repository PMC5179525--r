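## Codon alignment container and FASTA I/O.

#' Construct a codon alignment
#'
#' A \code{codon_alignment} stores aligned in-frame coding sequences as a
#' taxa x sites integer matrix of codon states (indices into
#' \code{\link{codon_states}}); gaps and ambiguous codons are \code{NA} and
#' are treated as missing data by the likelihood machinery.
#'
#' @param sequences Named character vector of aligned nucleotide sequences
#'   (equal lengths, length divisible by 3) or a character matrix of codons.
#' @param allow_stop How to treat internal stop codons: \code{"error"}
#'   (default) or \code{"mask"} (replaced by missing data with a warning).
#' @return Object of class \code{codon_alignment} with elements \code{ids}
#'   and \code{codon} (integer matrix, \code{NA} = missing).
#' @export
codon_alignment <- function(sequences, allow_stop = c("error", "mask")) {
  allow_stop <- match.arg(allow_stop)
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must have unique names")
  len <- unique(nchar(sequences))
  if (length(len) != 1) stop("aligned sequences must have equal length")
  if (len %% 3 != 0) stop("alignment length must be divisible by 3")
  nsite <- len / 3
  tab <- codon_tables()
  codons_txt <- t(vapply(toupper(sequences), function(s) {
    substring(s, seq(1, len, 3), seq(3, len, 3))
  }, character(nsite)))
  state <- match(codons_txt, tab$codons)
  gc <- Biostrings::GENETIC_CODE
  is_stop <- codons_txt %in% names(gc)[gc == "*"]
  if (any(is_stop)) {
    if (allow_stop == "error")
      stop("internal stop codon(s) in alignment; use allow_stop = \"mask\" to treat as missing")
    warning(sum(is_stop), " stop codon(s) masked as missing data")
  }
  m <- matrix(state, nrow = length(sequences))
  rownames(m) <- names(sequences)
  structure(list(ids = names(sequences), codon = m),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment:", length(x$ids), "sequences x", ncol(x$codon),
      "codon sites (", sum(is.na(x$codon)), "missing codons )\n")
  invisible(x)
}

#' @export
as.character.codon_alignment <- function(x, ...) {
  tab <- codon_tables()
  txt <- matrix("---", nrow = nrow(x$codon), ncol = ncol(x$codon))
  ok <- !is.na(x$codon)
  txt[ok] <- tab$codons[x$codon[ok]]
  out <- apply(txt, 1, paste0, collapse = "")
  names(out) <- x$ids
  out
}

#' Read an in-frame codon FASTA alignment
#'
#' @param path Path to a FASTA file of aligned coding sequences.
#' @param allow_stop Passed to \code{\link{codon_alignment}}.
#' @return A \code{codon_alignment}.
#' @export
read_codon_fasta <- function(path, allow_stop = c("error", "mask")) {
  dna <- Biostrings::readBStringSet(path)
  seqs <- as.character(dna)
  names(seqs) <- sub("\\s.*$", "", names(dna))
  codon_alignment(seqs, allow_stop = match.arg(allow_stop))
}

#' Write a codon alignment to FASTA
#'
#' @param aln A \code{codon_alignment}.
#' @param path Output path.
#' @export
write_codon_fasta <- function(aln, path) {
  seqs <- as.character(aln)
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
  invisible(path)
}
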