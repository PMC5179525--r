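## FPKM computation from fragment-count tables and expression-level
## categorization with per-subfamily roll-ups.

#' Fragments per kilobase per million mapped fragments
#'
#' \code{fpkm = counts * 1e9 / (length_bp * total_fragments)}: removes
#' library-size and transcript-length (fragmentation) bias. Vectorized and
#' invariant under joint rescaling of counts and totals.
#'
#' @param counts Fragment counts: a vector, or a genes x tissues matrix.
#' @param length_bp Per-gene effective length in bp (> 0), recycled along
#'   rows of a matrix.
#' @param total_fragments Per-tissue total mapped fragments (> 0), recycled
#'   along columns of a matrix.
#' @return FPKM values with the shape of \code{counts}.
#' @export
fpkm <- function(counts, length_bp, total_fragments) {
  if (any(length_bp <= 0)) stop("effective length must be positive")
  if (any(total_fragments <= 0)) stop("total fragments must be positive")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.matrix(counts)) {
    sweep(sweep(counts * 1e9, 1, length_bp, "/"), 2, total_fragments, "/")
  } else {
    counts * 1e9 / (length_bp * total_fragments)
  }
}

#' Categorize expression levels
#'
#' Maps FPKM values to \code{low} (< \code{low} cutoff), \code{moderate}
#' (between the cutoffs, inclusive) and \code{high} (> \code{high} cutoff).
#' Alternatively, \code{mode = "tertile"} splits each tissue's genes into
#' equal thirds by rank.
#'
#' @param fpkm_matrix Genes x tissues FPKM matrix.
#' @param thresholds Numeric \code{c(low, high)} cutoffs
#'   (default \code{c(1, 10)}); values below \code{low} are low, above
#'   \code{high} are high, the rest moderate.
#' @param mode \code{"cutoff"} (default) or \code{"tertile"}.
#' @return Character matrix of categories with the input's dimnames.
#' @export
categorize_expression <- function(fpkm_matrix, thresholds = c(1, 10),
                                  mode = c("cutoff", "tertile")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(fpkm_matrix))
  out <- matrix("moderate", nrow(fpkm_matrix), ncol(fpkm_matrix),
                dimnames = dimnames(fpkm_matrix))
  if (mode == "cutoff") {
    stopifnot(length(thresholds) == 2, thresholds[1] < thresholds[2])
    out[fpkm_matrix < thresholds[1]] <- "low"
    out[fpkm_matrix > thresholds[2]] <- "high"
  } else {
    for (j in seq_len(ncol(fpkm_matrix))) {
      q <- stats::quantile(fpkm_matrix[, j], c(1, 2) / 3, names = FALSE)
      out[fpkm_matrix[, j] <= q[1], j] <- "low"
      out[fpkm_matrix[, j] > q[2], j] <- "high"
    }
  }
  out
}

#' Per-subfamily expression-category roll-up
#'
#' For every subfamily and tissue, the fraction of members in each
#' category. Fractions sum to 1 within each subfamily x tissue cell.
#'
#' @param categories Genes x tissues character matrix from
#'   \code{\link{categorize_expression}} (rownames = gene ids).
#' @param calls data.frame with \code{gene_id}, \code{subfamily}.
#' @return data.frame: \code{subfamily}, \code{tissue}, \code{category},
#'   \code{fraction}, \code{n_genes}.
#' @export
expression_rollup <- function(categories, calls) {
  lv <- c("low", "moderate", "high")
  rows <- list()
  for (sf in sort(unique(calls$subfamily))) {
    ids <- intersect(calls$gene_id[calls$subfamily == sf],
                     rownames(categories))
    if (!length(ids)) next
    for (tis in colnames(categories)) {
      f <- table(factor(categories[ids, tis], levels = lv)) / length(ids)
      rows[[length(rows) + 1]] <-
        data.frame(subfamily = sf, tissue = tis, category = lv,
                   fraction = as.numeric(f), n_genes = length(ids),
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
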