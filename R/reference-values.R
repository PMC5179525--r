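## Accessors for the published reference values shipped with the package:
## per-subfamily gene counts of the two compared genomes and the reported
## codeml site-model likelihoods used for statistic recomputation.

#' Published per-subfamily gene counts of the two compared genomes
#'
#' The reported LRR-RLK member counts per subfamily in the reference
#' lineage (Arabidopsis thaliana) and the query basal-angiosperm lineage
#' (Amborella trichopoda), together with the reported expansion ratio
#' R = n_reference / n_query (1 decimal).
#'
#' @return data.frame: \code{subfamily}, \code{n_reference},
#'   \code{n_query}, \code{ratio_reported}.
#' @export
published_subfamily_counts <- function() {
  utils::read.table(system.file("extdata", "subfamily_counts.tsv",
                                package = "lrrkit"),
                    sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Published codeml site-model likelihoods for the analyzed subfamilies
#'
#' Reported M0/M1/M3 parameter estimates and log-likelihoods for the five
#' analyzed subfamilies plus the reported M0-vs-M3 2|dlnL| statistics. The
#' subfamily-I M0 log-likelihood is reconstructed from that subfamily's
#' reported M3 log-likelihood and LRT statistic because the originally
#' reported value is internally inconsistent with them (see the
#' \code{m0_lnl_reconstructed} flag and the comments in the data file).
#'
#' @return data.frame with columns \code{subfamily}, \code{m0_omega},
#'   \code{m0_lnl}, \code{m0_lnl_reconstructed}, \code{m1_omega0},
#'   \code{m1_p0}, \code{m1_lnl}, \code{m3_lnl}, \code{lrt_m3_m0}.
#' @export
published_site_model_likelihoods <- function() {
  utils::read.table(system.file("extdata", "codeml_site_models.tsv",
                                package = "lrrkit"),
                    sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}
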