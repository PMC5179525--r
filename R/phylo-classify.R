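## Midpoint rooting and reference-guided subfamily classification on
## bootstrap-annotated phylogenies (ape "phylo" trees throughout).

#' Root a tree at its midpoint
#'
#' Places the root halfway along the path between the two leaves with the
#' largest patristic distance. Ties between equally distant leaf pairs are
#' broken by the lexicographic order of the (sorted) leaf-label pair, so
#' the result is deterministic.
#'
#' @param tree An \code{ape} \code{phylo} tree with branch lengths
#'   (>= 2 leaves).
#' @return A rooted \code{phylo} tree. All leaf-to-leaf patristic distances
#'   are preserved; the two maximally distant leaves are equidistant from
#'   the new root.
#' @export
midpoint_root <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  if (ntip < 2) stop("midpoint rooting needs at least 2 leaves")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (all(tree$edge.length == 0))
    stop("all branch lengths are zero; the midpoint is undefined")
  D <- stats::cophenetic(tree)
  # deterministic tie-break: scan pairs in lexicographic label order
  labs <- sort(rownames(D))
  best <- NULL
  for (i in seq_len(length(labs) - 1)) {
    for (j in (i + 1):length(labs)) {
      d <- D[labs[i], labs[j]]
      if (is.null(best) || d > best$d + 1e-12) best <- list(a = labs[i], b = labs[j], d = d)
    }
  }
  half <- best$d / 2
  if (ntip == 2) {
    out <- ape::read.tree(text = sprintf("(%s:%.10g,%s:%.10g);",
                                         tree$tip.label[1], half,
                                         tree$tip.label[2], half))
    return(out)
  }
  ia <- match(best$a, tree$tip.label)
  ib <- match(best$b, tree$tip.label)
  path <- ape::nodepath(tree, ia, ib)
  # walk from leaf a towards b accumulating edge lengths until `half` reached
  edge_len <- function(u, v) {
    k <- which((tree$edge[, 1] == u & tree$edge[, 2] == v) |
               (tree$edge[, 1] == v & tree$edge[, 2] == u))
    tree$edge.length[k]
  }
  acc <- 0
  for (s in seq_len(length(path) - 1)) {
    u <- path[s]; v <- path[s + 1]
    len <- edge_len(u, v)
    if (acc + len >= half - 1e-12) {
      # midpoint lies on edge (u, v) at distance (half - acc) from u.
      # phytools::reroot measures `position` from the *parent* side of the
      # edge above `node`, where node is the child end in the tree's own
      # orientation.
      k <- which(tree$edge[, 1] == u & tree$edge[, 2] == v)
      if (length(k)) {             # u is parent of v
        pos <- half - acc
        node <- v
      } else {                     # v is parent of u
        node <- u
        pos <- len - (half - acc)
      }
      if (pos <= 1e-12) pos <- 0
      if (pos >= len) pos <- len
      rooted <- phytools::reroot(tree, node, position = pos)
      return(rooted)
    }
    acc <- acc + len
  }
  stop("internal error: midpoint not located on the path") # nocov
}

#' Classify query leaves into subfamilies from reference-labelled clades
#'
#' Assigns every unlabelled (query) leaf of a rooted tree to a subfamily
#' using reference leaves of known subfamily. For each subfamily the
#' maximal clade containing only that subfamily's references is found;
#' query leaves inside inherit the label, and the call is marked
#' \code{supported} when the clade's bootstrap support exceeds the
#' threshold. Subfamilies whose references do not form such a clade
#' (paraphyly) are flagged with \code{monophyly_uncertain} (the asterisk
#' convention) and their queries are assigned by the majority label of the
#' references in the query's smallest reference-containing ancestor clade.
#' Queries whose majority-rule label belongs to a cleanly monophyletic
#' subfamily they fall outside of are reported \code{"unclassified"}.
#'
#' @param tree Rooted \code{phylo}; node labels, when present, are read as
#'   numeric bootstrap supports (0-100).
#' @param reference_labels Named character vector mapping reference leaf
#'   labels to subfamily names (or a two-column data.frame
#'   \code{gene_id}, \code{subfamily}).
#' @param support_threshold Bootstrap support above which a clade counts as
#'   supported (default 80, strict inequality).
#' @return data.frame with one row per query leaf: \code{gene_id},
#'   \code{subfamily}, \code{supported}, \code{monophyly_uncertain}.
#' @export
assign_subfamilies <- function(tree, reference_labels, support_threshold = 80) {
  stopifnot(inherits(tree, "phylo"))
  if (is.data.frame(reference_labels)) {
    rl <- stats::setNames(as.character(reference_labels[[2]]),
                          as.character(reference_labels[[1]]))
  } else rl <- reference_labels
  rl <- rl[names(rl) %in% tree$tip.label]
  if (!length(rl)) stop("no reference labels match any tree leaf")
  ntip <- length(tree$tip.label)
  ref_idx <- match(names(rl), tree$tip.label)
  queries <- setdiff(seq_len(ntip), ref_idx)
  supports <- suppressWarnings(as.numeric(tree$node.label))

  tips_under <- function(node) {
    if (node <= ntip) node else unlist(phangorn::Descendants(tree, node, "tips"))
  }
  node_support <- function(node) {
    if (node <= ntip || !length(supports)) return(NA_real_)
    supports[node - ntip]
  }
  parent_of <- function(node) {
    k <- which(tree$edge[, 2] == node)
    if (length(k)) tree$edge[k, 1] else NA_integer_
  }
  ref_labels_under <- function(node) {
    tl <- tree$tip.label[intersect(tips_under(node), ref_idx)]
    unname(rl[tl])
  }

  labels <- sort(unique(rl))
  clade_node <- stats::setNames(rep(NA_integer_, length(labels)), labels)
  uncertain <- stats::setNames(rep(FALSE, length(labels)), labels)
  for (L in labels) {
    refs_L <- ref_idx[rl[tree$tip.label[ref_idx]] == L]
    node <- if (length(refs_L) == 1) refs_L else ape::getMRCA(tree, refs_L)
    if (any(ref_labels_under(node) != L)) {
      uncertain[L] <- TRUE
      next
    }
    # maximal: extend towards the root while the clade stays pure
    repeat {
      pa <- parent_of(node)
      if (is.na(pa)) break
      labs_pa <- ref_labels_under(pa)
      if (any(labs_pa != L)) break
      node <- pa
    }
    clade_node[L] <- node
  }

  calls <- data.frame(gene_id = tree$tip.label[queries],
                      subfamily = "unclassified",
                      supported = FALSE, monophyly_uncertain = FALSE,
                      stringsAsFactors = FALSE)
  assigned <- rep(FALSE, length(queries))
  for (L in labels[!uncertain]) {
    node <- clade_node[L]
    inside <- queries %in% tips_under(node)
    calls$subfamily[inside] <- L
    calls$supported[inside] <- isTRUE(node_support(node) > support_threshold)
    assigned <- assigned | inside
  }
  # majority-rule fallback for the remaining queries
  for (qi in which(!assigned)) {
    q <- queries[qi]
    node <- q
    repeat {
      node <- parent_of(node)
      if (is.na(node)) break
      labs <- ref_labels_under(node)
      if (length(labs)) break
    }
    if (is.na(node) || !length(labs)) next
    tab <- sort(table(labs), decreasing = TRUE)
    winners <- names(tab)[tab == tab[1]]
    L <- sort(winners)[1]
    if (!uncertain[L]) next  # outside the clean clade of L: stays unclassified
    calls$subfamily[qi] <- L
    calls$supported[qi] <- isTRUE(node_support(node) > support_threshold)
    calls$monophyly_uncertain[qi] <- TRUE
  }
  calls
}
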