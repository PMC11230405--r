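#' Parse a Newick tree
#'
#' Thin validating wrapper around [ape::read.tree()]. Missing branch lengths
#' default to 0. Duplicate leaf names, negative branch lengths and malformed
#' strings are rejected.
#'
#' @param text a single Newick statement terminated by `;`.
#' @return an [ape::phylo] tree in postorder.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  if (!grepl(";", text)) stop("Newick parse error: missing terminating ';'")
  tr <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) NULL
  )
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop("Newick parse error near: ", substr(trimws(text), 1, 40))
  }
  if (anyDuplicated(tr$tip.label)) {
    dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
    stop("duplicate leaf names: ", paste(dup, collapse = ", "))
  }
  if (is.null(tr$edge.length)) {
    tr$edge.length <- rep(0, nrow(tr$edge))
  }
  tr$edge.length[is.na(tr$edge.length)] <- 0
  if (any(!is.finite(tr$edge.length))) stop("non-finite branch length")
  if (any(tr$edge.length < 0)) {
    stop("negative branch length on edge ", which(tr$edge.length < 0)[1])
  }
  ape::reorder.phylo(tr, "postorder")
}

#' Serialise a tree to Newick
#' @param tree an `ape::phylo` tree.
#' @return a Newick string ending in `;`.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree)
}

#' Per-edge branch scale factors
#'
#' Builds the per-edge multiplier vector used by the likelihood routines:
#' every branch gets `global`, and the terminal branch leading to each leaf
#' named in `terminal` gets `global * terminal[leaf]` (the foreground-branch
#' rate multiplier of the acceleration test). The vector is aligned with the
#' postorder edge matrix of `tree`.
#'
#' @param tree an `ape::phylo` tree.
#' @param global scale applied to every branch (e.g. the conserved scale rho).
#' @param terminal named numeric vector of extra multipliers for terminal
#'   branches, names are leaf labels.
#' @return numeric vector, one positive factor per edge.
#' @export
branch_scales <- function(tree, global = 1, terminal = NULL) {
  tree <- ape::reorder.phylo(tree, "postorder")
  stopifnot(is.numeric(global), length(global) == 1, global > 0)
  sc <- rep(global, nrow(tree$edge))
  if (length(terminal)) {
    if (is.null(names(terminal)) || any(!nzchar(names(terminal)))) {
      stop("terminal scales must be named by leaf label")
    }
    bad <- setdiff(names(terminal), tree$tip.label)
    if (length(bad)) stop("not a leaf of the tree: ", paste(bad, collapse = ", "))
    if (any(terminal <= 0)) stop("branch scales must be > 0")
    idx <- match(names(terminal), tree$tip.label)
    for (k in seq_along(idx)) {
      e <- which(tree$edge[, 2] == idx[k])
      sc[e] <- sc[e] * terminal[k]
    }
  }
  sc
}

#' Number of nodes (tips + internal) of a phylo tree
#' @noRd
n_nodes_total <- function(tree) length(tree$tip.label) + tree$Nnode
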