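#' Pruning-algorithm log-likelihoods for alignment columns
#'
#' Computes the Felsenstein pruning log-likelihood of each alignment column
#' under the substitution model, with every branch length `t_b` replaced by
#' `scales_b * t_b`. Gap/missing leaf states (code 0) contribute a
#' partial-likelihood vector of ones.
#'
#' @param tree an `ape::phylo` tree.
#' @param model a [hky_model()].
#' @param columns integer matrix of encoded states (see [encode_bases()]),
#'   one row per leaf (rownames must match the tree's leaf labels, in any
#'   order), one column per alignment column. A character matrix is encoded
#'   automatically.
#' @param scales per-edge scale factors from [branch_scales()], or a single
#'   number applied to every branch.
#' @return numeric vector of per-column log-likelihoods.
#' @export
columns_log_likelihood <- function(tree, model, columns, scales = 1) {
  stopifnot(inherits(model, "subst_model"))
  tree <- ape::reorder.phylo(tree, "postorder")
  if (is.character(columns)) columns <- encode_bases(columns)
  if (!is.matrix(columns)) columns <- matrix(columns, ncol = 1)
  tips <- tree$tip.label
  if (is.null(rownames(columns))) {
    if (nrow(columns) != length(tips)) {
      stop("columns has ", nrow(columns), " rows but the tree has ",
           length(tips), " leaves")
    }
  } else {
    missing <- setdiff(tips, rownames(columns))
    extra <- setdiff(rownames(columns), tips)
    if (length(missing) || length(extra)) {
      stop("leaf mismatch; missing from columns: ",
           paste(missing, collapse = ", "),
           "; not in tree: ", paste(extra, collapse = ", "))
    }
    columns <- columns[tips, , drop = FALSE]
  }
  if (length(scales) == 1) scales <- rep(scales, nrow(tree$edge))
  if (length(scales) != nrow(tree$edge)) {
    stop("scales must have one entry per edge")
  }
  if (any(!is.finite(scales)) || any(scales <= 0)) stop("scales must be > 0")
  storage.mode(columns) <- "integer"
  pruning_loglik(tree$edge, n_nodes_total(tree), length(tips),
                 tree$edge.length * scales,
                 model$U, model$lambda, model$Uinv, unname(model$pi), columns)
}

#' @rdname columns_log_likelihood
#' @param column a single column: named character/integer vector over leaves.
#' @export
column_log_likelihood <- function(tree, model, column, scales = 1) {
  m <- matrix(column, ncol = 1, dimnames = list(names(column), NULL))
  columns_log_likelihood(tree, model, m, scales)[1]
}

#' Simulate alignment columns along a tree
#'
#' Draws the root state from the equilibrium frequencies and evolves it down
#' the tree with transition matrices on scaled branches. Deterministic for a
#' fixed seed.
#'
#' @inheritParams columns_log_likelihood
#' @param n number of columns, >= 1.
#' @param seed integer seed; all randomness flows through it.
#' @return integer matrix (leaves x n) of state codes 1..4, rownames = leaf
#'   labels.
#' @export
simulate_columns <- function(tree, model, n, scales = 1, seed) {
  stopifnot(n >= 1)
  tree <- ape::reorder.phylo(tree, "postorder")
  if (length(scales) == 1) scales <- rep(scales, nrow(tree$edge))
  stopifnot(length(scales) == nrow(tree$edge))
  n_tip <- length(tree$tip.label)
  withr::with_seed(seed, {
    states <- matrix(0L, n_nodes_total(tree), n)
    root <- tree$edge[nrow(tree$edge), 1]
    states[root, ] <- sample.int(4, n, replace = TRUE, prob = model$pi)
    # preorder = reverse postorder: parent states always set first
    for (e in rev(seq_len(nrow(tree$edge)))) {
      P <- transition_matrix(model, tree$edge.length[e] * scales[e])
      par <- tree$edge[e, 1]
      ch <- tree$edge[e, 2]
      for (s in 1:4) {
        idx <- which(states[par, ] == s)
        if (length(idx)) {
          states[ch, idx] <- sample.int(4, length(idx), replace = TRUE,
                                        prob = P[s, ])
        }
      }
    }
    out <- states[seq_len(n_tip), , drop = FALSE]
    rownames(out) <- tree$tip.label
    out
  })
}
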