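# Weighted co-expression network: unsigned adjacency |cor|^beta, topological
# overlap, average-linkage module detection, eigengenes/kME and the hub-gene
# rule (top 10% intramodular connectivity with kME > 0.8).

#' Unsigned weighted adjacency from an expression matrix
#'
#' `a_ij = |cor(x_i, x_j)|^beta` (Pearson), with `a_ii = 0`. Genes with
#' constant expression are dropped with a warning.
#'
#' @param expression numeric matrix, genes x samples (>= 3 samples).
#' @param beta soft-thresholding power, > 0 (default 6).
#' @return symmetric adjacency matrix in `[0, 1]`.
#' @export
build_adjacency <- function(expression, beta = 6) {
  if (beta <= 0) stop("beta must be > 0")
  if (ncol(expression) < 3) stop("need at least 3 samples")
  sds <- apply(expression, 1, sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " constant-expression gene(s)")
    expression <- expression[sds > 0, , drop = FALSE]
  }
  a <- abs(cor(t(expression)))^beta
  diag(a) <- 0
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `L_ij = sum_u a_iu a_uj` and `k_i = sum_j a_ij`; `TOM_ii = 1`. The
#' module dissimilarity used downstream is `1 - TOM`.
#'
#' @param adjacency symmetric adjacency from [build_adjacency()].
#' @return symmetric TOM matrix in `[0, 1]`.
#' @export
topological_overlap <- function(adjacency) {
  if (!isSymmetric(unname(adjacency))) stop("adjacency must be symmetric")
  L <- adjacency %*% adjacency
  k <- rowSums(adjacency)
  denom <- outer(k, k, pmin) + 1 - adjacency
  tom <- (L + adjacency) / denom
  diag(tom) <- 1
  tom
}

#' Detect co-expression modules
#'
#' Average-linkage hierarchical clustering on `1 - TOM` with a flat cut at
#' `cut_height`; clusters smaller than `min_module_size` get label 0
#' (unassigned). Labels are renumbered by decreasing module size.
#'
#' @param tom matrix from [topological_overlap()].
#' @param min_module_size minimum module size (default 20).
#' @param cut_height flat cut height on the `1 - TOM` dendrogram. The
#'   default 0.9 reflects the scale of TOM dissimilarities: unrelated genes
#'   sit near 1 (sharing essentially no weighted neighbourhood), co-module
#'   genes well below it even at moderate noise.
#' @return integer vector of module labels named by gene.
#' @export
detect_modules <- function(tom, min_module_size = 20, cut_height = 0.9) {
  n <- nrow(tom)
  genes <- rownames(tom)
  if (is.null(genes)) genes <- paste0("g", seq_len(n))
  if (n < min_module_size) {
    return(setNames(rep(0L, n), genes))
  }
  hc <- hclust(as.dist(1 - tom), method = "average")
  raw <- cutree(hc, h = cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_module_size]
  labels <- rep(0L, n)
  if (length(keep)) {
    keep <- keep[order(-sizes[keep])]
    for (i in seq_along(keep)) labels[raw == as.integer(keep[i])] <- i
  }
  setNames(labels, genes)
}

#' Module eigengenes, kME and summaries
#'
#' The eigengene is the first right-singular direction of the
#' gene-standardised module submatrix (unit norm), sign-aligned so that it
#' correlates non-negatively with the mean module profile. `kME` is each
#' gene's correlation with its module eigengene; a one-gene module's
#' eigengene is that gene's standardised profile.
#'
#' @param expression genes x samples matrix.
#' @param labels module labels from [detect_modules()] (label 0 is skipped).
#' @return named list per module label: `eigengene` (per-sample, unit
#'   norm), `kME` (named per gene), `genes`, `connectivity` (intramodular
#'   `k_i`, filled by [hub_genes()] callers via adjacency when needed).
#' @export
module_eigengene <- function(expression, labels) {
  stopifnot(!is.null(rownames(expression)))
  mods <- sort(unique(labels[labels > 0]))
  out <- list()
  for (m in mods) {
    genes <- names(labels)[labels == m]
    sub <- expression[genes, , drop = FALSE]
    z <- t(scale(t(sub)))
    if (length(genes) == 1) {
      e <- as.numeric(z)
      e <- e / sqrt(sum(e^2))
    } else {
      sv <- svd(z, nu = 0, nv = 1)
      e <- sv$v[, 1]
    }
    if (cor(e, colMeans(z)) < 0) e <- -e
    kme <- apply(sub, 1, cor, y = e)
    out[[as.character(m)]] <- list(module = m, eigengene = e,
                                   kME = kme, genes = genes)
  }
  out
}

#' Hub genes of each module
#'
#' Implements the hub rule: rank module genes by intramodular connectivity
#' `k_i = sum_{j in module, j != i} a_ij` (connection weight to all other
#' module genes), take the top `ceil(top_frac * module size)`, and retain
#' those with module membership `kME > kme_min`. Ties in `k` break by
#' higher kME, then lexicographic gene id. `ceil()` guarantees at least one
#' candidate in small modules.
#'
#' @param adjacency adjacency matrix from [build_adjacency()].
#' @param summaries output of [module_eigengene()].
#' @param top_frac fraction of the module taken by connectivity rank
#'   (default 0.10).
#' @param kme_min module-membership threshold (default 0.8, strict `>`).
#' @return named list per module: `hubs`, `candidates`, `connectivity`.
#' @export
hub_genes <- function(adjacency, summaries, top_frac = 0.10, kme_min = 0.8) {
  out <- list()
  for (nm in names(summaries)) {
    s <- summaries[[nm]]
    genes <- s$genes
    k <- rowSums(adjacency[genes, genes, drop = FALSE])
    ord <- order(-k, -s$kME[genes], genes)
    n_top <- ceiling(top_frac * length(genes))
    candidates <- genes[ord][seq_len(n_top)]
    hubs <- candidates[s$kME[candidates] > kme_min]
    out[[nm]] <- list(module = s$module, hubs = hubs,
                      candidates = candidates, connectivity = k)
  }
  out
}

#' Per-module gene-set enrichment
#'
#' Upper-tail hypergeometric test of a gene set within each module, BH
#' corrected across modules.
#'
#' @param labels module labels (named by gene; 0 = unassigned, still part
#'   of the universe).
#' @param gene_set character vector of genes (subset of the universe).
#' @param universe gene universe; defaults to all labelled genes.
#' @return data.frame: module, size, overlap, p, q.
#' @export
module_geneset_enrichment <- function(labels, gene_set,
                                      universe = names(labels)) {
  mods <- sort(unique(labels[labels > 0]))
  if (!length(mods)) stop("no modules")
  rows <- lapply(mods, function(m) {
    genes <- names(labels)[labels == m]
    h <- hypergeometric_overlap(genes, gene_set, universe)
    data.frame(module = m, size = length(genes), overlap = h$overlap,
               p = h$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
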