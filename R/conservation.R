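#' Parameters of the two-state conservation phylo-HMM
#'
#' The HMM has a neutral state (branch scale 1) and a conserved state
#' (branch scale `rho`). `mu` is the conserved-to-neutral switch probability
#' and `nu` the neutral-to-conserved one, so the expected conserved-element
#' length is `1/mu` and the stationary conserved coverage `nu/(mu+nu)`.
#' Defaults give 45-bp expected elements at ~5% coverage, consistent with
#' the short (tens of bp) conserved elements the pipeline targets; both are
#' configurable.
#'
#' @param rho conserved branch scale in (0, 1]; `NA` means estimate it by
#'   maximising the HMM likelihood over a coarse grid with golden-section
#'   refinement.
#' @param expected_length expected conserved element length in bp (sets
#'   `mu = 1/expected_length`).
#' @param coverage stationary conserved-state probability (sets `nu`).
#' @param mu,nu explicit transition probabilities, overriding
#'   `expected_length`/`coverage`.
#' @param mode decoding mode, `"posterior"` (default) or `"viterbi"`.
#' @param threshold posterior threshold for the conserved call; a tie at
#'   exactly the threshold decodes as conserved.
#' @param min_length minimum conserved-region length in bp (default 20).
#' @param min_informative_frac region-level filter: minimum mean fraction of
#'   non-missing leaves over the region's columns (0 disables).
#' @return an object of class `phylo_hmm_params`.
#' @export
phylo_hmm_params <- function(rho = 0.3, expected_length = 45, coverage = 0.05,
                             mu = 1 / expected_length,
                             nu = mu * coverage / (1 - coverage),
                             mode = c("posterior", "viterbi"),
                             threshold = 0.5, min_length = 20,
                             min_informative_frac = 0) {
  mode <- match.arg(mode)
  if (!is.na(rho) && (rho <= 0 || rho > 1)) stop("rho must be in (0, 1]")
  stopifnot(mu > 0, mu < 1, nu > 0, nu < 1, threshold > 0, threshold < 1,
            min_length >= 1)
  structure(list(rho = rho, mu = mu, nu = nu, mode = mode,
                 threshold = threshold, min_length = as.integer(min_length),
                 min_informative_frac = min_informative_frac),
            class = "phylo_hmm_params")
}

logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  ifelse(is.infinite(m) & m < 0, -Inf, m + log(exp(a - m) + exp(b - m)))
}

# log-space forward-backward over a 2 x n log-emission matrix.
# Rows: 1 = neutral, 2 = conserved. Returns list(posterior_conserved, loglik).
hmm_forward_backward <- function(loge, mu, nu, init = NULL) {
  n <- ncol(loge)
  lT <- log(matrix(c(1 - nu, mu, nu, 1 - mu), 2, 2))  # [from, to]
  if (is.null(init)) init <- c(mu, nu) / (mu + nu)
  la <- matrix(-Inf, 2, n)
  la[, 1] <- log(init) + loge[, 1]
  for (t in 2:n) {
    la[1, t] <- loge[1, t] + logsumexp2(la[1, t - 1] + lT[1, 1], la[2, t - 1] + lT[2, 1])
    la[2, t] <- loge[2, t] + logsumexp2(la[1, t - 1] + lT[1, 2], la[2, t - 1] + lT[2, 2])
  }
  lb <- matrix(0, 2, n)
  if (n > 1) for (t in (n - 1):1) {
    lb[1, t] <- logsumexp2(lT[1, 1] + loge[1, t + 1] + lb[1, t + 1],
                           lT[1, 2] + loge[2, t + 1] + lb[2, t + 1])
    lb[2, t] <- logsumexp2(lT[2, 1] + loge[1, t + 1] + lb[1, t + 1],
                           lT[2, 2] + loge[2, t + 1] + lb[2, t + 1])
  }
  lz <- logsumexp2(la[1, n], la[2, n])
  list(posterior = exp(la[2, ] + lb[2, ] - lz), loglik = lz)
}

# log-space Viterbi; returns logical vector (TRUE = conserved).
hmm_viterbi <- function(loge, mu, nu, init = NULL) {
  n <- ncol(loge)
  lT <- log(matrix(c(1 - nu, mu, nu, 1 - mu), 2, 2))
  if (is.null(init)) init <- c(mu, nu) / (mu + nu)
  dp <- matrix(-Inf, 2, n)
  bt <- matrix(1L, 2, n)
  dp[, 1] <- log(init) + loge[, 1]
  for (t in 2:n) {
    for (s in 1:2) {
      cand <- dp[, t - 1] + lT[, s]
      bt[s, t] <- which.max(cand)
      dp[s, t] <- loge[s, t] + max(cand)
    }
  }
  path <- integer(n)
  path[n] <- which.max(dp[, n])
  if (n > 1) for (t in (n - 1):1) path[t] <- bt[path[t + 1], t + 1]
  path == 2L
}

#' Per-column conserved-state posteriors
#'
#' Runs log-space forward-backward over the phylogenetic column
#' log-likelihoods emitted by the neutral (scale 1) and conserved (scale
#' `rho`) states. Log-space recursions keep the computation stable for
#' arbitrarily long alignments.
#'
#' @param columns encoded column matrix (leaves x n), see [encode_bases()].
#' @param tree an `ape::phylo` tree.
#' @param model a [hky_model()].
#' @param params a [phylo_hmm_params()] with a concrete `rho`.
#' @return numeric vector of conserved-state posteriors in `[0, 1]`.
#' @export
forward_backward <- function(columns, tree, model, params) {
  stopifnot(inherits(params, "phylo_hmm_params"), !is.na(params$rho))
  if (is.character(columns)) columns <- encode_bases(columns)
  if (ncol(columns) < 1) stop("need at least one column")
  loge <- rbind(columns_log_likelihood(tree, model, columns, 1),
                columns_log_likelihood(tree, model, columns, params$rho))
  bad <- which(!is.finite(loge[1, ]) | !is.finite(loge[2, ]))
  if (length(bad)) stop("non-finite emission at column ", bad[1])
  hmm_forward_backward(loge, params$mu, params$nu)$posterior
}

#' Call conserved regions from a multiple alignment
#'
#' Decodes the two-state phylo-HMM (posterior threshold or Viterbi), maps
#' maximal conserved runs to reference coordinates (columns where the
#' reference is gapped carry no coordinate; a run spanning them is emitted
#' as the containing reference interval) and filters to `min_length`.
#'
#' @param aln a [cg_alignment()].
#' @param tree an `ape::phylo` tree.
#' @param model a [hky_model()].
#' @param params a [phylo_hmm_params()]; if `params$rho` is `NA` it is
#'   estimated by grid search + golden-section refinement of the HMM
#'   likelihood.
#' @return data.frame of conserved regions: id, chrom, start, end, length,
#'   score (mean conserved posterior), sorted and non-overlapping. Empty
#'   alignment gives an empty set.
#' @export
call_conserved_regions <- function(aln, tree, model, params = phylo_hmm_params()) {
  stopifnot(inherits(aln, "cg_alignment"))
  empty <- data.frame(id = character(), chrom = character(), start = integer(),
                      end = integer(), length = integer(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (ncol(aln$seqs) == 0) return(empty)
  columns <- encode_bases(aln$seqs)
  if (is.na(params$rho)) params$rho <- estimate_hmm_rho(columns, tree, model, params)

  loge <- rbind(columns_log_likelihood(tree, model, columns, 1),
                columns_log_likelihood(tree, model, columns, params$rho))
  bad <- which(!is.finite(loge[1, ]) | !is.finite(loge[2, ]))
  if (length(bad)) stop("non-finite emission at column ", bad[1])
  fb <- hmm_forward_backward(loge, params$mu, params$nu)
  post <- fb$posterior
  state <- if (params$mode == "viterbi") {
    hmm_viterbi(loge, params$mu, params$nu)
  } else {
    post >= params$threshold
  }

  runs <- rle(state)
  ends_col <- cumsum(runs$lengths)
  starts_col <- ends_col - runs$lengths + 1L
  keep <- which(runs$values)
  if (!length(keep)) return(empty)
  coords <- ref_coords(aln)
  frac_inf <- colMeans(columns != 0L)
  out <- list()
  for (k in keep) {
    cols_k <- starts_col[k]:ends_col[k]
    pos <- coords[cols_k]
    pos <- pos[!is.na(pos)]
    if (!length(pos)) next  # run entirely inside a reference gap
    start <- min(pos)
    end <- max(pos) + 1L
    if (end - start < params$min_length) next
    if (params$min_informative_frac > 0 &&
        mean(frac_inf[cols_k]) < params$min_informative_frac) next
    out[[length(out) + 1L]] <- data.frame(
      chrom = aln$ref_chrom, start = start, end = end,
      length = end - start, score = mean(post[cols_k]),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$start), , drop = FALSE]
  res <- data.frame(id = sprintf("cr_%05d", seq_len(nrow(res))), res,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

# Maximise the total HMM log-likelihood over the conserved scale rho:
# coarse grid 0.1..0.9 then optimize() refinement around the grid optimum.
estimate_hmm_rho <- function(columns, tree, model, params) {
  ll_neutral <- columns_log_likelihood(tree, model, columns, 1)
  obj <- function(rho) {
    loge <- rbind(ll_neutral,
                  columns_log_likelihood(tree, model, columns, rho))
    hmm_forward_backward(loge, params$mu, params$nu)$loglik
  }
  grid <- seq(0.1, 0.9, by = 0.1)
  vals <- vapply(grid, obj, numeric(1))
  g <- grid[which.max(vals)]
  opt <- optimize(obj, c(max(0.01, g - 0.1), min(1, g + 0.1)),
                  maximum = TRUE, tol = 1e-4)
  opt$maximum
}

#' Score threshold achieving a target conserved-region FDR
#'
#' Simulates a fully neutral alignment of `n_null_bp` columns under the
#' model, calls candidate regions with the same parameters, and returns the
#' smallest score threshold at which the expected number of null regions
#' (scaled to the observed footprint) over the observed count is at most
#' `target`.
#'
#' @param observed_scores scores of the observed conserved regions.
#' @param tree,model,params as in [call_conserved_regions()].
#' @param n_null_bp columns of neutral sequence to simulate (>= 10 x
#'   `min_length`).
#' @param seed integer seed for the null simulation.
#' @param target target FDR (default 0.05); `target >= 1` returns the
#'   minimum observed score.
#' @param observed_bp footprint (bp) of the observed alignment, used to
#'   scale the null counts; defaults to `n_null_bp` (scale 1).
#' @return list with `threshold`, `null_scores`, `fdr_at_threshold`.
#' @export
estimate_cr_fdr <- function(observed_scores, tree, model,
                            params = phylo_hmm_params(), n_null_bp, seed,
                            target = 0.05, observed_bp = n_null_bp) {
  if (!length(observed_scores)) stop("no observed conserved regions")
  stopifnot(n_null_bp >= 10 * params$min_length)
  cols <- simulate_columns(tree, model, n_null_bp, scales = 1, seed = seed)
  aln <- cg_alignment(decode_bases(cols), ref = tree$tip.label[1])
  null <- call_conserved_regions(aln, tree, model, params)
  null_scores <- null$score
  if (target >= 1) {
    thr <- min(observed_scores)
    return(list(threshold = thr, null_scores = null_scores,
                fdr_at_threshold = NA_real_))
  }
  factor <- observed_bp / n_null_bp
  cand <- sort(unique(observed_scores))
  fdr <- vapply(cand, function(thr) {
    sum(null_scores >= thr) * factor / sum(observed_scores >= thr)
  }, numeric(1))
  ok <- which(fdr <= target)
  if (!length(ok)) {
    return(list(threshold = Inf, null_scores = null_scores,
                fdr_at_threshold = min(fdr)))
  }
  list(threshold = cand[min(ok)], null_scores = null_scores,
       fdr_at_threshold = fdr[min(ok)])
}
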