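#' Fit the conserved branch scale of a region
#'
#' Maximum-likelihood estimate of the single scale `rho` applied to every
#' branch, over (0, 1]. Used as the null model of the acceleration test.
#'
#' @param columns encoded column matrix (leaves x n).
#' @param tree an `ape::phylo` tree.
#' @param model a [hky_model()].
#' @param lower lower bound of the search interval.
#' @return the ML estimate `rho_hat`; exactly 1 when the boundary is at
#'   least as good as the interior optimum.
#' @export
fit_conserved_scale <- function(columns, tree, model, lower = 1e-3) {
  if (is.character(columns)) columns <- encode_bases(columns)
  if (all(columns == 0L)) stop("all columns are missing data")
  obj <- function(rho) sum(columns_log_likelihood(tree, model, columns, rho))
  opt <- optimize(obj, c(lower, 1), maximum = TRUE, tol = 1e-6)
  if (obj(1) >= opt$objective) 1 else opt$maximum
}

#' Lineage-specific acceleration likelihood-ratio test
#'
#' Null model: every branch scaled by the region's fitted conserved scale
#' `rho_hat`. Alternative: additionally the foreground terminal branch scaled
#' by `rho_hat * r`, with `r` optimised over `[1, 1000]`. The test is
#' one-sided for acceleration, so the LRT statistic is compared with the
#' boundary mixture `0.5 chi2_0 + 0.5 chi2_1`: p = 1 when the statistic is 0
#' and `0.5 P(chi2_1 >= Lambda)` otherwise.
#'
#' @param columns encoded column matrix for the region (leaves x n).
#' @param tree an `ape::phylo` tree.
#' @param model a [hky_model()].
#' @param foreground leaf name of the tested lineage.
#' @param rho optional fixed conserved scale; fitted per region when `NULL`.
#' @param r_max upper bound of the rate-multiplier search.
#' @param max_missing_frac regions whose foreground row is gapped/missing in
#'   at least this fraction of columns are flagged untestable (excluded from
#'   FDR correction); such regions are the deletion caller's territory, so
#'   AR and DEL calls stay mutually exclusive per lineage.
#' @return one-row data.frame: lineage, rho_hat, L0, L1, r_hat, lambda, p,
#'   testable.
#' @export
acceleration_lrt <- function(columns, tree, model, foreground, rho = NULL,
                             r_max = 1000, max_missing_frac = 0.8) {
  if (is.character(columns)) columns <- encode_bases(columns)
  tips <- ape::reorder.phylo(tree, "postorder")$tip.label
  if (!foreground %in% tips) stop("foreground lineage is not a leaf: ", foreground)
  fg_row <- columns[foreground, ]
  if (mean(fg_row == 0L) >= max_missing_frac) {
    return(data.frame(lineage = foreground, rho_hat = NA_real_,
                      L0 = NA_real_, L1 = NA_real_, r_hat = NA_real_,
                      lambda = NA_real_, p = NA_real_, testable = FALSE,
                      stringsAsFactors = FALSE))
  }
  if (is.null(rho)) rho <- fit_conserved_scale(columns, tree, model)
  L0 <- sum(columns_log_likelihood(tree, model, columns,
                                   branch_scales(tree, rho)))
  obj <- function(logr) {
    sc <- branch_scales(tree, rho, terminal = setNames(exp(logr), foreground))
    sum(columns_log_likelihood(tree, model, columns, sc))
  }
  opt <- optimize(obj, c(0, log(r_max)), maximum = TRUE, tol = 1e-6)
  # compare against both boundaries (r = 1 is the null itself)
  cand_logr <- c(0, opt$maximum, log(r_max))
  cand_ll <- c(L0, opt$objective, obj(log(r_max)))
  best <- which.max(cand_ll)
  L1 <- max(cand_ll[best], L0)
  lambda <- max(0, 2 * (L1 - L0))
  r_hat <- if (lambda <= 1e-9) 1 else exp(cand_logr[best])
  p <- if (lambda <= 1e-9) 1 else 0.5 * pchisq(lambda, df = 1, lower.tail = FALSE)
  data.frame(lineage = foreground, rho_hat = rho, L0 = L0, L1 = L1,
             r_hat = r_hat, lambda = lambda, p = p, testable = TRUE,
             stringsAsFactors = FALSE)
}

#' Run the acceleration test over all regions and lineages
#'
#' Extracts each region's columns from the alignment by reference
#' coordinates and applies [acceleration_lrt()] per lineage.
#'
#' @param aln a [cg_alignment()].
#' @param crs conserved-region data.frame from [call_conserved_regions()].
#' @param tree,model as in [acceleration_lrt()].
#' @param lineages character vector of tested leaf names.
#' @param rho optional fixed conserved scale (global-rho fast mode);
#'   per-region ML fit when `NULL`.
#' @return data.frame with one row per region x lineage (cr_id first).
#' @export
acceleration_scan <- function(aln, crs, tree, model, lineages, rho = NULL) {
  columns_all <- encode_bases(aln$seqs)
  coords <- ref_coords(aln)
  out <- vector("list", nrow(crs) * length(lineages))
  k <- 0L
  for (i in seq_len(nrow(crs))) {
    sel <- which(!is.na(coords) & coords >= crs$start[i] & coords < crs$end[i])
    cols <- columns_all[, sel, drop = FALSE]
    rho_i <- if (is.null(rho)) fit_conserved_scale(cols, tree, model) else rho
    for (lin in lineages) {
      k <- k + 1L
      res <- acceleration_lrt(cols, tree, model, lin, rho = rho_i)
      out[[k]] <- data.frame(cr_id = crs$id[i], res, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call accelerated regions at a target FDR
#'
#' Benjamini-Hochberg correction applied within each lineage separately,
#' over testable regions only.
#'
#' @param results data.frame from [acceleration_scan()] (needs cr_id,
#'   lineage, p, testable).
#' @param target_fdr FDR level (default 0.05).
#' @return list: `calls` (named list lineage -> cr_id vector) and `results`
#'   (input augmented with a `q` column).
#' @export
call_accelerated_regions <- function(results, target_fdr = 0.05) {
  if (is.null(results) || !nrow(results)) {
    return(list(calls = list(), results = results))
  }
  results$q <- NA_real_
  for (lin in unique(results$lineage)) {
    idx <- which(results$lineage == lin & results$testable)
    if (length(idx)) results$q[idx] <- p.adjust(results$p[idx], method = "BH")
  }
  calls <- lapply(split(results, results$lineage), function(d) {
    d$cr_id[!is.na(d$q) & d$q <= target_fdr]
  })
  list(calls = calls, results = results)
}

#' Call lineage-specific deletions within conserved regions
#'
#' A region is called deleted in a lineage when at least `gap_threshold` of
#' its reference columns are gap/unaligned for that lineage AND at least
#' `flank_aligned_threshold` of the columns in each `flank_bp` flank are
#' aligned for it — the flank requirement distinguishes deletion from
#' missing data.
#'
#' @param crs conserved-region data.frame (id, start, end).
#' @param aln a [cg_alignment()].
#' @param lineage leaf name tested.
#' @param gap_threshold minimum gapped fraction inside the region (default
#'   0.8).
#' @param flank_bp flank width in bp (default 500).
#' @param flank_aligned_threshold minimum aligned fraction in each flank
#'   (default 0.5).
#' @return data.frame: cr_id, lineage, gap_frac, flank_left, flank_right,
#'   truncated (flank clipped at a contig edge), call.
#' @export
call_deletions <- function(crs, aln, lineage, gap_threshold = 0.8,
                           flank_bp = 500, flank_aligned_threshold = 0.5) {
  stopifnot(gap_threshold > 0, gap_threshold <= 1,
            flank_aligned_threshold > 0, flank_aligned_threshold <= 1)
  if (!lineage %in% rownames(aln$seqs)) stop("unknown lineage: ", lineage)
  coords <- ref_coords(aln)
  gapped <- aln$seqs[lineage, ] == "-"
  n_ref <- max(coords, na.rm = TRUE) + 1L
  frac_gap <- function(lo, hi) {  # [lo, hi) on reference; NA if empty
    sel <- which(!is.na(coords) & coords >= lo & coords < hi)
    if (!length(sel)) return(NA_real_)
    mean(gapped[sel])
  }
  out <- lapply(seq_len(nrow(crs)), function(i) {
    s <- crs$start[i]; e <- crs$end[i]
    gf <- frac_gap(s, e)
    lf_lo <- max(0L, s - flank_bp)
    rf_hi <- min(n_ref, e + flank_bp)
    truncated <- (s - flank_bp < 0) || (e + flank_bp > n_ref)
    fl <- frac_gap(lf_lo, s)
    fr <- frac_gap(e, rf_hi)
    al_l <- if (is.na(fl)) 0 else 1 - fl
    al_r <- if (is.na(fr)) 0 else 1 - fr
    call <- !is.na(gf) && gf >= gap_threshold &&
      al_l >= flank_aligned_threshold && al_r >= flank_aligned_threshold
    data.frame(cr_id = crs$id[i], lineage = lineage, gap_frac = gf,
               flank_left = al_l, flank_right = al_r, truncated = truncated,
               call = call, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
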