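# Overlap enrichment statistics: Haldane-corrected odds ratios with Fisher
# exact p, Woolf heterogeneity across strata, hypergeometric set overlap,
# locus-set (LOLA-style) enrichment, consensus peaks, and the cross-species
# peak partition feeding the loss-of-function comparison.

#' Odds-ratio test on a 2x2 table
#'
#' Computes `OR = (a d)/(b c)` with the Haldane-Anscombe +0.5 correction
#' applied to every cell when any cell is 0 (flagged), the 95% CI from the
#' normal approximation on the log odds ratio, and the two-sided Fisher
#' exact p-value (point-probability method, via [stats::fisher.test()]).
#'
#' @param a,b,c,d non-negative integer cells: query-in-target, query-out,
#'   background-in-target, background-out.
#' @return object of class `enrichment_result`: table, or, ci (length 2),
#'   p, haldane.
#' @export
or_test <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be non-negative integers")
  }
  haldane <- any(cells == 0)
  cc <- if (haldane) cells + 0.5 else cells
  or <- (cc["a"] * cc["d"]) / (cc["b"] * cc["c"])
  se <- sqrt(sum(1 / cc))
  ci <- exp(log(or) + c(-1, 1) * qnorm(0.975) * se)
  p <- fisher.test(matrix(cells, 2, 2, byrow = TRUE))$p.value
  structure(list(table = cells, or = unname(or), ci = unname(ci), p = p,
                 haldane = haldane),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("2x2 [%d %d; %d %d]: OR = %.3f (95%% CI %.3f-%.3f), p = %.3g%s\n",
              x$table[1], x$table[2], x$table[3], x$table[4],
              x$or, x$ci[1], x$ci[2], x$p,
              if (x$haldane) " [Haldane +0.5]" else ""))
  invisible(x)
}

#' Interval-overlap enrichment of a query element set
#'
#' Builds the 2x2 table of any-overlap with `target_regions` for the query
#' elements versus the remaining background elements (query rows are removed
#' from the background to avoid double counting) and applies [or_test()].
#'
#' @param query_elements,background_elements,target_regions data.frames with
#'   chrom, start, end (0-based half-open). Query must be a subset of the
#'   background universe.
#' @return an `enrichment_result`.
#' @export
enrichment_2x2 <- function(query_elements, background_elements,
                           target_regions) {
  if (!nrow(query_elements)) stop("empty query element set")
  key <- function(df) paste(df$chrom, df$start, df$end)
  bg <- background_elements[!key(background_elements) %in% key(query_elements), ,
                            drop = FALSE]
  tgt <- intervals_to_gr(target_regions)
  q_in <- GenomicRanges::countOverlaps(intervals_to_gr(query_elements), tgt) > 0
  b_in <- if (nrow(bg)) {
    GenomicRanges::countOverlaps(intervals_to_gr(bg), tgt) > 0
  } else {
    logical(0)
  }
  or_test(sum(q_in), sum(!q_in), sum(b_in), sum(!b_in))
}

#' Woolf test of odds-ratio homogeneity across strata
#'
#' Per-stratum log odds ratios are combined with inverse-variance weights
#' `w_i = 1/(1/a + 1/b + 1/c + 1/d)`; the statistic
#' `X^2 = sum w_i (lnOR_i - pooled)^2` is chi-square with `strata - 1`
#' degrees of freedom under homogeneity. Haldane +0.5 is applied per
#' stratum when any of its cells is 0.
#'
#' @param stratum_tables list of length-4 numeric vectors `(a, b, c, d)`,
#'   or a 4-column matrix with one stratum per row; at least 2 strata.
#' @return list of class `woolf_result`: statistic, df, p, pooled_log_or,
#'   log_or (per stratum), weights.
#' @export
woolf_test <- function(stratum_tables) {
  if (is.matrix(stratum_tables)) {
    stratum_tables <- split(stratum_tables, row(stratum_tables))
  }
  if (length(stratum_tables) < 2) stop("Woolf test needs at least 2 strata")
  cells <- lapply(stratum_tables, function(x) {
    stopifnot(length(x) == 4)
    if (any(x == 0)) x + 0.5 else x
  })
  log_or <- vapply(cells, function(x) log(x[1] * x[4] / (x[2] * x[3])),
                   numeric(1))
  w <- vapply(cells, function(x) 1 / sum(1 / x), numeric(1))
  pooled <- sum(w * log_or) / sum(w)
  x2 <- sum(w * (log_or - pooled)^2)
  df <- length(cells) - 1L
  structure(list(statistic = x2, df = df,
                 p = pchisq(x2, df, lower.tail = FALSE),
                 pooled_log_or = pooled, log_or = unname(log_or),
                 weights = unname(w)),
            class = "woolf_result")
}

#' @export
print.woolf_result <- function(x, ...) {
  cat(sprintf("Woolf heterogeneity: X2 = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p))
  invisible(x)
}

#' Upper-tail hypergeometric overlap test
#'
#' `P(X >= |A intersect B|)` for the overlap of two subsets of a finite
#' universe, computed with the exact (log-space stable) hypergeometric tail.
#'
#' @param setA,setB character vectors, subsets of `universe`.
#' @param universe the finite universe of ids.
#' @return list: p, overlap, expected.
#' @export
hypergeometric_overlap <- function(setA, setB, universe) {
  offA <- setdiff(setA, universe)
  offB <- setdiff(setB, universe)
  if (length(offA) || length(offB)) {
    stop("not in universe: ", paste(head(c(offA, offB), 5), collapse = ", "))
  }
  setA <- unique(setA); setB <- unique(setB); universe <- unique(universe)
  k <- length(intersect(setA, setB))
  N <- length(universe)
  p <- if (k == 0) 1 else phyper(k - 1, length(setA), N - length(setA),
                                 length(setB), lower.tail = FALSE)
  list(p = p, overlap = k, expected = length(setA) * length(setB) / N)
}

#' LOLA-style locus-set overlap enrichment
#'
#' Applies [enrichment_2x2()] of the query element set against each region
#' set of a collection, with BH correction across sets.
#'
#' @param element_set query elements (chrom, start, end).
#' @param region_set_collection named list of region data.frames.
#' @param universe_elements background element universe containing the
#'   query.
#' @return data.frame: set, a, b, c, d, or, ci_lo, ci_hi, p, q, haldane.
#' @export
locus_set_enrichment <- function(element_set, region_set_collection,
                                 universe_elements) {
  stopifnot(length(region_set_collection) >= 1,
            !is.null(names(region_set_collection)))
  rows <- lapply(names(region_set_collection), function(nm) {
    e <- enrichment_2x2(element_set, universe_elements,
                        region_set_collection[[nm]])
    data.frame(set = nm, a = e$table[1], b = e$table[2], c = e$table[3],
               d = e$table[4], or = e$or, ci_lo = e$ci[1], ci_hi = e$ci[2],
               p = e$p, haldane = e$haldane, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Consensus peaks across replicates
#'
#' Base pairs covered by at least `min_reps` replicate peak sets, merged
#' into maximal intervals; intervals narrower than `min_width` bp are
#' dropped to suppress single-bp coverage artifacts at jittered edges.
#'
#' @param replicate_bed_list list of peak data.frames (chrom, start, end).
#' @param min_reps minimum replicate support (default 4).
#' @param min_width minimum output interval width in bp (default 50).
#' @return consensus peak data.frame (chrom, start, end), sorted.
#' @export
consensus_peaks <- function(replicate_bed_list, min_reps = 4, min_width = 50) {
  all_gr <- do.call(c, lapply(replicate_bed_list, intervals_to_gr))
  if (!length(all_gr)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  cov <- GenomicRanges::coverage(all_gr)
  sl <- IRanges::slice(cov, lower = min_reps, rangesOnly = TRUE)
  out <- do.call(rbind, lapply(names(sl), function(ch) {
    r <- sl[[ch]]
    if (!length(r)) return(NULL)
    data.frame(chrom = ch, start = IRanges::start(r) - 1L,
               end = IRanges::end(r), stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  out <- out[out$end - out$start >= min_width, , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition two species' peak sets into specific and shared classes
#'
#' Peaks are first merged within each species (overlapping input peaks are
#' collapsed); a peak is `shared` when it any-overlaps a peak of the other
#' species (1 bp suffices), otherwise species-specific. Every merged peak
#' is assigned exactly once.
#'
#' @param peaks_species1,peaks_species2 peak data.frames in one shared
#'   (pre-mapped) coordinate system.
#' @param species names used in the class labels.
#' @return data.frame: chrom, start, end, species, class with classes
#'   `<sp1>-specific`, `shared`, `<sp2>-specific`.
#' @export
classify_species_peaks <- function(peaks_species1, peaks_species2,
                                   species = c("species1", "species2")) {
  merge_peaks <- function(df) {
    gr <- GenomicRanges::reduce(intervals_to_gr(df))
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
  }
  p1 <- merge_peaks(peaks_species1)
  p2 <- merge_peaks(peaks_species2)
  ov1 <- GenomicRanges::countOverlaps(intervals_to_gr(p1),
                                      intervals_to_gr(p2)) > 0
  ov2 <- GenomicRanges::countOverlaps(intervals_to_gr(p2),
                                      intervals_to_gr(p1)) > 0
  p1$species <- species[1]
  p1$class <- ifelse(ov1, "shared", paste0(species[1], "-specific"))
  p2$species <- species[2]
  p2$class <- ifelse(ov2, "shared", paste0(species[2], "-specific"))
  out <- rbind(p1, p2)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Loss-of-function enrichment of accelerated regions
#'
#' Tests the AR set against background CRs for overlap with each class of a
#' cross-species peak partition: the focal species' specific peaks, shared
#' peaks, and the other species' specific peaks. Depletion in own/shared
#' classes with enrichment in other-specific peaks is the loss-of-function
#' signature.
#'
#' @param ars accelerated-region data.frame (chrom, start, end).
#' @param cr_background background CR universe containing the ARs.
#' @param peak_partition output of [classify_species_peaks()].
#' @return named list of `enrichment_result` per class; empty classes are
#'   skipped with a message.
#' @export
lof_enrichment <- function(ars, cr_background, peak_partition) {
  out <- list()
  for (cl in unique(peak_partition$class)) {
    regions <- peak_partition[peak_partition$class == cl, , drop = FALSE]
    if (!nrow(regions)) {
      message("skipping empty partition class: ", cl)
      next
    }
    out[[cl]] <- enrichment_2x2(ars, cr_background, regions)
  }
  out
}
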