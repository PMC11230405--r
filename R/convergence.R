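#' Parallel (convergent) elements across lineages of a group
#'
#' A conserved region called (accelerated or deleted) in at least
#' `min_lineages` lineages of one group — hibernator foreground or matched
#' homeotherm control — is a parallel element (pHibAR/pHibDEL or
#' pHomeoAR/pHomeoDEL).
#'
#' @param per_lineage_calls named list: lineage -> character vector of
#'   called CR ids.
#' @param background_cr_ids the shared background CR universe.
#' @param group group label recorded on the output (e.g. `"foreground"`).
#' @param min_lineages minimum number of lineages sharing the call
#'   (default 2).
#' @return data.frame: cr_id, group, n_lineages, lineages (comma-joined).
#' @export
find_parallel_elements <- function(per_lineage_calls, background_cr_ids,
                                   group = "foreground", min_lineages = 2) {
  all_calls <- unlist(per_lineage_calls, use.names = FALSE)
  bad <- setdiff(all_calls, background_cr_ids)
  if (length(bad)) stop("unknown CR id: ", paste(head(bad, 5), collapse = ", "))
  empty <- data.frame(cr_id = character(), group = character(),
                      n_lineages = integer(), lineages = character(),
                      stringsAsFactors = FALSE)
  if (!length(all_calls)) return(empty)
  hits <- lapply(names(per_lineage_calls), function(lin) {
    ids <- unique(per_lineage_calls[[lin]])
    if (!length(ids)) return(NULL)
    data.frame(cr_id = ids, lineage = lin, stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  tab <- split(hits$lineage, hits$cr_id)
  tab <- tab[lengths(tab) >= min_lineages]
  if (!length(tab)) return(empty)
  out <- data.frame(cr_id = names(tab), group = group,
                    n_lineages = lengths(tab),
                    lineages = vapply(tab, function(x)
                      paste(sort(x), collapse = ","), character(1)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$cr_id), , drop = FALSE]
}

#' Bootstrap null for the excess of parallel elements
#'
#' Each replicate draws, independently for each lineage, the same number of
#' CR ids as that lineage's observed calls, uniformly without replacement
#' from the background universe, and counts CRs drawn in at least
#' `min_lineages` lineages. The empirical p-value uses the add-one
#' estimator `(1 + #{null >= observed}) / (B + 1)` and therefore never
#' reports 0.
#'
#' @inheritParams find_parallel_elements
#' @param B bootstrap replicates (default 1000).
#' @param seed integer seed (required; logged on the result).
#' @return list of class `bootstrap_result`: observed, B, null_counts,
#'   p, null_mean, null_sd, seed.
#' @export
bootstrap_parallel_excess <- function(per_lineage_calls, background_cr_ids,
                                      min_lineages = 2, B = 1000, seed) {
  if (B < 1) stop("B must be >= 1")
  n_bg <- length(background_cr_ids)
  sizes <- vapply(per_lineage_calls, function(x) length(unique(x)), integer(1))
  if (any(sizes > n_bg)) stop("a lineage has more calls than the background universe")
  observed <- nrow(find_parallel_elements(per_lineage_calls,
                                          background_cr_ids,
                                          min_lineages = min_lineages))
  null_counts <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      draws <- unlist(lapply(sizes, function(k) sample.int(n_bg, k)),
                      use.names = FALSE)
      sum(tabulate(draws, n_bg) >= min_lineages)
    }, integer(1))
  })
  structure(list(observed = observed, B = B, null_counts = null_counts,
                 p = (1 + sum(null_counts >= observed)) / (B + 1),
                 null_mean = mean(null_counts), null_sd = sd(null_counts),
                 seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("Parallel-element bootstrap: observed =", x$observed,
      "; null", sprintf("%.2f +/- %.2f", x$null_mean, x$null_sd),
      "; B =", x$B, "; p =", format(x$p), "; seed =", x$seed, "\n")
  invisible(x)
}

#' Length histogram of parallel elements
#'
#' @param parallel_elements data.frame from [find_parallel_elements()].
#' @param crs conserved-region table with id and length columns.
#' @param bin_width histogram bin width in bp (default 10).
#' @return data.frame: bin_start, bin_end, count; total count conserved.
#' @export
size_distribution <- function(parallel_elements, crs, bin_width = 10) {
  stopifnot(bin_width >= 1)
  if (!nrow(parallel_elements)) {
    return(data.frame(bin_start = integer(), bin_end = integer(),
                      count = integer()))
  }
  len <- crs$length[match(parallel_elements$cr_id, crs$id)]
  if (anyNA(len)) stop("parallel element not in the CR table")
  bin <- floor(len / bin_width)
  tab <- table(bin)
  data.frame(bin_start = as.integer(names(tab)) * bin_width,
             bin_end = (as.integer(names(tab)) + 1L) * bin_width,
             count = as.integer(tab))
}
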