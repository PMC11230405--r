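# PWM log-odds scanning and differential TFBS enrichment between sequence
# groups, with the per-pairing chi-square summary of enrichment direction.

#' Build a log-odds PWM from a count matrix
#'
#' Per position, `p = (count + pseudocount) / sum(count + pseudocount)` and
#' log-odds `log2(p / background)` in bits. The maximum attainable score is
#' the sum of per-position maxima.
#'
#' @param counts 4 x width count matrix (rows A, C, G, T), counts >= 0 and
#'   no all-zero position.
#' @param background background base frequencies (default uniform), all > 0.
#' @param pseudocount added to every cell (default 0.25).
#' @param id motif identifier.
#' @return object of class `pwm`: id, counts, logodds, max_score, width,
#'   background, pseudocount.
#' @export
pwm_logodds <- function(counts, background = rep(0.25, 4),
                        pseudocount = 0.25, id = "motif") {
  stopifnot(nrow(counts) == 4, all(counts >= 0))
  if (any(colSums(counts) == 0)) stop("PWM has an all-zero position")
  if (any(background <= 0)) stop("background frequencies must be > 0")
  background <- background / sum(background)
  rownames(counts) <- DNA_BASES4
  p <- sweep(counts + pseudocount, 2, colSums(counts + pseudocount), "/")
  lo <- log2(p / background)
  structure(list(id = id, counts = counts, logodds = lo,
                 max_score = sum(apply(lo, 2, max)),
                 width = ncol(counts), background = background,
                 pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> ", x$id, ": width ", x$width, ", max score ",
      round(x$max_score, 3), " bits\n", sep = "")
  invisible(x)
}

score_windows <- function(codes, lo) {
  w <- ncol(lo)
  n <- length(codes)
  if (n < w) return(numeric(0))
  n_win <- n - w + 1L
  sc <- numeric(n_win)
  ok <- rep(TRUE, n_win)
  for (j in seq_len(w)) {
    cj <- codes[j:(j + n_win - 1L)]
    valid <- cj > 0L
    ok <- ok & valid
    sc[valid] <- sc[valid] + lo[cbind(cj[valid], j)]
  }
  sc[!ok] <- -Inf  # windows containing non-ACGT characters never match
  sc
}

#' Scan a sequence for PWM hits
#'
#' Scores every window on both strands and reports those with score at
#' least `threshold_frac * max_score`. Reverse-strand hits are reported in
#' forward coordinates. Overlapping hits are all reported.
#'
#' @param sequence a DNA string.
#' @param pwm a [pwm_logodds()].
#' @param threshold_frac score threshold as a fraction of the maximum
#'   score, in (0, 1] (default 0.8).
#' @param both_strands scan the reverse complement too (default TRUE).
#' @return data.frame: offset (0-based, forward coordinates), strand,
#'   score. Sequences shorter than the motif give an empty frame.
#' @export
scan_sequence <- function(sequence, pwm, threshold_frac = 0.8,
                          both_strands = TRUE) {
  stopifnot(inherits(pwm, "pwm"),
            threshold_frac > 0, threshold_frac <= 1)
  chars <- strsplit(toupper(sequence), "")[[1]]
  codes <- encode_bases(chars)
  thr <- threshold_frac * pwm$max_score
  w <- pwm$width
  L <- length(codes)
  empty <- data.frame(offset = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (L < w) return(empty)
  fwd <- score_windows(codes, pwm$logodds)
  fidx <- which(fwd >= thr)
  hits <- data.frame(offset = fidx - 1L,
                     strand = rep("+", length(fidx)),
                     score = fwd[fidx], stringsAsFactors = FALSE)
  if (both_strands) {
    rc <- encode_bases(revcomp_chars(chars))
    rev_sc <- score_windows(rc, pwm$logodds)
    idx <- which(rev_sc >= thr)
    if (length(idx)) {
      hits <- rbind(hits, data.frame(
        offset = L - (idx - 1L) - w, strand = "-",
        score = rev_sc[idx], stringsAsFactors = FALSE))
    }
  }
  hits <- hits[order(hits$offset, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Per-motif enrichment between two sequence groups
#'
#' For each motif, counts sequences with at least one hit in the query and
#' background groups, applies the Haldane-corrected odds ratio + Fisher
#' test ([or_test()]) and BH across motifs. A motif is called enriched in a
#' group when `q <= q_max` with the OR pointing toward that group.
#'
#' @param query_sequences,background_sequences named character vectors of
#'   DNA sequences (both non-empty).
#' @param pwms list of [pwm_logodds()] objects.
#' @param threshold_frac passed to [scan_sequence()].
#' @param q_max significance level for the direction call (default 0.05).
#' @return data.frame: motif, n_query_hit, n_query, n_background_hit,
#'   n_background, or, p, q, enriched_in (`"query"`, `"background"` or
#'   `"none"`), haldane.
#' @export
group_motif_enrichment <- function(query_sequences, background_sequences,
                                   pwms, threshold_frac = 0.8, q_max = 0.05) {
  if (!length(query_sequences) || !length(background_sequences)) {
    stop("both sequence groups must be non-empty")
  }
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  has_hit <- function(seqs, pwm) {
    vapply(seqs, function(s) nrow(scan_sequence(s, pwm, threshold_frac)) > 0,
           logical(1))
  }
  rows <- lapply(pwms, function(pwm) {
    qh <- sum(has_hit(query_sequences, pwm))
    bh <- sum(has_hit(background_sequences, pwm))
    e <- or_test(qh, length(query_sequences) - qh,
                 bh, length(background_sequences) - bh)
    data.frame(motif = pwm$id, n_query_hit = qh,
               n_query = length(query_sequences),
               n_background_hit = bh,
               n_background = length(background_sequences),
               or = e$or, p = e$p, haldane = e$haldane,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out$enriched_in <- ifelse(out$q > q_max, "none",
                            ifelse(out$or > 1, "query", "background"))
  rownames(out) <- NULL
  out
}

#' Chi-square test of enrichment-direction counts per species pairing
#'
#' For each hibernator/control pairing, tests the observed counts of motifs
#' enriched in the homeotherm versus the hibernator against an equal split
#' under the no-bias null: `X^2 = sum (O - E)^2 / E`, df = categories - 1.
#'
#' @param counts numeric vector of category counts for one pairing, or a
#'   matrix/data.frame with one pairing per row.
#' @return data.frame: pairing, statistic, df, p.
#' @export
differential_motif_chisq <- function(counts) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("pairing", seq_len(nrow(counts)))
  }
  rows <- lapply(rownames(counts), function(nm) {
    o <- counts[nm, ]
    if (sum(o) < 1) stop("pairing ", nm, " has zero total count")
    e <- rep(sum(o) / length(o), length(o))
    if (any(e == 0)) stop("zero expected cell")
    x2 <- sum((o - e)^2 / e)
    df <- length(o) - 1L
    data.frame(pairing = nm, statistic = x2, df = df,
               p = pchisq(x2, df, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
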