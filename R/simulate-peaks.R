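#' Simulate replicate peak sets with dropout and boundary jitter
#'
#' Each replicate keeps each true peak independently with probability
#' `1 - dropout`; retained peaks get Gaussian boundary jitter (rounded to
#' bp, clipped so intervals stay valid and non-negative).
#'
#' @param true_peaks data.frame with chrom, start, end.
#' @param n_reps number of replicates (default 8).
#' @param dropout per-replicate per-peak dropout probability in `[0, 1)`.
#' @param jitter_sd boundary jitter standard deviation in bp (default 10).
#' @param seed integer seed.
#' @return list: `replicates` (list of peak data.frames), `truth`.
#' @export
simulate_peak_replicates <- function(true_peaks, n_reps = 8, dropout = 0.2,
                                     jitter_sd = 10, seed) {
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  reps <- withr::with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      keep <- runif(nrow(true_peaks)) >= dropout
      pk <- true_peaks[keep, , drop = FALSE]
      if (nrow(pk) && jitter_sd > 0) {
        pk$start <- pmax(0L, pk$start + round(rnorm(nrow(pk), sd = jitter_sd)))
        pk$end <- pk$end + round(rnorm(nrow(pk), sd = jitter_sd))
        bad <- pk$end <= pk$start
        pk$end[bad] <- pk$start[bad] + 1L
      }
      rownames(pk) <- NULL
      pk
    })
  })
  list(replicates = reps, truth = true_peaks)
}

#' Simulate sequence groups with planted motif instances
#'
#' "With" sequences are background-composition random DNA carrying exactly
#' one sampled motif instance at a recorded position on a random strand;
#' "without" sequences are plain background DNA (chance matches may occur,
#' but no instance is planted).
#'
#' @param pwm a [pwm_logodds()] object (instances are sampled from its
#'   per-position base probabilities).
#' @param n_with,n_without group sizes.
#' @param seq_len sequence length, >= motif width.
#' @param seed integer seed.
#' @param background base composition of the random sequence (default the
#'   PWM's background).
#' @return list: `with` and `without` (named character vectors), `truth`
#'   (data.frame seq, offset (0-based), strand).
#' @export
simulate_motif_sequences <- function(pwm, n_with, n_without, seq_len, seed,
                                     background = pwm$background) {
  stopifnot(inherits(pwm, "pwm"))
  if (seq_len < pwm$width) stop("seq_len must be >= motif width")
  probs <- sweep(pwm$counts + pwm$pseudocount, 2,
                 colSums(pwm$counts + pwm$pseudocount), "/")
  w <- pwm$width
  withr::with_seed(seed, {
    rand_seq <- function() {
      paste(sample(DNA_BASES4, seq_len, replace = TRUE, prob = background),
            collapse = "")
    }
    withs <- character(n_with)
    truth <- data.frame(seq = sprintf("with_%03d", seq_len(n_with)),
                        offset = NA_integer_, strand = NA_character_,
                        stringsAsFactors = FALSE)
    for (i in seq_len(n_with)) {
      s <- strsplit(rand_seq(), "")[[1]]
      inst <- vapply(seq_len(w), function(j) {
        sample(DNA_BASES4, 1, prob = probs[, j])
      }, character(1))
      strand <- sample(c("+", "-"), 1)
      if (strand == "-") inst <- revcomp_chars(inst)
      off <- sample.int(seq_len - w + 1L, 1) - 1L
      s[(off + 1):(off + w)] <- inst
      withs[i] <- paste(s, collapse = "")
      truth$offset[i] <- off
      truth$strand[i] <- strand
    }
    names(withs) <- truth$seq
    withouts <- vapply(seq_len(n_without), function(i) rand_seq(),
                       character(1))
    names(withouts) <- sprintf("without_%03d", seq_len(n_without))
    list(with = withs, without = withouts, truth = truth)
  })
}
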