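#' Simulate a binned contact map with planted element-promoter enrichment
#'
#' One chromosome is tiled with `n_bins` fixed-width bins. Every unordered
#' bin pair involving a promoter bin (and, at a lower rate, every other
#' pair) can carry a planted contact: pairs between an element-containing
#' bin and a promoter bin contact with probability
#' `min(1, enrichment_factor * contact_prob)`, all other pairs with
#' `contact_prob`. Planted contacts receive overdispersed
#' (negative-binomial) read counts shifted above the significance
#' thresholds of the downstream contact filter; non-contact pairs receive
#' background negative-binomial counts. The observed/expected column is
#' count over the background mean, and q-values are BH-adjusted
#' negative-binomial upper-tail p-values under the background model, so the
#' downstream filter (count >= 12, obs/exp > 2, q <= 0.01) recovers
#' essentially the planted graph.
#'
#' The truth component records the analytic odds ratio of "bin has >= 1
#' planted promoter contact" for element versus background bins, the
#' quantity the downstream enrichment test estimates.
#'
#' @param n_bins number of bins.
#' @param promoter_bins indices (1-based) of promoter bins.
#' @param element_bins indices of element-containing bins (disjoint from
#'   `promoter_bins`).
#' @param enrichment_factor multiplier on the element-to-promoter contact
#'   probability, >= 1.
#' @param seed integer seed.
#' @param bin_width bin width in bp (default 10000).
#' @param contact_prob background promoter-contact probability per pair
#'   (default 0.03).
#' @param nonprom_contact_prob contact probability for pairs without a
#'   promoter bin (default `contact_prob / 3`; yields E-E contacts).
#' @param count_mu,count_size negative-binomial parameters of the planted
#'   count excess (added to the count threshold 12).
#' @param noise_mu,noise_size negative-binomial parameters of background
#'   counts.
#' @return list: `bedpe` (contacts data.frame), `bins` (chrom, start, end,
#'   promoter, element), `truth` (true_or, contact_pairs, parameters).
#' @export
simulate_contacts <- function(n_bins, promoter_bins, element_bins,
                              enrichment_factor, seed, bin_width = 10000,
                              contact_prob = 0.03,
                              nonprom_contact_prob = contact_prob / 3,
                              count_mu = 30, count_size = 5,
                              noise_mu = 2, noise_size = 2) {
  if (enrichment_factor < 1) stop("enrichment_factor must be >= 1")
  if (any(element_bins < 1 | element_bins > n_bins)) {
    stop("element bin outside the binned range")
  }
  if (any(promoter_bins < 1 | promoter_bins > n_bins)) {
    stop("promoter bin outside the binned range")
  }
  if (length(intersect(element_bins, promoter_bins))) {
    stop("element bins must be distinct from promoter bins")
  }
  pairs <- t(utils::combn(n_bins, 2))
  is_prom <- seq_len(n_bins) %in% promoter_bins
  is_elem <- seq_len(n_bins) %in% element_bins
  pair_prom <- is_prom[pairs[, 1]] | is_prom[pairs[, 2]]
  # element <-> promoter pairs get the enriched probability
  pair_ep <- (is_elem[pairs[, 1]] & is_prom[pairs[, 2]]) |
    (is_prom[pairs[, 1]] & is_elem[pairs[, 2]])
  prob <- ifelse(pair_ep, pmin(1, enrichment_factor * contact_prob),
                 ifelse(pair_prom, contact_prob, nonprom_contact_prob))

  withr::with_seed(seed, {
    planted <- runif(nrow(pairs)) < prob
    count <- rnbinom(nrow(pairs), mu = noise_mu, size = noise_size)
    count[planted] <- 12L + rnbinom(sum(planted), mu = count_mu,
                                    size = count_size)
  })
  obs_exp <- count / noise_mu
  pval <- pnbinom(count - 1, mu = noise_mu, size = noise_size,
                  lower.tail = FALSE)
  qval <- p.adjust(pval, method = "BH")

  starts <- (seq_len(n_bins) - 1L) * bin_width
  bedpe <- data.frame(
    chrom1 = "chr1", start1 = starts[pairs[, 1]],
    end1 = starts[pairs[, 1]] + bin_width,
    chrom2 = "chr1", start2 = starts[pairs[, 2]],
    end2 = starts[pairs[, 2]] + bin_width,
    count = count, obs_exp = obs_exp, qvalue = qval,
    stringsAsFactors = FALSE)
  bins <- data.frame(chrom = "chr1", start = starts,
                     end = starts + bin_width,
                     promoter = is_prom, element = is_elem,
                     stringsAsFactors = FALSE)

  K <- length(promoter_bins)
  p_elem <- 1 - (1 - pmin(1, enrichment_factor * contact_prob))^K
  p_bg <- 1 - (1 - contact_prob)^K
  true_or <- (p_elem / (1 - p_elem)) / (p_bg / (1 - p_bg))
  list(bedpe = bedpe, bins = bins,
       truth = list(true_or = true_or,
                    p_contact_element = p_elem, p_contact_background = p_bg,
                    contact_pairs = pairs[planted, , drop = FALSE],
                    enrichment_factor = enrichment_factor, seed = seed))
}
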