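#' Simulate an expression matrix with planted co-expression modules
#'
#' Each module is driven by one latent factor (standard normal across
#' samples): gene expression = loading x factor + Gaussian noise. Loadings
#' are graded so the planted hubs are known: a hub tier of
#' `ceil(hub_frac * size)` genes per module carries `hub_loading`, the
#' remaining genes carry loadings graded down through `loading_range`.
#' Genes beyond the planted modules are independent noise.
#'
#' @param n_genes total genes.
#' @param n_samples samples (columns).
#' @param module_sizes integer vector of planted module sizes; the sum must
#'   not exceed `n_genes`.
#' @param noise_sd Gaussian noise standard deviation, >= 0 (default 0.3).
#' @param hub_frac fraction of each module planted as hubs (default 0.10).
#' @param hub_loading latent-factor loading of planted hubs (default 0.95).
#' @param loading_range loading range (high to low) of the non-hub module
#'   genes (default 0.7 down to 0.4). The gap below `hub_loading` keeps the
#'   planted hub tier statistically identifiable from connectivity at
#'   realistic sample sizes; with near-touching loadings the "planted hub"
#'   label would not be a recoverable quantity.
#' @param seed integer seed.
#' @return list: `expression` (genes x samples matrix), `truth`
#'   (data.frame gene, module, loading, hub).
#' @export
simulate_expression <- function(n_genes, n_samples, module_sizes,
                                noise_sd = 0.3, hub_frac = 0.10,
                                hub_loading = 0.95,
                                loading_range = c(0.7, 0.4), seed) {
  if (noise_sd < 0) stop("noise sd must be >= 0")
  if (sum(module_sizes) > n_genes) stop("module sizes exceed n_genes")
  genes <- sprintf("g%04d", seq_len(n_genes))
  truth <- data.frame(gene = genes, module = 0L, loading = 0,
                      hub = FALSE, stringsAsFactors = FALSE)
  withr::with_seed(seed, {
    expr <- matrix(rnorm(n_genes * n_samples, sd = max(noise_sd, 1)),
                   n_genes, n_samples,
                   dimnames = list(genes, sprintf("s%02d", seq_len(n_samples))))
    # background genes keep unit-ish variance even at noise_sd = 0 so
    # correlations stay defined
    offset <- 0L
    for (m in seq_along(module_sizes)) {
      size <- module_sizes[m]
      idx <- offset + seq_len(size)
      n_hub <- ceiling(hub_frac * size)
      loadings <- c(rep(hub_loading, n_hub),
                    seq(loading_range[1], loading_range[2],
                        length.out = size - n_hub))
      factor_m <- rnorm(n_samples)
      noise <- matrix(rnorm(size * n_samples, sd = noise_sd), size, n_samples)
      expr[idx, ] <- loadings %o% factor_m + noise
      truth$module[idx] <- m
      truth$loading[idx] <- loadings
      truth$hub[idx] <- seq_len(size) <= n_hub
      offset <- offset + size
    }
  })
  list(expression = expr, truth = truth)
}

#' Planted hub genes of a simulated expression matrix
#' @param truth truth table from [simulate_expression()].
#' @param module module label.
#' @return character vector of planted hub gene ids.
#' @export
planted_hubs <- function(truth, module) {
  truth$gene[truth$module == module & truth$hub]
}
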