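test_that("forward-backward posteriors match exhaustive path enumeration on
           a 12-column toy", {
  tree <- tree3()
  m <- hky_model()
  cols <- simulate_columns(tree, m, 12, scales = 0.4, seed = 21)
  loge <- rbind(columns_log_likelihood(tree, m, cols, 1),
                columns_log_likelihood(tree, m, cols, 0.3))
  mu <- 1 / 45
  nu <- mu * 0.05 / 0.95
  got <- convar:::hmm_forward_backward(loge, mu, nu)$posterior
  want <- enumerate_hmm_posterior(loge, mu, nu)
  expect_equal(got, want, tolerance = 1e-10)
  expect_equal(forward_backward(cols, tree, m,
                                phylo_hmm_params(rho = 0.3)), got,
               tolerance = 1e-12)
})

test_that("degenerate chains behave as expected: absorbing neutral state and
           uniform emissions", {
  tree <- tree3()
  m <- hky_model()
  cols <- simulate_columns(tree, m, 50, scales = 1, seed = 3)
  # nu -> 0: the chain (almost) never enters the conserved state
  p_absorb <- forward_backward(cols, tree, m,
                               phylo_hmm_params(rho = 0.3, mu = 0.02,
                                                nu = 1e-12))
  expect_true(all(p_absorb < 1e-6))
  # all-missing columns: emissions cancel, posterior equals the stationary
  # conserved probability
  gaps <- matrix("-", nrow = 3, ncol = 30,
                 dimnames = list(tree$tip.label, NULL))
  params <- phylo_hmm_params(rho = 0.3)
  p_unif <- forward_backward(gaps, tree, m, params)
  expect_equal(p_unif,
               rep(params$nu / (params$mu + params$nu), 30),
               tolerance = 1e-12)
})

test_that("a planted conserved segment is recovered as one high-overlap CR", {
  tree <- demo_tree()
  m <- hky_model()
  layout <- genome_layout(
    layout_segment(2400, "neutral"),
    layout_segment(200, "conserved", rho = 0.3),
    layout_segment(2400, "neutral"))
  params <- phylo_hmm_params(rho = 0.3)
  good <- vapply(1:20, function(s) {
    sim <- simulate_alignment(tree, m, layout, seed = 100 + s)
    crs <- call_conserved_regions(sim$alignment, tree, m, params)
    if (nrow(crs) != 1) return(FALSE)
    ov <- min(crs$end, 2600) - max(crs$start, 2400)
    ov / max(200, crs$length) >= 0.9
  }, logical(1))
  expect_gte(sum(good), 18)
})

test_that("short runs are filtered by min_length and empty alignments give
           empty sets", {
  tree <- demo_tree()
  m <- hky_model()
  layout <- genome_layout(
    layout_segment(1000, "neutral"),
    layout_segment(200, "conserved", rho = 0.3),
    layout_segment(1000, "neutral"))
  sim <- simulate_alignment(tree, m, layout, seed = 5)
  loose <- call_conserved_regions(sim$alignment, tree, m,
                                  phylo_hmm_params(rho = 0.3, min_length = 20))
  strict <- call_conserved_regions(sim$alignment, tree, m,
                                   phylo_hmm_params(rho = 0.3, min_length = 300))
  expect_gt(nrow(loose), 0)
  expect_equal(nrow(strict), 0)

  empty <- cg_alignment(matrix("A", 12, 0,
                               dimnames = list(demo_tree()$tip.label, NULL)),
                        ref = "bg_A")
  expect_equal(nrow(call_conserved_regions(empty, tree, m,
                                           phylo_hmm_params(rho = 0.3))), 0)
})

test_that("decoding properties hold: posterior/viterbi containment, block
           splitting at deep-neutral positions, and the score-sum bound", {
  tree <- demo_tree()
  m <- hky_model()
  layout <- genome_layout(
    layout_segment(1500, "neutral"),
    layout_segment(150, "conserved", rho = 0.3),
    layout_segment(3000, "neutral"),
    layout_segment(150, "conserved", rho = 0.3),
    layout_segment(1500, "neutral"))
  sim <- simulate_alignment(tree, m, layout, seed = 12)
  params <- phylo_hmm_params(rho = 0.3)
  crs <- call_conserved_regions(sim$alignment, tree, m, params)
  expect_gt(nrow(crs), 0)

  # high-posterior columns are also decoded conserved by Viterbi
  cols <- encode_bases(sim$alignment$seqs)
  post <- forward_backward(cols, tree, m, params)
  loge <- rbind(columns_log_likelihood(tree, m, cols, 1),
                columns_log_likelihood(tree, m, cols, params$rho))
  vit <- convar:::hmm_viterbi(loge, params$mu, params$nu)
  expect_true(all(vit[post > 0.95]))

  # score-sum bound: mean posterior x length >= min_length x threshold
  expect_true(all(crs$score * crs$length >=
                    params$min_length * params$threshold - 1e-9))

  # splitting the alignment deep inside a neutral stretch and concatenating
  # the calls reproduces the unsplit calls
  cut <- 3200L
  left <- cg_alignment(sim$alignment$seqs[, 1:cut], ref = sim$alignment$ref)
  right <- cg_alignment(sim$alignment$seqs[, (cut + 1):ncol(sim$alignment$seqs)],
                        ref = sim$alignment$ref, ref_start = cut)
  crs_l <- call_conserved_regions(left, tree, m, params)
  crs_r <- call_conserved_regions(right, tree, m, params)
  merged <- rbind(crs_l[, -1], crs_r[, -1])
  expect_equal(merged$start, crs$start)
  expect_equal(merged$end, crs$end)
})

test_that("FDR thresholding is monotone in the target and trivial at
           target 1", {
  tree <- demo_tree()
  m <- hky_model()
  sim <- simulate_alignment(tree, m, demo_layout(n_accel = 0, n_del = 0),
                            seed = 31)
  params <- phylo_hmm_params(rho = 0.3)
  crs <- call_conserved_regions(sim$alignment, tree, m, params)
  expect_gt(nrow(crs), 3)

  t1 <- estimate_cr_fdr(crs$score, tree, m, params, n_null_bp = 20000,
                        seed = 7, target = 1)
  expect_equal(t1$threshold, min(crs$score))

  thr <- vapply(c(0.5, 0.2, 0.05), function(tg) {
    estimate_cr_fdr(crs$score, tree, m, params, n_null_bp = 20000,
                    seed = 7, target = tg)$threshold
  }, numeric(1))
  expect_true(all(diff(thr) >= 0))
  expect_error(estimate_cr_fdr(numeric(0), tree, m, params, 20000, seed = 1),
               "no observed")
})
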