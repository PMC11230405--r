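test_that("adjacency construction follows |cor|^beta with zero diagonal", {
  x <- matrix(rnorm(5 * 3), 1, 15)  # placeholder, replaced below
  expr <- rbind(g1 = c(1, 2, 3, 4, 5),
                g2 = c(2, 4, 6, 8, 10),
                g3 = c(1.5, 3, 4.5, 6, 7.5))
  a <- build_adjacency(expr, beta = 6)
  expect_equal(a[upper.tri(a)], rep(1, 3), tolerance = 1e-12)
  expect_equal(diag(a), rep(0, 3), ignore_attr = TRUE)
  expect_equal(rowSums(a), rep(2, 3), ignore_attr = TRUE, tolerance = 1e-12)

  withr::with_seed(4, {
    e2 <- matrix(rnorm(10 * 20), 10, 20,
                 dimnames = list(paste0("g", 1:10), NULL))
    a1 <- build_adjacency(e2, beta = 1)
    cc <- abs(cor(t(e2)))
    diag(cc) <- 0
    expect_equal(a1, cc, tolerance = 1e-12)
  })
  expect_error(build_adjacency(expr, beta = 0), "beta")
  expect_error(build_adjacency(expr[, 1:2]), "3 samples")
  expect_warning(build_adjacency(rbind(expr, g4 = rep(1, 5))), "constant")
})

test_that("independent noise genes have near-zero adjacency at beta 6", {
  es <- simulate_expression(80, 60, module_sizes = integer(0), seed = 6)
  a <- build_adjacency(es$expression, beta = 6)
  expect_lt(mean(a[upper.tri(a)]), 0.01)
})

test_that("topological overlap matches the direct formula", {
  ones <- matrix(1, 5, 5)
  diag(ones) <- 0
  expect_equal(topological_overlap(ones),
               matrix(1, 5, 5), ignore_attr = TRUE, tolerance = 1e-12)

  zero <- matrix(0, 4, 4)
  tz <- topological_overlap(zero)
  expect_equal(tz - diag(4), matrix(0, 4, 4), tolerance = 1e-12)

  withr::with_seed(9, {
    a <- matrix(runif(16), 4, 4)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    tom <- topological_overlap(a)
    k <- rowSums(a)
    for (i in 1:4) for (j in 1:4) {
      if (i == j) next
      L <- sum(a[i, ] * a[, j])
      want <- (L + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
      expect_equal(tom[i, j], want, tolerance = 1e-12)
    }
  })
  expect_error(topological_overlap(matrix(runif(9), 3, 3)), "symmetric")
})

test_that("module detection recovers planted modules and leaves noise
           unassigned", {
  es <- simulate_expression(200, 60, module_sizes = c(50, 50, 50),
                            noise_sd = 0.2, seed = 15)
  tom <- topological_overlap(build_adjacency(es$expression))
  labels <- detect_modules(tom)
  expect_gte(adjusted_rand_index(labels[es$truth$module > 0],
                                 es$truth$module[es$truth$module > 0]), 0.9)

  noise <- simulate_expression(120, 60, module_sizes = integer(0), seed = 8)
  ltn <- detect_modules(topological_overlap(build_adjacency(noise$expression)))
  expect_gte(mean(ltn == 0), 0.9)

  # permuting gene order permutes labels consistently
  perm <- withr::with_seed(2, sample(nrow(tom)))
  lp <- detect_modules(tom[perm, perm])
  expect_gte(adjusted_rand_index(lp, labels[perm]), 0.999)

  few <- matrix(0.5, 5, 5, dimnames = list(paste0("g", 1:5), paste0("g", 1:5)))
  diag(few) <- 1
  expect_true(all(detect_modules(few, min_module_size = 20) == 0))
})

test_that("module eigengenes summarise the latent factor with aligned sign", {
  # identical profiles: kME is exactly 1
  prof <- rnorm(30)
  expr <- rbind(g1 = prof, g2 = prof, g3 = prof)
  summ <- module_eigengene(expr, setNames(c(1L, 1L, 1L), rownames(expr)))
  expect_equal(unname(summ[["1"]]$kME), rep(1, 3), tolerance = 1e-12)
  expect_equal(sum(summ[["1"]]$eigengene^2), 1, tolerance = 1e-12)

  # planted single-factor module: eigengene tracks the factor
  withr::with_seed(5, {
    factor_s <- rnorm(60)
    loadings <- seq(0.95, 0.5, length.out = 50)
    mat <- loadings %o% factor_s +
      matrix(rnorm(50 * 60, sd = 0.3), 50, 60)
    rownames(mat) <- sprintf("g%02d", 1:50)
    s2 <- module_eigengene(mat, setNames(rep(1L, 50), rownames(mat)))
    expect_gte(abs(cor(s2[["1"]]$eigengene, factor_s)), 0.95)
    # flipping all signs flips the eigengene but not |kME|
    s3 <- module_eigengene(-mat, setNames(rep(1L, 50), rownames(mat)))
    expect_equal(abs(s3[["1"]]$kME), abs(s2[["1"]]$kME), tolerance = 1e-9)
    # the top-kME gene sits in the top loading quintile
    expect_lte(unname(which.max(s2[["1"]]$kME)), 10L)
  })

  # one-gene module: eigengene is the standardised profile
  one <- module_eigengene(expr[1, , drop = FALSE],
                          setNames(1L, "g1"))
  z <- as.numeric(scale(prof))
  expect_equal(abs(cor(one[["1"]]$eigengene, z)), 1, tolerance = 1e-12)
})

test_that("the hub rule takes the connectivity top decile filtered by kME", {
  # module of 10 genes: exactly ceil(1) = 1 candidate
  genes <- sprintf("g%02d", 1:10)
  a <- matrix(0.2, 10, 10, dimnames = list(genes, genes))
  a["g03", ] <- a[, "g03"] <- 0.9  # clear connectivity leader
  diag(a) <- 0
  kme <- setNames(rep(0.9, 10), genes)
  summaries <- list("1" = list(module = 1L, genes = genes, kME = kme))
  h <- hub_genes(a, summaries)
  expect_equal(h[["1"]]$candidates, "g03")
  expect_equal(h[["1"]]$hubs, "g03")

  # strict kME threshold: 0.79 excluded, 0.81 included
  kme2 <- kme
  kme2["g03"] <- 0.79
  h2 <- hub_genes(a, list("1" = list(module = 1L, genes = genes, kME = kme2)))
  expect_length(h2[["1"]]$hubs, 0)
  kme2["g03"] <- 0.81
  h3 <- hub_genes(a, list("1" = list(module = 1L, genes = genes, kME = kme2)))
  expect_equal(h3[["1"]]$hubs, "g03")

  # monotone: raising kme_min never grows the hub set
  es <- simulate_expression(150, 60, module_sizes = c(60), noise_sd = 0.3,
                            seed = 44)
  adj <- build_adjacency(es$expression)
  labels <- detect_modules(topological_overlap(adj))
  summ <- module_eigengene(es$expression, labels)
  prev <- Inf
  for (km in c(0.5, 0.7, 0.8, 0.9, 0.97)) {
    n_hub <- length(hub_genes(adj, summ, kme_min = km)[[1]]$hubs)
    expect_lte(n_hub, prev)
    prev <- n_hub
  }
})

test_that("module gene-set enrichment ranks the planted module first", {
  labels <- setNames(c(rep(1L, 30), rep(2L, 30), rep(0L, 40)),
                     sprintf("g%03d", 1:100))
  own <- names(labels)[labels == 1]
  res <- module_geneset_enrichment(labels, own)
  expect_equal(res$module[which.min(res$p)], 1)
  expect_lt(res$q[res$module == 1], 1e-10)

  none <- module_geneset_enrichment(labels, character(0))
  expect_true(all(none$p == 1))
})
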