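# Independent oracles and small fixtures shared across tests. Everything
# here deliberately avoids the package's fast code paths: likelihoods by
# explicit enumeration, HMM posteriors by summing over all state paths,
# statistics by direct formula evaluation.

tree2 <- function() parse_newick("(A:0.1,B:0.1);")
tree3 <- function() parse_newick("((A:0.1,B:0.2):0.05,C:0.3);")
tree5 <- function() {
  parse_newick("(((A:0.11,B:0.07):0.05,C:0.21):0.04,(D:0.09,E:0.3):0.13);")
}

# Brute-force column likelihood: sum over every assignment of states to
# internal nodes, using transition_matrix() directly.
brute_force_loglik <- function(tree, model, column, scales = 1) {
  tree <- ape::reorder.phylo(tree, "postorder")
  if (length(scales) == 1) scales <- rep(scales, nrow(tree$edge))
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  root <- tree$edge[nrow(tree$edge), 1]
  codes <- column[tree$tip.label]
  if (is.character(codes)) codes <- encode_bases(codes)
  P <- lapply(seq_len(nrow(tree$edge)), function(e) {
    transition_matrix(model, tree$edge.length[e] * scales[e])
  })
  total <- 0
  grid <- as.matrix(expand.grid(rep(list(1:4), n_int)))
  for (g in seq_len(nrow(grid))) {
    assign_state <- function(node) {
      if (node <= n_tip) codes[node] else grid[g, node - n_tip]
    }
    prob <- unname(model$pi[assign_state(root)])
    for (e in seq_len(nrow(tree$edge))) {
      par_s <- assign_state(tree$edge[e, 1])
      ch <- tree$edge[e, 2]
      ch_s <- assign_state(ch)
      if (ch <= n_tip && ch_s == 0L) next  # missing leaf: marginalised out
      prob <- prob * P[[e]][par_s, ch_s]
    }
    total <- total + prob
  }
  log(total)
}

# Exhaustive 2-state HMM posterior: sum over all 2^n state paths.
enumerate_hmm_posterior <- function(loge, mu, nu) {
  n <- ncol(loge)
  init <- c(mu, nu) / (mu + nu)
  trans <- matrix(c(1 - nu, mu, nu, 1 - mu), 2, 2)  # [from, to]
  paths <- as.matrix(expand.grid(rep(list(1:2), n)))
  w <- apply(paths, 1, function(s) {
    lp <- log(init[s[1]]) + loge[s[1], 1]
    if (n > 1) for (t in 2:n) {
      lp <- lp + log(trans[s[t - 1], s[t]]) + loge[s[t], t]
    }
    exp(lp)
  })
  post <- vapply(seq_len(n), function(t) {
    sum(w[paths[, t] == 2]) / sum(w)
  }, numeric(1))
  post
}

# Adjusted Rand index between two label vectors.
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_i * sum_j / n2
  (sum_ij - expected) / ((sum_i + sum_j) / 2 - expected)
}

# Two-sided Fisher p by full enumeration of the hypergeometric table
# distribution with the observed margins (point-probability method).
fisher_p_enum <- function(a, b, c, d) {
  m1 <- a + b
  m2 <- c + d
  k <- a + c
  lo <- max(0, k - m2)
  hi <- min(k, m1)
  probs <- vapply(lo:hi, function(x) {
    choose(m1, x) * choose(m2, k - x) / choose(m1 + m2, k)
  }, numeric(1))
  p_obs <- probs[a - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Upper-tail hypergeometric P(X >= k) by direct summation.
hyper_tail_enum <- function(k, sizeA, sizeB, N) {
  if (k == 0) return(1)
  kk <- k:min(sizeA, sizeB)
  sum(choose(sizeA, kk) * choose(N - sizeA, sizeB - kk)) / choose(N, sizeB)
}

# Woolf heterogeneity statistic written directly from the formula.
woolf_enum <- function(tables) {
  tabs <- lapply(tables, function(x) if (any(x == 0)) x + 0.5 else x)
  lnor <- sapply(tabs, function(x) log((x[1] * x[4]) / (x[2] * x[3])))
  w <- sapply(tabs, function(x) 1 / (1 / x[1] + 1 / x[2] + 1 / x[3] + 1 / x[4]))
  pooled <- sum(w * lnor) / sum(w)
  sum(w * (lnor - pooled)^2)
}

# Brute-force PWM scanner: score every window on both strands one by one.
brute_scan <- function(sequence, pwm, threshold_frac = 0.8) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  w <- pwm$width
  L <- length(chars)
  thr <- threshold_frac * pwm$max_score
  hits <- list()
  score_at <- function(sub) {
    s <- 0
    for (j in seq_len(w)) {
      code <- match(sub[j], c("A", "C", "G", "T"))
      if (is.na(code)) return(-Inf)
      s <- s + pwm$logodds[code, j]
    }
    s
  }
  if (L >= w) for (off in 0:(L - w)) {
    sub <- chars[(off + 1):(off + w)]
    s <- score_at(sub)
    if (s >= thr) hits[[length(hits) + 1]] <-
        data.frame(offset = off, strand = "+", score = s)
    s2 <- score_at(rev(c(A = "T", C = "G", G = "C", T = "A")[sub]))
    if (s2 >= thr) hits[[length(hits) + 1]] <-
        data.frame(offset = off, strand = "-", score = s2)
  }
  if (!length(hits)) {
    return(data.frame(offset = integer(), strand = character(),
                      score = numeric()))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$offset, out$strand), ]
  rownames(out) <- NULL
  out
}

random_column <- function(tree, seed, p_missing = 0.15) {
  withr::with_seed(seed, {
    x <- sample(c(0:4), length(tree$tip.label), replace = TRUE,
                prob = c(p_missing, rep((1 - p_missing) / 4, 4)))
    setNames(x, tree$tip.label)
  })
}
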