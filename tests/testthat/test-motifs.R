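test_that("PWM log-odds follow the closed forms", {
  uniform <- matrix(5, 4, 6)
  p <- pwm_logodds(uniform)
  expect_equal(p$logodds, matrix(0, 4, 6), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(p$max_score, 0)

  single <- matrix(c(100, 0, 0, 0), 4, 1)
  sharp <- pwm_logodds(single, pseudocount = 1e-9)
  expect_equal(unname(sharp$logodds[1, 1]), 2, tolerance = 1e-6)  # log2(4)

  # monotone: increasing a base's count never decreases its log-odds
  lo1 <- pwm_logodds(matrix(c(10, 5, 5, 5), 4, 1))$logodds[1, 1]
  lo2 <- pwm_logodds(matrix(c(20, 5, 5, 5), 4, 1))$logodds[1, 1]
  expect_gt(lo2, lo1)

  expect_error(pwm_logodds(uniform, background = c(0.5, 0.5, 0, 0)),
               "background")
  expect_error(pwm_logodds(matrix(0, 4, 2)), "all-zero")
})

test_that("JASPAR round trip preserves count matrices", {
  pwms <- list(m1 = matrix(1:32, 4, 8, dimnames = list(c("A", "C", "G", "T"),
                                                       NULL)),
               m2 = matrix(5, 4, 3, dimnames = list(c("A", "C", "G", "T"),
                                                    NULL)))
  path <- withr::local_tempfile(fileext = ".jaspar")
  write_jaspar(pwms, path)
  back <- read_jaspar(path)
  expect_equal(back$m1, pwms$m1, ignore_attr = TRUE)
  expect_equal(back$m2, pwms$m2, ignore_attr = TRUE)
})

test_that("scanning finds consensus and reverse-complement hits at the
           right offsets", {
  pwm <- demo_pwm()
  # TGACGTCA is palindromic: the consensus hits on both strands at offset 0
  h <- scan_sequence("TGACGTCA", pwm)
  expect_equal(nrow(h), 2)
  expect_equal(h$offset, c(0, 0))
  expect_setequal(h$strand, c("+", "-"))
  expect_equal(max(h$score), pwm$max_score, tolerance = 1e-9)

  seq2 <- paste0("AAAA", "TGACGTCA", "AAAA")
  h2 <- scan_sequence(seq2, pwm)
  expect_true(any(h2$offset == 4 & h2$strand == "+"))

  # reverse complement of the consensus: minus-strand hit, forward coords
  rc_seq <- paste0("CCCC", "TGACGTCA", "CCCC")
  rc_chars <- strsplit(rc_seq, "")[[1]]
  rc_full <- paste(rev(c(A = "T", C = "G", G = "C", T = "A")[rc_chars]),
                   collapse = "")
  h3 <- scan_sequence(rc_full, pwm)
  expect_true(any(h3$strand == "-" & h3$offset == 4))

  expect_equal(nrow(scan_sequence("ACGT", pwm)), 0)  # shorter than motif
})

test_that("the scanner equals the brute-force all-window oracle on random
           sequences", {
  pwm <- demo_pwm()
  soft <- pwm_logodds(matrix(c(8, 2, 1, 1,
                               1, 8, 2, 1,
                               2, 1, 8, 1,
                               1, 1, 2, 8,
                               8, 1, 2, 1), 4, 5), id = "soft")
  withr::with_seed(33, {
    for (i in 1:200) {
      s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                 collapse = "")
      p <- if (i %% 2 == 0) pwm else soft
      thr <- if (i %% 3 == 0) 0.6 else 0.8
      got <- scan_sequence(s, p, threshold_frac = thr)
      want <- brute_scan(s, p, threshold_frac = thr)
      expect_equal(got$offset, want$offset)
      expect_equal(got$strand, want$strand)
      expect_equal(got$score, want$score, tolerance = 1e-9)
    }
  })
})

test_that("planted instances are recalled and background stays quiet", {
  pwm <- demo_pwm()
  sim <- simulate_motif_sequences(pwm, n_with = 100, n_without = 100,
                                  seq_len = 200, seed = 19)
  recall <- mean(vapply(seq_along(sim$with), function(i) {
    h <- scan_sequence(sim$with[i], pwm)
    any(h$offset == sim$truth$offset[i])
  }, logical(1)))
  expect_gte(recall, 0.9)
  false_rate <- mean(vapply(sim$without, function(s) {
    nrow(scan_sequence(s, pwm)) > 0
  }, logical(1)))
  expect_lte(false_rate, 0.05)
})

test_that("group enrichment detects planted differences and is
           direction-consistent", {
  pwm <- demo_pwm()
  sim <- simulate_motif_sequences(pwm, n_with = 60, n_without = 140,
                                  seq_len = 150, seed = 55)
  query <- c(sim$with, sim$without[1:40])            # 60% carry the motif
  background <- c(sim$without[41:140],
                  simulate_motif_sequences(pwm, 10, 90, 150,
                                           seed = 56)$without)
  res <- group_motif_enrichment(query, background, list(pwm))
  expect_lt(res$q, 0.05)
  expect_equal(res$enriched_in, "query")

  flipped <- group_motif_enrichment(background, query, list(pwm))
  expect_equal(flipped$enriched_in, "background")
  expect_equal(flipped$or, 1 / res$or, tolerance = 1e-9)

  same <- group_motif_enrichment(sim$without[1:50], sim$without[51:100],
                                 list(pwm))
  expect_equal(same$enriched_in, "none")
  expect_true(same$haldane)  # motif absent from both groups

  expect_error(group_motif_enrichment(character(0), background, list(pwm)),
               "non-empty")
})

test_that("the per-pairing chi-square summary follows its formula", {
  even <- differential_motif_chisq(c(50, 50))
  expect_equal(even$statistic, 0)
  expect_equal(even$p, 1)

  skew <- differential_motif_chisq(c(70, 30))
  expect_equal(skew$statistic, 16)  # (20^2/50) + (20^2/50)
  expect_equal(skew$df, 1)
  expect_equal(skew$p, pchisq(16, 1, lower.tail = FALSE))

  scaled <- differential_motif_chisq(c(700, 300))
  expect_equal(scaled$statistic, 160)

  multi <- differential_motif_chisq(rbind(pair1 = c(70, 30),
                                          pair2 = c(55, 45)))
  expect_equal(nrow(multi), 2)
  expect_error(differential_motif_chisq(c(0, 0)), "zero total")
})
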