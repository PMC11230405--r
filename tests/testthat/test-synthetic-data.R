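test_that("alignment simulation plants segments with correct structure and
           round-trips through MAF", {
  tree <- demo_tree()
  m <- hky_model()
  layout <- genome_layout(layout_segment(1000, "neutral"))
  sim <- simulate_alignment(tree, m, layout, seed = 1)
  expect_equal(ncol(sim$alignment$seqs), 1000)
  expect_equal(nrow(sim$truth), 1)
  expect_equal(sim$truth$class, "neutral")
  expect_true(all(sim$alignment$seqs[sim$alignment$ref, ] != "-"))

  path <- withr::local_tempfile(fileext = ".maf")
  write_maf(sim$alignment, path)
  blocks <- expect_no_warning(read_maf(path))
  expect_length(blocks, 1)
  expect_identical(blocks[[1]]$seqs, sim$alignment$seqs)
  expect_equal(blocks[[1]]$ref, sim$alignment$ref)

  expect_error(
    simulate_alignment(tree, m,
                       genome_layout(layout_segment(10, "accelerated",
                                                    rho = 0.3, r = 4,
                                                    lineages = "not_a_leaf")),
                       seed = 1),
    "not a leaf")
})

test_that("reverse-strand reference rows are mapped onto forward orientation", {
  maf <- c("##maf version=1", "a score=0",
           "s ref.chr1 2 6 - 20 AC-GTTG",
           "s other.s1 0 7 + 7 ACCGTTG")
  path <- withr::local_tempfile(lines = maf)
  b <- read_maf(path)[[1]]
  # forward-orientation start = srcSize - start - size = 20 - 2 - 6 = 12
  expect_equal(b$ref_start, 12)
  expect_equal(paste(b$seqs["ref", ], collapse = ""), "CAAC-GT")
  expect_equal(paste(b$seqs["other", ], collapse = ""), "CAACGGT")
})

test_that("planted conserved segments show elevated identity and deletions
           are gapped with aligned flanks", {
  tree <- demo_tree()
  m <- hky_model()
  layout <- genome_layout(
    layout_segment(600, "neutral"),
    layout_segment(200, "conserved", rho = 0.3),
    layout_segment(600, "neutral"))
  pairwise_identity <- function(seqs) {
    pairs <- utils::combn(nrow(seqs), 2)
    mean(apply(pairs, 2, function(p) mean(seqs[p[1], ] == seqs[p[2], ])))
  }
  wins <- vapply(1:20, function(s) {
    sim <- simulate_alignment(tree, m, layout, seed = s)
    cons <- sim$alignment$seqs[, 601:800]
    neut <- sim$alignment$seqs[, 1:600]
    pairwise_identity(cons) > pairwise_identity(neut)
  }, logical(1))
  expect_gte(sum(wins), 18)

  layout_del <- genome_layout(
    layout_segment(600, "neutral"),
    layout_segment(80, "deleted", rho = 0.3, lineages = "hib_C"),
    layout_segment(600, "neutral"))
  sim <- simulate_alignment(tree, m, layout_del, seed = 4, ref = "bg_A")
  inside <- sim$alignment$seqs["hib_C", 601:680]
  flank <- sim$alignment$seqs["hib_C", c(101:600, 681:1180)]
  expect_equal(mean(inside == "-"), 1.0)
  expect_lt(mean(flank == "-"), 0.2)
})

test_that("contact simulation is deterministic, validates inputs, and has a
           unit odds ratio truth at enrichment 1", {
  s1 <- simulate_contacts(60, promoter_bins = 1:10, element_bins = 21:26,
                          enrichment_factor = 1, seed = 9)
  s2 <- simulate_contacts(60, promoter_bins = 1:10, element_bins = 21:26,
                          enrichment_factor = 1, seed = 9)
  expect_identical(s1$bedpe, s2$bedpe)
  expect_equal(s1$truth$true_or, 1)
  s3 <- simulate_contacts(60, 1:10, 21:26, enrichment_factor = 3, seed = 9)
  expect_gt(s3$truth$true_or, 1)
  expect_error(simulate_contacts(60, 1:10, element_bins = 70,
                                 enrichment_factor = 2, seed = 1),
               "outside the binned range")
  expect_error(simulate_contacts(60, 1:10, element_bins = 5,
                                 enrichment_factor = 2, seed = 1),
               "distinct")
  expect_error(simulate_contacts(60, 1:10, 21:26, enrichment_factor = 0.5,
                                 seed = 1), ">= 1")
})

test_that("expression simulation plants perfect modules at zero noise and
           near-independent background genes", {
  es0 <- simulate_expression(60, 30, module_sizes = c(20), noise_sd = 0,
                             seed = 2)
  mod <- es0$expression[es0$truth$module == 1, ]
  cors <- cor(t(mod))
  expect_equal(abs(cors), matrix(1, nrow(mod), nrow(mod)),
               ignore_attr = TRUE, tolerance = 1e-12)

  es <- simulate_expression(120, 60, module_sizes = c(30), noise_sd = 0.3,
                            seed = 3)
  bg <- es$expression[es$truth$module == 0, ]
  cc <- abs(cor(t(bg)))
  # for independent Gaussians, E|r| = sqrt(2 / (pi (n - 1))) ~ 0.104 at n = 60
  expect_equal(mean(cc[upper.tri(cc)]), sqrt(2 / (pi * 59)),
               tolerance = 0.15)
  expect_lt(mean(cc[upper.tri(cc)]), 0.12)

  expect_identical(simulate_expression(50, 20, 10, seed = 5)$expression,
                   simulate_expression(50, 20, 10, seed = 5)$expression)
  expect_error(simulate_expression(50, 20, 10, noise_sd = -1, seed = 1),
               ">= 0")
})

test_that("peak replicates honour dropout, jitter and determinism", {
  peaks <- data.frame(chrom = "chr1", start = seq(0, 9000, by = 1000),
                      end = seq(0, 9000, by = 1000) + 300)
  none <- simulate_peak_replicates(peaks, n_reps = 3, dropout = 0,
                                   jitter_sd = 0, seed = 1)
  for (r in none$replicates) expect_equal(r, peaks, ignore_attr = TRUE)

  # near-total dropout: consensus at >= 4 of 8 is (almost surely) empty
  heavy <- simulate_peak_replicates(peaks, n_reps = 8, dropout = 0.95,
                                    jitter_sd = 0, seed = 2)
  expect_equal(nrow(consensus_peaks(heavy$replicates, min_reps = 4)), 0)

  expect_identical(
    simulate_peak_replicates(peaks, 8, 0.3, seed = 7)$replicates,
    simulate_peak_replicates(peaks, 8, 0.3, seed = 7)$replicates)
  expect_error(simulate_peak_replicates(peaks, 8, dropout = 1, seed = 1),
               "dropout")
})

test_that("motif sequence groups carry exactly the planted instances", {
  pwm <- demo_pwm()
  sim <- simulate_motif_sequences(pwm, n_with = 30, n_without = 30,
                                  seq_len = 150, seed = 11)
  expect_length(sim$with, 30)
  expect_true(all(nchar(sim$with) == 150))
  expect_true(all(sim$truth$offset >= 0 &
                    sim$truth$offset + pwm$width <= 150))
  # the planted instance is recoverable at the recorded position
  hit_at_truth <- vapply(seq_len(30), function(i) {
    h <- scan_sequence(sim$with[i], pwm)
    any(h$offset == sim$truth$offset[i] & h$strand == sim$truth$strand[i])
  }, logical(1))
  expect_gte(mean(hit_at_truth), 0.9)
  expect_identical(
    simulate_motif_sequences(pwm, 10, 10, 100, seed = 3),
    simulate_motif_sequences(pwm, 10, 10, 100, seed = 3))
  expect_error(simulate_motif_sequences(pwm, 5, 5, seq_len = 4, seed = 1),
               "motif width")
})

test_that("truth tables round-trip through the BED writer", {
  tree <- demo_tree()
  sim <- simulate_alignment(tree, hky_model(), demo_layout(), seed = 2)
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(sim$truth, path)
  back <- read_bed(path)
  expect_equal(back$start, sim$truth$start)
  expect_equal(back$end, sim$truth$end)
  expect_equal(back$class, sim$truth$class)
})
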