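mk_bedpe <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(chrom1 = "chr1", start1 = r[1] * 10000, end1 = (r[1] + 1) * 10000,
               chrom2 = "chr1", start2 = r[2] * 10000, end2 = (r[2] + 1) * 10000,
               count = r[3], obs_exp = r[4], qvalue = r[5])
  }))
}

test_that("contact filtering enforces all three thresholds and collapses
           symmetric duplicates", {
  bedpe <- mk_bedpe(c(0, 5, 11, 3, 0.001),    # count too low
                    c(0, 6, 12, 2.5, 0.005),  # kept
                    c(6, 0, 12, 2.5, 0.005),  # symmetric duplicate
                    c(1, 7, 20, 1.5, 0.001),  # obs/exp too low
                    c(2, 8, 20, 3.0, 0.02))   # q too high
  map <- load_and_filter_contacts(bedpe)
  expect_equal(nrow(map$contacts), 1)
  expect_equal(map$contacts$bin1, "chr1:0")
  expect_equal(map$contacts$bin2, "chr1:60000")

  bad <- bedpe
  bad$start1[2] <- 12345  # not bin-aligned
  expect_error(load_and_filter_contacts(bad), "line 3")
})

test_that("promoter annotation uses half-open TSS windows that can straddle
           bin boundaries", {
  bedpe <- mk_bedpe(c(0, 5, 12, 2.5, 0.005))
  map <- load_and_filter_contacts(bedpe, chrom_sizes = c(chr1 = 100000))
  tss <- data.frame(gene = c("gA", "gB"), chrom = "chr1", strand = "+",
                    tss = c(10000, 35000))
  map <- annotate_promoter_bins(map, tss)
  # gA promoter [8000, 12000) intersects bins chr1:0 and chr1:10000
  expect_true("gA" %in% map$bins$genes[[1]])
  expect_true("gA" %in% map$bins$genes[[2]])
  # gB promoter [33000, 37000) stays within bin chr1:30000
  expect_equal(map$bins$genes[[4]], "gB")
  expect_equal(lengths(map$bins$genes[c(3, 5:10)]), rep(0L, 7))
})

test_that("element contact classes form a partition with correct gene
           assignment", {
  # bin 0 (promoter gA) - bin 5 (element): E-P
  # bin 2 (promoter gC) - bin 0: P-P for elements in bin 2
  bedpe <- mk_bedpe(c(0, 5, 12, 2.5, 0.005),
                    c(0, 2, 15, 3.0, 0.001))
  map <- load_and_filter_contacts(bedpe, chrom_sizes = c(chr1 = 100000))
  tss <- data.frame(gene = c("gA", "gC"), chrom = "chr1", strand = "+",
                    tss = c(5000, 25000))
  map <- annotate_promoter_bins(map, tss)
  elements <- data.frame(
    id = c("in_EP_bin", "in_PP_bin", "orphan"),
    chrom = "chr1",
    start = c(52000, 22000, 82000),
    end = c(52200, 22200, 82200))
  cls <- classify_element_contacts(elements, map)$classes
  expect_equal(cls$class[cls$id == "in_EP_bin"], "E-P")
  expect_equal(cls$genes[cls$id == "in_EP_bin"], "gA")
  expect_equal(cls$class[cls$id == "in_PP_bin"], "P-P")
  expect_equal(cls$class[cls$id == "orphan"], "no-P")
  expect_equal(cls$subclass[cls$id == "orphan"], "no-P:no-contacts")
  # partition property
  expect_equal(sum(table(cls$class)), nrow(elements))

  off_map <- data.frame(id = "off", chrom = "chrZ", start = 0, end = 100)
  res <- classify_element_contacts(off_map, map)
  expect_equal(nrow(res$excluded), 1)
  expect_equal(nrow(res$classes), 0)
})

test_that("consensus peaks require replicate support, minimum width, and
           are idempotent", {
  peak <- function(s, e) data.frame(chrom = "chr1", start = s, end = e)
  eight <- rep(list(peak(100, 400)), 8)
  expect_equal(consensus_peaks(eight, min_reps = 4), peak(100, 400),
               ignore_attr = TRUE)

  three <- c(rep(list(peak(100, 400)), 3), rep(list(peak(5000, 5400)), 5))
  cons <- consensus_peaks(three, min_reps = 4)
  expect_equal(cons$start, 5000)

  # staggered peaks overlap only pairwise: coverage never reaches 4
  staggered <- list(peak(0, 100), peak(80, 180), peak(160, 260),
                    peak(240, 340), peak(320, 420), peak(400, 500),
                    peak(480, 580), peak(560, 660))
  expect_equal(nrow(consensus_peaks(staggered, min_reps = 4)), 0)

  # narrow coverage spikes are suppressed
  spiky <- rep(list(peak(0, 30)), 8)
  expect_equal(nrow(consensus_peaks(spiky, min_reps = 4, min_width = 50)), 0)

  # idempotence: consensus of n copies of its own output returns itself
  out <- consensus_peaks(three, min_reps = 4)
  again <- consensus_peaks(rep(list(out), 5), min_reps = 5)
  expect_equal(again, out, ignore_attr = TRUE)
})

test_that("odds-ratio tests match direct formulas and handle zero cells", {
  sym <- or_test(10, 90, 10, 90)
  expect_equal(sym$or, 1)
  expect_equal(sym$p, 1)

  e <- or_test(30, 70, 10, 90)
  expect_equal(e$or, 30 * 90 / (70 * 10), tolerance = 1e-12)
  expect_true(e$ci[1] < e$or && e$or < e$ci[2])

  z <- or_test(0, 100, 10, 90)
  expect_true(z$haldane)
  expect_equal(z$or, (0.5 * 90.5) / (100.5 * 10.5), tolerance = 1e-12)

  # swapping query and background rows inverts the OR exactly
  a <- or_test(25, 75, 40, 60)
  b <- or_test(40, 60, 25, 75)
  expect_equal(a$or, 1 / b$or, tolerance = 1e-12)
  expect_error(or_test(1.5, 2, 3, 4), "integers")
})

test_that("interval-based enrichment removes the query from the background", {
  iv <- function(starts) data.frame(chrom = "chr1", start = starts,
                                    end = starts + 100)
  universe <- iv(seq(0, 99) * 1000)
  query <- iv(seq(0, 19) * 1000)
  target <- iv(seq(0, 29) * 1000 + 50)  # overlaps first 30 universe elements
  e <- enrichment_2x2(query, universe, target)
  expect_equal(unname(e$table), c(20, 0, 10, 70))
  expect_error(enrichment_2x2(universe[0, ], universe, target), "empty query")
})

test_that("Fisher p equals full table enumeration for small tables", {
  withr::with_seed(14, {
    for (i in 1:50) {
      n <- sample(8:40, 1)
      cells <- as.vector(stats::rmultinom(1, n, prob = runif(4, 0.05, 1)))
      got <- or_test(cells[1], cells[2], cells[3], cells[4])$p
      want <- fisher_p_enum(cells[1], cells[2], cells[3], cells[4])
      expect_equal(got, want, tolerance = 1e-10)
    }
  })
})

test_that("the Woolf test matches its closed form, including the frozen
           hand-worked example", {
  w <- woolf_test(list(c(30, 70, 10, 90), c(10, 90, 10, 90)))
  # independent hand evaluation: w1 = 6.2999, w2 = 4.5, lnOR1 = 1.3499,
  # pooled = 0.7874, X2 = 4.784
  expect_equal(w$weights, c(6.2999, 4.5), tolerance = 1e-4)
  expect_equal(w$log_or[1], log(30 * 90 / (70 * 10)), tolerance = 1e-12)
  expect_equal(w$statistic, 4.784, tolerance = 1e-3)
  expect_equal(w$df, 1)
  expect_equal(w$p, 0.0287, tolerance = 1e-2)

  same <- woolf_test(list(c(12, 34, 56, 78), c(12, 34, 56, 78)))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)

  ab <- woolf_test(list(c(30, 70, 10, 90), c(10, 90, 10, 90)))
  ba <- woolf_test(list(c(10, 90, 10, 90), c(30, 70, 10, 90)))
  expect_equal(ab$statistic, ba$statistic, tolerance = 1e-12)
  expect_error(woolf_test(list(c(1, 2, 3, 4))), "at least 2 strata")

  # 50 random strata sets against the independent formula evaluation
  withr::with_seed(3, {
    for (i in 1:50) {
      k <- sample(2:5, 1)
      tabs <- lapply(seq_len(k), function(j) sample(0:60, 4, replace = TRUE))
      tabs <- lapply(tabs, function(x) {
        x[x + c(x[2], x[1], x[4], x[3])[1] == 0] <- 1; x
      })
      expect_equal(woolf_test(tabs)$statistic, woolf_enum(tabs),
                   tolerance = 1e-8)
    }
  })
})

test_that("hypergeometric overlap matches exact enumeration", {
  universe <- paste0("u", 1:20)
  A <- universe[1:5]
  B <- universe[c(1:4, 6:9)]
  h <- hypergeometric_overlap(A, B, universe)
  expect_equal(h$overlap, 4)
  expect_equal(h$p, 7280 / 125970, tolerance = 1e-12)

  disj <- hypergeometric_overlap(universe[1:5], universe[6:10], universe)
  expect_equal(disj$p, 1)
  expect_error(hypergeometric_overlap(c(A, "zzz"), B, universe),
               "not in universe")

  withr::with_seed(21, {
    for (i in 1:30) {
      N <- sample(5:30, 1)
      u <- paste0("x", seq_len(N))
      a <- sample(u, sample(1:N, 1))
      b <- sample(u, sample(1:N, 1))
      got <- hypergeometric_overlap(a, b, u)$p
      want <- hyper_tail_enum(length(intersect(a, b)), length(a),
                              length(b), N)
      expect_equal(got, want, tolerance = 1e-12)
    }
  })
})

test_that("locus-set enrichment reports BH-corrected per-set results", {
  iv <- function(starts) data.frame(chrom = "chr1", start = starts,
                                    end = starts + 100)
  universe <- iv(seq(0, 199) * 1000)
  query <- iv(seq(0, 39) * 1000)
  sets <- list(
    enriched = iv(seq(0, 49) * 1000 + 10),   # covers all query elements
    unrelated = iv(seq(150, 199) * 1000 + 10))
  res <- locus_set_enrichment(query, sets, universe)
  expect_equal(nrow(res), 2)
  expect_lt(res$q[res$set == "enriched"], 0.05)
  expect_gt(res$or[res$set == "enriched"], 1)
  expect_lt(res$or[res$set == "unrelated"], 1)
  expect_true(all(res$q >= res$p))
})

test_that("cross-species peak partition assigns every merged peak once", {
  p <- function(s, e) data.frame(chrom = "chr1", start = s, end = e)
  same <- classify_species_peaks(p(c(0, 500), c(100, 700)),
                                 p(c(0, 500), c(100, 700)))
  expect_true(all(same$class == "shared"))

  disjoint <- classify_species_peaks(p(0, 100), p(5000, 5100),
                                     species = c("sq", "mm"))
  expect_setequal(disjoint$class, c("sq-specific", "mm-specific"))

  # one bp of overlap counts as shared
  onebp <- classify_species_peaks(p(0, 101), p(100, 200))
  expect_true(all(onebp$class == "shared"))

  # overlapping within-species peaks are merged before comparison
  merged <- classify_species_peaks(p(c(0, 50), c(100, 150)), p(5000, 5100))
  expect_equal(sum(merged$species == "species1"), 1)
  expect_equal(merged$end[merged$species == "species1"], 150)
})

test_that("loss-of-function planting produces the expected enrichment
           directions", {
  iv <- function(starts, w = 100) data.frame(chrom = "chr1", start = starts,
                                             end = starts + w)
  crs <- iv(seq(0, 199) * 1000)
  partition <- rbind(
    data.frame(iv(seq(0, 59) * 1000 + 10, 50), species = "mm",
               class = "mouse-specific"),
    data.frame(iv(seq(60, 119) * 1000 + 10, 50), species = "both",
               class = "shared"),
    data.frame(iv(seq(120, 179) * 1000 + 10, 50), species = "sq",
               class = "squirrel-specific"))
  # ARs placed preferentially in the other species' (mouse) specific peaks
  ars <- iv(c(seq(0, 29) * 1000, seq(60, 64) * 1000))
  res <- lof_enrichment(ars, crs, partition)
  expect_gt(res[["mouse-specific"]]$or, 1)
  expect_lt(res[["shared"]]$or, 1)
  expect_lt(res[["squirrel-specific"]]$or, 1)
  expect_lt(res[["mouse-specific"]]$p, 0.05)
})
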