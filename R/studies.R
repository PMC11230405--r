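# Simulation studies over the fixture tree: type-I calibration and power of
# the acceleration LRT, convergence recovery with the bootstrap null,
# deletion-calling performance, contact-enrichment CI coverage, hub-gene
# recovery, and motif-enrichment detection. These drive the analysis
# scripts and the acceptance checks, so every number they report is
# recomputed from fresh simulations.

#' Type-I error of the acceleration LRT under the null
#'
#' Simulates `n` conserved regions with no foreground acceleration (r = 1)
#' and reports the empirical rejection rate at `alpha`.
#'
#' @param n number of null regions (default 2000).
#' @param region_length region length in bp. The default 200 puts the test
#'   in its asymptotic regime; the LRT is conservative (never
#'   anticonservative) at very short regions.
#' @param rho planted conserved scale (default 0.3).
#' @param foreground tested lineage.
#' @param alpha nominal level (default 0.05).
#' @param seed integer seed.
#' @return list: rejection_rate, n, p_values.
#' @export
lrt_null_calibration <- function(n = 2000, region_length = 200, rho = 0.3,
                                 foreground = "hib_A", alpha = 0.05, seed) {
  tree <- demo_tree()
  model <- hky_model()
  seeds <- withr::with_seed(seed, sample.int(2^31 - 1, n))
  sc <- branch_scales(tree, rho)
  p <- vapply(seq_len(n), function(i) {
    cols <- simulate_columns(tree, model, region_length, sc, seed = seeds[i])
    acceleration_lrt(cols, tree, model, foreground)$p
  }, numeric(1))
  list(rejection_rate = mean(p < alpha), n = n, p_values = p)
}

#' Power of the acceleration LRT across planted rate multipliers
#'
#' @param r_grid planted foreground multipliers (default 2, 4, 8).
#' @param n regions per condition (default 300).
#' @param region_length region length in bp (default 40, the modal parallel
#'   accelerated element size).
#' @inheritParams lrt_null_calibration
#' @return data.frame: r, power.
#' @export
lrt_power_curve <- function(r_grid = c(2, 4, 8), n = 300, region_length = 40,
                            rho = 0.3, foreground = "hib_A", alpha = 0.05,
                            seed) {
  tree <- demo_tree()
  model <- hky_model()
  seeds <- withr::with_seed(seed, sample.int(2^31 - 1, n * length(r_grid)))
  power <- vapply(seq_along(r_grid), function(k) {
    sc <- branch_scales(tree, rho,
                        terminal = setNames(r_grid[k], foreground))
    p <- vapply(seq_len(n), function(i) {
      cols <- simulate_columns(tree, model, region_length, sc,
                               seed = seeds[(k - 1) * n + i])
      acceleration_lrt(cols, tree, model, foreground)$p
    }, numeric(1))
    mean(p < alpha)
  }, numeric(1))
  data.frame(r = r_grid, power = power)
}

#' Convergence recovery study
#'
#' Builds a universe of `n_background` conserved regions with
#' `n_planted` of them accelerated in two foreground lineages, runs the
#' full per-lineage AR pipeline (LRT + per-lineage BH), collects parallel
#' elements, and tests the excess with the bootstrap null.
#'
#' @param n_background total conserved regions (default 5000).
#' @param n_planted regions accelerated in both planted lineages
#'   (default 50).
#' @param planted_lineages the two accelerated foreground lineages.
#' @param r planted rate multiplier (default 8).
#' @param region_length bp per region (default 40).
#' @param rho conserved scale (default 0.3).
#' @param B bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @return list: recovery (fraction of planted-and-per-lineage-significant
#'   regions reported parallel), n_parallel, n_planted_sig, bootstrap
#'   (a `bootstrap_result`), calls.
#' @export
convergence_recovery_study <- function(n_background = 5000, n_planted = 50,
                                       planted_lineages = c("hib_A", "hib_B"),
                                       r = 8, region_length = 40, rho = 0.3,
                                       B = 1000, seed) {
  tree <- demo_tree()
  model <- hky_model()
  fg <- demo_lineages()$foreground
  segs <- lapply(seq_len(n_background), function(i) {
    if (i <= n_planted) {
      layout_segment(region_length, "accelerated", rho = rho, r = r,
                     lineages = planted_lineages)
    } else {
      layout_segment(region_length, "conserved", rho = rho)
    }
  })
  layout <- do.call(genome_layout, segs)
  sim <- simulate_alignment(tree, model, layout, seed = seed, ref = "bg_A")
  crs <- data.frame(id = sprintf("cr_%05d", seq_len(n_background)),
                    chrom = "chr1",
                    start = (seq_len(n_background) - 1L) * region_length,
                    end = seq_len(n_background) * region_length,
                    length = region_length, stringsAsFactors = FALSE)
  scan <- acceleration_scan(sim$alignment, crs, tree, model, fg)
  ar <- call_accelerated_regions(scan)
  parallel <- find_parallel_elements(ar$calls, crs$id, group = "foreground")

  planted_ids <- crs$id[seq_len(n_planted)]
  sig_count <- rowSums(vapply(planted_lineages, function(l) {
    planted_ids %in% ar$calls[[l]]
  }, logical(n_planted)))
  planted_sig <- planted_ids[sig_count >= 2]
  recovery <- if (length(planted_sig)) {
    mean(planted_sig %in% parallel$cr_id)
  } else {
    NA_real_
  }
  boot_seed <- withr::with_seed(seed, sample.int(2^31 - 1, 1))
  boot <- bootstrap_parallel_excess(ar$calls, crs$id, B = B,
                                    seed = boot_seed)
  list(recovery = recovery, n_parallel = nrow(parallel),
       n_planted_sig = length(planted_sig), bootstrap = boot,
       calls = ar$calls, crs = crs, parallel = parallel)
}

#' Bootstrap p-value calibration under a fully null generator
#'
#' Each replicate dataset draws per-lineage call sets uniformly at random
#' from the background universe (the bootstrap's own null) and records the
#' bootstrap p-value; under the null the fraction below `alpha` should sit
#' near `alpha` (slightly under, by the add-one estimator and count ties).
#'
#' @param n_datasets replicate datasets (default 100).
#' @param n_background CR universe size (default 5000).
#' @param calls_per_lineage call-set size per lineage (default 60).
#' @param n_lineages lineages per dataset (default 4).
#' @param B bootstrap replicates per dataset (default 1000).
#' @param alpha level (default 0.05).
#' @param seed integer seed.
#' @return list: fraction_below_alpha, p_values.
#' @export
bootstrap_null_calibration <- function(n_datasets = 100, n_background = 5000,
                                       calls_per_lineage = 60,
                                       n_lineages = 4, B = 1000,
                                       alpha = 0.05, seed) {
  universe <- sprintf("cr_%05d", seq_len(n_background))
  seeds <- withr::with_seed(seed, sample.int(2^31 - 1, 2 * n_datasets))
  p <- vapply(seq_len(n_datasets), function(d) {
    calls <- withr::with_seed(seeds[d], {
      lapply(setNames(nm = paste0("lin", seq_len(n_lineages))), function(l) {
        sample(universe, calls_per_lineage)
      })
    })
    bootstrap_parallel_excess(calls, universe, B = B,
                              seed = seeds[n_datasets + d])$p
  }, numeric(1))
  list(fraction_below_alpha = mean(p < alpha), p_values = p)
}

#' Deletion-calling performance on planted deletions
#'
#' Per seed, simulates an alignment with deleted and plain-conserved
#' segments (aligned >= 500 bp flanks), calls deletions for every
#' foreground lineage on the true segment coordinates, and accumulates
#' precision/recall. Also verifies that an entirely unaligned lineage
#' yields no calls.
#'
#' @param n_seeds replicate alignments (default 20).
#' @param n_del,n_cons planted deleted / control conserved segments.
#' @param seed integer seed.
#' @return list: precision, recall, missing_data_calls.
#' @export
deletion_performance_study <- function(n_seeds = 20, n_del = 6, n_cons = 6,
                                       seed) {
  tree <- demo_tree()
  model <- hky_model()
  fg <- demo_lineages()$foreground
  seeds <- withr::with_seed(seed, sample.int(2^31 - 1, n_seeds))
  tp <- fp <- fn <- 0
  missing_calls <- 0
  for (s in seq_len(n_seeds)) {
    del_lin <- fg[(s %% 2) + 1:2]  # alternate planted lineage pairs
    segs <- list(layout_segment(600, "neutral"))
    for (i in seq_len(n_del)) {
      segs <- c(segs, list(layout_segment(60, "deleted", rho = 0.3,
                                          lineages = del_lin),
                           layout_segment(600, "neutral")))
    }
    for (i in seq_len(n_cons)) {
      segs <- c(segs, list(layout_segment(60, "conserved", rho = 0.3),
                           layout_segment(600, "neutral")))
    }
    layout <- do.call(genome_layout, segs)
    sim <- simulate_alignment(tree, model, layout, seed = seeds[s],
                              ref = "bg_A")
    truth <- sim$truth[sim$truth$class != "neutral", ]
    crs <- data.frame(id = sprintf("seg_%02d", seq_len(nrow(truth))),
                      start = truth$start, end = truth$end)
    for (lin in fg) {
      calls <- call_deletions(crs, sim$alignment, lin)
      is_true <- truth$class == "deleted" & lin %in% del_lin
      tp <- tp + sum(calls$call & is_true)
      fp <- fp + sum(calls$call & !is_true)
      fn <- fn + sum(!calls$call & is_true)
    }
    # missing data: wipe one lineage entirely; nothing may be called
    wiped <- sim$alignment
    wiped$seqs["hib_D", ] <- "-"
    missing_calls <- missing_calls +
      sum(call_deletions(crs, wiped, "hib_D")$call)
  }
  list(precision = tp / (tp + fp), recall = tp / (tp + fn),
       missing_data_calls = missing_calls)
}

# 2x2 of element vs background bins against significant-promoter-contact
# bins, computed from a simulated contact map.
contact_or_from_sim <- function(sim) {
  cmap <- load_and_filter_contacts(sim$bedpe)
  bin_ids <- paste0("chr1:", sim$bins$start)
  prom_ids <- bin_ids[sim$bins$promoter]
  partners <- function(b) {
    c(cmap$contacts$bin2[cmap$contacts$bin1 == b],
      cmap$contacts$bin1[cmap$contacts$bin2 == b])
  }
  has_prom_contact <- vapply(bin_ids, function(b) {
    any(partners(b) %in% prom_ids)
  }, logical(1))
  elem <- sim$bins$element
  bg <- !sim$bins$element & !sim$bins$promoter
  or_test(sum(elem & has_prom_contact), sum(elem & !has_prom_contact),
          sum(bg & has_prom_contact), sum(bg & !has_prom_contact))
}

#' CI coverage of the contact-enrichment odds ratio
#'
#' For each seed, simulates a contact map at the given enrichment factor,
#' filters it, computes the element-vs-background odds ratio of having a
#' significant promoter contact, and checks whether the 95% CI covers the
#' generator's analytic true odds ratio.
#'
#' @param n_seeds replicate maps (default 100).
#' @param enrichment_factor planted factor (1 = null).
#' @param n_bins,n_promoters,n_elements map dimensions.
#' @param seed integer seed.
#' @return list: coverage, n_seeds, true_or, estimates.
#' @export
contact_ci_coverage_study <- function(n_seeds = 100, enrichment_factor = 3,
                                      n_bins = 120, n_promoters = 20,
                                      n_elements = 15, seed) {
  seeds <- withr::with_seed(seed, sample.int(2^31 - 1, n_seeds))
  prom <- seq_len(n_promoters)
  elem <- n_promoters + seq_len(n_elements)
  covered <- logical(n_seeds)
  ors <- numeric(n_seeds)
  true_or <- NA_real_
  for (s in seq_len(n_seeds)) {
    sim <- simulate_contacts(n_bins, prom, elem, enrichment_factor,
                             seed = seeds[s])
    true_or <- sim$truth$true_or
    e <- contact_or_from_sim(sim)
    covered[s] <- e$ci[1] <= true_or && true_or <= e$ci[2]
    ors[s] <- e$or
  }
  list(coverage = mean(covered), n_seeds = n_seeds, true_or = true_or,
       estimates = ors)
}

#' Module and hub recovery on planted-module expression data
#'
#' @param n_seeds replicate expression matrices (default 20).
#' @param n_genes,n_samples,module_sizes,noise_sd generator settings
#'   (defaults: 200 genes, 60 samples, three 50-gene modules, sd 0.3).
#' @param seed integer seed.
#' @return list: mean_ari, mean_jaccard, per_seed (data.frame).
#' @export
hub_recovery_study <- function(n_seeds = 20, n_genes = 200, n_samples = 60,
                               module_sizes = c(50, 50, 50), noise_sd = 0.3,
                               seed) {
  seeds <- withr::with_seed(seed, sample.int(2^31 - 1, n_seeds))
  ari <- jac <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    es <- simulate_expression(n_genes, n_samples, module_sizes,
                              noise_sd = noise_sd, seed = seeds[s])
    adj <- build_adjacency(es$expression)
    labels <- detect_modules(topological_overlap(adj))
    truth_mod <- es$truth$module
    in_mod <- truth_mod > 0
    tab <- table(labels[in_mod], truth_mod[in_mod])
    comb2 <- function(x) x * (x - 1) / 2
    sij <- sum(comb2(tab)); si <- sum(comb2(rowSums(tab)))
    sj <- sum(comb2(colSums(tab))); n2 <- comb2(sum(tab))
    expd <- si * sj / n2
    ari[s] <- (sij - expd) / ((si + sj) / 2 - expd)

    summ <- module_eigengene(es$expression, labels)
    hubs <- hub_genes(adj, summ)
    jacs <- vapply(seq_along(module_sizes), function(m) {
      planted <- planted_hubs(es$truth, m)
      # the detected module containing most of the planted genes
      mod_genes <- es$truth$gene[es$truth$module == m]
      lab <- names(sort(table(labels[mod_genes]), decreasing = TRUE))[1]
      if (lab == "0" || !lab %in% names(hubs)) return(0)
      found <- hubs[[lab]]$hubs
      length(intersect(found, planted)) / length(union(found, planted))
    }, numeric(1))
    jac[s] <- mean(jacs)
  }
  list(mean_ari = mean(ari), mean_jaccard = mean(jac),
       per_seed = data.frame(seed = seeds, ari = ari, jaccard = jac))
}

#' Detection rate of planted group-level motif enrichment
#'
#' Per seed, builds a query group with the motif planted in
#' `frac_query` of its sequences and a background group at
#' `frac_background`, and tests whether the per-motif enrichment is called
#' in the query direction at `q <= 0.05`.
#'
#' @param n_seeds replicate datasets (default 100).
#' @param n_per_group sequences per group (default 200).
#' @param frac_query,frac_background planted carrier fractions (defaults
#'   0.6 / 0.1).
#' @param seq_len sequence length (default 200).
#' @param seed integer seed.
#' @return list: detection_rate, n_seeds.
#' @export
motif_detection_study <- function(n_seeds = 100, n_per_group = 200,
                                  frac_query = 0.6, frac_background = 0.1,
                                  seq_len = 200, seed) {
  pwm <- demo_pwm()
  seeds <- withr::with_seed(seed, sample.int(2^31 - 1, n_seeds))
  detected <- vapply(seq_len(n_seeds), function(s) {
    n_q_with <- round(frac_query * n_per_group)
    n_b_with <- round(frac_background * n_per_group)
    sim <- simulate_motif_sequences(
      pwm, n_with = n_q_with + n_b_with,
      n_without = 2 * n_per_group - n_q_with - n_b_with,
      seq_len = seq_len, seed = seeds[s])
    query <- c(sim$with[seq_len(n_q_with)],
               sim$without[seq_len(n_per_group - n_q_with)])
    background <- c(sim$with[n_q_with + seq_len(n_b_with)],
                    sim$without[n_per_group - n_q_with +
                                  seq_len(n_per_group - n_b_with)])
    res <- group_motif_enrichment(query, background, list(pwm))
    res$enriched_in == "query"
  }, logical(1))
  list(detection_rate = mean(detected), n_seeds = n_seeds)
}
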