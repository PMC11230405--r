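# End-to-end demonstration pipeline over the shipped 12-leaf fixture:
# simulate -> call CRs -> acceleration/deletion tests -> convergence ->
# contact integration -> co-expression hubs -> motif enrichment.
# The analysis/ scripts, the smoke test and the acceptance script all run
# through these entry points so every stage is exercised by one code path.

#' Demonstration PWM: a sharp 8-bp consensus motif
#'
#' A nearly invariant TGACGTCA site (CRE-like). Sharp columns keep planted
#' instances recoverable at the default stringent score threshold.
#'
#' @return a [pwm_logodds()] object.
#' @export
demo_pwm <- function() {
  consensus <- c("T", "G", "A", "C", "G", "T", "C", "A")
  counts <- matrix(1, 4, length(consensus), dimnames = list(DNA_BASES4, NULL))
  for (j in seq_along(consensus)) counts[consensus[j], j] <- 597
  pwm_logodds(counts, id = "demo_TGACGTCA")
}

#' Demonstration genome layout with planted truth
#'
#' Interleaves neutral spacers with planted conserved, accelerated and
#' deleted segments on the fixture tree's lineages. Accelerated segments
#' are planted in pairs of hibernator lineages so parallel (convergent)
#' elements exist by construction; deletions keep >= 500 bp aligned flanks.
#'
#' @param n_conserved plain conserved segments (length `len_conserved`).
#' @param n_accel accelerated segments, planted in 2 hibernator lineages.
#' @param n_del deleted segments, planted in 1-2 hibernator lineages.
#' @param len_conserved,len_accel,len_del segment lengths (bp).
#' @param spacer neutral spacer length (bp), >= 500 so deletion flanks are
#'   aligned.
#' @param rho conserved branch scale.
#' @param r acceleration multiplier of the planted foreground branches.
#' @param accel_lineages,del_lineages lineage sets used for planting.
#' @return a [genome_layout()].
#' @export
demo_layout <- function(n_conserved = 14, n_accel = 8, n_del = 6,
                        len_conserved = 100, len_accel = 40, len_del = 60,
                        spacer = 600, rho = 0.3, r = 6,
                        accel_lineages = c("hib_A", "hib_B"),
                        del_lineages = c("hib_C", "hib_D")) {
  segs <- list(layout_segment(spacer, "neutral"))
  add <- function(segs, seg) c(segs, list(seg, layout_segment(spacer, "neutral")))
  for (i in seq_len(n_conserved)) {
    segs <- add(segs, layout_segment(len_conserved, "conserved", rho = rho))
  }
  for (i in seq_len(n_accel)) {
    segs <- add(segs, layout_segment(len_accel, "accelerated", rho = rho,
                                     r = r, lineages = accel_lineages))
  }
  for (i in seq_len(n_del)) {
    segs <- add(segs, layout_segment(len_del, "deleted", rho = rho,
                                     lineages = del_lineages))
  }
  do.call(genome_layout, segs)
}

#' Run the full demonstration pipeline
#'
#' Simulates every input with planted truth, writes/reads the interchange
#' files when `dir` is given (MAF, BED, BEDPE, TSV, FASTA), and runs all
#' analysis stages. Returns a nested summary with the planted truth
#' alongside each stage's calls so recovery can be scored.
#'
#' @param seed integer seed; all stage seeds derive from it.
#' @param dir optional directory for the interchange files; `NULL` keeps
#'   everything in memory.
#' @param target_fdr FDR level for AR calls (default 0.05).
#' @param bootstrap_B bootstrap replicates (default 1000).
#' @return a list of per-stage results (see the analysis scripts for how
#'   each component is consumed).
#' @export
run_demo_pipeline <- function(seed, dir = NULL, target_fdr = 0.05,
                              bootstrap_B = 1000) {
  tree <- demo_tree()
  model <- hky_model()
  lineages <- demo_lineages()
  seeds <- withr::with_seed(seed, sample.int(2^31 - 1, 10))

  ## 1. alignment with planted conserved/accelerated/deleted segments
  layout <- demo_layout()
  sim <- simulate_alignment(tree, model, layout, seed = seeds[1],
                            ref = "bg_A")
  aln <- sim$alignment
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_maf(aln, file.path(dir, "alignment.maf"))
    write_bed(sim$truth, file.path(dir, "truth_segments.bed"))
    aln <- read_maf(file.path(dir, "alignment.maf"))[[1]]
  }

  ## 2. conserved regions, called on the background homeotherms only so
  ## that foreground acceleration cannot erode the conservation signal
  params <- phylo_hmm_params(rho = 0.3)
  bg_tree <- ape::keep.tip(tree, lineages$background)
  bg_aln <- aln
  bg_aln$seqs <- bg_aln$seqs[lineages$background, , drop = FALSE]
  crs <- call_conserved_regions(bg_aln, bg_tree, model, params)

  ## 3. per-lineage acceleration + deletion
  scan <- acceleration_scan(aln, crs, tree, model,
                            c(lineages$foreground, lineages$control))
  ar <- call_accelerated_regions(scan, target_fdr = target_fdr)
  del_calls <- lapply(setNames(nm = c(lineages$foreground, lineages$control)),
                      function(lin) {
                        d <- call_deletions(crs, aln, lin)
                        d$cr_id[d$call]
                      })

  ## 4. convergence
  fg_ar <- ar$calls[intersect(names(ar$calls), lineages$foreground)]
  ctl_ar <- ar$calls[intersect(names(ar$calls), lineages$control)]
  fg_del <- del_calls[lineages$foreground]
  parallel_ar <- find_parallel_elements(fg_ar, crs$id, group = "foreground")
  parallel_ctl <- find_parallel_elements(ctl_ar, crs$id, group = "control")
  parallel_del <- find_parallel_elements(fg_del, crs$id, group = "foreground")
  boot <- bootstrap_parallel_excess(fg_ar, crs$id, B = bootstrap_B,
                                    seed = seeds[2])

  ## 5. contact map: parallel-AR bins planted as promoter-enriched
  n_bins <- 120
  prom_bins <- seq(5, 120, by = 6)
  elem_bins <- head(setdiff(seq(3, 80, by = 4), prom_bins), 12)
  contacts_sim <- simulate_contacts(n_bins, prom_bins, elem_bins,
                                    enrichment_factor = 3, seed = seeds[3])
  bedpe <- contacts_sim$bedpe
  if (!is.null(dir)) {
    write_bedpe(bedpe, file.path(dir, "contacts.bedpe"))
    bedpe <- read_bedpe(file.path(dir, "contacts.bedpe"))
  }
  cmap <- load_and_filter_contacts(bedpe)
  n_genes_tss <- 60
  tss <- data.frame(gene = sprintf("g%04d", seq_len(n_genes_tss)),
                    chrom = "chr1", strand = "+",
                    tss = (rep(prom_bins, length.out = n_genes_tss) - 1L) * 10000L + 5000L)
  cmap <- annotate_promoter_bins(cmap, tss)
  mk_elements <- function(bins) {
    data.frame(chrom = "chr1", start = (bins - 1L) * 10000L + 4000L,
               end = (bins - 1L) * 10000L + 4200L, stringsAsFactors = FALSE)
  }
  elements <- mk_elements(contacts_sim$bins$start[contacts_sim$bins$element] / 10000 + 1)
  classification <- classify_element_contacts(elements, cmap)
  universe <- mk_elements(which(!contacts_sim$bins$promoter))
  sig_bins <- unique(c(cmap$contacts$bin1, cmap$contacts$bin2))
  prom_contact_bins <- sig_bins[vapply(sig_bins, function(b) {
    partners <- c(cmap$contacts$bin2[cmap$contacts$bin1 == b],
                  cmap$contacts$bin1[cmap$contacts$bin2 == b])
    any(lengths(cmap$bins$genes[match(partners, cmap$bins$bin_id)]) > 0)
  }, logical(1))]
  target <- cmap$bins[cmap$bins$bin_id %in% prom_contact_bins,
                      c("chrom", "start", "end")]
  contact_enrichment <- enrichment_2x2(elements, universe, target)

  ## 6. co-expression modules and hubs
  expr_sim <- simulate_expression(n_genes = 200, n_samples = 60,
                                  module_sizes = c(50, 50, 50),
                                  noise_sd = 0.3, seed = seeds[4])
  expr <- expr_sim$expression
  if (!is.null(dir)) {
    write_expression(expr, file.path(dir, "expression.tsv"))
    expr <- read_expression(file.path(dir, "expression.tsv"))
  }
  adj <- build_adjacency(expr)
  tom <- topological_overlap(adj)
  labels <- detect_modules(tom)
  summaries <- module_eigengene(expr, labels)
  hubs <- hub_genes(adj, summaries)
  genes_contacted <- contacted_genes(classification)
  mod_enrich <- module_geneset_enrichment(
    labels, intersect(genes_contacted, names(labels)))

  ## 7. consensus peaks from replicate peak sets
  true_peaks <- data.frame(chrom = "chr1",
                           start = seq(1000, by = 5000, length.out = 40),
                           end = seq(1000, by = 5000, length.out = 40) + 400)
  peak_sim <- simulate_peak_replicates(true_peaks, n_reps = 8,
                                       dropout = 0.2, seed = seeds[5])
  consensus <- consensus_peaks(peak_sim$replicates, min_reps = 4)

  ## 8. motif enrichment: homeotherm-vs-hibernator orthologue groups
  pwm <- demo_pwm()
  motif_sim <- simulate_motif_sequences(pwm, n_with = 100, n_without = 100,
                                        seq_len = 200, seed = seeds[6])
  motif_enrich <- group_motif_enrichment(motif_sim$with, motif_sim$without,
                                         list(pwm))
  chisq <- differential_motif_chisq(matrix(c(7, 1), 1,
                                           dimnames = list("demo_pairing", NULL)))

  list(seed = seed, tree = tree, layout = layout, truth = sim$truth,
       alignment = aln, crs = crs, scan = scan, ar = ar,
       deletions = del_calls,
       parallel = list(ar = parallel_ar, control = parallel_ctl,
                       del = parallel_del),
       bootstrap = boot,
       contacts = list(sim = contacts_sim, map = cmap,
                       classification = classification,
                       enrichment = contact_enrichment),
       coexpression = list(truth = expr_sim$truth, labels = labels,
                           summaries = summaries, hubs = hubs,
                           module_enrichment = mod_enrich),
       peaks = list(sim = peak_sim, consensus = consensus),
       motifs = list(sim = motif_sim, enrichment = motif_enrich,
                     chisq = chisq))
}

#' Score recovery of planted truth by the pipeline
#'
#' Reciprocal-overlap matching of called conserved regions against planted
#' non-neutral segments, plus per-class call recovery.
#'
#' @param result output of [run_demo_pipeline()].
#' @param min_reciprocal minimum reciprocal overlap fraction counting a
#'   planted segment as recovered (default 0.5).
#' @return list of summary numbers.
#' @export
score_demo_recovery <- function(result, min_reciprocal = 0.5) {
  truth <- result$truth
  crs <- result$crs
  planted <- truth[truth$class != "neutral", , drop = FALSE]
  rec <- vapply(seq_len(nrow(planted)), function(i) {
    ov <- pmin(planted$end[i], crs$end) - pmax(planted$start[i], crs$start)
    any(ov / pmax(planted$end[i] - planted$start[i], crs$length) >=
          min_reciprocal)
  }, logical(1))
  match_class <- function(cr_ids, class) {
    idx <- match(cr_ids, crs$id)
    vapply(idx, function(j) {
      ov <- pmin(truth$end, crs$end[j]) - pmax(truth$start, crs$start[j])
      cls <- truth$class[which.max(ov)]
      cls == class
    }, logical(1))
  }
  par_ar <- result$parallel$ar$cr_id
  par_del <- result$parallel$del$cr_id
  list(
    n_planted = nrow(planted),
    cr_recovery = mean(rec),
    n_crs = nrow(crs),
    n_parallel_ar = length(par_ar),
    parallel_ar_precision = if (length(par_ar))
      mean(match_class(par_ar, "accelerated")) else NA_real_,
    n_parallel_del = length(par_del),
    parallel_del_precision = if (length(par_del))
      mean(match_class(par_del, "deleted")) else NA_real_,
    bootstrap_p = result$bootstrap$p
  )
}
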