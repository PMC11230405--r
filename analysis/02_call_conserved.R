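#!/usr/bin/env Rscript

# Stage 2 - call conserved regions (CRs) from the simulated alignment with
# the two-state phylo-HMM. Conservation is assessed on the background
# homeotherm leaves only, so later foreground acceleration cannot mask the
# underlying constraint. A neutral-simulation FDR threshold for the CR
# scores is estimated alongside.

suppressPackageStartupMessages(library(convar))

seed <- as.integer(Sys.getenv("CONVAR_SEED", "1"))
data_dir <- "results/data"

tree <- parse_newick(paste(readLines(file.path(data_dir, "tree.nwk")),
                           collapse = ""))
model <- hky_model()
aln <- read_maf(file.path(data_dir, "alignment.maf"))[[1]]
lineages <- demo_lineages()

bg_tree <- ape::keep.tip(tree, lineages$background)
bg_aln <- aln
bg_aln$seqs <- bg_aln$seqs[lineages$background, , drop = FALSE]

params <- phylo_hmm_params(rho = 0.3, min_length = 20)
crs <- call_conserved_regions(bg_aln, bg_tree, model, params)
write_bed(crs[, c("chrom", "start", "end", "id", "score", "length")],
          "results/conserved_regions.bed")

fdr <- estimate_cr_fdr(crs$score, bg_tree, model, params,
                       n_null_bp = 50000, seed = seed,
                       observed_bp = ncol(aln$seqs))
cat("called", nrow(crs), "conserved regions;",
    "score threshold for 5% FDR:", round(fdr$threshold, 3),
    "(", sum(crs$score >= fdr$threshold), "pass )\n")

truth <- read_bed(file.path(data_dir, "truth_segments.bed"))
planted <- truth[truth$class != "neutral", ]
recovered <- vapply(seq_len(nrow(planted)), function(i) {
  ov <- pmin(planted$end[i], crs$end) - pmax(planted$start[i], crs$start)
  length(ov) && max(ov / pmax(planted$end[i] - planted$start[i],
                              crs$length)) >= 0.5
}, logical(1))
cat("planted-segment recovery at 50% reciprocal overlap:",
    round(mean(recovered), 3), "\n")
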