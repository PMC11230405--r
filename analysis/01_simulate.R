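#!/usr/bin/env Rscript

# Stage 1 - simulate every input of the comparative pipeline with planted
# truth: a 12-species alignment carrying conserved / accelerated / deleted
# segments, a binned chromatin-contact map with element->promoter
# enrichment, an expression matrix with three planted co-expression
# modules, replicate peak sets, two-species H3K27ac-style peak sets, and
# hibernator/homeotherm orthologue sequence groups for a motif panel.
# Everything downstream (02-07) consumes only the files written here.

suppressPackageStartupMessages(library(convar))

seed <- as.integer(Sys.getenv("CONVAR_SEED", "1"))
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seeds <- withr::with_seed(seed, sample.int(2^31 - 1, 20))

tree <- demo_tree()
model <- hky_model()
writeLines(write_newick(tree), file.path(out, "tree.nwk"))

## multi-species alignment with planted segment classes
layout <- demo_layout()
sim <- simulate_alignment(tree, model, layout, seed = seeds[1], ref = "bg_A")
write_maf(sim$alignment, file.path(out, "alignment.maf"))
write_bed(sim$truth, file.path(out, "truth_segments.bed"))
cat("alignment:", ncol(sim$alignment$seqs), "columns,",
    sum(sim$truth$class != "neutral"), "planted non-neutral segments\n")

## contact map: promoter bins, element bins, 3x planted enrichment
contacts <- simulate_contacts(n_bins = 120,
                              promoter_bins = seq(5, 120, by = 6),
                              element_bins = head(setdiff(seq(3, 80, by = 4),
                                                          seq(5, 120, by = 6)), 12),
                              enrichment_factor = 3, seed = seeds[2])
write_bedpe(contacts$bedpe, file.path(out, "contacts.bedpe"))
write_bed(contacts$bins, file.path(out, "contact_bins.bed"))
tss <- data.frame(gene = sprintf("g%04d", 1:60), chrom = "chr1",
                  strand = "+",
                  tss = (rep(seq(5, 120, by = 6), length.out = 60) - 1L) *
                    10000L + 5000L)
write.table(tss, file.path(out, "tss.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("contacts: true odds ratio", round(contacts$truth$true_or, 2), "\n")

## expression matrix with three planted modules and hub tiers
expr <- simulate_expression(n_genes = 200, n_samples = 60,
                            module_sizes = c(50, 50, 50), noise_sd = 0.3,
                            seed = seeds[3])
write_expression(expr$expression, file.path(out, "expression.tsv"))
write.table(expr$truth, file.path(out, "expression_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

## replicate accessibility peak sets (consensus rule input)
true_peaks <- data.frame(chrom = "chr1",
                         start = seq(1000, by = 5000, length.out = 40),
                         end = seq(1000, by = 5000, length.out = 40) + 400)
reps <- simulate_peak_replicates(true_peaks, n_reps = 8, dropout = 0.2,
                                 seed = seeds[4])
for (r in seq_along(reps$replicates)) {
  write_bed(reps$replicates[[r]], file.path(out, sprintf("atac_rep%02d.bed", r)))
}
write_bed(true_peaks, file.path(out, "atac_truth.bed"))

## two-species active-CRE peak sets over the alignment coordinates:
## "mouse" peaks cover the accelerated segments plus half of the plain
## conserved ones; "squirrel" peaks cover the conserved ones - so ARs fall
## preferentially in mouse-specific peaks (the loss-of-function signature)
truth <- sim$truth
acc <- truth[truth$class == "accelerated", ]
con <- truth[truth$class == "conserved", ]
pad <- function(d, w = 20) data.frame(chrom = d$chrom, start = pmax(0, d$start - w),
                                      end = d$end + w)
mouse_peaks <- pad(rbind(acc, con[seq(1, nrow(con), by = 2), ]))
squirrel_peaks <- pad(con)
write_bed(mouse_peaks, file.path(out, "h3k27ac_mouse.bed"))
write_bed(squirrel_peaks, file.path(out, "h3k27ac_squirrel.bed"))

## motif panel and orthologue sequence groups per clade pairing:
## motifs 1-4 planted in the homeotherm orthologues, 5-6 in neither
consensi <- c("TGACGTCA", "CACGTGTT", "GGGCGGGA", "TTTCACGC",
              "AGATAAGA", "CCAATCAG")
pwms <- lapply(seq_along(consensi), function(i) {
  bases <- strsplit(consensi[i], "")[[1]]
  counts <- matrix(1, 4, length(bases),
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(bases)) counts[bases[j], j] <- 597
  counts
})
names(pwms) <- sprintf("motif_%02d", seq_along(pwms))
write_jaspar(pwms, file.path(out, "motifs.jaspar"))
for (i in seq_along(pwms)) {
  pwm <- pwm_logodds(pwms[[i]], id = names(pwms)[i])
  msim <- simulate_motif_sequences(pwm, n_with = 120, n_without = 280,
                                   seq_len = 200, seed = seeds[5 + i])
  planted <- i <= 4
  homeo <- if (planted) c(msim$with, msim$without[1:80]) else
    msim$without[1:200]
  hib <- msim$without[81:280]
  write_fasta(homeo, file.path(out, sprintf("orthologs_homeo_%s.fa",
                                            names(pwms)[i])))
  write_fasta(hib, file.path(out, sprintf("orthologs_hib_%s.fa",
                                          names(pwms)[i])))
}
cat("wrote fixtures under ", out, "\n", sep = "")
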