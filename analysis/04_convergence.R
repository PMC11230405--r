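#!/usr/bin/env Rscript

# Stage 4 - collect parallel (convergent) events: CRs accelerated or
# deleted in two or more hibernator lineages (and, symmetrically, in the
# homeotherm controls), test the excess against the without-replacement
# bootstrap null, and summarise the CR-length distribution of the parallel
# elements.

suppressPackageStartupMessages(library(convar))

seed <- as.integer(Sys.getenv("CONVAR_SEED", "1"))
crs <- read_bed("results/conserved_regions.bed")
acc <- read.table("results/acceleration_tests.tsv", header = TRUE,
                  sep = "\t", stringsAsFactors = FALSE)
dels <- read.table("results/deletion_tests.tsv", header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
lineages <- demo_lineages()

ar_calls <- lapply(setNames(nm = unique(acc$lineage)), function(l) {
  d <- acc[acc$lineage == l & !is.na(acc$q) & acc$q <= 0.05, ]
  d$cr_id
})
del_calls <- lapply(setNames(nm = unique(dels$lineage)), function(l) {
  dels$cr_id[dels$lineage == l & dels$call]
})

groups <- list(foreground = lineages$foreground,
               control = lineages$control)
summary_rows <- list()
for (g in names(groups)) {
  for (kind in c("AR", "DEL")) {
    calls <- (if (kind == "AR") ar_calls else del_calls)[groups[[g]]]
    calls <- calls[!vapply(calls, is.null, logical(1))]
    pe <- find_parallel_elements(calls, crs$id, group = g)
    boot <- bootstrap_parallel_excess(calls, crs$id, B = 1000,
                                      seed = seed + match(g, names(groups)) * 10 +
                                        match(kind, c("AR", "DEL")))
    cat(sprintf("%-10s %-4s parallel elements: %3d  (null %.2f +/- %.2f, p = %.4g)\n",
                g, kind, nrow(pe), boot$null_mean, boot$null_sd, boot$p))
    if (nrow(pe)) {
      pe$kind <- kind
      summary_rows[[paste(g, kind)]] <- pe
    }
  }
}
parallel <- do.call(rbind, summary_rows)
write.table(parallel, "results/parallel_elements.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

hist <- size_distribution(parallel[parallel$group == "foreground", ], crs)
write.table(hist, "results/parallel_size_distribution.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("modal parallel-element CR length bin:",
    hist$bin_start[which.max(hist$count)], "-",
    hist$bin_end[which.max(hist$count)], "bp\n")
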