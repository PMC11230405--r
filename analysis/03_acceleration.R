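#!/usr/bin/env Rscript

# Stage 3 - test every CR for lineage-specific acceleration (likelihood-
# ratio test on the terminal branch, BH within lineage) and for
# lineage-specific deletion, in the four hibernator foregrounds and their
# four matched homeotherm controls.

suppressPackageStartupMessages(library(convar))

data_dir <- "results/data"
tree <- parse_newick(paste(readLines(file.path(data_dir, "tree.nwk")),
                           collapse = ""))
model <- hky_model()
aln <- read_maf(file.path(data_dir, "alignment.maf"))[[1]]
crs <- read_bed("results/conserved_regions.bed")
lineages <- demo_lineages()
tested <- c(lineages$foreground, lineages$control)

scan <- acceleration_scan(aln, crs, tree, model, tested)
ar <- call_accelerated_regions(scan, target_fdr = 0.05)
write.table(ar$results, "results/acceleration_tests.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

calls_tab <- data.frame(
  lineage = names(ar$calls),
  group = ifelse(names(ar$calls) %in% lineages$foreground,
                 "foreground", "control"),
  n_ar = lengths(ar$calls))
print(calls_tab, row.names = FALSE)

ar_rows <- do.call(rbind, lapply(names(ar$calls), function(l) {
  ids <- ar$calls[[l]]
  if (!length(ids)) return(NULL)
  cbind(crs[match(ids, crs$id), c("chrom", "start", "end", "id")],
        lineage = l)
}))
if (!is.null(ar_rows)) write_bed(ar_rows, "results/accelerated_regions.bed")

dels <- do.call(rbind, lapply(tested, function(l) {
  call_deletions(crs, aln, l)
}))
write.table(dels, "results/deletion_tests.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("deletion calls per lineage:\n")
print(table(dels$lineage[dels$call]))
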