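#!/usr/bin/env Rscript

# Stage 5 - regulatory integration: filter the contact map to significant
# contacts (count >= 12, obs/exp > 2, q <= 0.01), annotate promoter bins
# from the TSS table, classify planted elements into P-P / E-P / no-P
# contact classes, test element enrichment in promoter-contacting bins,
# build consensus peaks from the replicate accessibility sets, and run the
# cross-species loss-of-function comparison.

suppressPackageStartupMessages(library(convar))

data_dir <- "results/data"
cmap <- load_and_filter_contacts(file.path(data_dir, "contacts.bedpe"))
tss <- read.table(file.path(data_dir, "tss.tsv"), header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
cmap <- annotate_promoter_bins(cmap, tss)
print(cmap)

bins <- read_bed(file.path(data_dir, "contact_bins.bed"))
mk_elements <- function(sel) {
  data.frame(chrom = "chr1", start = bins$start[sel] + 4000L,
             end = bins$start[sel] + 4200L)
}
elements <- mk_elements(bins$element)
classes <- classify_element_contacts(elements, cmap)$classes
write.table(classes, "results/contact_classes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
tab <- table(classes$class)
cat("contact classes:", paste(names(tab), tab, collapse = ", "), "\n")

## enrichment of elements in significant-promoter-contact bins vs the
## non-promoter bin universe
sig_bins <- unique(c(cmap$contacts$bin1, cmap$contacts$bin2))
prom_contact <- vapply(sig_bins, function(b) {
  partners <- c(cmap$contacts$bin2[cmap$contacts$bin1 == b],
                cmap$contacts$bin1[cmap$contacts$bin2 == b])
  any(lengths(cmap$bins$genes[match(partners, cmap$bins$bin_id)]) > 0)
}, logical(1))
target <- cmap$bins[cmap$bins$bin_id %in% sig_bins[prom_contact],
                    c("chrom", "start", "end")]
universe <- mk_elements(!bins$promoter)
enr <- enrichment_2x2(elements, universe, target)
print(enr)

## consensus accessibility peaks: >= 4 of 8 replicates
reps <- lapply(sprintf("%s/atac_rep%02d.bed", data_dir, 1:8), read_bed)
consensus <- consensus_peaks(reps, min_reps = 4)
write_bed(consensus, "results/consensus_peaks.bed")
truth_peaks <- read_bed(file.path(data_dir, "atac_truth.bed"))
cat("consensus peaks:", nrow(consensus), "of", nrow(truth_peaks),
    "true peaks\n")

## cross-species peak partition and loss-of-function enrichment of the
## parallel accelerated regions against background CRs
mouse <- read_bed(file.path(data_dir, "h3k27ac_mouse.bed"))
squirrel <- read_bed(file.path(data_dir, "h3k27ac_squirrel.bed"))
partition <- classify_species_peaks(squirrel, mouse,
                                    species = c("squirrel", "mouse"))
cat("peak partition:", paste(names(table(partition$class)),
                             table(partition$class), collapse = ", "), "\n")

crs <- read_bed("results/conserved_regions.bed")
parallel <- read.table("results/parallel_elements.tsv", header = TRUE,
                       sep = "\t", stringsAsFactors = FALSE)
ars <- crs[crs$id %in% parallel$cr_id[parallel$kind == "AR" &
                                        parallel$group == "foreground"], ]
if (nrow(ars)) {
  lof <- lof_enrichment(ars[, c("chrom", "start", "end")],
                        crs[, c("chrom", "start", "end")], partition)
  rows <- do.call(rbind, lapply(names(lof), function(cl) {
    data.frame(class = cl, or = lof[[cl]]$or, p = lof[[cl]]$p,
               ci_lo = lof[[cl]]$ci[1], ci_hi = lof[[cl]]$ci[2])
  }))
  write.table(rows, "results/lof_enrichment.tsv", sep = "\t", quote = FALSE,
              row.names = FALSE)
  print(rows, row.names = FALSE)
} else {
  cat("no parallel ARs available for the loss-of-function comparison\n")
}
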