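#!/usr/bin/env Rscript

# Stage 7 - differential TFBS motif content between homeotherm and
# hibernator orthologue groups: per-motif hit enrichment (Fisher + BH over
# the panel) and the chi-square summary of enrichment-direction counts
# against an equal split.

suppressPackageStartupMessages(library(convar))

data_dir <- "results/data"
counts <- read_jaspar(file.path(data_dir, "motifs.jaspar"))
pwms <- lapply(names(counts), function(id) pwm_logodds(counts[[id]], id = id))
names(pwms) <- names(counts)

rows <- lapply(names(pwms), function(id) {
  homeo <- read_fasta(file.path(data_dir,
                                sprintf("orthologs_homeo_%s.fa", id)))
  hib <- read_fasta(file.path(data_dir, sprintf("orthologs_hib_%s.fa", id)))
  res <- group_motif_enrichment(homeo, hib, list(pwms[[id]]))
  res$motif <- id
  res
})
res <- do.call(rbind, rows)
res$q <- p.adjust(res$p, method = "BH")  # BH across the whole panel
res$enriched_in <- ifelse(res$q > 0.05, "none",
                          ifelse(res$or > 1, "homeotherm", "hibernator"))
write.table(res, "results/motif_enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(res[, c("motif", "n_query_hit", "n_background_hit", "or", "q",
              "enriched_in")], row.names = FALSE)

n_homeo <- sum(res$enriched_in == "homeotherm")
n_hib <- sum(res$enriched_in == "hibernator")
cat(sprintf("motifs enriched in homeotherm orthologues: %d; in hibernator: %d\n",
            n_homeo, n_hib))
if (n_homeo + n_hib > 0) {
  chi <- differential_motif_chisq(matrix(c(n_homeo, n_hib), 1,
                                         dimnames = list("clade_pairing", NULL)))
  print(chi, row.names = FALSE)
  write.table(chi, "results/motif_direction_chisq.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
}
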