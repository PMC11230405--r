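# Binned chromatin-contact maps (PLAC-seq-style input): fixed-width bins,
# significant pairwise contacts, promoter annotation, element classification.

intervals_to_gr <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

#' Build a binned contact map from filtered BEDPE contacts
#'
#' Retains only contacts passing all three significance thresholds of the
#' contact caller (read count, observed/expected ratio, FDR q-value), stores
#' each pair once in canonical order, and tiles the covered chromosomes with
#' fixed-width bins.
#'
#' @param bedpe contacts data.frame (see [read_bedpe()]) or a file path.
#' @param bin_width bin width in bp (default 10000). Anchor intervals must
#'   be aligned to it.
#' @param min_count minimum read count (default 12, inclusive).
#' @param min_oe minimum observed/expected ratio (default 2, exclusive).
#' @param max_q maximum q-value (default 0.01, inclusive).
#' @param chrom_sizes optional named vector of chromosome sizes in bp; by
#'   default bins extend to the furthest contact anchor.
#' @return object of class `contact_map`: `bins` (chrom, start, end, bin_id,
#'   genes), `contacts` (bin1, bin2 ids, count, obs_exp, qvalue),
#'   `bin_width`.
#' @export
load_and_filter_contacts <- function(bedpe, bin_width = 10000,
                                     min_count = 12, min_oe = 2,
                                     max_q = 0.01, chrom_sizes = NULL) {
  if (is.character(bedpe)) bedpe <- read_bedpe(bedpe)
  need <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
            "count", "obs_exp", "qvalue")
  bad <- setdiff(need, names(bedpe))
  if (length(bad)) stop("BEDPE missing columns: ", paste(bad, collapse = ", "))
  malformed <- which(!is.finite(bedpe$count) | !is.finite(bedpe$obs_exp) |
                       !is.finite(bedpe$qvalue) |
                       bedpe$start1 %% bin_width != 0 |
                       bedpe$start2 %% bin_width != 0)
  if (length(malformed)) stop("malformed BEDPE row at line ", malformed[1] + 1L)

  keep <- bedpe$count >= min_count & bedpe$obs_exp > min_oe &
    bedpe$qvalue <= max_q
  sig <- bedpe[keep, , drop = FALSE]

  bin_id <- function(chrom, start) paste0(chrom, ":", start)
  chroms <- sort(unique(c(bedpe$chrom1, bedpe$chrom2)))
  if (is.null(chrom_sizes)) {
    chrom_sizes <- vapply(chroms, function(ch) {
      max(c(bedpe$end1[bedpe$chrom1 == ch], bedpe$end2[bedpe$chrom2 == ch]))
    }, numeric(1))
  }
  bins <- do.call(rbind, lapply(chroms, function(ch) {
    starts <- seq(0L, chrom_sizes[[ch]] - 1L, by = bin_width)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + bin_width, chrom_sizes[[ch]]),
               stringsAsFactors = FALSE)
  }))
  bins$bin_id <- bin_id(bins$chrom, bins$start)
  bins$genes <- vector("list", nrow(bins))

  b1 <- bin_id(sig$chrom1, sig$start1)
  b2 <- bin_id(sig$chrom2, sig$start2)
  swap <- b2 < b1
  tmp <- b1[swap]; b1[swap] <- b2[swap]; b2[swap] <- tmp
  contacts <- data.frame(bin1 = b1, bin2 = b2, count = sig$count,
                         obs_exp = sig$obs_exp, qvalue = sig$qvalue,
                         stringsAsFactors = FALSE)
  contacts <- contacts[!duplicated(paste(contacts$bin1, contacts$bin2)), ,
                       drop = FALSE]
  rownames(contacts) <- NULL
  structure(list(bins = bins, contacts = contacts, bin_width = bin_width),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  n_prom <- sum(lengths(x$bins$genes) > 0)
  cat("<contact_map> ", nrow(x$bins), " bins (", x$bin_width, " bp), ",
      nrow(x$contacts), " significant contacts, ", n_prom,
      " promoter bins\n", sep = "")
  invisible(x)
}

#' Annotate promoter bins from a TSS table
#'
#' A bin lists gene `g` iff the promoter window `[TSS - halfwidth,
#' TSS + halfwidth)` intersects the bin; a window straddling a bin boundary
#' annotates both bins. Strand only determines which end of the gene is the
#' TSS (the `tss` column already encodes it).
#'
#' @param map a `contact_map`.
#' @param tss data.frame with columns gene, chrom, strand, tss (0-based
#'   position).
#' @param promoter_halfwidth half-width of the promoter window in bp
#'   (default 2000).
#' @return the map with `bins$genes` filled.
#' @export
annotate_promoter_bins <- function(map, tss, promoter_halfwidth = 2000) {
  stopifnot(inherits(map, "contact_map"),
            all(c("gene", "chrom", "tss") %in% names(tss)))
  prom <- data.frame(chrom = tss$chrom,
                     start = pmax(0L, tss$tss - promoter_halfwidth),
                     end = tss$tss + promoter_halfwidth)
  hits <- GenomicRanges::findOverlaps(intervals_to_gr(prom),
                                      intervals_to_gr(map$bins))
  genes <- vector("list", nrow(map$bins))
  for (k in seq_along(hits)) {
    b <- S4Vectors::subjectHits(hits)[k]
    genes[[b]] <- c(genes[[b]], tss$gene[S4Vectors::queryHits(hits)[k]])
  }
  map$bins$genes <- lapply(genes, function(g) sort(unique(g)))
  map
}

#' Classify elements by their promoter-contact context
#'
#' Elements are assigned to bins by any-overlap (an element spanning two
#' bins belongs to both; contacts are unioned). Classes: `P-P` when an
#' element bin contains a promoter and significantly contacts another
#' promoter bin; `E-P` when its bins lack promoters but significantly
#' contact at least one promoter bin; `no-P` otherwise, with a sub-flag
#' separating bins with no significant contacts at all from bins contacting
#' only non-promoter bins. The three classes partition the element set.
#'
#' @param elements data.frame with chrom, start, end and optionally id.
#' @param map an annotated `contact_map`.
#' @return list with `classes` (id, class, subclass, genes) and `excluded`
#'   (elements on unbinned contigs, flagged).
#' @export
classify_element_contacts <- function(elements, map) {
  stopifnot(inherits(map, "contact_map"))
  if (is.null(elements$id)) {
    elements$id <- sprintf("el_%05d", seq_len(nrow(elements)))
  }
  onmap <- elements$chrom %in% map$bins$chrom
  excluded <- elements[!onmap, , drop = FALSE]
  elements <- elements[onmap, , drop = FALSE]

  hits <- GenomicRanges::findOverlaps(intervals_to_gr(elements),
                                      intervals_to_gr(map$bins))
  el_bins <- split(map$bins$bin_id[S4Vectors::subjectHits(hits)],
                   elements$id[S4Vectors::queryHits(hits)])

  has_prom <- setNames(lengths(map$bins$genes) > 0, map$bins$bin_id)
  genes_of <- setNames(map$bins$genes, map$bins$bin_id)
  partners <- c(split(map$contacts$bin2, map$contacts$bin1),
                split(map$contacts$bin1, map$contacts$bin2))
  partners <- tapply(unlist(partners, use.names = FALSE),
                     rep(names(partners), lengths(partners)),
                     unique, simplify = FALSE)

  out <- lapply(elements$id, function(id) {
    bins <- el_bins[[id]]
    if (is.null(bins)) bins <- character()
    pp <- FALSE; ep <- FALSE; any_contact <- FALSE
    genes <- character()
    for (b in bins) {
      pb <- partners[[b]]
      if (is.null(pb)) pb <- character()
      if (length(pb)) any_contact <- TRUE
      prom_partners <- pb[has_prom[pb]]
      if (length(prom_partners)) {
        if (has_prom[[b]]) pp <- TRUE else ep <- TRUE
        genes <- c(genes, unlist(genes_of[prom_partners], use.names = FALSE))
      }
    }
    class <- if (pp) "P-P" else if (ep) "E-P" else "no-P"
    subclass <- if (class != "no-P") class
      else if (any_contact) "no-P:nonpromoter-contacts" else "no-P:no-contacts"
    data.frame(id = id, class = class, subclass = subclass,
               genes = paste(sort(unique(genes)), collapse = ","),
               stringsAsFactors = FALSE)
  })
  classes <- if (length(out)) do.call(rbind, out) else
    data.frame(id = character(), class = character(),
               subclass = character(), genes = character(),
               stringsAsFactors = FALSE)
  rownames(classes) <- NULL
  list(classes = classes, excluded = excluded)
}

#' Genes contacted by a set of elements
#'
#' Convenience accessor: union of contacted promoter genes over an element
#' classification (P-P and E-P elements contribute their gene sets).
#'
#' @param classification result of [classify_element_contacts()].
#' @return sorted character vector of gene ids.
#' @export
contacted_genes <- function(classification) {
  g <- unlist(strsplit(classification$classes$genes, ","), use.names = FALSE)
  sort(unique(g[nzchar(g)]))
}
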