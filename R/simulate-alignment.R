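#' Genome layout for alignment simulation
#'
#' A layout is an ordered set of segments, each neutral, conserved,
#' accelerated or deleted. Conserved segments evolve at branch scale
#' `rho` on every branch; accelerated segments additionally scale the named
#' foreground terminal branches by `r`; deleted segments are conserved in the
#' background but emit gap characters for the named lineages.
#'
#' @param length segment length in bp, >= 1.
#' @param class one of `"neutral"`, `"conserved"`, `"accelerated"`,
#'   `"deleted"`.
#' @param rho conserved branch scale in (0, 1]; required for non-neutral
#'   classes.
#' @param r foreground rate multiplier >= 1 (accelerated segments).
#' @param lineages character vector of leaf names: the accelerated foreground
#'   lineages, or the deleted lineages.
#' @return one-row data.frame; combine rows with [genome_layout()].
#' @export
layout_segment <- function(length, class = c("neutral", "conserved",
                                             "accelerated", "deleted"),
                           rho = NA_real_, r = NA_real_,
                           lineages = character()) {
  class <- match.arg(class)
  stopifnot(length >= 1)
  if (class != "neutral") {
    if (!is.finite(rho) || rho <= 0 || rho > 1) {
      stop("non-neutral segments need a conserved scale rho in (0, 1]")
    }
  }
  if (class == "accelerated") {
    if (!is.finite(r) || r < 1) stop("acceleration multiplier r must be >= 1")
    if (!length(lineages)) stop("accelerated segments need foreground lineages")
  }
  if (class == "deleted" && !length(lineages)) {
    stop("deleted segments need deleted lineages")
  }
  data.frame(length = as.integer(length), class = class, rho = rho, r = r,
             lineages = paste(lineages, collapse = ","),
             stringsAsFactors = FALSE)
}

#' @rdname layout_segment
#' @param ... one-row segment data.frames from [layout_segment()].
#' @export
genome_layout <- function(...) {
  out <- do.call(rbind, list(...))
  rownames(out) <- NULL
  out
}

#' Simulate a multi-species alignment with planted truth
#'
#' Neutral segments evolve at branch scale 1, conserved at `rho` on all
#' branches, accelerated at `rho` on background branches and `rho * r` on each
#' named foreground terminal branch. Deleted segments are simulated as
#' conserved, then the deleted lineages' rows are replaced by gaps. The
#' reference row is gapless, so reference coordinates equal cumulative
#' segment positions.
#'
#' @param tree an `ape::phylo` tree.
#' @param model a [hky_model()].
#' @param layout a [genome_layout()].
#' @param seed integer seed.
#' @param ref reference species (a leaf; must not appear in any deleted
#'   lineage set). Defaults to the first leaf.
#' @param chrom reference chromosome name used in coordinates.
#' @return list with `alignment` (a [cg_alignment()]) and `truth`
#'   (BED-with-extra-columns data.frame: chrom, start, end, class, rho, r,
#'   lineages; 0-based half-open, sorted, non-overlapping).
#' @export
simulate_alignment <- function(tree, model, layout, seed,
                               ref = NULL, chrom = "chr1") {
  tree <- ape::reorder.phylo(tree, "postorder")
  tips <- tree$tip.label
  if (is.null(ref)) ref <- tips[1]
  stopifnot(ref %in% tips)
  all_lin <- unlist(strsplit(layout$lineages[nzchar(layout$lineages)], ","))
  bad <- setdiff(all_lin, tips)
  if (length(bad)) stop("layout lineage is not a leaf: ", paste(bad, collapse = ", "))
  if (ref %in% unlist(strsplit(layout$lineages[layout$class == "deleted"], ","))) {
    stop("the reference species cannot carry a planted deletion")
  }

  seg_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max,
                                                 nrow(layout)))
  pieces <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    seg <- layout[i, ]
    lin <- strsplit(seg$lineages, ",")[[1]]
    scales <- switch(seg$class,
      neutral = branch_scales(tree, 1),
      conserved = branch_scales(tree, seg$rho),
      deleted = branch_scales(tree, seg$rho),
      accelerated = branch_scales(tree, seg$rho,
                                  terminal = setNames(rep(seg$r, length(lin)), lin))
    )
    cols <- simulate_columns(tree, model, seg$length, scales, seed = seg_seeds[i])
    chars <- decode_bases(cols)
    if (seg$class == "deleted") chars[lin, ] <- "-"
    pieces[[i]] <- chars
  }
  seqs <- do.call(cbind, pieces)
  ends <- cumsum(layout$length)
  truth <- data.frame(chrom = chrom, start = c(0L, ends[-length(ends)]),
                      end = ends, class = layout$class, rho = layout$rho,
                      r = layout$r, lineages = layout$lineages,
                      stringsAsFactors = FALSE)
  list(alignment = cg_alignment(seqs, ref = ref, ref_chrom = chrom),
       truth = truth)
}

#' Demonstration tree: 12 leaves in 4 clades
#'
#' Each clade pairs one hibernator foreground leaf (`hib_*`) with its closest
#' control homeotherm (`ctl_*`) plus one background homeotherm (`bg_*`),
#' mirroring the paired hibernator/control design of the comparative
#' analysis. Branch lengths are neutral substitutions/site at a mammal-like
#' scale. Shipped as `inst/extdata/demo_tree.nwk`.
#'
#' @return an `ape::phylo` tree.
#' @export
demo_tree <- function() {
  parse_newick(paste(readLines(system.file("extdata", "demo_tree.nwk",
                                           package = "convar")),
                     collapse = ""))
}

#' Lineage configuration for the demonstration tree
#'
#' @return list with `foreground` (hibernators), `control` (matched
#'   homeotherms) and `background` leaves.
#' @export
demo_lineages <- function() {
  cl <- c("A", "B", "C", "D")
  list(foreground = paste0("hib_", cl),
       control = paste0("ctl_", cl),
       background = paste0("bg_", cl))
}
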