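#' Multiple-alignment block anchored on a reference species
#'
#' In-memory container for one alignment block: a character matrix (rows =
#' species, columns = alignment columns, values A/C/G/T/-) plus the reference
#' anchoring (species name, chromosome, 0-based start on the reference).
#' The reference row may contain gaps; columns where it does carry no
#' reference coordinate.
#'
#' @param seqs character matrix with species rownames.
#' @param ref reference species name (must be a rowname).
#' @param ref_chrom reference chromosome/contig name.
#' @param ref_start 0-based start of the block on the reference.
#' @return an object of class `cg_alignment`.
#' @export
cg_alignment <- function(seqs, ref, ref_chrom = "chr1", ref_start = 0L) {
  stopifnot(is.matrix(seqs), !is.null(rownames(seqs)), ref %in% rownames(seqs))
  structure(list(seqs = seqs, ref = ref, ref_chrom = ref_chrom,
                 ref_start = as.integer(ref_start)),
            class = "cg_alignment")
}

#' @export
print.cg_alignment <- function(x, ...) {
  cat("<cg_alignment> ", nrow(x$seqs), " species x ", ncol(x$seqs),
      " columns; ref ", x$ref, " (", x$ref_chrom, ":", x$ref_start, ")\n",
      sep = "")
  invisible(x)
}

#' Reference coordinate of each alignment column
#'
#' @param aln a [cg_alignment()].
#' @return integer vector: 0-based reference position per column, `NA` where
#'   the reference row is gapped.
#' @export
ref_coords <- function(aln) {
  refrow <- aln$seqs[aln$ref, ]
  isbase <- refrow != "-"
  pos <- rep(NA_integer_, length(refrow))
  pos[isbase] <- aln$ref_start + seq_len(sum(isbase)) - 1L
  pos
}

#' Write alignment blocks to a MAF file
#'
#' Standard MAF: an `a` line per block, `s` lines with src, 0-based start,
#' size (non-gap bases), strand, srcSize and the alignment text.
#'
#' @param blocks a [cg_alignment()] or list of them.
#' @param path output file.
#' @param src_sizes optional named vector of source sequence sizes; defaults
#'   to each row's non-gap length plus its start.
#' @export
write_maf <- function(blocks, path, src_sizes = NULL) {
  if (inherits(blocks, "cg_alignment")) blocks <- list(blocks)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (aln in blocks) {
    writeLines("a score=0.0", con)
    sp <- rownames(aln$seqs)
    sp <- c(aln$ref, setdiff(sp, aln$ref))  # reference row leads the block
    for (s in sp) {
      txt <- paste(aln$seqs[s, ], collapse = "")
      size <- sum(aln$seqs[s, ] != "-")
      start <- if (s == aln$ref) aln$ref_start else 0L
      src <- if (s == aln$ref) paste0(s, ".", aln$ref_chrom) else paste0(s, ".scaf1")
      ssz <- if (!is.null(src_sizes) && s %in% names(src_sizes)) {
        src_sizes[[s]]
      } else {
        start + size
      }
      writeLines(sprintf("s %s %d %d + %d %s", src, start, size, ssz, txt), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Read a MAF file
#'
#' Parses `a`/`s` lines of the plain MAF dialect. The first `s` row of each
#' block is taken as the reference. If the reference row is on the `-`
#' strand, the whole block is reverse-complemented onto the forward strand
#' of the reference (starts remapped through srcSize); other rows keep their
#' printed, already-aligned text.
#'
#' @param path MAF file.
#' @return list of [cg_alignment()] blocks.
#' @export
read_maf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  blocks <- list()
  cur <- NULL
  flush_block <- function(cur) {
    if (is.null(cur) || !length(cur$species)) return(NULL)
    widths <- nchar(cur$text)
    if (length(unique(widths)) != 1) {
      stop("MAF block with unequal row widths at species ",
           cur$species[1])
    }
    seqs <- do.call(rbind, strsplit(toupper(cur$text), ""))
    rownames(seqs) <- cur$species
    ref_start <- cur$start[1]
    if (cur$strand[1] == "-") {
      seqs <- t(apply(seqs, 1, revcomp_chars))
      ref_start <- cur$srcSize[1] - cur$start[1] - cur$size[1]
    }
    cg_alignment(seqs, ref = cur$species[1], ref_chrom = cur$chrom[1],
                 ref_start = ref_start)
  }
  for (ln in lines) {
    if (grepl("^a", ln)) {
      b <- flush_block(cur)
      if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
      cur <- list(species = character(), chrom = character(),
                  start = integer(), size = integer(),
                  strand = character(), srcSize = integer(),
                  text = character())
    } else if (grepl("^s\\s", ln)) {
      if (is.null(cur)) stop("MAF 's' line before any 'a' line")
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(f) != 7) stop("malformed MAF 's' line: ", ln)
      src <- strsplit(f[2], ".", fixed = TRUE)[[1]]
      cur$species <- c(cur$species, src[1])
      cur$chrom <- c(cur$chrom, if (length(src) > 1) paste(src[-1], collapse = ".") else "chr1")
      cur$start <- c(cur$start, as.integer(f[3]))
      cur$size <- c(cur$size, as.integer(f[4]))
      cur$strand <- c(cur$strand, f[5])
      cur$srcSize <- c(cur$srcSize, as.integer(f[6]))
      cur$text <- c(cur$text, f[7])
    }
  }
  b <- flush_block(cur)
  if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
  blocks
}
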