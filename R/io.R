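# Plain-text tabular I/O for the pipeline's interchange formats. All BED-style
# tables are 0-based half-open and may carry extra named columns, so they are
# written as headerless TSV in column order with a fixed schema per format.

#' Write/read BED-with-extra-columns tables
#'
#' @param x data.frame whose first three columns are chrom, start, end.
#' @param path file path.
#' @export
write_bed <- function(x, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write/read BEDPE contact tables
#'
#' Schema: chrom1, start1, end1, chrom2, start2, end2, count, obs_exp, qvalue.
#' @param x contacts data.frame.
#' @param path file path.
#' @export
write_bedpe <- function(x, path) {
  need <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
            "count", "obs_exp", "qvalue")
  stopifnot(all(need %in% names(x)))
  write.table(x[, need], path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' @rdname write_bedpe
#' @export
read_bedpe <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
            "count", "obs_exp", "qvalue")
  bad <- setdiff(need, names(x))
  if (length(bad)) stop("BEDPE missing columns: ", paste(bad, collapse = ", "))
  x
}

#' Write/read a genes x samples expression matrix as TSV
#' @param mat numeric matrix with gene rownames and sample colnames.
#' @param path file path.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}

#' Write/read FASTA via Biostrings
#' @param seqs named character vector of DNA sequences.
#' @param path file path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Read a JASPAR-style count-matrix file
#'
#' Plain JASPAR format: a `>id name` header line followed by four rows
#' `A [ 1 2 ... ]` etc. Several motifs per file are allowed.
#'
#' @param path file path.
#' @return named list of 4 x width count matrices (rows A, C, G, T).
#' @export
read_jaspar <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no JASPAR records in ", path)
  out <- list()
  for (h in seq_along(heads)) {
    i <- heads[h]
    id <- strsplit(sub("^>", "", lines[i]), "\\s+")[[1]][1]
    rows <- lines[(i + 1):(i + 4)]
    m <- t(vapply(rows, function(r) {
      nums <- gsub("[][A-Za-z]", " ", r)
      as.numeric(strsplit(trimws(nums), "\\s+")[[1]])
    }, FUN.VALUE = numeric(length(strsplit(trimws(gsub("[][A-Za-z]", " ", rows[1])), "\\s+")[[1]]))))
    rownames(m) <- DNA_BASES4
    out[[id]] <- m
  }
  out
}

#' Write motifs in JASPAR count-matrix format
#' @param pwms named list of 4 x width count matrices.
#' @param path file path.
#' @export
write_jaspar <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(pwms)) {
    writeLines(paste0(">", id), con)
    m <- pwms[[id]]
    for (b in DNA_BASES4) {
      writeLines(paste0(b, " [ ", paste(m[b, ], collapse = " "), " ]"), con)
    }
  }
  invisible(path)
}
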