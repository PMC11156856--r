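#' Read and write FASTA and aligned FASTA
#'
#' Thin wrappers over Biostrings. `read_msa_fasta` additionally checks that
#' all rows have equal length and returns a plain named character vector,
#' the MSA representation the rest of the package uses.
#'
#' @param path file path.
#' @return `read_fasta`/`read_msa_fasta`: named character vector of
#'   sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' @rdname read_fasta
#' @export
read_msa_fasta <- function(path) {
  x <- read_fasta(path)
  if (length(unique(nchar(x))) != 1)
    stop("not an alignment: rows have unequal lengths")
  x
}

#' @rdname read_fasta
#' @param seqs named character vector of (possibly gapped) sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Read and write BED intervals
#'
#' On disk BED is 0-based half-open; in memory the package uses 1-based
#' inclusive `start`/`end` columns, and these functions convert.
#'
#' @param path file path.
#' @return Data frame with `chrom`, `start`, `end` (1-based inclusive) and
#'   `name` when present.
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  df$start <- df$start + 1L        # to 1-based inclusive
  df
}

#' @rdname read_bed
#' @param intervals data frame with `chrom`, `start`, `end` (1-based
#'   inclusive) and optional further columns.
#' @export
write_bed <- function(intervals, path) {
  out <- intervals
  out$start <- out$start - 1L      # to 0-based half-open
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write bedGraph per-bp signal
#'
#' @param path file path.
#' @param length track length; runs beyond it are an error.
#' @return `read_bedgraph`: numeric per-bp vector (positions with no record
#'   are 0).
#' @export
read_bedgraph <- function(path, length) {
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "value")
  if (any(df$end > length)) stop("bedGraph runs beyond the stated length")
  out <- numeric(length)
  for (i in seq_len(nrow(df)))
    out[(df$start[i] + 1L):df$end[i]] <- df$value[i]
  out
}

#' @rdname read_bedgraph
#' @param values numeric per-bp vector.
#' @param chrom chromosome / sequence name written in column 1.
#' @export
write_bedgraph <- function(values, path, chrom = "consensus") {
  r <- rle(values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths      # already 0-based half-open starts
  keep <- r$values != 0
  write.table(data.frame(chrom, starts[keep], ends[keep], r$values[keep]),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write sparse cell-by-gene matrices (MatrixMarket)
#'
#' @param mtx,cells,genes paths to the MTX file and the row (cell) and
#'   column (gene) label files (one label per line).
#' @return `read_cell_matrix`: a dgCMatrix with dimnames.
#' @export
read_cell_matrix <- function(mtx, cells, genes) {
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  dimnames(m) <- list(readLines(cells), readLines(genes))
  m
}

#' @rdname read_cell_matrix
#' @param m matrix (cells x genes).
#' @export
write_cell_matrix <- function(m, mtx, cells, genes) {
  Matrix::writeMM(methods::as(Matrix::Matrix(m * 1, sparse = TRUE),
                              "generalMatrix"), mtx)
  writeLines(rownames(m), cells)
  writeLines(colnames(m), genes)
  invisible(mtx)
}

#' Read and write contact matrices as upper-triangle triplets
#'
#' The text format standard Hi-C dump utilities produce: tab-separated
#' `bin_i`, `bin_j`, `count` with `i <= j` (1-based bins here).
#'
#' @param path file path.
#' @param n_bins matrix dimension.
#' @return `read_contacts`: symmetric numeric matrix.
#' @export
read_contacts <- function(path, n_bins) {
  df <- read.table(path, sep = "\t")
  m <- matrix(0, n_bins, n_bins)
  m[cbind(df[[1]], df[[2]])] <- df[[3]]
  m[cbind(df[[2]], df[[1]])] <- df[[3]]
  m
}

#' @rdname read_contacts
#' @param m symmetric matrix (or `contact_matrix`).
#' @export
write_contacts <- function(m, path) {
  if (inherits(m, "contact_matrix")) m <- m$counts
  ut <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
  write.table(data.frame(ut[, 1], ut[, 2], m[ut]), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
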