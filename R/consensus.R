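#' Build a majority-rule consensus from a multiple alignment
#'
#' Per alignment column, character frequencies are computed over all rows,
#' with gap characters counted in the denominator. If the modal character
#' reaches `threshold` the consensus takes that character, otherwise `N`.
#' Columns whose consensus character is the gap are dropped; `kept_columns`
#' records the surviving original column indices. Ties: a non-gap character
#' beats the gap; a tie between two bases yields `N`.
#'
#' @param msa named character vector of equal-length gapped sequences over
#'   `{A,C,G,T,N,-}` (or a `Biostrings::DNAMultipleAlignment`).
#' @param threshold modal-frequency threshold (default 0.5).
#' @return Object of class `"consensus"`: list with `sequence` (character,
#'   may contain `N`) and `kept_columns` (strictly increasing integer
#'   vector of original MSA columns).
#' @export
build_consensus <- function(msa, threshold = 0.5) {
  m <- as_msa_matrix(msa)
  if (nrow(m) == 0 || ncol(m) == 0) stop("empty MSA")
  cons <- apply(m, 2, function(col) {
    tab <- table(col)
    freq <- as.vector(tab) / length(col)
    top <- which(freq == max(freq))
    ch <- names(tab)[top]
    if (length(ch) > 1) {            # tie among modal characters
      ch <- setdiff(ch, "-")         # prefer a non-gap over the gap
      if (length(ch) != 1) ch <- "N" # tie between bases
    }
    if (max(freq) >= threshold) ch else "N"
  })
  keep <- which(cons != "-")
  structure(list(sequence = paste(cons[keep], collapse = ""),
                 kept_columns = keep),
            class = "consensus")
}

#' @export
print.consensus <- function(x, ...) {
  cat("Consensus of", length(x$kept_columns), "columns:",
      substr(x$sequence, 1, 60),
      if (nchar(x$sequence) > 60) "..." else "", "\n")
  invisible(x)
}

# Accept a named character vector of gapped rows or a DNAMultipleAlignment;
# return a rows x columns character matrix.
as_msa_matrix <- function(msa) {
  if (methods::is(msa, "DNAMultipleAlignment") ||
      methods::is(msa, "DNAStringSet"))
    msa <- as.character(msa)
  stopifnot(is.character(msa))
  if (length(msa) == 0) stop("empty MSA")
  if (length(unique(nchar(msa))) != 1)
    stop("MSA rows must have equal length")
  if (!is.null(names(msa)) && anyDuplicated(names(msa)))
    stop("MSA row names must be unique")
  m <- do.call(rbind, strsplit(toupper(msa), ""))
  rownames(m) <- names(msa)
  m
}

#' Per-paralog base-to-consensus coordinate maps
#'
#' For every row of the MSA, maps each ungapped base position to the
#' consensus position of its alignment column (or `NA` when the column was
#' dropped from the consensus). Maps are strictly increasing on their mapped
#' domain (collinearity).
#'
#' @param msa the alignment the consensus was built from.
#' @param consensus a [build_consensus()] result for `msa`.
#' @return Object of class `"coordinate_map"`: named list of integer vectors
#'   (one per MSA row), `NA` marking unmapped bases; attribute
#'   `"consensus_length"`.
#' @export
build_coordinate_map <- function(msa, consensus) {
  m <- as_msa_matrix(msa)
  if (max(consensus$kept_columns) > ncol(m))
    stop("consensus does not match this MSA")
  col_to_cons <- rep(NA_integer_, ncol(m))
  col_to_cons[consensus$kept_columns] <- seq_along(consensus$kept_columns)
  maps <- lapply(seq_len(nrow(m)), function(i) {
    ungapped_cols <- which(m[i, ] != "-")
    col_to_cons[ungapped_cols]
  })
  names(maps) <- rownames(m)
  structure(maps, class = "coordinate_map",
            consensus_length = length(consensus$kept_columns))
}

#' Project a per-bp signal track onto consensus coordinates
#'
#' Each mapped paralog base carries its value to its consensus position;
#' consensus positions with no mapped base get 0; signal on unmapped bases
#' is dropped. The output total equals the input total over mapped
#' positions.
#'
#' @param track numeric vector over the paralog's ungapped positions.
#' @param map one element of a [build_coordinate_map()] (integer vector with
#'   `NA` for unmapped bases), or a `coordinate_map` plus `paralog=`.
#' @param paralog row name, required when `map` is a full `coordinate_map`.
#' @return Numeric vector over consensus positions.
#' @export
project_signal <- function(track, map, paralog = NULL) {
  cons_len <- attr(map, "consensus_length")
  if (inherits(map, "coordinate_map")) {
    if (is.null(paralog)) stop("paralog must be named for a coordinate_map")
    map <- map[[paralog]]
  }
  if (is.null(cons_len)) cons_len <- max(map, na.rm = TRUE)
  if (length(track) != length(map))
    stop("track length (", length(track), ") does not match paralog length (",
         length(map), ")")
  out <- numeric(cons_len)
  ok <- !is.na(map)
  if (!any(ok)) {
    warning("no paralog base maps to the consensus; returning zeros")
    return(out)
  }
  out[map[ok]] <- track[ok]
  out
}

#' Uniform noise floor for pileup tracks
#'
#' The per-bp coverage a sequencing library would spread uniformly over a
#' genome: `2 * read_pairs * read_length / genome_length`. A 30 million
#' pair, 75 bp library on a 3 Gb genome gives 1.5x per bp, the default
#' uniform noise added to pileup views so sparsely covered tracks do not
#' dominate after normalization.
#'
#' @param read_pairs number of read pairs (`>= 0`).
#' @param read_length read length in bp (`>= 0`).
#' @param genome_length genome size in bp (`> 0`).
#' @return Per-bp coverage (numeric scalar).
#' @examples
#' noise_floor(3e7, 75, 3e9)  # 1.5
#' @export
noise_floor <- function(read_pairs, read_length, genome_length) {
  if (genome_length <= 0) stop("genome_length must be > 0")
  if (read_pairs < 0 || read_length < 0)
    stop("read_pairs and read_length must be >= 0")
  2 * read_pairs * read_length / genome_length
}

#' Normalize projected tracks to a common sum and stack them
#'
#' Each track is scaled so that its sum over the region equals `target_sum`
#' (all tracks become directly comparable), then a uniform per-bp noise is
#' added. A track whose raw sum is zero becomes pure noise.
#'
#' @param tracks list (or matrix rows) of equal-length non-negative numeric
#'   vectors on consensus coordinates.
#' @param target_sum common sum after scaling (default 1e4).
#' @param noise_per_bp uniform noise added at every position (default
#'   `noise_floor(3e7, 75, 3e9)` = 1.5).
#' @return Numeric matrix, one row per track.
#' @export
normalize_and_stack <- function(tracks, target_sum = 1e4,
                                noise_per_bp = noise_floor(3e7, 75, 3e9)) {
  if (is.matrix(tracks)) tracks <- asplit(tracks, 1)
  if (target_sum <= 0) stop("target_sum must be > 0")
  lens <- lengths(tracks)
  if (length(unique(lens)) != 1) stop("all tracks must have equal length")
  out <- t(vapply(tracks, function(tr) {
    if (any(tr < 0)) stop("negative values in input track")
    s <- sum(tr)
    scaled <- if (s > 0) tr * (target_sum / s) else numeric(length(tr))
    scaled + noise_per_bp
  }, numeric(lens[1])))
  rownames(out) <- names(tracks)
  out
}
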