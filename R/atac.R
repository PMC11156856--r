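#' Extend Tn5 insertion events into pseudo reads
#'
#' Each insertion event is extended `half_width` bp up- and downstream,
#' yielding a `2 * half_width` bp interval (150 bp at the default 75)
#' centered on the insertion site. Intervals are 0-based half-open and are
#' clipped at chromosome bounds with a warning.
#'
#' @param positions integer vector of insertion positions (0-based bp), or a
#'   data frame with a `position` column.
#' @param half_width extension in bp on each side (`> 0`; default 75).
#' @param chrom_length optional chromosome length for right clipping.
#' @return Data frame with `start`, `end` (0-based half-open).
#' @export
pseudo_reads <- function(positions, half_width = 75L, chrom_length = NULL) {
  if (half_width <= 0) stop("half_width must be > 0")
  if (is.data.frame(positions)) positions <- positions$position
  start <- positions - half_width
  end <- positions + half_width
  clipped <- start < 0
  if (!is.null(chrom_length)) clipped <- clipped | end > chrom_length
  if (any(clipped)) {
    warning(sum(clipped), " pseudo read(s) clipped at chromosome bounds")
    start <- pmax(start, 0)
    if (!is.null(chrom_length)) end <- pmin(end, chrom_length)
  }
  data.frame(start = start, end = end)
}

#' Pile up pseudo reads and normalize for sequencing depth
#'
#' Computes the per-bp coverage of pseudo reads over a region and scales it
#' by `scale / total_events_in_library`, so libraries sequenced to different
#' depths give comparable tracks.
#'
#' @param reads data frame with `start`, `end` (0-based half-open).
#' @param region length-2 vector `c(start, end)` (0-based half-open).
#' @param total_events total insertion events in the library (`> 0`).
#' @param scale depth-normalization constant (default 1e7).
#' @return Numeric vector of normalized coverage over `region`.
#' @export
pileup_and_depth_normalize <- function(reads, region, total_events,
                                       scale = 1e7) {
  if (total_events <= 0) stop("total_events must be > 0")
  if (length(region) != 2 || region[2] <= region[1])
    stop("region must be c(start, end) with end > start")
  L <- region[2] - region[1]
  delta <- numeric(L + 1L)
  s <- pmax(reads$start, region[1]) - region[1]
  e <- pmin(reads$end, region[2]) - region[1]
  ok <- e > s
  for (i in which(ok)) {
    delta[s[i] + 1L] <- delta[s[i] + 1L] + 1
    delta[e[i] + 1L] <- delta[e[i] + 1L] - 1
  }
  cumsum(delta)[seq_len(L)] * (scale / total_events)
}

#' Count pseudo reads overlapping each element across samples
#'
#' Entry `(element, sample)` is the number of pseudo reads in that sample
#' with at least 1 bp overlap with the element interval (half-open
#' arithmetic: touching intervals do not overlap). Elements must not
#' overlap each other, so attribution is unambiguous.
#'
#' @param reads_by_sample named list of pseudo-read data frames
#'   (`start`, `end`).
#' @param maps data frame of element intervals: `name`, `start`, `end`
#'   (0-based half-open).
#' @return Integer matrix, elements x samples.
#' @export
count_map_matrix <- function(reads_by_sample, maps) {
  o <- order(maps$start)
  if (any(maps$end[o][-nrow(maps)] > maps$start[o][-1]))
    stop("element intervals overlap; attribution would be ambiguous")
  counts <- vapply(reads_by_sample, function(rd) {
    vapply(seq_len(nrow(maps)), function(k) {
      sum(rd$start < maps$end[k] & rd$end > maps$start[k])
    }, integer(1))
  }, integer(nrow(maps)))
  counts <- matrix(counts, nrow = nrow(maps),
                   dimnames = list(maps$name, names(reads_by_sample)))
  counts
}

#' Normalize an element-by-sample count matrix to a median reference
#'
#' Scales each sample's column so its total equals the raw total of the
#' reference sample -- the sample whose raw total is the median across
#' samples (lower median for an even count), so the normalization target is
#' always one of the actual samples.
#'
#' @param m numeric matrix, elements x samples.
#' @return List with `matrix` (normalized), `reference` (sample name) and
#'   `factors` (per-sample scale factors).
#' @export
normalize_map_matrix <- function(m) {
  totals <- colSums(m)
  if (any(totals == 0))
    stop("sample(s) with zero total signal: ",
         paste(colnames(m)[totals == 0], collapse = ", "))
  o <- order(totals)
  ref_idx <- o[floor((length(totals) + 1) / 2)]   # lower median
  factors <- totals[ref_idx] / totals
  list(matrix = sweep(m, 2, factors, "*"),
       reference = colnames(m)[ref_idx],
       factors = factors)
}
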