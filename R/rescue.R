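#' Normalized alignment score
#'
#' Raw alignment score divided by read length. Under end-to-end scoring the
#' highest possible raw score is 0 (perfect match); mismatches and indels
#' make it negative, so the normalized score lies in `(-Inf, 0]` and is
#' comparable across read lengths.
#'
#' @param score raw alignment score (`<= 0`).
#' @param read_length read length in bp (`> 0`).
#' @return Numeric vector of normalized scores.
#' @examples
#' normalized_score(-15, 75)  # -0.2
#' @export
normalized_score <- function(score, read_length) {
  if (any(read_length <= 0)) stop("read_length must be > 0")
  score / read_length
}

# exact cutoff comparison: score / len >= cutoff without float round-off at
# the boundary. The cutoff is turned into a rational num/den (den = 1e7).
passes_cutoff <- function(score, read_length, cutoff) {
  den <- 1e7
  num <- round(cutoff * den)
  score * den >= num * read_length
}

#' Assign one multimapping read among candidate paralogous regions
#'
#' Implements the normalized-score rescue rule for reads mapping ambiguously
#' among near-identical loci. Placements with normalized score below
#' `cutoff` are removed; if none survive the read is discarded. Among
#' survivors, the read is assigned to every placement achieving the maximum
#' score: all of them if several tie (`multi_equal`), or the single best one
#' (`unique_best`). A target-region placement that passes the cutoff but is
#' strictly below the read's best score anywhere is never assigned
#' (`removed_better_elsewhere`).
#'
#' @param alignments data frame with columns `region`, `score` (raw, `<= 0`),
#'   `read_length`, and optionally `inside_target` (logical; default all
#'   `TRUE`) for all candidate placements of one read. Duplicate placements
#'   at the same region are collapsed to the best-scoring one.
#' @param cutoff normalized-score cutoff (default -0.1); the boundary is
#'   inclusive (`nAS >= cutoff` is retained) and compared exactly.
#' @return Object of class `"rescue_decision"`: list with `assigned_regions`
#'   (character, possibly empty) and `reason` (one of `multi_equal`,
#'   `unique_best`, `discarded_low_score`, `removed_better_elsewhere`).
#' @export
rescue_assign <- function(alignments, cutoff = -0.1) {
  if (is.null(alignments) || nrow(alignments) == 0) {
    warning("no alignments for this read; discarding")
    return(structure(list(assigned_regions = character(0),
                          reason = "discarded_low_score"),
                     class = "rescue_decision"))
  }
  if ("read_id" %in% names(alignments) &&
      length(unique(alignments$read_id)) > 1)
    stop("rescue_assign expects the alignments of a single read")
  if (is.null(alignments$inside_target)) alignments$inside_target <- TRUE
  # collapse duplicate placements at one region to the best-scoring one
  best_by_region <- tapply(alignments$score, alignments$region, max)
  keep <- !duplicated(alignments$region)
  a <- alignments[keep, , drop = FALSE]
  a$score <- as.vector(best_by_region[a$region])

  surv <- a[passes_cutoff(a$score, a$read_length, cutoff), , drop = FALSE]
  if (nrow(surv) == 0)
    return(structure(list(assigned_regions = character(0),
                          reason = "discarded_low_score"),
                     class = "rescue_decision"))
  top <- surv$score == max(surv$score)
  assigned <- surv$region[top & surv$inside_target]
  reason <- if (length(assigned) == 0) "removed_better_elsewhere"
            else if (sum(top) > 1) "multi_equal" else "unique_best"
  structure(list(assigned_regions = sort(assigned), reason = reason),
            class = "rescue_decision")
}

#' @export
print.rescue_decision <- function(x, ...) {
  cat("rescue decision:", x$reason,
      if (length(x$assigned_regions))
        paste0("-> {", paste(x$assigned_regions, collapse = ", "), "}")
      else "", "\n")
  invisible(x)
}

#' Rescue every read in an alignment table
#'
#' @param alignments data frame with `read_id`, `region`, `score`,
#'   `read_length` (and optionally `inside_target`).
#' @param cutoff normalized-score cutoff.
#' @return Named list of [rescue_assign()] decisions, one per read.
#' @export
rescue_all <- function(alignments, cutoff = -0.1) {
  split_idx <- split(seq_len(nrow(alignments)), alignments$read_id)
  lapply(split_idx, function(i)
    rescue_assign(alignments[i, , drop = FALSE], cutoff = cutoff))
}

#' Merge rescued assignments with primary-pipeline reads
#'
#' Per region, takes the union of reads assigned by the rescue procedure and
#' reads placed there by the primary pipeline, deduplicated by read id.
#'
#' @param rescued named list of `rescue_decision`s (names = read ids), as
#'   from [rescue_all()].
#' @param primary_reads named list: per region, character vector of read ids
#'   assigned by the primary pipeline.
#' @return List with `reads` (per-region read-id sets) and `counts` (named
#'   integer vector).
#' @export
merge_with_primary <- function(rescued, primary_reads = list()) {
  regions <- union(unique(unlist(lapply(rescued, `[[`,
                                        "assigned_regions"))),
                   names(primary_reads))
  reads <- lapply(regions, function(rg) {
    from_rescue <- names(rescued)[vapply(rescued, function(d)
      rg %in% d$assigned_regions, logical(1))]
    sort(union(from_rescue, primary_reads[[rg]]))
  })
  names(reads) <- regions
  list(reads = reads, counts = lengths(reads))
}

#' Brute-force rescue oracle from raw sequences
#'
#' Independent cross-check for the rescue pipeline: scores the read against
#' every candidate region with `Biostrings::pairwiseAlignment` (full
#' dynamic programming, pattern-global / subject-local), then applies the
#' rescue rule. Intended for tests on small instances.
#'
#' @param read_seq read sequence (`<= 200` bp).
#' @param region_seqs named character vector of candidate region sequences
#'   (`<= 32`).
#' @param scoring list with `mismatch`, `gap_open`, `gap_extend` penalties
#'   (positive integers; gap of length k costs `gap_open + k * gap_extend`).
#' @param cutoff normalized-score cutoff.
#' @return A `rescue_decision`, plus attribute `"scores"` with the raw
#'   per-region scores.
#' @export
oracle_rescue <- function(read_seq, region_seqs,
                          scoring = list(mismatch = 6L, gap_open = 5L,
                                         gap_extend = 3L),
                          cutoff = -0.1) {
  if (nchar(read_seq) > 200 || length(region_seqs) > 32)
    stop("oracle refuses large instances (read <= 200 bp, <= 32 candidates)")
  if (is.null(names(region_seqs)))
    names(region_seqs) <- sprintf("R%02d", seq_along(region_seqs))
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 0, mismatch = -scoring$mismatch, baseOnly = TRUE)
  scores <- vapply(region_seqs, function(ref) {
    Biostrings::pairwiseAlignment(
      pattern = read_seq, subject = ref, type = "global-local",
      substitutionMatrix = submat,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
      scoreOnly = TRUE)
  }, numeric(1))
  dec <- rescue_assign(data.frame(region = names(region_seqs),
                                  score = scores,
                                  read_length = nchar(read_seq)),
                       cutoff = cutoff)
  attr(dec, "scores") <- scores
  dec
}
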