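#' Architecture filter for CAGE-style alignments
#'
#' Removes alignments matching any of three per-record rules: (a) template
#' length above `max_tlen` (10 kb default), (b) more than `max_softclip`
#' (3 bp) of soft clipping, (c) one or more mismatches. Each rule is a
#' strict inequality on its stated boundary, so a 3 bp soft clip and a
#' 10 kb template are kept.
#'
#' @param alignments data frame with columns `tlen` (template length),
#'   `softclip` (total soft-clipped bases) and `mismatches` (NM-style
#'   count); missing `mismatches` is an error since rule (c) cannot be
#'   applied.
#' @param max_tlen,max_softclip rule boundaries.
#' @return List with `kept` (surviving rows) and `removed` (named counts of
#'   records matching each rule; a record can match several).
#' @export
architecture_filter <- function(alignments, max_tlen = 10000L,
                                max_softclip = 3L) {
  if (is.null(alignments$mismatches))
    stop("mismatch counts are required to apply the mismatch rule")
  rule_a <- abs(alignments$tlen) > max_tlen
  rule_b <- alignments$softclip > max_softclip
  rule_c <- alignments$mismatches > 0
  drop <- rule_a | rule_b | rule_c
  list(kept = alignments[!drop, , drop = FALSE],
       removed = c(template_length = sum(rule_a),
                   soft_clipping = sum(rule_b),
                   mismatches = sum(rule_c)))
}

#' Proximity-window UMI deduplication
#'
#' In a position-sorted alignment table, records sharing a UMI within
#' `window_records` records of the most recently retained copy are treated
#' as PCR duplicates; only the first alignment of each UMI in a window is
#' kept.
#'
#' @param alignments data frame with columns `position` and `umi`, sorted by
#'   `position` (unsorted input is an error).
#' @param window_records window size in records (default 100000).
#' @return The deduplicated data frame.
#' @export
umi_proximity_dedup <- function(alignments, window_records = 100000L) {
  if (is.unsorted(alignments$position))
    stop("alignments must be sorted by position")
  n <- nrow(alignments)
  keep <- logical(n)
  last_kept <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    u <- as.character(alignments$umi[i])
    prev <- last_kept[[u]]
    if (is.null(prev) || i - prev > window_records) {
      keep[i] <- TRUE
      last_kept[[u]] <- i
    }
  }
  alignments[keep, , drop = FALSE]
}

# Riemann zeta by truncated sum plus integral tail (alpha > 1)
zeta_fn <- function(alpha, n = 1e5) {
  k <- seq_len(n)
  sum(k^(-alpha)) + n^(1 - alpha) / (alpha - 1) - 0.5 * n^(-alpha)
}

#' Power-law normalization of TSS tag counts
#'
#' Fits a log-log linear regression to the reverse cumulative distribution
#' of raw tag counts within `fit_range`, then maps each raw count to the
#' value it would have under a reference power law with exponent `-alpha`
#' scaled to a total of `T` tags. The mapping is monotone non-decreasing,
#' making samples of different depths and count distributions directly
#' comparable.
#'
#' @param counts non-negative raw tag counts (one per TSS position).
#' @param alpha reference power-law exponent (default 1.2, `> 1`).
#' @param T reference library total (default 1e6).
#' @param fit_range count range used for the regression (default
#'   `c(5, 1000)`).
#' @return Numeric vector of normalized values (0 stays 0). Falls back to
#'   simple scaling to total `T`, with a warning, when fewer than 2
#'   distinct count values lie in `fit_range`.
#' @export
powerlaw_normalize <- function(counts, alpha = 1.2, T = 1e6,
                               fit_range = c(5, 1000)) {
  if (any(counts < 0)) stop("counts must be >= 0")
  if (alpha <= 1 || T <= 0) stop("require alpha > 1 and T > 0")
  vals <- sort(unique(counts[counts >= fit_range[1] &
                             counts <= fit_range[2]]))
  if (length(vals) < 2) {
    warning("fewer than 2 distinct count values in fit_range; ",
            "falling back to simple scaling to total T")
    s <- sum(counts)
    return(if (s > 0) counts * (T / s) else counts)
  }
  revcum <- vapply(vals, function(v) sum(counts >= v), numeric(1))
  fit <- lm(log10(revcum) ~ log10(vals))
  a <- coef(fit)[[2]]; b <- coef(fit)[[1]]
  # reference law: revcum_ref(x) = K x^(-alpha); total tags = K * zeta(alpha)
  logK <- log10(T / zeta_fn(alpha))
  out <- numeric(length(counts))
  pos <- counts > 0
  out[pos] <- 10^((a * log10(counts[pos]) + b - logK) / (-alpha))
  out
}

#' Distance-based clustering of TSS positions into tag clusters
#'
#' Positions whose normalized signal reaches `threshold` in at least
#' `min_samples` samples seed clusters; same-strand seeds within `max_dist`
#' bp are merged by single linkage. Clusters consisting of a single
#' position are removed unless their pooled signal exceeds
#' `keep_singletons_above` (strict).
#'
#' @param positions data frame with `chrom`, `pos`, `strand`.
#' @param values numeric matrix (positions x samples) of normalized signal.
#' @param threshold seed threshold on the normalized signal (default 2).
#' @param max_dist maximal merge distance in bp (default 50).
#' @param keep_singletons_above singleton rescue threshold on pooled signal
#'   (default 4; strict `>`).
#' @param min_samples number of samples required to pass `threshold`.
#' @return Data frame of clusters: `chrom`, `start`, `end` (1-based
#'   inclusive positions), `strand`, `n_pos`, `signal` (pooled over member
#'   positions and samples).
#' @export
distclu <- function(positions, values, threshold = 2, max_dist = 50L,
                    keep_singletons_above = 4, min_samples = 1L) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == nrow(positions))
  seed <- rowSums(values >= threshold) >= min_samples
  pooled <- rowSums(values)
  res <- list()
  idx <- which(seed)
  if (length(idx)) {
    key <- paste(positions$chrom[idx], positions$strand[idx])
    for (grp in split(idx, key)) {
      o <- grp[order(positions$pos[grp])]
      p <- positions$pos[o]
      brk <- cumsum(c(0L, diff(p) > max_dist))
      for (cl in split(seq_along(o), brk)) {
        members <- o[cl]
        res[[length(res) + 1L]] <- data.frame(
          chrom = positions$chrom[members[1]],
          start = min(positions$pos[members]),
          end = max(positions$pos[members]),
          strand = positions$strand[members[1]],
          n_pos = length(members),
          signal = sum(pooled[members]))
      }
    }
  }
  out <- do.call(rbind, c(res, list(data.frame(
    chrom = character(0), start = integer(0), end = integer(0),
    strand = character(0), n_pos = integer(0), signal = numeric(0)))))
  out <- out[out$n_pos > 1 | out$signal > keep_singletons_above, ,
             drop = FALSE]
  out <- out[order(out$chrom, out$strand, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# >= 1 bp overlap between 1-based inclusive intervals on matching
# chrom/strand
overlaps_any <- function(x, table) {
  vapply(seq_len(nrow(x)), function(i) {
    any(table$chrom == x$chrom[i] & table$strand == x$strand[i] &
          table$start <= x$end[i] & table$end >= x$start[i])
  }, logical(1))
}

#' Two-step (loose/strict) tag-cluster calling
#'
#' Runs [distclu()] twice: a loose pass where a single sample passing the
#' seed threshold suffices, and a strict pass requiring every sample to
#' pass. Accepted peaks are loose clusters overlapping (>= 1 bp, same
#' strand) at least one strict cluster; their boundaries come from the
#' loose pass, whose widths are more faithful. Regions on `allowlist`
#' (e.g. condition-specific promoters expressed in a subset of samples)
#' bypass the strict requirement.
#'
#' @inheritParams distclu
#' @param allowlist optional data frame of regions (`chrom`, `start`,
#'   `end`, `strand`) whose loose clusters are accepted without strict
#'   support.
#' @return Data frame of accepted clusters (loose boundaries), with a
#'   logical column `strict_supported`.
#' @export
two_step_peaks <- function(positions, values, threshold = 2, max_dist = 50L,
                           keep_singletons_above = 4, allowlist = NULL) {
  values <- as.matrix(values)
  loose <- distclu(positions, values, threshold, max_dist,
                   keep_singletons_above, min_samples = 1L)
  strict <- distclu(positions, values, threshold, max_dist,
                    keep_singletons_above, min_samples = ncol(values))
  if (nrow(loose) == 0) return(cbind(loose, strict_supported = logical(0)))
  supported <- overlaps_any(loose, strict)
  allowed <- if (!is.null(allowlist) && nrow(allowlist))
    overlaps_any(loose, allowlist) else rep(FALSE, nrow(loose))
  out <- loose[supported | allowed, , drop = FALSE]
  out$strict_supported <- supported[supported | allowed]
  rownames(out) <- NULL
  out
}

#' Cap-signature filter for tag clusters
#'
#' Retains clusters in which strictly more than `min_fraction` of reads
#' carry the cap signature (an unencoded 5' G added during template
#' switching on capped transcripts), removing clusters likely driven by
#' uncapped background RNA. A cluster with zero reads is removed with a
#' warning.
#'
#' @param clusters data frame with columns `capped_reads` and `total_reads`
#'   (or a precomputed `cap_fraction`).
#' @param min_fraction retention boundary (default 0.70; strict `>`).
#' @return The filtered data frame, with a `cap_fraction` column.
#' @export
cap_filter <- function(clusters, min_fraction = 0.70) {
  if (is.null(clusters$cap_fraction)) {
    empty <- clusters$total_reads == 0
    if (any(empty))
      warning(sum(empty), " cluster(s) with zero reads removed")
    clusters$cap_fraction <- ifelse(clusters$total_reads > 0,
                                    clusters$capped_reads /
                                      pmax(clusters$total_reads, 1), NA)
  }
  keep <- !is.na(clusters$cap_fraction) &
    clusters$cap_fraction > min_fraction
  out <- clusters[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Correlate promoter TSS signal with chromatin accessibility
#'
#' For a set of peaks quantified by both assays, scales the accessibility
#' values to a fixed total (1e5) across the used peaks, log2-transforms
#' both axes (with an optional pseudocount) and reports the Pearson
#' correlation with its two-tailed t-based p-value.
#'
#' @param cage per-peak TSS signal (already normalized, averaged over
#'   samples).
#' @param atac per-peak accessibility counts (e.g. Tn5 insertions).
#' @param pseudocount added before log2 (default 0; any non-positive value
#'   with pseudocount 0 is an error).
#' @param atac_total fixed-sum normalization target (default 1e5).
#' @return List with `table` (per-peak values used), `r`, `p`, `n`.
#' @export
promoter_signal_correlation <- function(cage, atac, pseudocount = 0,
                                        atac_total = 1e5) {
  if (length(cage) != length(atac)) stop("cage and atac lengths differ")
  if (length(cage) < 3) stop("need at least 3 peaks")
  atac_scaled <- atac * (atac_total / sum(atac))
  x <- cage + pseudocount
  y <- atac_scaled + pseudocount
  if (any(x <= 0) || any(y <= 0))
    stop("non-positive values cannot be log2-transformed; set a pseudocount")
  ct <- cor.test(log2(x), log2(y), method = "pearson")
  list(table = data.frame(cage = cage, atac_scaled = atac_scaled),
       r = unname(ct$estimate), p = ct$p.value, n = length(cage))
}
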