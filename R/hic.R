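#' Vanilla-coverage normalization of a contact matrix
#'
#' Divides each contact by the product of its anchors' coverage factors
#' `v_i = rowsum_i / mean(positive rowsums)`, so the normalized matrix
#' keeps the raw matrix's overall magnitude. Bins with zero coverage are
#' masked (`NA`).
#'
#' @param m symmetric raw count matrix, or a `contact_matrix` from
#'   [simulate_contact_matrix()].
#' @return List with `normalized` (matrix with masked bins `NA`),
#'   `coverage` (raw row sums) and `v` (normalization vector).
#' @export
vc_normalize <- function(m) {
  if (inherits(m, "contact_matrix")) m <- m$counts
  rs <- rowSums(m)
  if (all(rs == 0)) stop("all-zero contact matrix")
  v <- rs / mean(rs[rs > 0])
  vv <- outer(v, v)
  norm <- m / vv
  norm[rs == 0, ] <- NA
  norm[, rs == 0] <- NA
  list(normalized = norm, coverage = rs, v = v)
}

#' Mean interaction frequency in a hotspot and its neighborhood
#'
#' The hotspot is an inner rectangle of bin pairs; its neighborhood is the
#' frame between the inner and an enclosing outer rectangle. Means are
#' arithmetic over unmasked (non-`NA`) entries.
#'
#' @param normalized normalized contact matrix.
#' @param inner,outer length-4 integer vectors
#'   `c(row_start, row_end, col_start, col_end)` in bin units; `inner` must
#'   lie within `outer`, both within the matrix.
#' @return Named numeric vector `c(inner =, neighborhood =)`.
#' @export
hotspot_strength <- function(normalized, inner, outer) {
  n <- nrow(normalized)
  chk <- function(r) r[1] >= 1 && r[3] >= 1 && r[2] <= n && r[4] <= n &&
    r[1] <= r[2] && r[3] <= r[4]
  if (!chk(inner) || !chk(outer)) stop("rectangle outside matrix")
  if (inner[1] < outer[1] || inner[2] > outer[2] ||
      inner[3] < outer[3] || inner[4] > outer[4])
    stop("inner rectangle must lie within outer")
  in_mask <- matrix(FALSE, n, n)
  in_mask[inner[1]:inner[2], inner[3]:inner[4]] <- TRUE
  out_mask <- matrix(FALSE, n, n)
  out_mask[outer[1]:outer[2], outer[3]:outer[4]] <- TRUE
  nb <- out_mask & !in_mask
  if (!any(nb)) stop("empty neighborhood")
  c(inner = mean(normalized[in_mask], na.rm = TRUE),
    neighborhood = mean(normalized[nb], na.rm = TRUE))
}

#' Scale per-sample coverage profiles to a common sum
#'
#' Each sample's coverage profile (the VC normalization vector) is scaled
#' to sum exactly `target`; the cross-sample mean profile is what the
#' matched-background selection uses as "read coverage".
#'
#' @param profiles list of non-negative numeric vectors of equal length.
#' @param target common sum (default 100000).
#' @return List with `scaled` (list of profiles) and `mean` (elementwise
#'   mean profile).
#' @export
normalize_coverage_profiles <- function(profiles, target = 1e5) {
  lens <- lengths(profiles)
  if (length(unique(lens)) != 1) stop("profiles must have equal length")
  scaled <- lapply(profiles, function(p) {
    s <- sum(p)
    if (s <= 0) stop("zero-sum coverage profile")
    p * (target / s)
  })
  list(scaled = scaled, mean = Reduce(`+`, scaled) / length(scaled))
}

#' Select distance- and coverage-matched background interactions
#'
#' For a foreground bin pair, keeps candidate pairs whose genomic distance
#' differs by at most `tolerance` bp (inclusive), excludes the foreground
#' itself plus any declared foreground set, and returns the `k` candidates
#' whose anchor coverages are nearest the foreground's in the 2D space of
#' (centromeric, telomeric) anchor coverage (Euclidean distance). Ties are
#' broken deterministically by distance difference, then anchor indices.
#'
#' @param fg length-2 integer vector `c(i, j)` with `i <= j` (bin indices).
#' @param candidates data frame with columns `i`, `j` (`i <= j`), the
#'   candidate universe.
#' @param coverage per-bin coverage values (e.g. the mean scaled profile
#'   from [normalize_coverage_profiles()]).
#' @param bin_size bin width in bp.
#' @param k number of backgrounds (default 10).
#' @param tolerance distance tolerance in bp (default 5000, inclusive).
#' @param exclude optional data frame (`i`, `j`) of declared foregrounds to
#'   exclude from the candidate universe.
#' @return Data frame of the `k` selected rows with `dist_bp` and
#'   `coverage_dist` columns; fewer than `k` eligible candidates is an
#'   error stating the shortfall.
#' @export
matched_background <- function(fg, candidates, coverage, bin_size,
                               k = 10L, tolerance = 5000,
                               exclude = NULL) {
  dist_fg <- (fg[2] - fg[1]) * bin_size
  cand <- candidates
  cand$dist_bp <- (cand$j - cand$i) * bin_size
  cand$dist_diff <- abs(cand$dist_bp - dist_fg)
  drop <- (cand$i == fg[1] & cand$j == fg[2])
  if (!is.null(exclude) && nrow(exclude))
    drop <- drop | (paste(cand$i, cand$j) %in% paste(exclude$i, exclude$j))
  cand <- cand[!drop & cand$dist_diff <= tolerance, , drop = FALSE]
  if (nrow(cand) < k)
    stop("only ", nrow(cand), " eligible background candidates for k = ", k,
         " (short by ", k - nrow(cand), ")")
  cand$coverage_dist <- sqrt((coverage[cand$i] - coverage[fg[1]])^2 +
                               (coverage[cand$j] - coverage[fg[2]])^2)
  o <- order(cand$coverage_dist, cand$dist_diff, cand$i, cand$j)
  out <- cand[o[seq_len(k)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' All bin pairs of a matrix region as a candidate universe
#'
#' @param n_bins number of bins.
#' @param mask optional logical vector of bins to exclude (e.g. zero
#'   coverage).
#' @return Data frame with `i`, `j` (`i <= j`), off-diagonal pairs only.
#' @export
all_bin_pairs <- function(n_bins, mask = NULL) {
  pr <- which(upper.tri(matrix(0, n_bins, n_bins)), arr.ind = TRUE)
  out <- data.frame(i = pr[, 1], j = pr[, 2])
  if (!is.null(mask)) out <- out[!mask[out$i] & !mask[out$j], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Average contact profile around all pairs of anchors
#'
#' For every unordered pair of anchors (the smaller index, toward the
#' centromere, indexes rows; the larger, columns), extracts the
#' `(2w+1) x (2w+1)` submatrix of normalized frequencies centered on the
#' pair and averages elementwise over pairs. Pairs whose window extends off
#' the matrix are skipped with a warning.
#'
#' @param anchors integer vector of anchor bin indices.
#' @param normalized normalized contact matrix.
#' @param window_bins half-window `w` in bins.
#' @return List with `profile` (averaged matrix), `n_pairs` (pairs
#'   aggregated) and `pairs` (data frame `i`, `j`).
#' @export
aggregate_pair_profiles <- function(anchors, normalized, window_bins = 2L) {
  if (length(anchors) < 2) stop("need at least 2 anchors")
  cmb <- utils::combn(sort(anchors), 2)
  n <- nrow(normalized); w <- window_bins
  acc <- matrix(0, 2 * w + 1, 2 * w + 1)
  used <- 0L
  skipped <- 0L
  pairs <- data.frame(i = cmb[1, ], j = cmb[2, ])
  for (k in seq_len(ncol(cmb))) {
    i <- cmb[1, k]; j <- cmb[2, k]
    if (i - w < 1 || i + w > n || j - w < 1 || j + w > n) {
      skipped <- skipped + 1L
      next
    }
    acc <- acc + normalized[(i - w):(i + w), (j - w):(j + w)]
    used <- used + 1L
  }
  if (skipped) warning(skipped, " pair(s) skipped: window off the matrix")
  if (used == 0) stop("no pair had a full window inside the matrix")
  list(profile = acc / used, n_pairs = used, pairs = pairs)
}

#' Welch t-test of foreground vs background interaction strength
#'
#' Two-tailed unequal-variance t-test; when several tests form a family,
#' [enrichment_test_family()] adjusts them with Benjamini-Hochberg.
#'
#' @param fg,bg numeric vectors (`>= 2` values each).
#' @return List with `t`, `p`, `df`.
#' @export
enrichment_test <- function(fg, bg) {
  if (length(fg) < 2 || length(bg) < 2) stop("need >= 2 values per group")
  if (sd(fg) == 0 && sd(bg) == 0) {
    equal <- isTRUE(all.equal(mean(fg), mean(bg)))
    return(list(t = if (equal) 0 else Inf, p = if (equal) 1 else 0,
                df = NA_real_))
  }
  tt <- t.test(fg, bg, var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' @rdname enrichment_test
#' @param tests list of `list(fg =, bg =)` pairs forming one test family.
#' @return For the family version: data frame with `t`, `p`, `fdr`.
#' @export
enrichment_test_family <- function(tests) {
  res <- lapply(tests, function(x) enrichment_test(x$fg, x$bg))
  out <- data.frame(t = vapply(res, `[[`, numeric(1), "t"),
                    p = vapply(res, `[[`, numeric(1), "p"))
  out$fdr <- fdr_adjust(out$p)
  out
}
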