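#' Binarize a count matrix into detection calls
#'
#' An entry is `TRUE` iff the cell has at least one pass-filter read for the
#' gene. Binarization reflects the near all-or-none expression of the
#' receptor genes this analysis targets.
#'
#' @param counts numeric matrix, cells x genes (counts `>= 0`).
#' @return Logical matrix of the same shape; genes detected in no cell are
#'   listed in attribute `"all_zero_genes"`.
#' @export
binarize <- function(counts) {
  if (any(counts < 0)) stop("counts must be >= 0")
  m <- counts >= 1
  attr(m, "all_zero_genes") <- colnames(m)[colSums(m) == 0]
  m
}

#' Contingency table of binary co-expression for a gene pair
#'
#' Partitions all cells by the binary expression of genes `x` and `y`:
#' `a` = x-y-, `b` = x-y+, `c` = x+y-, `d` = x+y+ (so `a+b+c+d` is the
#' number of cells).
#'
#' @param m logical matrix, cells x genes.
#' @param x,y distinct gene names present in `m`.
#' @return Named numeric vector `c(a, b, c, d)` of class `"contingency"`.
#' @export
contingency <- function(m, x, y) {
  if (identical(x, y)) stop("x and y must differ")
  if (!all(c(x, y) %in% colnames(m)))
    stop("missing gene(s): ", paste(setdiff(c(x, y), colnames(m)),
                                    collapse = ", "))
  xv <- m[, x]; yv <- m[, y]
  structure(c(a = sum(!xv & !yv), b = sum(!xv & yv),
              c = sum(xv & !yv), d = sum(xv & yv)),
            class = "contingency")
}

#' Odds ratio of a 2x2 co-expression table
#'
#' The odds of `y` expression in `x+` cells over the odds in `x-` cells:
#' `(d/c) / (b/a) = (a*d) / (b*c)`. Degenerate tables are flagged rather
#' than continuity-corrected: `Inf` when only `b*c` is zero, `NaN`
#' (undefined) when both products are zero.
#'
#' @param t a [contingency()] table (or named vector with `a,b,c,d`).
#' @return Numeric scalar in `[0, Inf]`, or `NaN` when undefined.
#' @export
odds_ratio <- function(t) {
  ad <- t[["a"]] * t[["d"]]
  bc <- t[["b"]] * t[["c"]]
  if (bc == 0 && ad == 0) return(NaN)
  if (bc == 0) return(Inf)
  ad / bc
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Enumerates every table with the observed margins and sums the
#' hypergeometric probabilities of those no more probable than the observed
#' table (within relative tolerance 1e-7), the conventional two-sided
#' definition.
#'
#' @param t a [contingency()] table (named `a,b,c,d`).
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(t) {
  a <- t[["a"]]; b <- t[["b"]]; c <- t[["c"]]; d <- t[["d"]]
  n <- a + b + c + d
  if (n == 0) return(1)
  # margins: x+ row total = c + d; y+ column total = b + d
  k_range <- max(0, (c + d) + (b + d) - n):min(c + d, b + d)
  probs <- dhyper(k_range, b + d, a + c, c + d)
  p_obs <- dhyper(d, b + d, a + c, c + d)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, returned in input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values in `[0, 1]`.
#' @export
fdr_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Odds ratios with Fisher tests for every gene pair
#'
#' @param m logical cells x genes matrix (one sample).
#' @return Data frame with one row per ordered pair (x, y), x != y:
#'   `or`, `p`, `fdr` (BH across all pairs of the sample).
#' @export
coexpression_table <- function(m) {
  genes <- colnames(m)
  pairs <- expand.grid(x = genes, y = genes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$x != pairs$y, , drop = FALSE]
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    ct <- contingency(m, pairs$x[i], pairs$y[i])
    data.frame(x = pairs$x[i], y = pairs$y[i],
               or = odds_ratio(ct), p = fisher_exact(ct))
  })
  out <- do.call(rbind, res)
  out$fdr <- fdr_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' Combine per-sample co-expression results into heatmap entries
#'
#' Per gene pair, the reported odds ratio is the arithmetic mean across
#' samples and the reported significance is the least significant (largest)
#' FDR. Pairs with a non-finite odds ratio in any sample are flagged and
#' their mean withheld.
#'
#' @param results list of [coexpression_table()] data frames over the same
#'   gene pairs.
#' @return Data frame `x`, `y`, `or_mean`, `fdr_max`, `flagged`.
#' @export
combine_samples <- function(results) {
  if (length(results) < 1) stop("no samples")
  key <- function(df) paste(df$x, df$y)
  k1 <- key(results[[1]])
  for (df in results[-1]) {
    if (!identical(sort(key(df)), sort(k1)))
      stop("samples cover different gene-pair sets")
  }
  aligned <- lapply(results, function(df) df[match(k1, key(df)), ])
  ors <- sapply(aligned, `[[`, "or")
  fdrs <- sapply(aligned, `[[`, "fdr")
  if (is.null(dim(ors))) { ors <- matrix(ors, ncol = 1)
                           fdrs <- matrix(fdrs, ncol = 1) }
  flagged <- apply(ors, 1, function(v) any(!is.finite(v)))
  data.frame(x = aligned[[1]]$x, y = aligned[[1]]$y,
             or_mean = ifelse(flagged, NA_real_, rowMeans(ors)),
             fdr_max = apply(fdrs, 1, max),
             flagged = flagged)
}
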