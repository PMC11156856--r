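#' Per-column modal nucleotide identity of an MSA
#'
#' For every alignment column, the most frequent nucleotide among rows and
#' its frequency, with gaps counted in the denominator but never eligible
#' as the modal character (conservation refers to nucleotides, not shared
#' deletions).
#'
#' @param msa named character vector of gapped rows (or
#'   `DNAMultipleAlignment`).
#' @return Data frame with `column`, `base`, `freq` (`freq` in `[0, 1]`).
#' @export
column_identity <- function(msa) {
  m <- as_msa_matrix(msa)
  lv <- c(DNA_BASES, "N")
  res <- apply(m, 2, function(col) {
    tab <- tabulate(match(col, lv), nbins = length(lv))
    top <- which.max(tab)
    c(tab[top] / length(col), top)
  })
  data.frame(column = seq_len(ncol(m)),
             base = lv[res[2, ]],
             freq = as.numeric(res[1, ]))
}

#' Call highly conserved elements from a column-identity profile
#'
#' Maximal runs of consecutive columns whose modal nucleotide frequency
#' reaches `min_frac`, reported when at least `min_len` columns long (both
#' boundaries inclusive).
#'
#' @param profile a [column_identity()] data frame.
#' @param min_len minimal run length in columns (default 10).
#' @param min_frac minimal per-column identity (default 0.9).
#' @return Data frame with `start`, `end` (column indices, inclusive) and
#'   `length`.
#' @export
conserved_runs <- function(profile, min_len = 10L, min_frac = 0.9) {
  pass <- profile$freq >= min_frac
  r <- rle(pass)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  out <- data.frame(start = profile$column[starts[keep]],
                    end = profile$column[ends[keep]])
  out$length <- out$end - out$start + 1L
  out
}

#' Position weight matrix from base probabilities
#'
#' @param probs 4 x w numeric matrix (rows `A`, `C`, `G`, `T`; columns sum
#'   to 1) of per-position base probabilities, or a count matrix
#'   (normalized internally).
#' @param background length-4 base distribution (default uniform).
#' @param pseudocount added to every cell before renormalization (default
#'   0.01), so no log-odds is infinite.
#' @return Object of class `"pwm"`: list with `probs`, `background`,
#'   `width`.
#' @export
pwm <- function(probs, background = rep(0.25, 4), pseudocount = 0.01) {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4) stop("probs must have 4 rows (A, C, G, T)")
  rownames(probs) <- DNA_BASES
  probs <- sweep(probs, 2, colSums(probs), "/")    # counts -> probabilities
  probs <- probs + pseudocount
  probs <- sweep(probs, 2, colSums(probs), "/")
  background <- background / sum(background)
  if (any(background <= 0)) stop("background must be positive")
  structure(list(probs = probs, background = background,
                 width = ncol(probs)), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM of width", x$width, "\n")
  print(round(x$probs, 3))
  invisible(x)
}

# reverse complement of a PWM: reverse columns, swap complementary rows
pwm_revcomp <- function(p) {
  pr <- p$probs[c("T", "G", "C", "A"), rev(seq_len(p$width)), drop = FALSE]
  rownames(pr) <- DNA_BASES
  structure(list(probs = pr, background = p$background[4:1],
                 width = p$width), class = "pwm")
}

# integer-discretized log-odds score matrix and the exact null distribution
# of the total score for a random background k-mer, by DP convolution
pwm_score_model <- function(p, granularity = 1e-3) {
  lo <- log2(p$probs / p$background)
  s <- round(lo / granularity)             # integer scores per cell
  offset <- -min(s)                        # shift so all cells >= 0
  s_shift <- s + offset
  max_total <- sum(apply(s_shift, 2, max))
  dist <- numeric(max_total + 1L)          # index = shifted score + 1
  dist[1] <- 1
  for (j in seq_len(ncol(s))) {
    nxt <- numeric(max_total + 1L)
    for (b in 1:4) {
      sh <- s_shift[b, j]
      pb <- p$background[b]
      if (sh == 0) nxt <- nxt + dist * pb
      else {
        n <- length(dist)
        nxt[(sh + 1):n] <- nxt[(sh + 1):n] + dist[1:(n - sh)] * pb
      }
    }
    dist <- nxt
  }
  list(scores = s, granularity = granularity, offset = offset, null = dist)
}

# exact p-value: P(score of random background k-mer >= observed), on the
# discretized integer scale
pwm_pvalue <- function(model, int_score_shifted) {
  tail <- rev(cumsum(rev(model$null)))
  i <- int_score_shifted + 1L
  if (i < 1) return(1)
  if (i > length(tail)) return(0)
  tail[i]
}

#' Scan a sequence with a PWM using exact p-values
#'
#' Slides the motif along the sequence (both strands by default), scores
#' each offset by discretized log-odds against the background, and computes
#' for every hit the exact tail probability of its score under the
#' background base distribution (dynamic-programming convolution over the
#' per-position score distributions, the same construction FIMO-style
#' scanners use). Hits with `p < p_cutoff` are reported.
#'
#' @param sequence nucleotide string (`length >= width` for any hit).
#' @param p a [pwm()].
#' @param p_cutoff report hits with `p < p_cutoff` (default 0.01, strict).
#' @param both_strands scan the reverse complement too (default TRUE).
#' @param granularity score discretization step in log2 units (default
#'   1e-3).
#' @return Data frame with `offset` (1-based start), `strand`, `score`
#'   (log2 odds), `p`.
#' @export
pwm_scan <- function(sequence, p, p_cutoff = 0.01, both_strands = TRUE,
                     granularity = 1e-3) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  empty <- data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0), p = numeric(0))
  if (n < p$width) return(empty)
  base_idx <- match(strsplit(sequence, "")[[1]], DNA_BASES)
  strands <- if (both_strands) c("+", "-") else "+"
  res <- list()
  for (st in strands) {
    pw <- if (st == "+") p else pwm_revcomp(p)
    model <- pwm_score_model(pw, granularity)
    w <- pw$width
    for (off in seq_len(n - w + 1L)) {
      idx <- base_idx[off:(off + w - 1L)]
      if (anyNA(idx)) next                       # ambiguous base in window
      int_shifted <- sum(model$scores[cbind(idx, seq_len(w))]) +
        model$offset * w
      pv <- pwm_pvalue(model, int_shifted)
      if (pv < p_cutoff)
        res[[length(res) + 1L]] <- data.frame(
          offset = off, strand = st,
          score = (int_shifted - model$offset * w) * granularity,
          p = pv)
    }
  }
  out <- do.call(rbind, c(res, list(empty)))
  out[order(out$p, out$offset), , drop = FALSE]
}

#' Sliding-window percent identity of a pairwise alignment
#'
#' Percent identity per `window`-column sliding window (step 1) of a gapped
#' pairwise alignment; gaps count as mismatches. Maximal merged regions
#' longer than `min_region` columns with identity strictly above
#' `highlight` percent are reported, the display convention of
#' VISTA-style conservation plots.
#'
#' @param a,b equal-length gapped sequences.
#' @param window window size in alignment columns (default 100). An
#'   alignment shorter than the window is scored as one whole-length
#'   window, with a warning.
#' @param highlight identity percentage boundary for highlighted regions
#'   (default 70, strict `>`).
#' @param min_region minimal highlighted-region length in columns
#'   (default 100, strict `>`).
#' @return List with `identity` (per-window percentages, named by window
#'   start) and `regions` (data frame `start`, `end`, `length` in
#'   alignment columns).
#' @export
window_identity <- function(a, b, window = 100L, highlight = 70,
                            min_region = 100L) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  if (length(ca) != length(cb)) stop("sequences must be aligned")
  L <- length(ca)
  match_vec <- as.numeric(ca == cb & ca != "-")
  if (L < window) {
    warning("alignment shorter than window; scoring one whole-length window")
    pct <- 100 * mean(match_vec)
    regions <- if (pct > highlight && L > min_region)
      data.frame(start = 1L, end = L, length = L)
    else data.frame(start = integer(0), end = integer(0),
                    length = integer(0))
    return(list(identity = stats::setNames(pct, 1L), regions = regions))
  }
  cm <- c(0, cumsum(match_vec))
  starts <- seq_len(L - window + 1L)
  pct <- 100 * (cm[starts + window] - cm[starts]) / window
  # merge columns covered by any above-threshold window into regions
  covered <- logical(L)
  for (s in starts[pct > highlight]) covered[s:(s + window - 1L)] <- TRUE
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  st <- ends - r$lengths + 1L
  keep <- r$values & r$lengths > min_region
  regions <- data.frame(start = st[keep], end = ends[keep])
  regions$length <- regions$end - regions$start + 1L
  list(identity = stats::setNames(pct, starts), regions = regions)
}

#' Search direct and inverted homologous segments between two sequences
#'
#' Seed-and-extend search in the spirit of a dot plot: exact shared k-mers
#' seed ungapped diagonals, seeds are extended with an x-drop rule, and
#' overlapping extensions on one diagonal are merged into maximal segments.
#' Segments at least `min_len` long with identity at least `min_identity`
#' are reported, on the forward strand and (optionally) against the
#' reverse complement of `b`, with inverted hits mapped back to original
#' `b` coordinates.
#'
#' @param a,b nucleotide strings.
#' @param min_len minimal segment length in bp (default 100; the related
#'   (35, 0.60) screen is reproduced by lowering this).
#' @param min_identity minimal fractional identity (default 0.60).
#' @param search_inverted also search the reverse complement (default
#'   TRUE).
#' @param seed_len exact-match seed length (default 8).
#' @return Data frame with `start_a`, `end_a`, `start_b`, `end_b`
#'   (1-based, on the original strands), `strand` (`+`/`-`), `length`,
#'   `identity`.
#' @export
homology_search <- function(a, b, min_len = 100L, min_identity = 0.60,
                            search_inverted = TRUE, seed_len = 8L) {
  if (!nchar(a) || !nchar(b)) stop("sequences must be non-empty")
  out <- diag_homology(toupper(a), toupper(b), min_len, min_identity,
                       seed_len)
  if (nrow(out)) out$strand <- "+"
  if (search_inverted) {
    brc <- revcomp(toupper(b))
    inv <- diag_homology(toupper(a), brc, min_len, min_identity, seed_len)
    if (nrow(inv)) {
      nb <- nchar(b)
      inv$strand <- "-"
      tmp <- inv$start_b
      inv$start_b <- nb - inv$end_b + 1L
      inv$end_b <- nb - tmp + 1L
      out <- rbind(out, inv)
    }
  }
  rownames(out) <- NULL
  out
}

# ungapped diagonal homology between two sequences (forward orientation)
diag_homology <- function(a, b, min_len, min_identity, seed_len) {
  empty <- data.frame(start_a = integer(0), end_a = integer(0),
                      start_b = integer(0), end_b = integer(0),
                      length = integer(0), identity = numeric(0),
                      strand = character(0))
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  if (na < seed_len || nb < seed_len) return(empty[, 1:6])
  kmer <- function(ch, k) {
    n <- length(ch) - k + 1L
    vapply(seq_len(n), function(i) paste(ch[i:(i + k - 1L)], collapse = ""),
           character(1))
  }
  ka <- kmer(ca, seed_len); kb <- kmer(cb, seed_len)
  hits <- merge(data.frame(pa = seq_along(ka), k = ka),
                data.frame(pb = seq_along(kb), k = kb), by = "k")
  if (!nrow(hits)) return(empty[, 1:6])
  hits$diag <- hits$pa - hits$pb
  segs <- list()
  for (dg in unique(hits$diag)) {
    # the shared diagonal as a binary match vector
    a_lo <- max(1L, 1L + dg); a_hi <- min(na, nb + dg)
    if (a_hi - a_lo + 1L < min_len) next
    ia <- a_lo:a_hi
    mvec <- ca[ia] == cb[ia - dg]
    seeds <- sort(unique(hits$pa[hits$diag == dg])) - a_lo + 1L
    segs[[length(segs) + 1L]] <-
      extend_on_diagonal(mvec, seeds, dg, a_lo, min_len, min_identity)
  }
  res <- do.call(rbind, c(segs, list(empty[, 1:6])))
  if (!nrow(res)) return(res)
  res <- res[order(res$start_a, res$start_b), , drop = FALSE]
  res
}

# x-drop extension of seeds along one diagonal's binary match vector,
# merging overlapping extensions, then exact identity/length filtering
extend_on_diagonal <- function(mvec, seeds, dg, a_lo, min_len,
                               min_identity) {
  n <- length(mvec)
  # score: +1 match, -x mismatch with x chosen so the break-even identity
  # equals min_identity: x = min_identity / (1 - min_identity)
  x <- min_identity / (1 - min_identity)
  score <- ifelse(mvec, 1, -x)
  xdrop <- 15
  covered <- logical(n)
  for (s in seeds) {
    if (covered[s]) next
    # extend right
    best <- 0; cur <- 0; r <- s
    j <- s
    while (j <= n) {
      cur <- cur + score[j]
      if (cur > best) { best <- cur; r <- j }
      if (best - cur > xdrop) break
      j <- j + 1L
    }
    # extend left
    best <- 0; cur <- 0; l <- s
    j <- s
    while (j >= 1) {
      cur <- cur + score[j]
      if (cur > best) { best <- cur; l <- j }
      if (best - cur > xdrop) break
      j <- j - 1L
    }
    covered[l:r] <- TRUE
  }
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  segs <- lapply(keep, function(k) {
    l <- starts[k]; rr <- ends[k]
    len <- rr - l + 1L
    idn <- mean(mvec[l:rr])
    if (len >= min_len && idn >= min_identity)
      data.frame(start_a = a_lo + l - 1L, end_a = a_lo + rr - 1L,
                 start_b = a_lo + l - 1L - dg, end_b = a_lo + rr - 1L - dg,
                 length = len, identity = idn)
  })
  do.call(rbind, segs)
}
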