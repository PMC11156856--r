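#' Simulate Tn5 insertion events over a paralog family
#'
#' Draws per-bp Poisson counts of transposase insertion events on every
#' paralog. The baseline intensity is `depth / locus length` per bp; inside
#' the footprint of a planted element the intensity is multiplied by that
#' element's entry in `enrichment` (default 1), emulating accessible
#' chromatin at regulatory elements.
#'
#' @param fam a `paralog_family`.
#' @param n_samples number of independent libraries to simulate.
#' @param depth expected insertion events per locus at multiplier 1
#'   (default from `fam$config`).
#' @param enrichment named numeric vector of fold-enrichments per planted
#'   element (all multipliers must be `>= 0`).
#' @param seed integer seed (default the family's).
#' @return List over samples; each sample is a list over paralogs of sorted
#'   integer insertion positions (1-based bp on that paralog).
#' @export
simulate_insertions <- function(fam, n_samples = 1L, depth = NULL,
                                enrichment = NULL, seed = NULL) {
  if (is.null(depth)) depth <- fam$config$depth
  if (is.null(seed)) seed <- fam$config$seed
  if (!is.null(enrichment)) {
    if (any(enrichment < 0)) stop("invalid config: multipliers must be >= 0")
    bad <- setdiff(names(enrichment), names(fam$elements))
    if (length(bad)) stop("unknown elements: ", paste(bad, collapse = ", "))
  }
  foot <- element_footprints(fam)
  with_stream_seed(seed, "insertions", {
    lapply(seq_len(n_samples), function(s) {
      out <- lapply(names(fam$paralogs), function(nm) {
        Lp <- nchar(fam$paralogs[[nm]])
        lambda <- rep(depth / Lp, Lp)
        if (nrow(foot)) {
          for (k in which(foot$paralog == nm)) {
            mult <- 1
            if (!is.null(enrichment) && foot$element[k] %in% names(enrichment))
              mult <- enrichment[[foot$element[k]]]
            lambda[foot$start[k]:foot$end[k]] <-
              lambda[foot$start[k]:foot$end[k]] * mult
          }
        }
        counts <- rpois(Lp, lambda)
        rep.int(seq_len(Lp), counts)
      })
      names(out) <- names(fam$paralogs)
      out
    })
  })
}

#' Simulate reads that multimap among paralogs
#'
#' Draws reads as (optionally error-mutated) substrings of randomly chosen
#' paralogs, then scores every read against every paralog with an exhaustive
#' affine-gap fitting alignment, emulating the candidate placements a
#' sensitive aligner reports across a family of near-identical loci. The
#' returned truth table records the generating paralog of each read.
#'
#' @param fam a `paralog_family`.
#' @param n_reads number of reads.
#' @param read_length read length in bp (must not exceed the shortest
#'   paralog).
#' @param error_rate per-base substitution error rate applied to each read.
#' @param scoring list with integer penalties `mismatch`, `gap_open`,
#'   `gap_extend` (gap of length k costs `gap_open + k * gap_extend`).
#' @param seed integer seed (default the family's).
#' @return List with `alignments` (data frame: read_id, region, score,
#'   read_length; one row per read x paralog), `truth` (read_id, origin,
#'   start, n_errors) and `reads` (named character vector of read sequences).
#' @export
simulate_multireads <- function(fam, n_reads, read_length = 100L,
                                error_rate = 0.005,
                                scoring = list(mismatch = 6L, gap_open = 5L,
                                               gap_extend = 3L),
                                seed = NULL) {
  if (is.null(seed)) seed <- fam$config$seed
  lens <- nchar(fam$paralogs)
  if (read_length > min(lens))
    stop("read_length exceeds the shortest paralog")
  with_stream_seed(seed, "multireads", {
    origin <- sample(names(fam$paralogs), n_reads, replace = TRUE)
    start <- vapply(origin, function(nm) {
      sample.int(lens[[nm]] - read_length + 1L, 1L)
    }, integer(1))
    reads <- character(n_reads)
    n_err <- integer(n_reads)
    for (i in seq_len(n_reads)) {
      b <- strsplit(substr(fam$paralogs[[origin[i]]], start[i],
                           start[i] + read_length - 1L), "")[[1]]
      mb <- mutate_bases(b, error_rate)
      n_err[i] <- sum(mb != b)
      reads[i] <- paste(mb, collapse = "")
    }
    ids <- sprintf("read%05d", seq_len(n_reads))
    names(reads) <- ids
    scores <- fit_align_matrix(reads, unname(fam$paralogs),
                               as.integer(scoring$mismatch),
                               as.integer(scoring$gap_open),
                               as.integer(scoring$gap_extend))
    alignments <- data.frame(
      read_id = rep(ids, times = length(lens)),
      region = rep(names(fam$paralogs), each = n_reads),
      score = as.vector(scores),
      read_length = read_length)
    list(alignments = alignments,
         truth = data.frame(read_id = ids, origin = origin, start = start,
                            n_errors = n_err, row.names = NULL),
         reads = reads)
  })
}

#' Simulate a binary cell-by-gene expression matrix with planted odds ratios
#'
#' Generates single-cell detection calls (expressed / not expressed) for a
#' panel of genes. Unplanted genes are independent Bernoulli draws at their
#' marginal probabilities. For each planted pair, the joint distribution is
#' the unique 2x2 table with the requested marginals and odds ratio (the
#' root of the Plackett quadratic inside the Frechet bounds), so downstream
#' odds-ratio estimates can be validated against known truth.
#'
#' @param n_cells number of cells.
#' @param gene_marginals named numeric vector of detection probabilities,
#'   all strictly inside (0, 1).
#' @param planted_pairs optional data frame with columns `x`, `y`,
#'   `odds_ratio` (`> 0`); pairs must not share genes.
#' @param seed integer seed.
#' @return Logical matrix (cells x genes) with attribute `"truth"` holding
#'   the planted joint probabilities.
#' @export
simulate_cell_matrix <- function(n_cells, gene_marginals,
                                 planted_pairs = NULL, seed = 1L) {
  if (any(gene_marginals <= 0) || any(gene_marginals >= 1))
    stop("feasibility error: marginals must lie strictly inside (0, 1)")
  genes <- names(gene_marginals)
  if (is.null(genes) || anyDuplicated(genes))
    stop("gene_marginals must be uniquely named")
  if (!is.null(planted_pairs) && nrow(planted_pairs)) {
    gg <- c(planted_pairs$x, planted_pairs$y)
    if (anyDuplicated(gg)) stop("planted pairs must be disjoint in genes")
    if (!all(gg %in% genes)) stop("planted pair gene not in marginals")
  }
  with_stream_seed(seed, "cells", {
    mat <- matrix(FALSE, n_cells, length(genes),
                  dimnames = list(sprintf("cell%05d", seq_len(n_cells)),
                                  genes))
    planted_genes <- character(0)
    truth <- NULL
    if (!is.null(planted_pairs) && nrow(planted_pairs)) {
      truth <- planted_pairs
      truth$p11 <- NA_real_
      for (k in seq_len(nrow(planted_pairs))) {
        x <- planted_pairs$x[k]; y <- planted_pairs$y[k]
        p11 <- solve_joint_probability(gene_marginals[[x]],
                                       gene_marginals[[y]],
                                       planted_pairs$odds_ratio[k])
        truth$p11[k] <- p11
        px <- gene_marginals[[x]]; py <- gene_marginals[[y]]
        probs <- c(p00 = 1 - px - py + p11, p01 = py - p11,
                   p10 = px - p11, p11 = p11)
        draw <- sample.int(4L, n_cells, replace = TRUE, prob = probs)
        mat[, x] <- draw >= 3L
        mat[, y] <- draw %in% c(2L, 4L)
        planted_genes <- c(planted_genes, x, y)
      }
    }
    for (g in setdiff(genes, planted_genes))
      mat[, g] <- runif(n_cells) < gene_marginals[[g]]
    attr(mat, "truth") <- truth
    mat
  })
}

#' Joint success probability for given marginals and odds ratio
#'
#' Solves for `p11 = P(x+, y+)` such that a 2x2 distribution with marginals
#' `(px, py)` has odds ratio `theta`. The solution is the unique root of the
#' Plackett quadratic inside the Frechet interval
#' `[max(0, px + py - 1), min(px, py)]`.
#'
#' @param px,py marginal probabilities in (0, 1).
#' @param theta target odds ratio, `> 0` and finite.
#' @return `p11` as a numeric scalar.
#' @export
solve_joint_probability <- function(px, py, theta) {
  if (!is.finite(theta) || theta <= 0)
    stop("feasibility error: odds ratio must be finite and > 0")
  if (px <= 0 || px >= 1 || py <= 0 || py >= 1)
    stop("feasibility error: marginals must lie strictly inside (0, 1)")
  if (theta == 1) return(px * py)
  lo <- max(0, px + py - 1)
  hi <- min(px, py)
  # log odds ratio is continuous and strictly increasing in p11 on (lo, hi)
  f <- function(p11) {
    log(p11) + log(1 - px - py + p11) - log(px - p11) - log(py - p11) -
      log(theta)
  }
  eps <- (hi - lo) * 1e-12
  if (f(lo + eps) > 0 || f(hi - eps) < 0)
    stop("feasibility error: no joint distribution attains this odds ratio")
  uniroot(f, c(lo + eps, hi - eps), tol = 1e-14)$root
}

#' Simulate a binned Hi-C style contact matrix
#'
#' Raw counts are Poisson with mean
#' `N * c_i * c_j * max(|i - j|, 1)^(-decay) * h_ij`, where `c` are per-bin
#' coverage biases and `h` is a multiplier field equal to 1 outside planted
#' rectangular hotspots. The matrix is symmetric: the upper triangle is
#' sampled and mirrored.
#'
#' @param n_bins number of bins (`>= 4`).
#' @param bin_size bin width in bp.
#' @param decay_exponent distance-decay exponent (`0` disables decay).
#' @param coverage_biases per-bin positive multipliers (recycled scalar ok).
#' @param hotspots list of `list(rows =, cols =, multiplier =)` entries with
#'   bin-index ranges; rows/cols must lie within the matrix.
#' @param mean_count Poisson mean scale `N`.
#' @param seed integer seed.
#' @return Object of class `"contact_matrix"`: list with `counts` (symmetric
#'   integer matrix), `bin_size`, `hotspots` and `expected` (the mean field,
#'   kept as simulation truth).
#' @export
simulate_contact_matrix <- function(n_bins, bin_size = 5000,
                                    decay_exponent = 1,
                                    coverage_biases = 1,
                                    hotspots = list(),
                                    mean_count = 50, seed = 1L) {
  if (n_bins < 4) stop("n_bins must be >= 4")
  cb <- rep_len(coverage_biases, n_bins)
  if (any(cb <= 0)) stop("coverage biases must be > 0")
  d <- abs(outer(seq_len(n_bins), seq_len(n_bins), "-"))
  hfield <- matrix(1, n_bins, n_bins)
  for (h in hotspots) {
    if (min(h$rows) < 1 || max(h$rows) > n_bins ||
        min(h$cols) < 1 || max(h$cols) > n_bins)
      stop("hotspot rectangle outside matrix")
    hfield[h$rows, h$cols] <- h$multiplier
    hfield[h$cols, h$rows] <- h$multiplier
  }
  mu <- mean_count * outer(cb, cb) * pmax(d, 1)^(-decay_exponent) * hfield
  with_stream_seed(seed, "contacts", {
    counts <- matrix(0, n_bins, n_bins)
    ut <- upper.tri(counts, diag = TRUE)
    counts[ut] <- rpois(sum(ut), mu[ut])
    counts <- counts + t(counts) - diag(diag(counts))
    structure(list(counts = counts, bin_size = bin_size,
                   hotspots = hotspots, expected = mu),
              class = "contact_matrix")
  })
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("Contact matrix:", nrow(x$counts), "bins of", x$bin_size, "bp,",
      length(x$hotspots), "planted hotspot(s)\n")
  invisible(x)
}
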