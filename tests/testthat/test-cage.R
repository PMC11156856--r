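test_that("architecture rules remove on strict boundaries", {
  aln <- data.frame(
    tlen = c(300L, 12000L, 10000L, 500L, 500L, 500L),
    softclip = c(0L, 0L, 0L, 4L, 3L, 0L),
    mismatches = c(0L, 0L, 0L, 0L, 0L, 1L))
  out <- architecture_filter(aln)
  expect_equal(nrow(out$kept), 3L)       # rows 1, 3, 5 survive
  expect_equal(unname(out$removed),
               c(1L, 1L, 1L))
  # 10 kb template and 3 bp soft clip are kept (strict >)
  expect_true(all(out$kept$tlen <= 10000))
  expect_error(architecture_filter(data.frame(tlen = 1, softclip = 0)),
               "mismatch")
})

test_that("rule order does not matter (per-record rules)", {
  set.seed(3)
  aln <- data.frame(tlen = sample(c(500L, 20000L), 50, TRUE),
                    softclip = sample(0:6, 50, TRUE),
                    mismatches = sample(0:2, 50, TRUE))
  full <- architecture_filter(aln)
  # applying rules one at a time in any order gives the same survivors
  s1 <- aln[abs(aln$tlen) <= 10000, ]
  s1 <- s1[s1$mismatches == 0, ]
  s1 <- s1[s1$softclip <= 3, ]
  expect_equal(full$kept, s1, ignore_attr = TRUE)
})

test_that("UMI deduplication respects the record window", {
  aln <- data.frame(position = c(1L, 2L, 3L, 10L),
                    umi = c("AAA", "AAA", "BBB", "AAA"))
  out <- umi_proximity_dedup(aln, window_records = 100L)
  expect_equal(out$position, c(1L, 3L))

  # same UMI but separated by more than the window: both kept
  n <- 30L
  aln2 <- data.frame(position = seq_len(n),
                     umi = c("AAA", rep("X", n - 2L), "AAA"))
  aln2$umi[2:(n - 1L)] <- sprintf("U%03d", 2:(n - 1L))
  out2 <- umi_proximity_dedup(aln2, window_records = 10L)
  expect_equal(nrow(out2), n)

  # all-distinct UMIs unchanged
  aln3 <- data.frame(position = 1:5, umi = letters[1:5])
  expect_equal(umi_proximity_dedup(aln3), aln3)

  expect_error(umi_proximity_dedup(data.frame(position = c(5L, 1L),
                                              umi = c("a", "b"))),
               "sorted")
})

test_that("power-law normalization is monotone and self-consistent", {
  set.seed(8)
  # counts drawn from the reference law itself
  alpha <- 1.2
  u <- runif(30000)
  counts <- floor(u^(-1 / alpha))
  counts <- counts[counts <= 5000]
  norm <- powerlaw_normalize(counts, alpha = alpha, T = 1e6)
  # monotone non-decreasing in the raw count
  o <- order(counts)
  expect_true(all(diff(norm[o]) >= -1e-9))
  # zeros map to zero
  expect_true(all(norm[counts == 0] == 0))
  # self-consistency: the map is close to a simple rescale to total T
  pos <- counts > 0
  ratio <- norm[pos] / (counts[pos] * (1e6 / sum(counts)))
  expect_lt(abs(median(ratio) - 1), 0.35)
  # identical multisets normalize identically
  expect_equal(powerlaw_normalize(rev(counts)), rev(norm))
})

test_that("degenerate count distributions fall back to simple scaling", {
  expect_warning(out <- powerlaw_normalize(c(0, 7, 7, 7), T = 100),
                 "falling back")
  expect_equal(sum(out), 100)
  expect_error(powerlaw_normalize(c(-1, 2)), ">= 0")
})

test_that("distclu merges within maxDist and handles singletons", {
  pos <- data.frame(chrom = "c", pos = c(100L, 130L, 200L),
                    strand = "-")
  vals <- matrix(c(5, 5, 6), ncol = 1)
  cl <- distclu(pos, vals, threshold = 2, max_dist = 50)
  # gap 30 merges, gap 70 splits
  expect_equal(cl$start, c(100L, 200L))
  expect_equal(cl$end, c(130L, 200L))

  # singleton signal 3 removed, 5 kept (strict > 4)
  singl <- data.frame(chrom = "c", pos = 200L, strand = "+")
  expect_equal(nrow(distclu(singl, matrix(3), keep_singletons_above = 4)),
               0L)
  expect_equal(nrow(distclu(singl, matrix(5), keep_singletons_above = 4)),
               1L)
  expect_equal(nrow(distclu(singl, matrix(4), keep_singletons_above = 4)),
               0L)

  # opposite strands never merge
  two <- data.frame(chrom = "c", pos = c(100L, 110L), strand = c("+", "-"))
  cl2 <- distclu(two, matrix(c(9, 9), ncol = 1))
  expect_equal(nrow(cl2), 2L)
})

test_that("distclu output partitions seeds with no near clusters", {
  set.seed(12)
  pos <- data.frame(chrom = "c", pos = sort(sample.int(5000L, 300)),
                    strand = "-")
  vals <- matrix(rexp(300, 1 / 3), ncol = 1)
  cl <- distclu(pos, vals, threshold = 2, max_dist = 50,
                keep_singletons_above = 0)
  # no two same-strand clusters within maxDist of each other
  if (nrow(cl) > 1)
    expect_true(all(cl$start[-1] - cl$end[-nrow(cl)] > 50))
  # member counts add up to the seed count
  expect_equal(sum(cl$n_pos), sum(vals >= 2))
})

test_that("two-step peak calling intersects loose with strict", {
  pos <- data.frame(chrom = "c", pos = c(100L, 120L, 500L), strand = "-")
  vals <- cbind(s1 = c(5, 5, 5), s2 = c(5, 5, 0),
                s3 = c(5, 5, 0), s4 = c(5, 5, 0))
  out <- two_step_peaks(pos, vals)
  # the 500 singleton is loose-only (1 of 4 samples): rejected
  expect_equal(nrow(out), 1L)
  expect_equal(out$start, 100L)
  expect_equal(out$end, 120L)

  # allowlisted region bypasses the strict requirement
  allow <- data.frame(chrom = "c", start = 450L, end = 550L, strand = "-")
  out2 <- two_step_peaks(pos, vals, allowlist = allow)
  expect_equal(nrow(out2), 2L)
  expect_false(out2$strict_supported[out2$start == 500L])
})

test_that("loose boundaries are used for accepted peaks", {
  # strict support only at the core positions; loose extends further
  pos <- data.frame(chrom = "c", pos = c(80L, 100L, 120L), strand = "-")
  vals <- cbind(s1 = c(5, 5, 5), s2 = c(0, 5, 0))
  out <- two_step_peaks(pos, vals)
  expect_equal(out$start, 80L)
  expect_equal(out$end, 120L)
})

test_that("cap-signature filtering is strictly above the threshold", {
  cl <- data.frame(id = 1:3, capped_reads = c(8L, 7L, 0L),
                   total_reads = c(10L, 10L, 10L))
  out <- cap_filter(cl)
  expect_equal(out$id, 1L)      # 0.8 kept; 0.7 and 0.0 removed
  expect_warning(out2 <- cap_filter(data.frame(id = 1, capped_reads = 0L,
                                               total_reads = 0L)),
                 "zero reads")
  expect_equal(nrow(out2), 0L)
})

test_that("promoter correlation matches the t-statistic closed form", {
  set.seed(21)
  n <- 15
  cage <- rexp(n, 1 / 50) + 1
  atac <- cage * exp(rnorm(n, 0, 0.4))
  res <- promoter_signal_correlation(cage, atac)
  r <- res$r
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(res$p, 2 * pt(-abs(tstat), n - 2), tolerance = 1e-10)
  expect_equal(sum(res$table$atac_scaled), 1e5)

  # scaling invariance on the log scale
  res2 <- promoter_signal_correlation(cage, atac * 37)
  expect_equal(res2$r, res$r, tolerance = 1e-12)

  # proportional vectors correlate perfectly
  res3 <- promoter_signal_correlation(cage, cage * 2)
  expect_equal(res3$r, 1, tolerance = 1e-12)

  expect_error(promoter_signal_correlation(c(0, 1, 2), c(1, 2, 3)),
               "pseudocount")
  expect_error(promoter_signal_correlation(1:2, 1:2), "3 peaks")
})
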