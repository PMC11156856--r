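test_that("VC normalization fixes uniform matrices and scales linearly", {
  m <- matrix(3, 6, 6)
  v <- vc_normalize(m)
  expect_equal(v$normalized, m)
  # doubling counts doubles the normalized matrix
  v2 <- vc_normalize(2 * m)
  expect_equal(v2$normalized, 2 * m)
  # zero-coverage bins are masked
  m2 <- m; m2[2, ] <- 0; m2[, 2] <- 0
  v3 <- vc_normalize(m2)
  expect_true(all(is.na(v3$normalized[2, ])))
  expect_true(all(is.na(v3$normalized[, 2])))
  expect_error(vc_normalize(matrix(0, 4, 4)), "all-zero")
})

test_that("VC removes planted coverage biases in expectation", {
  biases <- c(rep(1, 20), rep(3, 10), rep(0.5, 10))
  cm <- simulate_contact_matrix(40, decay_exponent = 0,
                                coverage_biases = biases,
                                mean_count = 200, seed = 71)
  v <- vc_normalize(cm)
  nm <- v$normalized
  hi <- mean(nm[21:30, 1:20])
  lo <- mean(nm[31:40, 1:20])
  expect_lt(abs(hi / lo - 1), 0.1)
})

test_that("hotspot strength means inner and frame values", {
  m <- matrix(1, 8, 8)
  m[3:4, 6:7] <- c(2, 2, 4, 4)
  hs <- hotspot_strength(m, inner = c(3, 4, 6, 7), outer = c(2, 5, 5, 8))
  expect_equal(unname(hs), c(3, 1))
  hs2 <- hotspot_strength(matrix(5, 8, 8), c(3, 4, 6, 7), c(2, 5, 5, 8))
  expect_equal(hs2[["inner"]], hs2[["neighborhood"]])
  expect_error(hotspot_strength(m, c(3, 4, 6, 9), c(2, 5, 5, 8)),
               "outside")
  expect_error(hotspot_strength(m, c(3, 4, 6, 7), c(3, 4, 6, 7)), "empty")
})

test_that("coverage profiles scale to the target and average", {
  pr <- normalize_coverage_profiles(list(c(1, 3), c(2, 2)), target = 4)
  expect_equal(pr$scaled[[1]], c(1, 3))
  expect_equal(pr$scaled[[2]], c(2, 2))
  expect_equal(pr$mean, c(1.5, 2.5))
  one <- normalize_coverage_profiles(list(c(2, 6)), target = 100)
  expect_equal(sum(one$scaled[[1]]), 100)
  expect_equal(one$mean, one$scaled[[1]])
  expect_error(normalize_coverage_profiles(list(c(0, 0))), "zero-sum")
  expect_error(normalize_coverage_profiles(list(1:2, 1:3)), "equal length")
})

test_that("matched backgrounds honour distance and coverage rules", {
  n <- 60
  cand <- all_bin_pairs(n)
  cov <- seq(10, 600, length.out = n)
  bs <- 1000
  fg <- c(10L, 30L)                    # distance 20 kb
  bg <- matched_background(fg, cand, cov, bin_size = bs, k = 10,
                           tolerance = 5000)
  expect_equal(nrow(bg), 10)
  # every selected background satisfies the distance constraint
  expect_true(all(abs((bg$j - bg$i) * bs - 20000) <= 5000))
  # the foreground itself is never selected
  expect_false(any(bg$i == 10 & bg$j == 30))
  # deterministic
  bg2 <- matched_background(fg, cand, cov, bin_size = bs, k = 10,
                            tolerance = 5000)
  expect_identical(bg, bg2)
  # the k nearest in coverage space are selected
  expect_true(all(bg$coverage_dist <= sort(bg$coverage_dist)[10]))
})

test_that("the distance tolerance boundary is inclusive", {
  # bin_size 1 so distances are in bp: fg distance 20000
  cand <- data.frame(i = c(1L, 1L, 2L), j = c(25001L, 25002L, 20002L))
  cov <- rep(1, 30000)
  fg <- c(1L, 20001L)
  # candidate differences: 5000 (eligible, inclusive), 5001 (excluded), 0
  bg <- matched_background(fg, cand, cov, bin_size = 1, k = 2,
                           tolerance = 5000)
  expect_setequal(bg$j, c(25001L, 20002L))
  expect_error(matched_background(fg, cand, cov, bin_size = 1, k = 3,
                                  tolerance = 5000),
               "short by 1")
})

test_that("declared foregrounds are excluded from the candidate universe", {
  cand <- all_bin_pairs(30)
  cov <- rep(1, 30)
  fg <- c(5L, 10L)
  excl <- data.frame(i = c(6L, 7L), j = c(11L, 12L))
  bg <- matched_background(fg, cand, cov, bin_size = 1000, k = 10,
                           tolerance = 5000, exclude = excl)
  expect_false(any(paste(bg$i, bg$j) %in% c("6 11", "7 12", "5 10")))
})

test_that("pair aggregation covers all anchor combinations", {
  cm <- simulate_contact_matrix(80, decay_exponent = 1, mean_count = 50,
                                seed = 72)
  v <- vc_normalize(cm)
  anchors <- seq(10, 65, by = 5)       # 12 anchors
  agg <- aggregate_pair_profiles(anchors, v$normalized, window_bins = 1)
  expect_equal(agg$n_pairs, 66)
  expect_equal(nrow(agg$pairs), 66)
  # 2 anchors: one pair, profile equals that window
  agg2 <- aggregate_pair_profiles(c(20L, 40L), v$normalized,
                                  window_bins = 1)
  expect_equal(agg2$n_pairs, 1)
  expect_equal(agg2$profile, v$normalized[19:21, 39:41])
  # constant matrix gives a constant profile
  agg3 <- aggregate_pair_profiles(c(10L, 30L, 50L), matrix(2, 60, 60), 2)
  expect_true(all(agg3$profile == 2))
  # off-matrix windows are skipped with a warning
  expect_warning(
    agg4 <- aggregate_pair_profiles(c(1L, 20L, 30L), matrix(1, 40, 40), 3),
    "skipped")
  expect_equal(agg4$n_pairs, 1)   # only the (20, 30) window fits
})

test_that("enrichment tests match the Welch closed form", {
  set.seed(73)
  fg <- rnorm(3, 5, 1); bg <- rnorm(3, 1, 2)
  res <- enrichment_test(fg, bg)
  orc <- welch_oracle(fg, bg)
  expect_equal(res$t, orc$t, tolerance = 1e-12)
  expect_equal(res$p, orc$p, tolerance = 1e-12)
  expect_equal(res$df, orc$df, tolerance = 1e-9)

  # identical constant groups: p = 1
  expect_equal(enrichment_test(c(2, 2), c(2, 2))$p, 1)

  # strong separation
  sep <- enrichment_test(rnorm(12, 100, 1), rnorm(120, 0, 1))
  expect_lt(sep$p, 1e-10)

  fam <- enrichment_test_family(list(list(fg = fg, bg = bg),
                                     list(fg = bg, bg = bg)))
  expect_equal(fam$fdr, fdr_adjust(fam$p))
  expect_error(enrichment_test(1, c(1, 2)), ">= 2")
})

test_that("null hotspots are not called enriched above the nominal rate", {
  # calibration: multiplier 1, many replicates, Welch test at 5%
  reject <- 0
  n_rep <- 60
  for (s in seq_len(n_rep)) {
    cm <- simulate_contact_matrix(
      50, decay_exponent = 1, mean_count = 100,
      hotspots = list(list(rows = 10:12, cols = 30:32, multiplier = 1)),
      seed = 7000 + s)
    v <- vc_normalize(cm)
    inner <- as.vector(v$normalized[10:12, 30:32])
    outer <- v$normalized[8:14, 28:34]
    outer[3:5, 3:5] <- NA
    p <- enrichment_test(inner, as.vector(outer[!is.na(outer)]))$p
    if (p < 0.05) reject <- reject + 1
  }
  expect_lte(reject / n_rep, 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep))
})
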