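test_that("column identity counts gaps in the denominator, never modal", {
  m1 <- c(r1 = "A", r2 = "A", r3 = "A", r4 = "C")
  expect_equal(column_identity(m1)$freq, 0.75)
  m2 <- c(r1 = "A", r2 = "A", r3 = "A", r4 = "-")
  expect_equal(column_identity(m2)$freq, 0.75)
  expect_equal(column_identity(m2)$base, "A")
  # 9 A + 1 gap over 10 rows: 0.9 with the gap in the denominator
  m3 <- setNames(c(rep("A", 9), "-"), paste0("r", 1:10))
  expect_equal(column_identity(m3)$freq, 0.9)
  m4 <- c(r1 = "G", r2 = "G")
  expect_equal(column_identity(m4)$freq, 1)
})

test_that("conserved runs respect inclusive length and identity bounds", {
  freq <- c(rep(0.95, 9), 0.5, rep(0.95, 10), 0.5, rep(0.95, 12))
  prof <- data.frame(column = seq_along(freq), base = "A", freq = freq)
  runs <- conserved_runs(prof, min_len = 10, min_frac = 0.9)
  # run of 9 dropped; runs of 10 and 12 reported (>= 10 inclusive)
  expect_equal(runs$length, c(10L, 12L))
  expect_equal(runs$start, c(11L, 22L))
  # identity exactly at the bound passes (>= 0.9)
  prof2 <- data.frame(column = 1:10, base = "A", freq = rep(0.9, 10))
  expect_equal(nrow(conserved_runs(prof2)), 1L)
})

test_that("a fully conserved planted element is recovered exactly", {
  fam <- tiny_family(seed = 41, n = 8, len = 800, sub = 0.15, indel = 0.005)
  el <- strrep("TGTGGTCA", 5)          # 40 bp
  fam <- plant_conserved_element(fam, el, carriers = names(fam$paralogs),
                                 at = 300)
  # divergent guards at both boundaries make the element's edges sharp
  fam <- plant_conserved_element(fam, strrep("ACGTG", 2), character(0),
                                 at = 290, decay = 0.6)
  fam <- plant_conserved_element(fam, strrep("CATGC", 2), character(0),
                                 at = 340, decay = 0.6)
  prof <- column_identity(fam$msa[names(fam$paralogs)])
  runs <- conserved_runs(prof, min_len = 10, min_frac = 0.9)
  cols <- element_columns(fam, "E1")
  hit <- runs[runs$start <= cols[1] & runs$end >= cols[length(cols)], ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$start, cols[1])
  expect_equal(hit$end, cols[length(cols)])
})

test_that("PWM hit p-values are exact: worked dinucleotide example", {
  p <- pwm(matrix(c(1, 0, 0, 0,
                    0, 1, 0, 0), nrow = 4), pseudocount = 1e-12)
  hits <- pwm_scan("GGACGG", p, p_cutoff = 0.07, both_strands = FALSE)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$offset, 3L)
  expect_equal(hits$p, 1 / 16)
})

test_that("PWM p-values match complete enumeration for short motifs", {
  set.seed(42)
  for (w in c(2, 4, 6, 8)) {
    counts <- matrix(rgamma(4 * w, 1), nrow = 4)
    p <- pwm(counts, pseudocount = 0.01)
    seqs <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
    hits <- pwm_scan(seqs, p, p_cutoff = 1.1, both_strands = FALSE)
    expect_equal(nrow(hits), 40 - w + 1)
    for (k in seq_len(nrow(hits))) {
      expect_equal(hits$p[k],
                   pwm_pvalue_bruteforce(p, hits$score[k]),
                   tolerance = 1e-9)
    }
  }
})

test_that("PWM p-values are non-increasing in score; both strands work", {
  set.seed(43)
  p <- pwm(matrix(rgamma(4 * 6, 1), nrow = 4))
  s <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  hits <- pwm_scan(s, p, p_cutoff = 1.1)
  expect_setequal(unique(hits$strand), c("+", "-"))
  o <- order(hits$score)
  expect_true(all(diff(hits$p[o]) <= 1e-12))
  # a planted consensus match on the minus strand is found
  cons <- paste(c("A", "C", "G", "T")[apply(p$probs, 2, which.max)],
                collapse = "")
  planted <- paste0(substr(s, 1, 80), revcomp(cons), substr(s, 87, 200))
  h2 <- pwm_scan(planted, p, p_cutoff = 1.1)
  best_minus <- h2[h2$strand == "-", ][1, ]
  expect_equal(best_minus$offset, 81L)
  # too-short sequences give empty results
  expect_equal(nrow(pwm_scan("ACG", p)), 0L)
})

test_that("window identity counts matches with gaps as mismatches", {
  a <- strrep("ACGTT", 40)             # 200 bp
  res <- window_identity(a, a, window = 100)
  expect_true(all(res$identity == 100))
  expect_equal(res$regions$length, 200L)

  # 20 mismatches in the first window
  b <- paste0(strrep("T", 20), substr(a, 21, 200))
  b <- sub("TTTTTTTTTTTTTTTTTTTT", strrep("G", 20), b)
  res2 <- window_identity(a, b, window = 100)
  first <- unname(res2$identity[1])
  expect_equal(first, 100 * (100 - sum(strsplit(substr(a, 1, 100), "")[[1]] !=
    strsplit(substr(b, 1, 100), "")[[1]])) / 100)

  # exactly 70 matches is not highlighted (strict > 70)
  a3 <- strrep("A", 100)
  b3 <- paste0(strrep("A", 70), strrep("C", 30))
  res3 <- window_identity(a3, b3, window = 100)
  expect_equal(unname(res3$identity), 70)
  expect_equal(nrow(res3$regions), 0L)

  # self-identity is 100% at every window
  set.seed(44)
  s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  expect_true(all(window_identity(s, s)$identity == 100))

  expect_warning(window_identity("ACGT", "ACGT", window = 100), "shorter")
})

test_that("homology search finds planted direct and inverted segments", {
  set.seed(45)
  rnd <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  a <- rnd(1000)
  seg <- substr(a, 401, 520)                       # 120 bp
  seg_mut <- paste(paracre:::mutate_bases(strsplit(seg, "")[[1]], 0.3),
                   collapse = "")                  # ~70-75% identity
  b_dir <- paste0(rnd(150), seg_mut, rnd(250))
  h <- homology_search(a, b_dir, min_len = 100, min_identity = 0.60)
  dir_hit <- h[h$strand == "+", ]
  expect_gte(nrow(dir_hit), 1)
  expect_lt(abs(dir_hit$start_a[1] - 401), 30)
  expect_true(all(dir_hit$identity >= 0.6))

  # inverted copy found only when searching the reverse complement
  b_inv <- paste0(rnd(150), revcomp(seg_mut), rnd(250))
  h_no <- homology_search(a, b_inv, min_len = 100, min_identity = 0.60,
                          search_inverted = FALSE)
  expect_equal(nrow(h_no), 0L)
  h_inv <- homology_search(a, b_inv, min_len = 100, min_identity = 0.60)
  expect_gte(nrow(h_inv[h_inv$strand == "-", ]), 1)
  inv_hit <- h_inv[h_inv$strand == "-", ][1, ]
  expect_lt(abs(inv_hit$start_b - 151), 30)

  # unrelated sequences yield nothing at this stringency
  h_null <- homology_search(rnd(1000), rnd(1000), min_len = 100,
                            min_identity = 0.60)
  expect_equal(nrow(h_null), 0L)
})

test_that("homology search is symmetric up to coordinate exchange", {
  set.seed(46)
  rnd <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  a <- rnd(600)
  seg <- substr(a, 201, 330)
  seg_mut <- paste(paracre:::mutate_bases(strsplit(seg, "")[[1]], 0.25),
                   collapse = "")
  b <- paste0(rnd(100), seg_mut, rnd(100))
  h_ab <- homology_search(a, b, min_len = 100, min_identity = 0.6,
                          search_inverted = FALSE)
  h_ba <- homology_search(b, a, min_len = 100, min_identity = 0.6,
                          search_inverted = FALSE)
  expect_equal(nrow(h_ab), nrow(h_ba))
  if (nrow(h_ab)) {
    expect_equal(h_ab$start_a, h_ba$start_b)
    expect_equal(h_ab$start_b, h_ba$start_a)
  }
})
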