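# Independent oracles used across tests. These deliberately avoid the code
# paths of the implementations they check.

# Two-sided Fisher p by direct enumeration with binomial coefficients
# (no dhyper): sums P(table) over all tables with the observed margins whose
# probability does not exceed the observed table's.
fisher_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  if (n == 0) return(1)
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  # P(table with x = count in cell a) under fixed margins
  xs <- max(0, r1 - c2):min(r1, c1)
  logp <- lchoose(c1, xs) + lchoose(c2, r1 - xs) - lchoose(n, r1)
  p <- exp(logp)
  p_obs <- exp(lchoose(c1, a) + lchoose(c2, b) - lchoose(n, r1))
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# Welch t statistic from the closed form
welch_oracle <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  p <- 2 * pt(-abs(tstat), df)
  list(t = tstat, p = p, df = df)
}

# a small default family used by several tests
tiny_family <- function(seed = 11, n = 4, len = 400, sub = 0.05,
                        indel = 0.005) {
  generate_paralog_family(sim_config(seed = seed, n_paralogs = n,
                                     ancestor_length = len,
                                     substitution_rate = sub,
                                     indel_rate = indel))
}

# brute-force PWM p-value: enumerate all 4^k background k-mers
pwm_pvalue_bruteforce <- function(p, score_log2, granularity = 1e-3) {
  w <- p$width
  kmers <- do.call(expand.grid, rep(list(1:4), w))
  lo <- log2(p$probs / p$background)
  int_sc <- round(lo / granularity)
  scores <- apply(kmers, 1, function(idx)
    sum(int_sc[cbind(idx, seq_len(w))]))
  probs <- apply(kmers, 1, function(idx) prod(p$background[idx]))
  obs <- round(score_log2 / granularity)
  sum(probs[scores >= obs - 0.5])
}
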