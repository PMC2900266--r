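# Independent oracles, kept deliberately naive and separate from the
# package implementation.

# explicit sort-based ranking (average ranks for ties)
oracle_rank <- function(v) {
  ord <- order(v)
  r <- numeric(length(v))
  i <- 1L
  while (i <= length(v)) {
    j <- i
    while (j < length(v) && v[ord[j + 1L]] == v[ord[i]]) j <- j + 1L
    r[ord[i:j]] <- mean(i:j)
    i <- j + 1L
  }
  r
}

# the printed no-tie formula 1 - 6*sum(d^2)/(L^3 - L)
oracle_spearman_formula <- function(x, y) {
  d <- oracle_rank(x) - oracle_rank(y)
  L <- length(x)
  1 - 6 * sum(d^2) / (L^3 - L)
}

# brute-force Pearson chi-square from expected counts off the margins
oracle_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# exhaustive null of the Spearman score for two length-3 vectors with
# distinct values under independent condition permutations
oracle_enumerate_null_L3 <- function(x, y) {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  out <- numeric(0)
  for (p in perms) for (q in perms)
    out <- c(out, oracle_spearman_formula(x[p], y[q]))
  out
}

# truth direction -> the scan direction that detects it: a pair whose x
# leads is detected when y is truncated from the front
scan_direction_for <- function(truth_direction, lag) {
  if (lag == 0L) "none"
  else if (truth_direction == "x_leads") "y_delayed"
  else "x_delayed"
}

# planted (lag, sign) recovery rate of the delay scan over a simulated
# dataset's coupled pairs
recovery_rate <- function(sim, max_delay = sim$config$max_delay) {
  tr <- sim$truth[sim$truth$relationship != "null", ]
  hit <- vapply(seq_len(nrow(tr)), function(k) {
    id <- tr$pair_id[k]
    sc <- scan_delays(sim$mrna[id, ], sim$protein[id, ],
                      max_delay = max_delay, ordered = sim$config$ordered)
    want_sign <- if (tr$sign[k] == "positive") 1 else -1
    sc$best_t == tr$lag[k] && sign(sc$best_gamma) == want_sign
  }, logical(1))
  mean(hit)
}
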