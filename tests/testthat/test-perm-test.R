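test_that("permutation null has the requested size and is reproducible", {
  set.seed(3)
  x <- rnorm(6); y <- rnorm(6)
  pn <- permutation_null(x, y, max_delay = 3, n_perm = 500, seed = 9)
  expect_length(pn$scores, 500)
  expect_true(all(pn$scores >= 0 & pn$scores <= 1))
  pn2 <- permutation_null(x, y, max_delay = 3, n_perm = 500, seed = 9)
  expect_identical(pn$scores, pn2$scores)
})

test_that("t=0 null on 3 distinct values lives on the enumerated support", {
  x <- c(0.3, 1.7, -0.2)
  y <- c(5, 2, 9)
  exact <- oracle_enumerate_null_L3(x, y)          # all 36 pairings
  expect_setequal(round(unique(exact), 10), c(1, 0.5, -0.5, -1))
  pn <- permutation_null(x, y, max_delay = 0, n_perm = 400, seed = 4)
  expect_true(all(round(pn$scores, 10) %in% round(unique(abs(exact)), 10)))
  # empirical frequency of |gamma0| = 1 near the enumerated 1/3
  expect_equal(mean(pn$scores == 1), mean(abs(exact) == 1), tolerance = 0.12)
})

test_that("p-values follow the add-one convention", {
  null3 <- structure(list(scores = c(0.1, 0.2, 0.3), n_perm = 3L),
                     class = "perm_null")
  expect_equal(perm_p_value(0.25, null3), 0.5)     # (1+1)/4
  expect_equal(perm_p_value(-0.25, null3), 0.5)    # two-sided on |gamma|
  expect_equal(perm_p_value(0.99, null3), 1 / 4)
  expect_equal(perm_p_value(0, null3), 1)
  pn <- permutation_null(rnorm(6), rnorm(6), 3, 500, seed = 1)
  expect_gte(perm_p_value(1, pn), 1 / 501)
})

test_that("Bonferroni adjustment is min(1, m p)", {
  expect_equal(bonferroni_adjust(0.01, 7), 0.07)
  expect_equal(bonferroni_adjust(0.3, 7), 1)
  expect_equal(bonferroni_adjust(0.3, 1), 0.3)
  expect_error(bonferroni_adjust(0.1, 0), ">= 1")
})

test_that("adjusted p never falls below raw p and raw p is bounded", {
  set.seed(21)
  for (i in 1:20) {
    tp <- test_pair(rnorm(8), rnorm(8), max_delay = 3, n_perm = 99,
                    seed = i)
    expect_gte(tp$p_raw, 1 / 100)
    expect_lte(tp$p_raw, 1)
    expect_gte(tp$p_adjusted, tp$p_raw)
  }
})

test_that("planted couplings on a 12-point course are detected and classed", {
  # noiseless lag-k pairs: gamma = 1 at the planted shift beats any null
  set.seed(8)
  for (k in 0:3) {
    d <- cumsum(rnorm(12 + k))
    x <- d[(k + 1):(k + 12)]
    y <- d[1:12]                      # y_i = x_{i-k}: x leads
    tp <- test_pair(x, y, max_delay = 3, n_perm = 500, seed = 100 + k)
    expect_true(tp$significant)
    expect_identical(tp$best_t, k)
    expect_identical(tp$class,
                     if (k == 0) "simultaneous" else paste0("delayed_", k))
  }
})

test_that("identical seeds reproduce every p exactly", {
  x <- cumsum(rnorm(10)); y <- cumsum(rnorm(10))
  a <- test_pair(x, y, max_delay = 3, n_perm = 200, seed = 77)
  b <- test_pair(x, y, max_delay = 3, n_perm = 200, seed = 77)
  expect_identical(a$p_raw, b$p_raw)
  expect_identical(a$p_adjusted, b$p_adjusted)
})

test_that("untestable and unordered pairs are handled per contract", {
  tp <- test_pair(rep(1, 6), rnorm(6), seed = 1)
  expect_identical(tp$class, "untestable")
  expect_true(is.na(tp$p_raw))

  # unordered pair with a monotone link can only be simultaneous or none
  set.seed(31)
  x <- rnorm(20); y <- x^3
  tp <- test_pair(x, y, ordered = FALSE, max_delay = 3, n_perm = 200,
                  seed = 2)
  expect_identical(tp$m, 1L)
  expect_true(tp$class %in% c("simultaneous", "none"))
  expect_identical(tp$class, "simultaneous")  # perfect monotone link
})

test_that("type-I error of the max-statistic test stays within bounds", {
  # reduced-size calibration check; the full 1000 x 500 run backs the
  # acceptance suite
  n_pairs <- 300
  rej <- logical(n_pairs)
  for (i in seq_len(n_pairs)) {
    set.seed(5000 + i)
    x <- cumsum(rnorm(6)); y <- cumsum(rnorm(6))
    tp <- test_pair(x, y, max_delay = 3, n_perm = 99, seed = 90000 + i)
    rej[i] <- isTRUE(tp$significant)
  }
  bound <- 0.05 + 3 * sqrt(0.05 * 0.95 / n_pairs)
  expect_lte(mean(rej), bound)
})

test_that("test_pairs assigns per-pair sub-seeds and reports all columns", {
  g <- golden_small_dataset()
  pairs <- data.frame(id_x = rownames(g$mrna), id_y = rownames(g$protein))
  res <- test_pairs(pairs, g$mrna, g$protein, n_perm = 99, seed = 5)
  expect_identical(nrow(res), 10L)
  expect_true(all(c("best_t", "direction", "gamma", "p_raw", "p_adjusted",
                    "significant", "class") %in% names(res)))
  expect_identical(res$class[7], "untestable")   # constant protein row
  res2 <- test_pairs(pairs, g$mrna, g$protein, n_perm = 99, seed = 5)
  expect_identical(res, res2)
  expect_error(test_pairs(data.frame(id_x = "nope", id_y = "g01"),
                          g$mrna, g$protein), "nope")
})
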